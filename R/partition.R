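
new_split_plan <- function(train, test, m, method, seed = NA_integer_) {
  train <- sort(as.integer(train)); test <- sort(as.integer(test))
  if (length(train) == 0L || length(test) == 0L)
    stopf("both train and test sets must be non-empty")
  if (length(intersect(train, test)))
    stopf("train and test sets overlap")
  if (!setequal(c(train, test), seq_len(m)))
    stopf("train and test must partition 1..m")
  structure(list(train = train, test = test, method = method, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan (%s): %d train / %d test\n",
              x$method, length(x$train), length(x$test)))
  invisible(x)
}

#' Random train/test split of compounds
#'
#' Draws a seeded uniform sample without replacement of `round(m *
#' test_fraction)` compound positions as the test set; the standard protocol
#' uses `test_fraction = 1/3` (2/3 train, 1/3 test).
#'
#' @param m number of compounds (>= 3).
#' @param test_fraction fraction of compounds held out, in (0, 1).
#' @param seed integer RNG seed; the same seed always yields the same plan.
#' @return A `split_plan` with sorted integer `train` and `test` position
#'   vectors (1-based, in activity-table row order).
#' @export
random_split <- function(m, test_fraction = 1 / 3, seed) {
  if (m < 3) stopf("need m >= 3 compounds to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must be in (0, 1)")
  n_test <- round(m * test_fraction)
  if (n_test < 1L || n_test >= m)
    stopf("test_fraction %.3f leaves an empty train or test set at m=%d",
          test_fraction, m)
  test <- with_seed(seed, sample.int(m, n_test))
  new_split_plan(setdiff(seq_len(m), test), test, m, "random", as.integer(seed))
}

# z-score matrix columns; zero-variance columns become all-zero so they
# contribute nothing to distances
zscore_cols <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- Inf
  sweep(sweep(M, 2, mu, "-"), 2, ifelse(is.finite(sd), sd, Inf), "/")
}

#' Greedy maximin diversity ranking of compounds
#'
#' Ranks compounds by structural diversity: the first compound of the table is
#' the reference and rank 1; each subsequent rank goes to the compound whose
#' minimum Euclidean distance (on per-feature z-scored descriptors) to all
#' already-ranked compounds is largest, ties broken by lowest row index, until
#' the whole set is ranked.
#'
#' @param y a [descriptor_table()] or numeric matrix (rows = compounds).
#' @return Integer permutation of `1..m`: `ranking[k]` is the row index holding
#'   diversity rank `k`.
#' @export
diversity_ranking <- function(y) {
  M <- if (inherits(y, "descriptor_table")) y$values else as.matrix(y)
  m <- nrow(M)
  if (m < 1) stopf("need at least one compound")
  if (m == 1) return(1L)
  D <- as.matrix(stats::dist(zscore_cols(M)))
  ranking <- integer(m)
  ranking[1] <- 1L
  remaining <- setdiff(seq_len(m), 1L)
  mindist <- D[remaining, 1L]
  for (k in 2:m) {
    pick <- remaining[which.max(mindist)] # which.max takes the first (lowest index) on ties
    ranking[k] <- pick
    keep <- remaining != pick
    remaining <- remaining[keep]
    if (!length(remaining)) break
    mindist <- pmin(mindist[keep], D[remaining, pick])
  }
  ranking
}

#' Diversity-ranked (Diverse Subset) train/test split
#'
#' Deterministic partition from [diversity_ranking()]: by default the training
#' set takes the head of the ranking — the most diverse, representative
#' compounds — and the test set the tail (`test_side = "tail"`); set
#' `test_side = "head"` to flip. Train size is
#' `ceiling((1 - test_fraction) * m)`.
#'
#' @param y a [descriptor_table()].
#' @param test_fraction fraction held out, in (0, 1); default 1/3.
#' @param test_side which end of the diversity ranking becomes the test set.
#' @return A `split_plan` with `method = "diverse_subset"` (no seed).
#' @export
diverse_split <- function(y, test_fraction = 1 / 3, test_side = c("tail", "head")) {
  test_side <- match.arg(test_side)
  m <- nrow(y$values)
  if (m < 3) stopf("need m >= 3 compounds to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must be in (0, 1)")
  # complement of the test count used by random_split, so both protocols
  # produce identical sizes (ceiling((1-f)*m) is unstable in floating point)
  n_train <- m - round(m * test_fraction)
  if (n_train < 1L || n_train >= m)
    stopf("degenerate split sizes at m=%d, test_fraction=%.3f", m, test_fraction)
  ranking <- diversity_ranking(y)
  head_ <- ranking[seq_len(if (test_side == "tail") n_train else m - n_train)]
  if (test_side == "tail") {
    new_split_plan(head_, setdiff(ranking, head_), m, "diverse_subset")
  } else {
    new_split_plan(setdiff(ranking, head_), head_, m, "diverse_subset")
  }
}

#' Write a split plan to CSV
#'
#' Two columns: `compound_id`, `role` (train/test), in activity-table row
#' order.
#'
#' @param plan a `split_plan`.
#' @param compound_ids compound identifiers positionally matching the plan.
#' @param path output CSV path.
#' @export
write_split_csv <- function(plan, compound_ids, path) {
  m <- length(plan$train) + length(plan$test)
  if (length(compound_ids) != m)
    stopf("compound_ids length %d does not match plan size %d",
          length(compound_ids), m)
  role <- character(m)
  role[plan$train] <- "train"
  role[plan$test] <- "test"
  utils::write.csv(data.frame(compound_id = compound_ids, role = role),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a split plan from CSV
#'
#' @param path CSV written by [write_split_csv()].
#' @param compound_ids compound identifiers defining positional order.
#' @return A `split_plan` with `method = "file"`.
#' @export
read_split_csv <- function(path, compound_ids) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  idx <- match(compound_ids, df$compound_id)
  if (anyNA(idx))
    stopf("split file is missing compounds: %s",
          paste(compound_ids[is.na(idx)], collapse = ", "))
  role <- df$role[idx]
  new_split_plan(which(role == "train"), which(role == "test"),
                 length(compound_ids), "file")
}
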