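#' Compound-by-cell-line activity table
#'
#' Container for a nonnegative activity matrix (PKi magnitudes) with an
#' observation mask. Rows are compounds, columns are cell lines; cells with
#' `mask == 0` are unobserved (missing) and carry no value. Matrix completion
#' treats held-out test cells exactly like missing cells.
#'
#' @param values numeric m x n matrix; `NA` entries are taken as unobserved
#'   unless `mask` is supplied. All observed entries must be finite and >= 0.
#' @param compound_ids character vector of m unique compound identifiers
#'   (default: rownames of `values`).
#' @param cellline_ids character vector of n unique cell-line identifiers
#'   (default: colnames of `values`).
#' @param mask optional m x n 0/1 matrix marking observed cells; defaults to
#'   `!is.na(values)`.
#' @return An object of class `activity_table` with fields `values` (NA at
#'   unobserved cells), `mask`, `compound_ids`, `cellline_ids`.
#' @examples
#' x <- activity_table(matrix(c(1, 2, NA, 4), 2, 2),
#'                     compound_ids = c("c1", "c2"),
#'                     cellline_ids = c("t1", "t2"))
#' sum(x$mask) # 3 observed cells
#' @export
activity_table <- function(values, compound_ids = rownames(values),
                           cellline_ids = colnames(values), mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- nrow(values); n <- ncol(values)
  if (is.null(compound_ids)) compound_ids <- paste0("compound_", seq_len(m))
  if (is.null(cellline_ids)) cellline_ids <- paste0("cellline_", seq_len(n))
  compound_ids <- as.character(compound_ids)
  cellline_ids <- as.character(cellline_ids)
  if (length(compound_ids) != m)
    stopf("length(compound_ids) (%d) != nrow(values) (%d)", length(compound_ids), m)
  if (length(cellline_ids) != n)
    stopf("length(cellline_ids) (%d) != ncol(values) (%d)", length(cellline_ids), n)
  if (anyDuplicated(compound_ids))
    stopf("duplicate compound ids: %s",
          paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "))
  if (anyDuplicated(cellline_ids))
    stopf("duplicate cell-line ids: %s",
          paste(unique(cellline_ids[duplicated(cellline_ids)]), collapse = ", "))
  if (is.null(mask)) {
    mask <- matrix(as.numeric(!is.na(values)), m, n)
  } else {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "double"
    if (!identical(dim(mask), dim(values)))
      stopf("mask and values must have identical shape")
    if (!all(mask %in% c(0, 1)))
      stopf("mask entries must be 0 or 1")
    if (any(mask == 1 & is.na(values)))
      stopf("cells marked observed in mask must carry a value")
  }
  values[mask == 0] <- NA_real_
  obs <- values[mask == 1]
  if (any(!is.finite(obs)))
    stopf("observed activity values must be finite")
  if (any(obs < 0)) {
    bad <- which(mask == 1 & values < 0, arr.ind = TRUE)[1, ]
    stopf("negative activity value at compound '%s', cell line '%s' (activities are PKi magnitudes, >= 0)",
          compound_ids[bad[1]], cellline_ids[bad[2]])
  }
  dimnames(values) <- dimnames(mask) <- list(compound_ids, cellline_ids)
  structure(list(values = values, mask = mask,
                 compound_ids = compound_ids, cellline_ids = cellline_ids),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("activity_table: %d compounds x %d cell lines, %d/%d cells observed\n",
              nrow(x$values), ncol(x$values), sum(x$mask), length(x$mask)))
  invisible(x)
}

#' @export
dim.activity_table <- function(x) dim(x$values)

#' Compound-by-descriptor table
#'
#' Container for a complete (no missing entries) descriptor matrix. Each
#' feature carries a kind tag, `"quantitative"` or `"qualitative"`, which
#' controls the dependency measure used by [weight_matrix()].
#'
#' @param values numeric m x r matrix, complete (no `NA`).
#' @param compound_ids character vector of m unique compound identifiers.
#' @param feature_names character vector of r unique feature names.
#' @param kinds per-feature kind, `"quantitative"` (default) or
#'   `"qualitative"`; recycled if length 1.
#' @return An object of class `descriptor_table`.
#' @export
descriptor_table <- function(values, compound_ids = rownames(values),
                             feature_names = colnames(values),
                             kinds = "quantitative") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- nrow(values); r <- ncol(values)
  if (is.null(compound_ids)) compound_ids <- paste0("compound_", seq_len(m))
  if (is.null(feature_names)) feature_names <- paste0("feature_", seq_len(r))
  compound_ids <- as.character(compound_ids)
  feature_names <- as.character(feature_names)
  if (length(compound_ids) != m || length(feature_names) != r)
    stopf("id/name lengths do not match the descriptor matrix shape")
  if (anyDuplicated(compound_ids))
    stopf("duplicate compound ids: %s",
          paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "))
  if (anyDuplicated(feature_names))
    stopf("duplicate feature names: %s",
          paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stopf("descriptor matrix must be complete; missing/non-finite value at compound '%s', feature '%s'",
          compound_ids[bad[1]], feature_names[bad[2]])
  }
  if (length(kinds) == 1L) kinds <- rep(kinds, r)
  if (length(kinds) != r) stopf("kinds must have length 1 or r")
  if (!all(kinds %in% c("quantitative", "qualitative")))
    stopf("feature kinds must be 'quantitative' or 'qualitative'")
  dimnames(values) <- list(compound_ids, feature_names)
  structure(list(values = values, compound_ids = compound_ids,
                 feature_names = feature_names, kinds = kinds),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("descriptor_table: %d compounds x %d features (%d qualitative)\n",
              nrow(x$values), ncol(x$values), sum(x$kinds == "qualitative")))
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

# read a CSV with first column = row ids, remaining columns numeric; cells in
# `missing_tokens` become NA, anything else non-numeric is a parse error
read_id_matrix <- function(path, missing_tokens, what) {
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2L) stopf("%s CSV needs an id column plus data columns: %s", what, path)
  ids <- raw[[1L]]
  cols <- names(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(cols))
  for (j in seq_along(cols)) {
    cell <- trimws(raw[[j + 1L]])
    miss <- cell %in% missing_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stopf("cannot parse %s value '%s' at row '%s', column '%s' in %s",
            what, cell[i], ids[i], cols[j], path)
    }
    vals[!miss, j] <- num[!miss]
  }
  list(ids = ids, cols = cols, values = vals)
}

#' Read an activity table from CSV
#'
#' Expects a header row of cell-line ids and a first column of compound ids.
#' Empty cells and cells equal to one of `missing_tokens` are unobserved.
#'
#' @param path CSV file path.
#' @param missing_tokens strings treated as missing; default empty string and
#'   `"NA"`.
#' @return An [activity_table()].
#' @seealso [write_activity_csv()]
#' @export
read_activity_csv <- function(path, missing_tokens = c("", "NA")) {
  parsed <- read_id_matrix(path, missing_tokens, "activity")
  activity_table(parsed$values, compound_ids = parsed$ids,
                 cellline_ids = parsed$cols)
}

#' Write an activity table to CSV
#'
#' Unobserved cells are written as empty strings, so a write/read round trip
#' reproduces values, ids, and mask exactly.
#'
#' @param x an [activity_table()].
#' @param path output file path.
#' @export
write_activity_csv <- function(x, path) {
  df <- data.frame(compound = x$compound_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a descriptor table from CSV
#'
#' Expects a header row of feature names and a first column of compound ids.
#' The matrix must be complete: any empty/missing cell is an error. An optional
#' two-column sidecar CSV (`feature_name,kind`) assigns feature kinds; features
#' not listed default to `"quantitative"`.
#'
#' @param path CSV file path.
#' @param kinds_path optional sidecar CSV mapping feature name to kind.
#' @return A [descriptor_table()].
#' @export
read_descriptor_csv <- function(path, kinds_path = NULL) {
  parsed <- read_id_matrix(path, c("", "NA"), "descriptor")
  if (anyNA(parsed$values)) {
    bad <- which(is.na(parsed$values), arr.ind = TRUE)[1, ]
    stopf("descriptor matrix must be complete; empty cell at row '%s', column '%s' in %s",
          parsed$ids[bad[1]], parsed$cols[bad[2]], path)
  }
  kinds <- rep("quantitative", length(parsed$cols))
  if (!is.null(kinds_path)) {
    side <- utils::read.csv(kinds_path, header = TRUE, check.names = FALSE,
                            colClasses = "character")
    if (ncol(side) < 2L) stopf("kind sidecar needs two columns: feature_name,kind")
    idx <- match(side[[1L]], parsed$cols)
    if (anyNA(idx))
      stopf("kind sidecar names unknown features: %s",
            paste(side[[1L]][is.na(idx)], collapse = ", "))
    kinds[idx] <- side[[2L]]
  }
  descriptor_table(parsed$values, compound_ids = parsed$ids,
                   feature_names = parsed$cols, kinds = kinds)
}

#' Write a descriptor table to CSV
#'
#' @param y a [descriptor_table()].
#' @param path output file path.
#' @param kinds_path optional path for the feature-kind sidecar CSV.
#' @export
write_descriptor_csv <- function(y, path, kinds_path = NULL) {
  df <- data.frame(compound = y$compound_ids, y$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(kinds_path)) {
    utils::write.csv(data.frame(feature_name = y$feature_names, kind = y$kinds),
                     kinds_path, row.names = FALSE)
  }
  invisible(path)
}

#' PKi magnitude from IC50 (Cheng-Prusoff conversion)
#'
#' Converts a half-maximal inhibitory concentration to the magnitude of the
#' log-transformed inhibition constant,
#' \deqn{|PK_i| = \left| -\log_{10}\frac{IC_{50}}{1 + [L]/K_D} \right|,}
#' where `[L]` is the free radioligand concentration and `K_D` its
#' dissociation constant. The absolute value keeps the activity matrix
#' nonnegative, as the factorization requires. All quantities are treated as
#' dimensionless magnitudes (IC50 and K_D in the same concentration units).
#'
#' @param ic50 positive IC50 value(s).
#' @param ligand_conc nonnegative radioligand concentration (default 0, in
#'   which case PKi = -log10(IC50)).
#' @param kd positive dissociation constant (default 1).
#' @return Nonnegative PKi magnitude(s).
#' @examples
#' pki_magnitude(1e-6)            # 6
#' pki_magnitude(1e-6, 1, 1)      # |-log10(5e-7)| = 6.3010...
#' @export
pki_magnitude <- function(ic50, ligand_conc = 0, kd = 1) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stopf("ic50 must be positive and finite")
  if (any(!is.finite(kd)) || any(kd <= 0))
    stopf("kd must be positive and finite")
  if (any(!is.finite(ligand_conc)) || any(ligand_conc < 0))
    stopf("ligand_conc must be nonnegative and finite")
  abs(-log10(ic50 / (1 + ligand_conc / kd)))
}

#' Align a descriptor table to an activity table's compound order
#'
#' Both tables must describe the same compound set; the descriptor rows are
#' reordered to match the activity table's row order, which is authoritative
#' for all downstream positional indexing.
#'
#' @param x an [activity_table()].
#' @param y a [descriptor_table()].
#' @return `list(activity = x, descriptors = y_reordered)`.
#' @export
align_tables <- function(x, y) {
  stopifnot(inherits(x, "activity_table"), inherits(y, "descriptor_table"))
  only_x <- setdiff(x$compound_ids, y$compound_ids)
  only_y <- setdiff(y$compound_ids, x$compound_ids)
  if (length(only_x) || length(only_y))
    stopf("compound id sets differ; only in activity table: {%s}; only in descriptor table: {%s}",
          paste(only_x, collapse = ", "), paste(only_y, collapse = ", "))
  idx <- match(x$compound_ids, y$compound_ids)
  y2 <- descriptor_table(y$values[idx, , drop = FALSE],
                         compound_ids = y$compound_ids[idx],
                         feature_names = y$feature_names, kinds = y$kinds)
  list(activity = x, descriptors = y2)
}

# TRUE when the two tables are already row-aligned
is_aligned <- function(x, y) identical(x$compound_ids, y$compound_ids)
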