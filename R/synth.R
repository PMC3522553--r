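#' Simulate a low-rank activity/descriptor pair with known ground truth
#'
#' Draws nonnegative factor matrices `U* (m x d)`, `V* (n x d)`, `W* (r x d)`
#' as absolute values of standard normal deviates, builds
#' `X = U* V*' + noise` (clipped at 0 to keep activities nonnegative) and
#' `Y = U* W*' + noise`, and masks a per-column fraction of activity cells
#' uniformly at random. Pure function of its arguments: the same seed always
#' reproduces the same tables.
#'
#' @param m,n,r,d dimensions; `d <= min(m, n, r)`.
#' @param noise_sd_x,noise_sd_y Gaussian noise standard deviations (default 0).
#' @param missing_fraction scalar or length-n vector of per-column missing
#'   fractions in \[0, 1); each column must keep at least 2 observed cells.
#' @param seed integer RNG seed.
#' @return `list(activity, descriptors, truth)` where `truth` carries the
#'   generating factors, the complete noise-free and noisy `X`, and the
#'   held-out cell indices per column.
#' @export
simulate_lowrank <- function(m, n, r, d, noise_sd_x = 0, noise_sd_y = 0,
                             missing_fraction = 0, seed) {
  if (d > min(m, n, r)) stopf("d must satisfy d <= min(m, n, r)")
  if (length(missing_fraction) == 1L) missing_fraction <- rep(missing_fraction, n)
  if (length(missing_fraction) != n)
    stopf("missing_fraction must be scalar or length n")
  if (any(missing_fraction < 0 | missing_fraction >= 1))
    stopf("missing fractions must be in [0, 1)")
  n_miss <- round(missing_fraction * m)
  if (any(m - n_miss < 2L))
    stopf("missing fraction leaves fewer than 2 observed cells in a column")
  with_seed(seed, {
    U <- abs(matrix(stats::rnorm(m * d), m, d))
    V <- abs(matrix(stats::rnorm(n * d), n, d))
    W <- abs(matrix(stats::rnorm(r * d), r, d))
    X_clean <- U %*% t(V)
    X_full <- X_clean + matrix(stats::rnorm(m * n, sd = noise_sd_x), m, n)
    X_full[X_full < 0] <- 0
    Y <- U %*% t(W) + matrix(stats::rnorm(m * r, sd = noise_sd_y), m, r)
    mask <- matrix(1, m, n)
    held <- vector("list", n)
    for (j in seq_len(n)) {
      if (n_miss[j] > 0L) {
        held[[j]] <- sort(sample.int(m, n_miss[j]))
        mask[held[[j]], j] <- 0
      } else held[[j]] <- integer(0)
    }
    values <- X_full
    values[mask == 0] <- NA_real_
    list(activity = activity_table(values, mask = mask),
         descriptors = descriptor_table(Y),
         truth = list(U = U, V = V, W = W, X_clean = X_clean, X_full = X_full,
                      held_out = held, noise_sd_x = noise_sd_x,
                      noise_sd_y = noise_sd_y, seed = seed))
  })
}

#' Simulate a drug-like-index shaped benchmark fixture
#'
#' Emulates the shape of a multi-cell-line inhibitor panel: 93 compounds
#' assayed against the four cell lines BxPC-3, NCI-H446, SW1990 and NCI-H157,
#' described by 28 integer count features with Poisson-like marginals.
#' Feature column 18 is identically zero — the analogue of a structural count
#' absent from every compound in the panel. Activities are a nonnegative
#' linear function of 5 designated signal features plus seeded Gaussian noise
#' (clipped at 0), on a PKi-like scale; the mask is full (no missing cells).
#'
#' @param seed integer RNG seed.
#' @param noise_sd activity noise standard deviation (default 0.3, small
#'   against the roughly 4-9 activity range).
#' @return `list(activity, descriptors, truth)`; `truth` records the signal
#'   feature indices, their coefficients, and the per-cell-line scales, so
#'   tests can assert planted-signal recovery.
#' @export
simulate_dli_fixture <- function(seed, noise_sd = 0.3) {
  m <- 93L; n <- 4L; r <- 28L
  zero_feature <- 18L
  celllines <- c("BxPC-3", "NCI-H446", "SW1990", "NCI-H157")
  with_seed(seed, {
    lam <- stats::rgamma(r, shape = 2, rate = 0.5) # Poisson means ~ mean 4
    Y <- vapply(seq_len(r), function(j) stats::rpois(m, lam[j]), numeric(m))
    Y[, zero_feature] <- 0
    signal_features <- sample(setdiff(seq_len(r), zero_feature), 5L)
    beta <- stats::runif(5L, 0.2, 1)
    raw <- drop(Y[, signal_features, drop = FALSE] %*% beta)
    raw_std <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else raw
    scales <- stats::runif(n, 0.6, 1.2)
    X <- vapply(seq_len(n), function(j) {
      a <- 6 + scales[j] * raw_std + stats::rnorm(m, sd = noise_sd)
      pmax(a, 0)
    }, numeric(m))
    compound_ids <- sprintf("cpd%02d", seq_len(m))
    list(activity = activity_table(X, compound_ids = compound_ids,
                                   cellline_ids = celllines),
         descriptors = descriptor_table(Y, compound_ids = compound_ids,
                                        feature_names = sprintf("DLI%d", seq_len(r))),
         truth = list(signal_features = signal_features, beta = beta,
                      zero_feature = zero_feature, scales = scales,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate multi-cell-line data with a tunable shared latent signal
#'
#' Builds activity columns that interpolate between independent
#' (`cross_column_signal = 0`) and identical-up-to-positive-scaling
#' (`cross_column_signal = 1`) latent structure: each compound carries a
#' shared score `z_i` derived from its latent factors, each column blends it
#' with an independent per-column component, and per-column positive scales
#' are applied. Descriptors reflect the latent factors but carry substantial
#' noise by default, so that in the high-signal regime the other columns —
#' not the descriptors — are the informative source for a held-out column.
#' This is the test bed for the collaborative gain of joint factorization
#' over per-column regression.
#'
#' @param m,n number of compounds and cell lines.
#' @param d latent dimension of the compound factors.
#' @param cross_column_signal blend weight in \[0, 1\].
#' @param r number of descriptor features (default 8).
#' @param noise_sd_x activity noise sd (default 0.1).
#' @param noise_sd_y descriptor noise sd (default 1).
#' @param seed integer RNG seed.
#' @return `list(activity, descriptors, truth)`; `truth` holds the factors,
#'   shared scores, per-column scales and the complete noisy matrix.
#' @export
simulate_shared_latent <- function(m, n, d = 2, cross_column_signal, r = 8,
                                   noise_sd_x = 0.1, noise_sd_y = 1, seed) {
  if (cross_column_signal < 0 || cross_column_signal > 1)
    stopf("cross_column_signal must be in [0, 1]")
  s <- cross_column_signal
  with_seed(seed, {
    U <- abs(matrix(stats::rnorm(m * d), m, d))
    g <- stats::runif(d, 0.5, 1.5)
    z <- drop(U %*% g) / sum(g)             # shared compound score, |N|-scale
    E <- abs(matrix(stats::rnorm(m * n), m, n)) # independent per-column part
    a <- stats::runif(n, 0.5, 2)            # per-column positive scales
    signal <- s * matrix(z, m, n) + (1 - s) * E
    X <- sweep(signal, 2, a, "*") +
      matrix(stats::rnorm(m * n, sd = noise_sd_x), m, n)
    X[X < 0] <- 0
    W <- abs(matrix(stats::rnorm(r * d), r, d))
    Y <- U %*% t(W) + matrix(stats::rnorm(m * r, sd = noise_sd_y), m, r)
    list(activity = activity_table(X),
         descriptors = descriptor_table(Y),
         truth = list(U = U, W = W, z = z, E = E, scales = a, X_full = X,
                      cross_column_signal = s, seed = seed))
  })
}
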