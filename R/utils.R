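
# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `expr` under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("seed must be a single finite number")
  withr::with_seed(as.integer(seed), expr)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix", name)
  invisible(x)
}

fnorm2 <- function(m) sum(m * m)

# observed activity values with unobserved cells replaced by `fill`
observed_values <- function(x, fill = 0) {
  v <- x$values
  v[x$mask == 0] <- fill
  v
}
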