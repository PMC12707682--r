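#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_matrix <- function(x, nrow = NULL, ncol = NULL, name = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stopf("`%s` must be a numeric matrix", name)
  if (!is.null(nrow) && nrow(x) != nrow) {
    stopf("`%s` must have %d rows (got %d)", name, nrow, nrow(x))
  }
  if (!is.null(ncol) && ncol(x) != ncol) {
    stopf("`%s` must have %d columns (got %d)", name, ncol, ncol(x))
  }
  invisible(x)
}

# Draw from a normal(mean, sd) truncated to [lo, hi] by inverse-CDF sampling.
# `mean` and `sd` may be vectors (recycled to length n); sd = 0 collapses to
# the clipped mean.
rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 1) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- clip01(mean)
  pos <- sd > 0
  if (any(pos)) {
    plo <- stats::pnorm(lo, mean[pos], sd[pos])
    phi <- stats::pnorm(hi, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), plo, phi)
    out[pos] <- stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12),
                             mean[pos], sd[pos])
  }
  out
}
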