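# Internal helpers shared across modules.

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed is expanded into per-stage seeds so that a stage can
#' be re-run in isolation and reproduce its output. The scheme is a fixed
#' integer hash of the stage name folded into the global seed, kept below
#' 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1103L + h * 12289) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# REML fit of the one-way random-intercept model y_ij = mu + b_i + e_ij,
# b ~ N(0, sB2), e ~ N(0, sW2), profiled over the variance ratio
# rho = sB2/sW2.  Used where thousands of fits are needed (permutation and
# multivariate-normal nulls); agreement with nlme::lme is asserted in the
# test suite.  Returns the two variance components.
#
# Profiled REML: with group sizes n_i, group means ybar_i, within-group sum
# of squares SSW, and w_i = n_i/(1 + n_i*rho):
#   mu_hat   = sum(w_i * ybar_i) / sum(w_i)
#   Q(rho)   = SSW + sum(w_i * (ybar_i - mu_hat)^2)
#   sW2_hat  = Q / (N - 1)
#   -2 REML  = (N-1) * log(sW2_hat) + sum(log(1 + n_i*rho)) + log(sum(w_i))
#              + const
.reml_random_intercept <- function(y, group) {
  group <- as.factor(group)
  n_i <- tabulate(group)
  keep <- n_i > 0L
  n_i <- n_i[keep]
  N <- length(y)
  r <- length(n_i)
  .assert(r >= 2L, "need at least two groups")
  ybar <- as.numeric(tapply(y, group, mean))[keep]
  ssw <- sum((y - ybar[as.integer(group)])^2)

  neg2reml <- function(lrho) {
    rho <- exp(lrho)
    w <- n_i / (1 + n_i * rho)
    mu <- sum(w * ybar) / sum(w)
    q <- ssw + sum(w * (ybar - mu)^2)
    s2 <- q / (N - 1)
    if (s2 <= 0) return(Inf)
    (N - 1) * log(s2) + sum(log1p(n_i * rho)) + log(sum(w))
  }

  # Bracket on a coarse grid, then refine; rho spans essentially 0..inf.
  grid <- seq(-14, 14, length.out = 57)
  vals <- vapply(grid, neg2reml, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(neg2reml, c(lo, hi))
  rho <- exp(opt$minimum)
  w <- n_i / (1 + n_i * rho)
  mu <- sum(w * ybar) / sum(w)
  s2 <- (ssw + sum(w * (ybar - mu)^2)) / (N - 1)
  # Collapse the boundary: ratios at the grid edge are numerically 0 / +inf.
  if (opt$minimum <= -13.9) rho <- 0
  list(var_between = rho * s2, var_within = s2, mu = mu)
}

# Lower Cholesky factor of a covariance matrix, with a small diagonal jitter
# escalation when the matrix is numerically semi-definite.
.safe_chol <- function(V, max_tries = 6L) {
  jit <- 0
  for (k in seq_len(max_tries)) {
    L <- tryCatch(t(chol(V + diag(jit, nrow(V)))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- if (jit == 0) 1e-8 else jit * 100
  }
  stop("covariance matrix is not positive definite after jitter", call. = FALSE)
}

# Empirical percentile (0..100) of `x` attained by value `q`:
# the fraction of values <= q.
.percentile_of <- function(q, x) 100 * mean(x <= q)
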