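# Qst estimation and its neutral references: label permutation, a
# multivariate-normal null parameterized by kinship, and the comparison to
# the genome-wide SNP Fst distribution.

#' Estimate Qst from genotypic means
#'
#' REML fit of `mean ~ 1` with a random region intercept on the per-genotype
#' means: `varB` is the region intercept variance (between regions), `varW`
#' the residual variance (among genotypes within regions), and
#' `Qst = varB / (varB + varW)`. Since replicates derive from selfed
#' progeny, both are broad-sense genetic components. The default engine is
#' `nlme::lme`; `"internal"` uses an equivalent profiled REML (used by the
#' resampling nulls; agreement is asserted in the test suite).
#'
#' @param means Data frame with `genotype_id` and `mean` (one row per
#'   genotype), e.g. from [genotypic_means()].
#' @param regions Per-genotype region labels (named vector, or data frame
#'   with `genotype_id` and `region`).
#' @param engine `"lme"` or `"internal"`.
#' @return List of class `qst_result`: `qst`, `var_between`, `var_within`,
#'   `n_regions`, `n_genotypes`.
#' @export
estimate_qst <- function(means, regions, engine = c("lme", "internal")) {
  engine <- match.arg(engine)
  if (is.data.frame(regions))
    regions <- stats::setNames(regions$region, regions$genotype_id)
  d <- data.frame(y = means$mean,
                  region = as.character(regions[means$genotype_id]))
  d <- d[!is.na(d$region) & is.finite(d$y), ]
  cnt <- table(d$region)
  .assert(length(cnt) >= 2 && all(cnt >= 3),
          "need >=2 regions with >=3 genotypes each")
  .assert(stats::var(d$y) > 0, "no variance in genotypic means")
  if (engine == "lme") {
    fit <- nlme::lme(y ~ 1, random = ~ 1 | region, data = d,
                     method = "REML")
    vc <- nlme::VarCorr(fit)
    vb <- as.numeric(vc["(Intercept)", "Variance"])
    vw <- as.numeric(vc["Residual", "Variance"])
  } else {
    cmp <- .reml_random_intercept(d$y, d$region)
    vb <- cmp$var_between; vw <- cmp$var_within
  }
  .assert(vb + vw > 0, "total genetic variance is zero")
  structure(list(qst = vb / (vb + vw), var_between = vb, var_within = vw,
                 n_regions = length(cnt), n_genotypes = nrow(d)),
            class = "qst_result")
}

#' @export
print.qst_result <- function(x, ...) {
  cat(sprintf("Qst = %.3f (varB = %.4g, varW = %.4g; %d regions, %d genotypes)\n",
              x$qst, x$var_between, x$var_within, x$n_regions,
              x$n_genotypes))
  invisible(x)
}

#' Permutation test for Qst exceeding the Fst reference
#'
#' Region labels are permuted across genotypes `n_perm` times; the test
#' statistic is `qst - fst95` (the observed Qst minus the 95th percentile of
#' the SNP Fst distribution), and
#' `p = (1 + #permuted statistic >= observed) / (n_perm + 1)`.
#'
#' @param means,regions As in [estimate_qst()].
#' @param fst95 95th percentile of the genome-wide per-SNP Fst distribution.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List: `p_perm`, `observed` (qst - fst95), `qst`, `perm_stats`.
#' @export
qst_permutation <- function(means, regions, fst95, n_perm = 1000,
                            seed = 1L) {
  .assert(n_perm > 0, "n_perm must be positive")
  if (is.data.frame(regions))
    regions <- stats::setNames(regions$region, regions$genotype_id)
  obs <- estimate_qst(means, regions, engine = "internal")
  lab <- as.character(regions[means$genotype_id])
  keep <- !is.na(lab) & is.finite(means$mean)
  y <- means$mean[keep]; lab <- lab[keep]
  set.seed(stage_seed(seed, "qst_perm"))
  stat <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    cmp <- .reml_random_intercept(y, sample(lab))
    stat[b] <- cmp$var_between / (cmp$var_between + cmp$var_within) - fst95
  }
  observed <- obs$qst - fst95
  list(p_perm = (1 + sum(stat >= observed)) / (n_perm + 1),
       observed = observed, qst = obs$qst, perm_stats = stat)
}

#' Multivariate-normal neutral null for Qst
#'
#' Simulates neutral genotypic values as draws from `MVN(0, Vg K)` using
#' the kinship matrix, recomputes Qst for each draw, and locates an
#' observed Qst in that null distribution. This predicts the amount of
#' phenotypic divergence expected from relatedness alone.
#'
#' @param K Kinship matrix over genotypes (dimnames = genotype ids).
#' @param regions Per-genotype region labels (named vector or data frame).
#' @param Vg Genetic variance used to scale the draws (e.g. the total
#'   variance of the observed genotypic means).
#' @param n_sims Number of draws (default 10000).
#' @param observed_qst Optional observed Qst to locate in the null.
#' @param seed Integer seed.
#' @return List: `null_qst` (vector), `percentiles` (90/95/99),
#'   `p` (fraction of simulated qst >= observed; NA if not supplied).
#' @export
qst_mvn_null <- function(K, regions, Vg = 1, n_sims = 10000,
                         observed_qst = NULL, seed = 1L) {
  .assert(n_sims > 0, "n_sims must be positive")
  if (is.data.frame(regions))
    regions <- stats::setNames(regions$region, regions$genotype_id)
  ids <- rownames(K) %||% names(regions)
  lab <- as.character(regions[ids])
  keep <- !is.na(lab)
  .assert(sum(keep) >= 6, "too few genotypes with region labels")
  K <- K[keep, keep, drop = FALSE]; lab <- lab[keep]
  L <- .safe_chol(Vg * K)
  set.seed(stage_seed(seed, "qst_mvn"))
  n <- nrow(K)
  null_qst <- numeric(n_sims)
  for (b in seq_len(n_sims)) {
    yv <- drop(L %*% stats::rnorm(n))
    cmp <- .reml_random_intercept(yv, lab)
    null_qst[b] <- cmp$var_between / (cmp$var_between + cmp$var_within)
  }
  list(null_qst = null_qst,
       percentiles = stats::quantile(null_qst, c(0.9, 0.95, 0.99)),
       p = if (is.null(observed_qst)) NA_real_
           else mean(null_qst >= observed_qst))
}

#' Percentile of the Fst distribution attained by a Qst value
#'
#' @param qst Scalar Qst.
#' @param fst Genome-wide per-SNP Fst values (vector or the data frame from
#'   [per_snp_fst()]).
#' @return List: `percentile` (0-100, the fraction of SNP Fst values
#'   `<= qst`), `exceeds_95` flag, `fst95`.
#' @export
qst_vs_fst <- function(qst, fst) {
  if (is.data.frame(fst)) fst <- fst$fst
  fst <- fst[!is.na(fst)]
  .assert(length(fst) > 0, "empty Fst distribution")
  pct <- .percentile_of(qst, fst)
  list(percentile = pct, exceeds_95 = pct >= 95,
       fst95 = stats::quantile(fst, 0.95, names = FALSE))
}
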