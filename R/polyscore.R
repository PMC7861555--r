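# LD clumping, polygenic scores, validation schemes and the Qx
# over-dispersion test of polygenic adaptation.

#' Greedy LD clumping of association results
#'
#' plink-style clumping: index SNPs are chosen by ascending p-value among
#' markers with `p < p_index`; every unassigned marker with
#' `p < p_secondary`, within `window/2` of the index on the same chromosome
#' and with squared Pearson genotype correlation `>= r2` joins the index's
#' clump. The SNP with the lowest p-value in a clump (the index) is retained
#' for downstream analyses. Ties on p are broken by position, then marker
#' id, so the result does not depend on input order.
#'
#' @param assoc Association table from [mixed_gwas()].
#' @param G The [geno_matrix] the associations were computed on.
#' @param p_index Index-SNP threshold (default 1e-4).
#' @param window Physical clump window in bp (default 1 Mb; members lie
#'   within `window/2` of the index).
#' @param p_secondary Secondary threshold for clump members (default 0.01).
#' @param r2 LD threshold, squared pairwise-complete Pearson correlation of
#'   genotype codes (default 0.5).
#' @return List of class `clump_set`: `index` (data frame of retained SNPs
#'   with `marker`, `chrom`, `pos`, `p`, `effect`, `maf`, `n_clumped`) and
#'   `clumps` (named list of member marker ids).
#' @export
ld_clump <- function(assoc, G, p_index = 1e-4, window = 1e6,
                     p_secondary = 0.01, r2 = 0.5) {
  a <- assoc[!is.na(assoc$p), ]
  a <- a[order(a$p, a$chrom, a$pos, a$marker), ]
  cand <- a[a$p < p_index, ]
  empty <- structure(list(index = a[0, c("marker", "chrom", "pos", "p",
                                         "effect", "maf")],
                          clumps = list()), class = "clump_set")
  if (nrow(cand) == 0) return(empty)
  sec <- a[a$p < p_secondary, ]
  assigned <- character(0)
  idx_rows <- list(); clumps <- list()
  for (i in seq_len(nrow(cand))) {
    id <- cand$marker[i]
    if (id %in% assigned) next
    near <- sec[sec$chrom == cand$chrom[i] &
                  abs(sec$pos - cand$pos[i]) <= window / 2 &
                  !(sec$marker %in% assigned) & sec$marker != id, ]
    members <- character(0)
    if (nrow(near) > 0) {
      g0 <- G$codes[, id]
      r2v <- suppressWarnings(
        stats::cor(g0, G$codes[, near$marker, drop = FALSE],
                   use = "pairwise.complete.obs"))^2
      members <- near$marker[!is.na(r2v) & r2v >= r2]
    }
    assigned <- c(assigned, id, members)
    idx_rows[[length(idx_rows) + 1L]] <- cand[i, ]
    clumps[[id]] <- members
  }
  index <- do.call(rbind, idx_rows)[, c("marker", "chrom", "pos", "p",
                                        "effect", "maf")]
  rownames(index) <- NULL
  structure(list(index = index, clumps = clumps), class = "clump_set")
}

#' @export
print.clump_set <- function(x, ...) {
  cat(sprintf("clump_set: %d index SNP(s), %d clumped member(s)\n",
              nrow(x$index), sum(lengths(x$clumps))))
  invisible(x)
}

#' Per-unit allele frequencies
#'
#' Frequencies of the coded allele per unit (a region, or each genotype as
#' its own population) computed as the mean of `code/2` over non-missing
#' calls.
#'
#' @param G A [geno_matrix].
#' @param units Per-line unit labels; defaults to one unit per line.
#' @param markers Optional marker ids to restrict to.
#' @return Units x markers matrix of frequencies in \[0, 1\].
#' @export
unit_freqs <- function(G, units = NULL, markers = NULL) {
  units <- units %||% G$lines
  codes <- G$codes
  if (!is.null(markers)) codes <- codes[, markers, drop = FALSE]
  f <- rowsum(codes / 2, units, na.rm = TRUE) /
    rowsum((!is.na(codes)) + 0, units)
  f
}

#' Polygenic scores from allele frequencies and effect sizes
#'
#' `Z = 2 * sum_l alpha_l p_l` per unit; for a single selfing genotype
#' `p_l = code/2` is 0, 1/2 or 1.
#'
#' @param freqs Units x markers matrix of allele frequencies (effects must
#'   be aligned to the same allele).
#' @param effects Per-marker effect sizes.
#' @return Data frame: `unit`, `score`; effects and marker ids kept as
#'   attributes.
#' @export
polygenic_score <- function(freqs, effects) {
  freqs <- as.matrix(freqs)
  .assert(ncol(freqs) == length(effects), "one effect per marker")
  .assert(all(is.na(freqs) | (freqs >= 0 & freqs <= 1)),
          "frequencies must lie in [0, 1]")
  z <- 2 * drop(freqs %*% effects)
  out <- data.frame(unit = rownames(freqs) %||% seq_len(nrow(freqs)),
                    score = z)
  attr(out, "effects") <- effects
  attr(out, "markers") <- colnames(freqs)
  out
}

#' Drift covariance among units from genome-wide frequencies
#'
#' Estimates the neutral among-unit covariance `F` from standardized
#' genome-wide allele frequencies: with `eps_l` the across-unit mean
#' frequency of marker l,
#' `F = (1/2m) * sum_l d_l d_l'` where `d_ml = (p_ml - eps_l) /
#' sqrt(eps_l (1 - eps_l))`. The factor 1/2 puts F on the scale at which
#' `Cov(Z) = 2 V_A F` for polygenic scores (the neutral null used by the Qx
#' test). Monomorphic markers are excluded.
#'
#' @param G A [geno_matrix].
#' @param units Per-line unit labels (default: each line its own unit).
#' @param markers Optional marker subset to estimate from.
#' @return Units x units covariance matrix.
#' @export
drift_covariance <- function(G, units = NULL, markers = NULL) {
  f <- unit_freqs(G, units, markers)
  eps <- colMeans(f, na.rm = TRUE)
  keep <- eps > 0 & eps < 1 & !is.na(eps)
  f <- f[, keep, drop = FALSE]; eps <- eps[keep]
  d <- sweep(f, 2, eps) / rep(sqrt(eps * (1 - eps)), each = nrow(f))
  d[is.na(d)] <- 0
  tcrossprod(d) / (2 * ncol(d))
}

#' Qx over-dispersion test for polygenic scores
#'
#' Tests whether polygenic scores are more differentiated among units than
#' expected under neutral drift. Scores are mean-centered across units; the
#' additive variance is `V_A = 4 sum_l alpha_l^2 eps_l (1 - eps_l)` with
#' `eps_l` the across-unit mean frequency, and
#' `Qx = Z_c' (2 V_A F)^+ Z_c` evaluated on the top `n_units - 1`
#' eigenvectors of the centered drift covariance `F`. Under neutrality Qx is
#' chi-squared with `n_units - 1` degrees of freedom. An empirical p-value
#' is computed from random marker sets (frequency-matched by across-unit
#' mean-frequency decile by default) carrying the same effect sizes.
#'
#' @param effects Per-marker effect sizes of the associated set.
#' @param freqs Units x markers frequency matrix for the associated set.
#' @param F Among-unit drift covariance (e.g. [drift_covariance()]).
#' @param G,units Optional genotypes and unit labels used to draw random
#'   marker sets for the empirical null.
#' @param n_null Number of random sets (0 skips the empirical p).
#' @param match_freq Match random markers to the associated markers'
#'   frequency deciles (default TRUE).
#' @param selfing If TRUE, doubles the drift scaling (variance of fully
#'   selfing units), i.e. `Qx = Z_c' (4 V_A F)^+ Z_c`.
#' @param seed Integer seed for the null draws.
#' @return List of class `qx_result`: `qx`, `df`, `p_chi2`, `p_empirical`
#'   (NA when `n_null = 0`), `n_markers`, `va`, `scores`, `null_qx`.
#' @export
qx_test <- function(effects, freqs, F, G = NULL, units = NULL, n_null = 0,
                    match_freq = TRUE, selfing = FALSE, seed = 1L) {
  freqs <- as.matrix(freqs)
  n_units <- nrow(freqs)
  .assert(n_units >= 3, "need at least 3 units")
  .assert(ncol(freqs) == length(effects), "one effect per marker")
  scale_fac <- if (selfing) 4 else 2

  Fc <- F
  ev <- eigen((Fc + t(Fc)) / 2, symmetric = TRUE)
  keep <- seq_len(n_units - 1L)
  .assert(all(ev$values[keep] > 1e-12 * max(ev$values)),
          "drift covariance not invertible after centering")

  qx_of <- function(alpha, fr) {
    z <- 2 * drop(fr %*% alpha)
    eps <- colMeans(fr)
    va <- 4 * sum(alpha^2 * eps * (1 - eps))
    if (va <= 0) return(c(NA_real_, NA_real_))
    zc <- z - mean(z)
    proj <- drop(crossprod(ev$vectors[, keep, drop = FALSE], zc))
    c(sum(proj^2 / (scale_fac * va * ev$values[keep])), va)
  }

  obs <- qx_of(effects, freqs)
  .assert(is.finite(obs[1]), "additive variance is zero")
  df <- n_units - 1L
  out <- list(qx = obs[1], df = df,
              p_chi2 = max(stats::pchisq(obs[1], df, lower.tail = FALSE),
                           1e-300),
              p_empirical = NA_real_, n_markers = length(effects),
              va = obs[2],
              scores = polygenic_score(freqs, effects), null_qx = NULL)
  if (n_null > 0) {
    .assert(!is.null(G), "G is required for the empirical null")
    set.seed(stage_seed(seed, "qx_null"))
    all_f <- unit_freqs(G, units)
    eps_all <- colMeans(all_f)
    poly <- eps_all > 0 & eps_all < 1
    all_f <- all_f[, poly, drop = FALSE]; eps_all <- eps_all[poly]
    m <- length(effects)
    if (match_freq) {
      br <- stats::quantile(pmin(eps_all, 1 - eps_all), seq(0, 1, 0.1))
      br[1] <- -Inf; br[length(br)] <- Inf
      bin_all <- cut(pmin(eps_all, 1 - eps_all), br, labels = FALSE)
      eps_obs <- colMeans(freqs)
      bin_obs <- cut(pmin(eps_obs, 1 - eps_obs), br, labels = FALSE)
      pools <- split(seq_along(bin_all), bin_all)
    }
    null_qx <- numeric(n_null)
    for (b in seq_len(n_null)) {
      pick <- if (match_freq)
        vapply(bin_obs, function(bb) {
          pool <- pools[[as.character(bb)]] %||% seq_along(eps_all)
          pool[sample.int(length(pool), 1L)]
        }, integer(1))
      else sample.int(ncol(all_f), m)
      null_qx[b] <- qx_of(effects, all_f[, pick, drop = FALSE])[1]
    }
    null_qx <- null_qx[is.finite(null_qx)]
    out$p_empirical <- (1 + sum(null_qx >= obs[1])) / (length(null_qx) + 1)
    out$null_qx <- null_qx
  }
  class(out) <- "qx_result"
  out
}

#' @export
print.qx_result <- function(x, ...) {
  cat(sprintf("Qx = %.3f on %d df (chi-square p = %.3g%s, %d markers)\n",
              x$qx, x$df, x$p_chi2,
              if (!is.na(x$p_empirical))
                sprintf(", empirical p = %.3g", x$p_empirical) else "",
              x$n_markers))
  invisible(x)
}

#' Validate polygenic scores against observed phenotypes
#'
#' Three schemes: `holdout80` runs the GWAS on 80% of the genotypes and
#' correlates scores with the observed phenotype of the held-out 20%;
#' `replicate_cv` runs the GWAS on the mean of two replicates and
#' correlates scores of all lines with the third replicate; `random_sets`
#' compares the score-phenotype correlation of the associated marker set
#' with the empirical distribution over `n_random` equally sized random
#' marker sets (effects taken from the same association table).
#' Correlations are Spearman's rho.
#'
#' @param pheno Lines x replicates phenotype matrix (rownames = line ids).
#' @param G Filtered [geno_matrix].
#' @param K Kinship matrix (computed from `G` when NULL).
#' @param scheme One of `"holdout80"`, `"replicate_cv"`, `"random_sets"`.
#' @param p_index Association threshold for score markers (default 1e-4).
#' @param n_random Random sets for `random_sets` (default 1000).
#' @param seed Integer seed.
#' @return List with `scheme`, `rho`, `p`, `n_markers`, and for
#'   `random_sets` also `rho_random_median`, `rho_random_q95`,
#'   `rho_random_max`, `exceedance` (fraction of random rho >= observed)
#'   and the vector `rho_random`.
#' @export
validate_scores <- function(pheno, G, K = NULL,
                            scheme = c("holdout80", "replicate_cv",
                                       "random_sets"),
                            p_index = 1e-4, n_random = 1000, seed = 1L) {
  scheme <- match.arg(scheme)
  .assert(is.matrix(pheno), "pheno must be a lines x replicates matrix")
  if (is.null(K)) K <- compute_kinship(G)
  set.seed(stage_seed(seed, paste0("validate_", scheme)))
  n <- nrow(pheno)
  score_of <- function(sub_G, eff, markers, lines) {
    fr <- sub_G$codes[lines, markers, drop = FALSE] / 2
    if (anyNA(fr)) {
      mu <- colMeans(fr, na.rm = TRUE)
      idx <- which(is.na(fr), arr.ind = TRUE)
      fr[idx] <- mu[idx[, 2]]
    }
    2 * drop(fr %*% eff)
  }
  run_gwas <- function(lines, y) {
    sub <- geno_matrix(G$codes[lines, , drop = FALSE], G$map, lines = lines,
                       regions = if (!is.null(G$regions))
                         G$regions[match(lines, G$lines)] else NULL)
    mixed_gwas(y, sub, K[lines, lines])
  }
  spearman <- function(a, b) {
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }

  if (scheme == "holdout80") {
    train <- sort(sample.int(n, round(0.8 * n)))
    test <- setdiff(seq_len(n), train)
    y_train <- rowMeans(pheno[train, , drop = FALSE])
    assoc <- run_gwas(G$lines[train], y_train)
    cl <- ld_clump(assoc, G, p_index = p_index)
    .assert(nrow(cl$index) > 0, "no markers below p_index in training GWAS")
    z <- score_of(G, cl$index$effect, cl$index$marker, G$lines[test])
    ct <- spearman(z, rowMeans(pheno[test, , drop = FALSE]))
    list(scheme = scheme, rho = ct$rho, p = ct$p,
         n_markers = nrow(cl$index), n_test = length(test))
  } else if (scheme == "replicate_cv") {
    .assert(ncol(pheno) >= 3, "replicate_cv needs at least 3 replicates")
    y12 <- rowMeans(pheno[, 1:2, drop = FALSE])
    assoc <- run_gwas(G$lines, y12)
    cl <- ld_clump(assoc, G, p_index = p_index)
    .assert(nrow(cl$index) > 0, "no markers below p_index")
    z <- score_of(G, cl$index$effect, cl$index$marker, G$lines)
    ct <- spearman(z, pheno[, 3])
    list(scheme = scheme, rho = ct$rho, p = ct$p, n_markers = nrow(cl$index))
  } else {
    y <- rowMeans(pheno)
    assoc <- run_gwas(G$lines, y)
    cl <- ld_clump(assoc, G, p_index = p_index)
    .assert(nrow(cl$index) > 0, "no markers below p_index")
    z <- score_of(G, cl$index$effect, cl$index$marker, G$lines)
    ct <- spearman(z, y)
    k <- nrow(cl$index)
    ok <- which(!is.na(assoc$p))
    rho_rand <- vapply(seq_len(n_random), function(b) {
      pick <- sample(ok, k)
      zb <- score_of(G, assoc$effect[pick], assoc$marker[pick], G$lines)
      suppressWarnings(stats::cor(zb, y, method = "spearman"))
    }, numeric(1))
    list(scheme = scheme, rho = ct$rho, p = ct$p, n_markers = k,
         rho_random_median = stats::median(rho_rand),
         rho_random_q95 = stats::quantile(rho_rand, 0.95, names = FALSE),
         rho_random_max = max(rho_rand),
         exceedance = mean(rho_rand >= ct$rho), rho_random = rho_rand)
  }
}
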