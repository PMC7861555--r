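# Kinship, marker filtering and EMMA/EMMAX-style mixed-model association.
#
# Model: y = X beta + u + e with u ~ N(0, sg2 K), e ~ N(0, se2 I).
# REML is profiled over delta = se2/sg2 on the eigenbasis of K; EMMAX keeps
# the null-model delta fixed for every marker, exact EMMA re-estimates it.

#' Filter markers on minor allele frequency and missingness
#'
#' Retains markers with `MAF >= maf_min` and missing fraction
#' `<= max_missing` (both boundaries inclusive: markers *below* the MAF
#' threshold or *above* the missingness threshold are removed). MAF is
#' computed on non-missing calls.
#'
#' @param G A [geno_matrix].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param max_missing Maximum missing-call fraction (default 0.05).
#' @return The filtered [geno_matrix].
#' @export
filter_markers <- function(G, maf_min = 0.05, max_missing = 0.05) {
  maf <- marker_maf(G)
  miss <- colMeans(is.na(G$codes))
  keep <- maf >= maf_min & miss <= max_missing
  if (!any(keep))
    stop("no markers pass filtering (", sum(maf < maf_min), " below MAF, ",
         sum(miss > max_missing), " above missingness)", call. = FALSE)
  geno_matrix(G$codes[, keep, drop = FALSE], G$map[keep, , drop = FALSE],
              lines = G$lines, regions = G$regions)
}

#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the average allele sharing `1 - |g_i - g_j| / 2` over
#' pairwise-complete markers; for fully homozygous lines this is the
#' proportion of identical genotype calls.
#'
#' @param G A [geno_matrix] with at least 2 lines.
#' @return Symmetric kinship matrix with unit diagonal, entries in \[0, 1\].
#' @export
compute_kinship <- function(G) {
  .assert(nrow(G$codes) >= 2, "need at least two lines")
  m <- G$codes / 2
  a0 <- (m == 0); a5 <- (m == 0.5); a1 <- (m == 1)
  a0[is.na(a0)] <- FALSE; a5[is.na(a5)] <- FALSE; a1[is.na(a1)] <- FALSE
  storage.mode(a0) <- storage.mode(a5) <- storage.mode(a1) <- "double"
  nn <- !is.na(m); storage.mode(nn) <- "double"
  D <- tcrossprod(a0, a1) + tcrossprod(a1, a0) +
    0.5 * (tcrossprod(a0, a5) + tcrossprod(a5, a0) +
             tcrossprod(a5, a1) + tcrossprod(a1, a5))
  C <- tcrossprod(nn)
  if (any(C == 0))
    stop("line pair(s) share no non-missing markers", call. = FALSE)
  K <- 1 - D / C
  dimnames(K) <- list(G$lines, G$lines)
  (K + t(K)) / 2
}

# Eigen-decomposition of K with the stability jitter from the design notes.
.kin_eigen <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < 1e-8) {
    e <- eigen(K + diag(1e-6, nrow(K)), symmetric = TRUE)
    if (min(e$values) < 0)
      stop("kinship matrix not positive semi-definite after jitter",
           call. = FALSE)
  }
  e
}

# Profiled -2 REML log-likelihood over log(delta); ytil/Xtil are rotated.
.neg2reml_delta <- function(ldelta, ytil, Xtil, lambda) {
  d <- exp(ldelta)
  w <- lambda + d
  Xs <- Xtil / sqrt(w)
  ys <- ytil / sqrt(w)
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  r <- ys - Xs %*% beta
  n <- length(ys); q <- ncol(Xtil)
  s2 <- sum(r^2) / (n - q)
  if (!is.finite(s2) || s2 <= 0) return(Inf)
  (n - q) * log(s2) + sum(log(w)) + determinant(XtX)$modulus[1]
}

#' REML variance components of the null mixed model
#'
#' Maximizes the restricted likelihood of `y = X beta + u + e`,
#' `u ~ N(0, sg2 K)`, `e ~ N(0, se2 I)` via the spectral decomposition of K
#' and a one-dimensional search over the variance ratio. The pseudo-
#' heritability `sg2 / (sg2 + se2)` is the fraction of phenotypic variance
#' explained by the estimated relatedness.
#'
#' @param y Phenotype vector (complete, aligned with K rows).
#' @param K Kinship matrix.
#' @param X Fixed-effect design matrix (default: intercept only).
#' @return List: `sigma_g2`, `sigma_e2`, `pseudo_h2`, `delta`, `reml`, and
#'   the cached eigen-decomposition (`eigen`).
#' @export
reml_null <- function(y, K, X = NULL) {
  .assert(!anyNA(y), "phenotype must be complete for lines in K")
  n <- length(y)
  .assert(nrow(K) == n, "K dimension must match phenotype length")
  if (is.null(X)) X <- matrix(1, n, 1)
  e <- .kin_eigen(K)
  ytil <- crossprod(e$vectors, y)
  Xtil <- crossprod(e$vectors, X)
  grid <- seq(-12, 12, length.out = 49)
  vals <- vapply(grid, .neg2reml_delta, numeric(1), ytil = ytil,
                 Xtil = Xtil, lambda = e$values)
  i <- which.min(vals)
  opt <- stats::optimize(.neg2reml_delta, c(grid[max(1, i - 1)],
                                            grid[min(length(grid), i + 1)]),
                         ytil = ytil, Xtil = Xtil, lambda = e$values)
  delta <- exp(opt$minimum)
  w <- e$values + delta
  Xs <- Xtil / sqrt(w); ys <- ytil / sqrt(w)
  beta <- solve(crossprod(Xs), crossprod(Xs, ys))
  s2g <- sum((ys - Xs %*% beta)^2) / (n - ncol(X))
  list(sigma_g2 = s2g, sigma_e2 = s2g * delta,
       pseudo_h2 = 1 / (1 + delta), delta = delta, reml = -opt$objective / 2,
       beta = drop(beta), eigen = e)
}

# Shared GLS association core over an arbitrary dosage matrix M (lines x
# markers, mean-imputed, zero-variance markers already flagged).
.gls_assoc <- function(y, M, K, X, method = c("emmax", "emma")) {
  method <- match.arg(method)
  n <- length(y)
  null <- reml_null(y, K, X)
  e <- null$eigen
  q <- ncol(X)
  res <- data.frame(effect = rep(NA_real_, ncol(M)), se = NA_real_,
                    stat = NA_real_, p = NA_real_)
  if (method == "emmax") {
    w <- e$values + null$delta
    ys <- crossprod(e$vectors, y) / sqrt(w)
    Xs <- crossprod(e$vectors, X) / sqrt(w)
    Gs <- crossprod(e$vectors, M) / sqrt(w)
    XtXi <- solve(crossprod(Xs))
    ry <- ys - Xs %*% (XtXi %*% crossprod(Xs, ys))
    RG <- Gs - Xs %*% (XtXi %*% crossprod(Xs, Gs))
    den <- colSums(RG^2)
    num <- drop(crossprod(RG, ry))
    sst <- sum(ry^2)
    df <- n - q - 1
    beta <- num / den
    rss <- pmax(sst - beta * num, 0)
    se <- sqrt(rss / df / den)
    tt <- beta / se
    res$effect <- beta; res$se <- se; res$stat <- tt
    res$p <- 2 * stats::pt(-abs(tt), df)
  } else {
    ytil <- crossprod(e$vectors, y)
    for (l in seq_len(ncol(M))) {
      Xl <- cbind(X, M[, l])
      Xtil <- crossprod(e$vectors, Xl)
      grid <- seq(-12, 12, length.out = 25)
      vals <- vapply(grid, .neg2reml_delta, numeric(1), ytil = ytil,
                     Xtil = Xtil, lambda = e$values)
      i <- which.min(vals)
      opt <- stats::optimize(.neg2reml_delta,
                             c(grid[max(1, i - 1)],
                               grid[min(length(grid), i + 1)]),
                             ytil = ytil, Xtil = Xtil, lambda = e$values)
      wl <- e$values + exp(opt$minimum)
      Xs <- Xtil / sqrt(wl); ys <- ytil / sqrt(wl)
      XtXi <- solve(crossprod(Xs))
      bet <- XtXi %*% crossprod(Xs, ys)
      df <- n - ncol(Xl)
      s2 <- sum((ys - Xs %*% bet)^2) / df
      se <- sqrt(s2 * XtXi[ncol(Xl), ncol(Xl)])
      tt <- bet[ncol(Xl)] / se
      res$effect[l] <- bet[ncol(Xl)]; res$se[l] <- se; res$stat[l] <- tt
      res$p[l] <- 2 * stats::pt(-abs(tt), df)
    }
  }
  res$p <- pmin(pmax(res$p, 1e-300), 1)
  attr(res, "pseudo_h2") <- null$pseudo_h2
  attr(res, "delta") <- null$delta
  res
}

#' Mixed-model genome-wide association (EMMAX / exact EMMA)
#'
#' EMMAX: variance components are estimated once under the null model and
#' reused for every marker; the phenotype and genotypes are rotated by the
#' eigen-decomposition of K and each marker is tested by generalized least
#' squares with a t-test on `n - rank(X) - 1` degrees of freedom. `"emma"`
#' re-estimates the variance ratio for every marker (exact, slow; for small
#' instances). Missing genotype calls are mean-imputed per marker for
#' testing. Markers with zero variance among phenotyped lines are skipped
#' (NA results) with a message.
#'
#' @param y Phenotype vector, one value per line of `G` (typically a
#'   genotypic mean).
#' @param G A [geno_matrix], already filtered with [filter_markers()].
#' @param K Kinship matrix (default: computed from `G`).
#' @param covariates Optional numeric matrix of fixed covariates (an
#'   intercept is always included).
#' @param method `"emmax"` (default) or `"emma"`.
#' @return Data frame with one row per marker: `marker`, `chrom`, `pos`,
#'   `maf`, `effect` (trait units per allele dose), `se`, `stat`, `p`.
#'   Attributes: `pseudo_h2`, `bonferroni` (0.05 / markers tested), `n`.
#' @export
mixed_gwas <- function(y, G, K = NULL, covariates = NULL,
                       method = c("emmax", "emma")) {
  method <- match.arg(method)
  .assert(length(y) == nrow(G$codes), "one phenotype value per line")
  if (is.null(K)) K <- compute_kinship(G)
  M <- G$codes
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2]]
  }
  v <- apply(M, 2, stats::var)
  skip <- v == 0 | !is.finite(v)
  if (any(skip))
    message(sum(skip), " zero-variance marker(s) skipped")
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates)
  res <- .gls_assoc(y, M[, !skip, drop = FALSE], K, X, method)
  out <- data.frame(marker = G$map$marker, chrom = G$map$chrom,
                    pos = G$map$pos, maf = marker_maf(G),
                    effect = NA_real_, se = NA_real_, stat = NA_real_,
                    p = NA_real_)
  out[!skip, c("effect", "se", "stat", "p")] <- res
  attr(out, "pseudo_h2") <- attr(res, "pseudo_h2")
  attr(out, "bonferroni") <- 0.05 / sum(!skip)
  attr(out, "n") <- length(y)
  out
}

#' Mixed-model association on loss-of-function gene states
#'
#' Runs the same mixed-model machinery as [mixed_gwas()] with the SNP dosage
#' matrix replaced by binary gene states (functional = 0, LOF = 1). The MAF
#' filter is applied to the LOF carrier frequency.
#'
#' @param y Phenotype vector, one value per genotype (column of `lof`).
#' @param lof Binary genes x genotypes matrix.
#' @param K Kinship matrix over the same genotypes.
#' @param maf_min Minimum carrier-frequency threshold (two-sided, default
#'   0.05); set to 0 to test every polymorphic gene.
#' @param method `"emmax"` or `"emma"`.
#' @return Data frame with one row per tested gene: `gene`, `freq`,
#'   `effect`, `se`, `stat`, `p`; attribute `bonferroni`.
#' @export
lof_gwas <- function(y, lof, K, maf_min = 0.05, method = c("emmax", "emma")) {
  .assert(all(lof %in% c(0, 1)), "LOF states must be binary")
  .assert(length(y) == ncol(lof), "one phenotype value per genotype")
  M <- t(lof)
  freq <- colMeans(M)
  keep <- pmin(freq, 1 - freq) >= maf_min & freq > 0 & freq < 1
  .assert(any(keep), "no polymorphic genes after frequency filter")
  res <- .gls_assoc(y, M[, keep, drop = FALSE], K,
                    matrix(1, length(y), 1), match.arg(method))
  out <- data.frame(gene = colnames(M)[keep], freq = freq[keep], res)
  attr(out, "pseudo_h2") <- attr(res, "pseudo_h2")
  attr(out, "bonferroni") <- 0.05 / sum(keep)
  rownames(out) <- NULL
  out
}

#' Kinship-corrected trait correlation
#'
#' Reports the Pearson correlation of two traits together with a p-value
#' from the mixed model `y = a + b x + u + e`, `u ~ N(0, sg2 K)` (Wald test
#' on b), which corrects the test for relatedness among lines. With `K = I`
#' this reduces to the classical Pearson test.
#'
#' @param x,y Paired trait vectors (pairwise-complete observations used).
#' @param K Kinship matrix aligned with `x` and `y`.
#' @return List: `r` (Pearson), `p` (kinship-corrected), `beta`, `se`, `n`.
#' @export
kinship_corrected_correlation <- function(x, y, K) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; K <- K[ok, ok, drop = FALSE]
  .assert(stats::sd(x) > 0 && stats::sd(y) > 0, "constant trait")
  n <- length(x)
  X <- cbind(1, x)
  null <- reml_null(y, K, X)
  e <- null$eigen
  w <- e$values + null$delta
  Xs <- crossprod(e$vectors, X) / sqrt(w)
  ys <- crossprod(e$vectors, y) / sqrt(w)
  XtXi <- solve(crossprod(Xs))
  beta <- XtXi %*% crossprod(Xs, ys)
  s2 <- sum((ys - Xs %*% beta)^2) / (n - 2)
  se <- sqrt(s2 * XtXi[2, 2])
  tt <- beta[2] / se
  list(r = stats::cor(x, y), p = 2 * stats::pt(-abs(tt), n - 2),
       beta = beta[2], se = se, n = n)
}
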