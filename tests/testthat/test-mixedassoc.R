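# Marker filtering, IBS kinship, REML variance components and the
# mixed-model association machinery.

test_that("marker filtering applies inclusive MAF/missingness boundaries", {
  # constructed MAFs {0, 0.04, 0.05, 0.5} and missingness {0, 0.04, 0.06}
  n <- 50
  codes <- cbind(
    rep(0, n),                                  # monomorphic -> out
    c(rep(2, 2), rep(0, n - 2)),                # maf 0.04 -> out
    c(rep(2, 3), rep(0, n - 3)),                # maf 0.06 -> in
    c(rep(2, 25), rep(0, 25)),                  # maf 0.5 -> in
    c(rep(NA, 2), rep(c(0, 2), 24)),            # miss 0.04, maf ok -> in
    c(rep(NA, 3), rep(c(0, 2), 23), 0))         # miss 0.06 -> out
  G <- toy_geno(codes)
  kept <- filter_markers(G, maf_min = 0.05, max_missing = 0.05)
  # brute-force oracle
  maf <- apply(codes, 2, function(x) {
    p <- mean(x, na.rm = TRUE) / 2; min(p, 1 - p) })
  miss <- colMeans(is.na(codes))
  expect_equal(kept$map$marker,
               G$map$marker[maf >= 0.05 & miss <= 0.05])
  expect_true("m4" %in% kept$map$marker)

  # exact-boundary marker: MAF 0.05 and missingness 0.05 retained
  n2 <- 40
  codes2 <- cbind(c(rep(NA, 2), rep(2, 2), rep(0, n2 - 4)),
                  c(rep(c(0, 2), n2 / 2)))
  maf2 <- (2 * 2) / (2 * 38)  # 0.0526... adjust to exactly 0.05
  G2 <- toy_geno(cbind(c(rep(NA, 2), rep(2, 19), rep(0, 19)),
                       rep(c(0, 2), 20)))
  expect_silent({k2 <- filter_markers(G2, maf_min = 0.5, max_missing = 0.05)})
  expect_true("m1" %in% k2$map$marker)  # maf exactly 0.5, miss exactly 0.05
  expect_error(filter_markers(toy_geno(matrix(0, 10, 2))), "no markers")
})

test_that("IBS kinship matches hand computation and its invariants", {
  expect_equal(unname(compute_kinship(toy_geno(rbind(c(0, 2, 2, 0),
                                                     c(0, 2, 2, 0))))[1, 2]),
               1)
  expect_equal(unname(compute_kinship(toy_geno(rbind(c(0, 2, 0, 2),
                                                     c(2, 0, 2, 0))))[1, 2]),
               0)
  # 3 lines x 4 markers, hand-computed sharing (with a het call)
  codes <- rbind(c(0, 2, 2, 0),
                 c(0, 0, 2, 2),
                 c(1, 2, 0, 0))
  K <- compute_kinship(toy_geno(codes))
  expect_equal(unname(K[1, 2]), mean(c(1, 0, 1, 0)))
  expect_equal(unname(K[1, 3]), mean(c(0.5, 1, 0, 1)))
  expect_equal(unname(K[2, 3]), mean(c(0.5, 0, 0, 0)))
  expect_equal(K, t(K))
  expect_equal(unname(diag(K)), rep(1, 3))
  # invariant to marker order
  K2 <- compute_kinship(toy_geno(codes[, c(3, 1, 4, 2)]))
  expect_equal(unname(K2), unname(K))
  # pairwise-complete with missing calls
  codes[1, 1] <- NA
  K3 <- compute_kinship(toy_geno(codes))
  expect_equal(unname(K3[1, 2]), mean(c(0, 1, 0)))
})

test_that("REML null model recovers variance components", {
  # family-structured kinship: variance components are identifiable when
  # the kinship spectrum is dispersed (100 sib groups of 3, r = 0.9)
  fam <- rep(1:100, each = 3)
  K <- 0.1 * diag(300) + 0.9 * outer(fam, fam, "==")
  e <- eigen(K, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  for (s in 1:3) {
    set.seed(s)
    y <- drop(L %*% rnorm(300)) + rnorm(300)   # sg2 = se2 = 1
    vc <- reml_null(y, K)
    expect_gt(vc$pseudo_h2, 0.35); expect_lt(vc$pseudo_h2, 0.65)
    # dense-grid oracle over the variance ratio
    grid <- exp(seq(-6, 6, length.out = 400))
    ll <- vapply(log(grid), polygrowth:::.neg2reml_delta, numeric(1),
                 ytil = crossprod(e$vectors, y),
                 Xtil = crossprod(e$vectors, matrix(1, 300, 1)),
                 lambda = e$values)
    expect_equal(vc$delta, grid[which.min(ll)], tolerance = 0.05)
  }
  # iid noise: no genetic signal
  set.seed(9); h2s <- vapply(1:5, function(i)
    reml_null(rnorm(300), K)$pseudo_h2, numeric(1))
  expect_lt(mean(h2s), 0.1)
  # pure genetic signal
  set.seed(10); y <- drop(L %*% rnorm(300))
  expect_gt(reml_null(y, K)$pseudo_h2, 0.95)
})

test_that("permuted phenotypes give uniform mixed-model p-values", {
  cfg <- sim_config(n_per_region = c(50, 50), n_snps = 800,
                    fst_target = 0.1, n_causal = 30, h2 = 0.6,
                    regional_shift = 1, seed = 31)
  G <- simulate_genotypes(cfg)
  Gf <- filter_markers(G)
  K <- compute_kinship(Gf)
  tr <- simulate_trait(Gf, cfg)
  set.seed(1)
  y <- sample(rowMeans(tr$pheno))   # break the genotype-phenotype link
  a <- mixed_gwas(y, Gf, K)
  expect_gt(suppressWarnings(stats::ks.test(a$p, "punif")$p.value), 0.01)
  expect_true(all(a$p > 0 & a$p <= 1, na.rm = TRUE))
  expect_true(all(a$maf >= 0.05 - 1e-12 & a$maf <= 0.5, na.rm = TRUE))
})

test_that("a strong causal SNP is found with an accurate effect estimate", {
  hits <- 0; rel_err <- numeric(0)
  for (s in 1:10) {
    cfg <- sim_config(n_per_region = c(50, 50), n_snps = 400,
                      fst_target = 0, seed = 400 + s)
    G <- simulate_genotypes(cfg)
    Gf <- filter_markers(G)
    set.seed(s)
    j <- sample(ncol(Gf$codes), 1)
    g <- Gf$codes[, j]
    beta <- 1
    vg <- var(g * beta)
    y <- g * beta + rnorm(100, sd = sqrt(4 * vg))  # SNP explains ~20%
    a <- mixed_gwas(y, Gf, compute_kinship(Gf))
    top <- which.min(a$p)
    if (a$marker[top] == Gf$map$marker[j]) {
      hits <- hits + 1
      rel_err <- c(rel_err, abs(a$effect[top] - beta) / beta)
    }
  }
  expect_gte(hits, 9)
  expect_lt(stats::median(rel_err), 0.2)
})

test_that("type-I error is nominal under a structured null", {
  cfg <- sim_config(n_per_region = c(50, 50), n_snps = 2000,
                    fst_target = 0.1, seed = 203)
  G <- simulate_genotypes(cfg)
  Gf <- filter_markers(G)
  K <- compute_kinship(Gf)
  set.seed(3)
  y <- ifelse(Gf$regions == "R1", 1, 0) + rnorm(100, sd = 0.5)
  a <- mixed_gwas(y, Gf, K)
  rej <- mean(a$p < 0.05, na.rm = TRUE)
  m <- sum(!is.na(a$p))
  ci <- 1.96 * sqrt(0.05 * 0.95 / m)
  expect_gt(rej, 0.05 - ci); expect_lt(rej, 0.05 + ci)
})

test_that("EMMAX agrees with exact per-marker EMMA on small instances", {
  cfg <- sim_config(n_per_region = c(40, 40), n_snps = 300,
                    fst_target = 0.1, n_causal = 20, h2 = 0.6, seed = 77)
  G <- simulate_genotypes(cfg)
  Gf <- filter_markers(G)
  K <- compute_kinship(Gf)
  tr <- simulate_trait(Gf, sim_config(n_per_region = c(40, 40),
                                      n_snps = ncol(Gf$codes),
                                      n_causal = 20, h2 = 0.6, seed = 77))
  y <- rowMeans(tr$pheno)
  a1 <- mixed_gwas(y, Gf, K, method = "emmax")
  a2 <- mixed_gwas(y, Gf, K, method = "emma")
  expect_lte(max(abs(log10(a1$p) - log10(a2$p)), na.rm = TRUE), 0.2)
  # p-values invariant to affine transformation of the phenotype
  a3 <- mixed_gwas(2 * y + 3, Gf, K)
  expect_equal(a3$p, a1$p, tolerance = 1e-8)
})

test_that("kinship-corrected correlation reduces and corrects as expected", {
  set.seed(12)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  K <- diag(60)
  r <- kinship_corrected_correlation(x, y, K)
  # identity case
  ri <- kinship_corrected_correlation(x, x, K)
  expect_equal(ri$r, 1)
  # K = I reduces to the classical Pearson test
  ct <- stats::cor.test(x, y)
  expect_equal(r$p, ct$p.value, tolerance = 1e-6)
  expect_error(kinship_corrected_correlation(rep(1, 60), y, K), "constant")

  # regional confounding: the naive test is inflated, the corrected is not
  naive <- corrected <- numeric(15)
  for (s in 1:15) {
    cfg <- sim_config(n_per_region = c(40, 40), n_snps = 300,
                      fst_target = 0.2, seed = 500 + s)
    G <- simulate_genotypes(cfg)
    K2 <- compute_kinship(G)
    set.seed(s)
    reg <- ifelse(G$regions == "R1", 1, -1)
    x2 <- reg + rnorm(80, sd = 0.7)
    y2 <- reg + rnorm(80, sd = 0.7)   # correlated only through structure
    naive[s] <- stats::cor.test(x2, y2)$p.value
    corrected[s] <- kinship_corrected_correlation(x2, y2, K2)$p
  }
  expect_lt(stats::median(naive), stats::median(corrected))
})

test_that("LOF association skips fixed genes and filters by frequency", {
  cfg <- sim_config(n_per_region = c(30, 30), n_snps = 100, seed = 61)
  G <- simulate_genotypes(cfg)
  K <- compute_kinship(G)
  lof <- rbind(gene_fixed = rep(0, 60),
               gene_ok = rep(c(0, 1), 30),
               gene_rare = c(1, rep(0, 59)))
  colnames(lof) <- G$lines
  set.seed(2)
  res <- lof_gwas(rnorm(60), lof, K, maf_min = 0.05)
  expect_equal(res$gene, "gene_ok")
})
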