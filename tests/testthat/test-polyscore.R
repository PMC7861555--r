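# LD clumping, polygenic scores, validation schemes and the Qx test.

test_that("ld_clump reproduces a brute-force clumping oracle", {
  # 10 markers: two perfectly correlated triplets (1-3 and 6-8)
  set.seed(11)
  base1 <- rbinom(40, 1, 0.5) * 2
  base2 <- rbinom(40, 1, 0.5) * 2
  other <- matrix(rbinom(40 * 4, 1, 0.5) * 2, 40, 4)
  codes <- cbind(base1, base1, base1, other[, 1], other[, 2],
                 base2, base2, base2, other[, 3], other[, 4])
  G <- toy_geno(codes, pos = as.integer(seq(1e4, 1e5, length.out = 10)))
  p <- c(0.004, 1e-6, 0.008, 0.5, 2e-5, 0.003, 1e-5, 0.009, 0.2, 0.7)
  assoc <- data.frame(marker = G$map$marker, chrom = G$map$chrom,
                      pos = G$map$pos, p = p,
                      effect = rnorm(10), maf = marker_maf(G))
  cl <- ld_clump(assoc, G, p_index = 1e-4, window = 1e6,
                 p_secondary = 0.01, r2 = 0.5)

  # exhaustive oracle: independent greedy reimplementation
  r2m <- suppressWarnings(stats::cor(codes))^2
  unassigned <- rep(TRUE, 10)
  oracle_index <- integer(0)
  repeat {
    cand <- which(unassigned & p < 1e-4)
    if (!length(cand)) break
    i <- cand[which.min(p[cand])]
    oracle_index <- c(oracle_index, i)
    members <- which(unassigned & p < 0.01 & seq_len(10) != i &
                       abs(assoc$pos - assoc$pos[i]) <= 5e5 &
                       r2m[i, ] >= 0.5)
    unassigned[c(i, members)] <- FALSE
  }
  expect_equal(cl$index$marker, assoc$marker[sort(oracle_index)][
    order(p[sort(oracle_index)])])
  # m2 clumps m1/m3; m7 clumps m6/m8; m5 alone
  expect_setequal(cl$index$marker, c("m2", "m7", "m5"))
  expect_setequal(cl$clumps[["m2"]], c("m1", "m3"))
  expect_setequal(cl$clumps[["m7"]], c("m6", "m8"))

  # input order invariance
  sh <- sample(nrow(assoc))
  cl2 <- ld_clump(assoc[sh, ], G, p_index = 1e-4)
  expect_equal(cl2$index$marker, cl$index$marker)

  # no candidates / singleton
  expect_equal(nrow(ld_clump(transform(assoc, p = pmax(p, 0.01)),
                             G)$index), 0)
  single <- transform(assoc, p = replace(rep(0.5, 10), 5, 1e-6))
  expect_equal(ld_clump(single, G)$index$marker, "m5")
})

test_that("polygenic scores follow Z = 2 sum(alpha p)", {
  fr <- rbind(u1 = c(0.2, 0.4), u2 = c(0.5, 0.1))
  expect_equal(polygenic_score(fr, c(0, 0))$score, c(0, 0))
  expect_equal(polygenic_score(fr, c(0.5, -1))$score[1],
               2 * (0.5 * 0.2 - 1 * 0.4))  # = -0.6
  # linear in effects
  a1 <- c(0.3, -0.2); a2 <- c(-1, 0.7)
  expect_equal(polygenic_score(fr, a1 + a2)$score,
               polygenic_score(fr, a1)$score + polygenic_score(fr, a2)$score)
  # a zero-effect marker changes nothing
  expect_equal(polygenic_score(cbind(fr, c(0.9, 0.3)), c(0.5, -1, 0))$score,
               polygenic_score(fr, c(0.5, -1))$score)
  expect_error(polygenic_score(rbind(c(1.2, 0)), c(1, 1)), "frequencies")
})

test_that("Qx is zero for identical units and chi-square under neutrality", {
  fr <- rbind(u1 = c(0.3, 0.6), u2 = c(0.3, 0.6), u3 = c(0.3, 0.6))
  q0 <- qx_test(c(0.5, -0.2), fr, diag(3) / 2)
  expect_equal(q0$qx, 0, tolerance = 1e-12)

  # neutral calibration under the Gaussian-drift model the chi-square null
  # is derived for: mean Qx ~ df and ~5% rejection at the 95% point
  nunits <- 10; f <- 0.05; m_eff <- 30; m_null <- 2000
  qxs <- rej <- numeric(300)
  set.seed(99)
  for (b in 1:300) {
    p0 <- runif(m_eff + m_null, 0.1, 0.9)
    dev <- matrix(rnorm(nunits * length(p0)), nunits) *
      rep(sqrt(f * p0 * (1 - p0)), each = nunits)
    fr <- matrix(pmin(pmax(rep(p0, each = nunits) + dev, 1e-3), 1 - 1e-3),
                 nunits)
    eff_fr <- fr[, 1:m_eff]; null_fr <- fr[, -(1:m_eff)]
    alpha <- rnorm(m_eff, sd = 0.1)
    eps <- colMeans(null_fr)
    d <- sweep(null_fr, 2, eps) /
      rep(sqrt(eps * (1 - eps)), each = nunits)
    Fm <- tcrossprod(d) / (2 * m_null)
    q <- qx_test(alpha, eff_fr, Fm)
    qxs[b] <- q$qx; rej[b] <- q$p_chi2 < 0.05
  }
  expect_gt(mean(qxs), 8.3); expect_lt(mean(qxs), 9.7)
  expect_gt(mean(rej), 0.02); expect_lt(mean(rej), 0.08)
})

test_that("Qx is invariant to flipping a marker's allele coding", {
  set.seed(5)
  fr <- matrix(runif(8 * 6, 0.1, 0.9), 8, 6)
  alpha <- rnorm(6)
  Fm <- drop(0.02) * diag(8) + 0.01
  q1 <- qx_test(alpha, fr, Fm)
  fr2 <- fr; fr2[, 3] <- 1 - fr2[, 3]
  alpha2 <- alpha; alpha2[3] <- -alpha2[3]
  q2 <- qx_test(alpha2, fr2, Fm)
  expect_equal(q2$qx, q1$qx, tolerance = 1e-12)
})

test_that("chi-square and empirical Qx p-values agree on neutral genotypes", {
  for (s in 1:3) {
    cfg <- sim_config(n_per_region = c(60, 60), n_snps = 1500,
                      fst_target = 0.05, seed = 600 + s)
    G <- filter_markers(simulate_genotypes(cfg))
    set.seed(s)
    pick <- sample(ncol(G$codes), 30)
    alpha <- rnorm(30, sd = 0.1)
    fr <- unit_freqs(G, markers = G$map$marker[pick])
    q <- qx_test(alpha, fr, drift_covariance(G), G = G, n_null = 400,
                 seed = s)
    expect_lt(abs(q$p_chi2 - q$p_empirical), 0.1)
  }
})

test_that("Qx detects divergent selection on polygenic scores", {
  # frequency shifts aligned with effect signs between two unit groups
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    nunits <- 10; m_eff <- 30; m_null <- 1500; f <- 0.05
    p0 <- runif(m_eff + m_null, 0.2, 0.8)
    dev <- matrix(rnorm(nunits * length(p0)), nunits) *
      rep(sqrt(f * p0 * (1 - p0)), each = nunits)
    fr <- matrix(pmin(pmax(rep(p0, each = nunits) + dev, 1e-3), 1 - 1e-3),
                 nunits)
    alpha <- rnorm(m_eff, sd = 0.1)
    sel <- 0.08 * sign(alpha)          # directional shift in units 1-5
    fr[1:5, 1:m_eff] <- pmin(pmax(
      fr[1:5, 1:m_eff] + rep(sel, each = 5), 1e-3), 1 - 1e-3)
    null_fr <- fr[, -(1:m_eff)]
    eps <- colMeans(null_fr)
    d <- sweep(null_fr, 2, eps) / rep(sqrt(eps * (1 - eps)),
                                      each = nunits)
    Fm <- tcrossprod(d) / (2 * m_null)
    qx_test(alpha, fr[, 1:m_eff], Fm)$p_chi2 < 0.05
  }, logical(1))
  expect_gte(sum(hits), 8)   # power > 80%
})

test_that("replicate cross-validation predicts a fully heritable trait", {
  cfg <- sim_config(n_per_region = c(100, 100), n_snps = 600,
                    fst_target = 0, n_causal = 8, h2 = 1, seed = 42)
  G <- filter_markers(simulate_genotypes(cfg))
  tr <- simulate_trait(G, cfg)
  v <- validate_scores(tr$pheno, G, scheme = "replicate_cv",
                       p_index = 1e-3, seed = 3)
  expect_gt(v$rho, 0.9)
  expect_error(validate_scores(tr$pheno[, 1:2], G,
                               scheme = "replicate_cv"), "3 replicates")
  expect_error(validate_scores(tr$pheno, G, scheme = "bogus"))
})

test_that("associated sets beat random marker sets for heritable traits", {
  cfg <- sim_config(n_per_region = c(100, 100), n_snps = 600,
                    fst_target = 0, n_causal = 12, h2 = 0.6, seed = 19)
  G <- filter_markers(simulate_genotypes(cfg))
  tr <- simulate_trait(G, cfg)
  v <- validate_scores(tr$pheno, G, scheme = "random_sets",
                       n_random = 300, seed = 4)
  expect_gt(v$rho, v$rho_random_q95)
  expect_equal(v$exceedance, 0)
  expect_length(v$rho_random, 300)
})

test_that("pure-noise phenotypes are not predicted out of sample", {
  cfg <- sim_config(n_per_region = c(100, 100), n_snps = 600,
                    fst_target = 0, seed = 77)
  G <- filter_markers(simulate_genotypes(cfg))
  set.seed(8)
  ph <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(G$lines, NULL))
  v <- validate_scores(ph, G, scheme = "holdout80", p_index = 0.01,
                       seed = 9)
  expect_lt(abs(v$rho), 0.3)
  expect_gt(v$p, 0.05)
})
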