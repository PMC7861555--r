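# Gene scores, duplicate pruning, GO enrichment and LD candidate windows.

toy_assoc <- function(pos, p, chrom = "chr1") {
  data.frame(marker = paste0("s", seq_along(pos)), chrom = chrom,
             pos = pos, p = p, effect = 0, maf = 0.2)
}

test_that("gene scores take internal minima and nearest-SNP fallbacks", {
  assoc <- toy_assoc(pos = c(100, 150, 900, 5000, 5200, 9000, 12000, 20000),
                     p = c(0.1, 0.001, 0.8, 0.02, 0.3, 0.05, 0.5, 1e-5))
  genes <- data.frame(gene_id = c("gA", "gB", "gC", "gD", "gE"),
                      chrom = "chr1",
                      start = c(50, 4900, 8000, 13000, 30000),
                      end = c(200, 5300, 8500, 14000, 31000))
  sc <- assign_gene_scores(assoc, genes)
  expect_equal(nrow(sc), 5)            # universe covered exactly once
  expect_equal(anyDuplicated(sc$gene_id), 0L)
  expect_equal(sc$p[sc$gene_id == "gA"], 0.001)  # min over internal SNPs
  expect_equal(sc$p[sc$gene_id == "gB"], 0.02)
  # gC has no internal SNP; nearest by midpoint (8250): s6 at 9000
  expect_equal(sc$marker[sc$gene_id == "gC"], "s6")
  expect_equal(sc$distance[sc$gene_id == "gC"], 9000 - 8250)

  # brute-force nearest-neighbour oracle over all genes
  for (i in seq_len(nrow(genes))) {
    inside <- assoc$pos >= genes$start[i] & assoc$pos <= genes$end[i]
    expected <- if (any(inside)) min(assoc$p[inside]) else {
      mid <- (genes$start[i] + genes$end[i]) / 2
      dd <- abs(assoc$pos - mid)
      min(assoc$p[dd == min(dd)])
    }
    expect_equal(sc$p[sc$gene_id == genes$gene_id[i]], expected)
  }

  # chromosome mismatch: gene skipped with a warning
  genes2 <- rbind(genes, data.frame(gene_id = "gX", chrom = "chr9",
                                    start = 1, end = 10))
  expect_warning(sc2 <- assign_gene_scores(assoc, genes2), "skipped")
  expect_false("gX" %in% sc2$gene_id)
})

test_that("tandem duplicate pruning follows the rank-distance rule", {
  genes <- data.frame(gene_id = sprintf("g%02d", 1:12), chrom = "chr1",
                      start = seq(1000, 12000, by = 1000),
                      end = seq(1000, 12000, by = 1000) + 500)
  # no qualifying pair: unchanged
  none <- data.frame(gene1 = "g01", gene2 = "g05", evalue = 1e-10)
  expect_equal(prune_tandem_duplicates(genes, none), genes)

  # pair 3 apart: downstream member removed; brute-force check
  pairs <- data.frame(gene1 = c("g02", "g03"), gene2 = c("g05", "g11"),
                      evalue = c(1e-40, 1e-35))
  pruned <- prune_tandem_duplicates(genes, pairs)
  expect_false("g05" %in% pruned$gene_id)   # 3 apart, downstream removed
  expect_true("g02" %in% pruned$gene_id)
  # g03 vs g11 are 8 ranks apart -> within 10, so g11 is removed too
  expect_true("g03" %in% pruned$gene_id)
  expect_false("g11" %in% pruned$gene_id)

  # pair >= 10 genes apart: both retained
  far <- data.frame(gene1 = "g01", gene2 = "g12", evalue = 1e-50)
  expect_equal(nrow(prune_tandem_duplicates(genes, far)), 12)

  # idempotent
  expect_equal(prune_tandem_duplicates(pruned, pairs), pruned)
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  universe <- paste0("g", 1:100)
  ann <- rbind(data.frame(gene_id = paste0("g", 1:10), term = "GO:1"),
               data.frame(gene_id = paste0("g", 11:16), term = "GO:2"),
               data.frame(gene_id = paste0("g", 17:21), term = "GO:3"))
  cand <- c(paste0("g", 1:4), "g50")  # 4 of 5 in GO:1
  res <- go_fisher(cand, universe, ann)
  # direct summation oracle: P(X >= 4), X ~ Hypergeom(K=10, N-K=90, n=5)
  p_ora <- sum(vapply(4:5, function(k)
    choose(10, k) * choose(90, 5 - k) / choose(100, 5), numeric(1)))
  expect_equal(res$p[res$term == "GO:1"], p_ora, tolerance = 1e-12)
  # term with exactly 5 annotated genes is suppressed
  expect_false("GO:3" %in% res$term)
  # candidates = universe: no enrichment possible
  res_all <- go_fisher(universe, universe, ann)
  expect_true(all(res_all$p == 1))
  expect_error(go_fisher(character(0), universe, ann), "empty")
  expect_error(go_fisher("not_in_universe", universe, ann), "subset")
  # order invariance
  res2 <- go_fisher(rev(cand), universe, ann)
  expect_equal(res2$p, res$p)
})

test_that("rank-based KS enrichment matches the ECDF sup-difference", {
  scores <- data.frame(gene_id = paste0("g", 1:20),
                       p = seq(0.001, 0.95, length.out = 20))
  ann <- data.frame(gene_id = paste0("g", c(1:6, 15)), term = "GO:9")
  res <- go_ks(scores, ann)
  ranks_in <- c(1:6, 15); ranks_out <- setdiff(1:20, ranks_in)
  # direct one-sided sup-difference of the two rank ECDFs
  d_plus <- max(vapply(sort(ranks_in), function(r)
    mean(ranks_in <= r) - mean(ranks_out <= r), numeric(1)))
  expect_equal(res$ks_stat[res$term == "GO:9"], d_plus, tolerance = 1e-12)

  # extreme enrichment: term genes occupy the top ranks exactly
  ann_top <- data.frame(gene_id = paste0("g", 1:6), term = "GO:9")
  res_top <- go_ks(scores, ann_top)
  expect_equal(res_top$ks_stat, 1)
  expect_lt(res_top$p, res$p[res$term == "GO:9"])

  # random ranks: p roughly uniform over seeds
  ps <- vapply(1:60, function(s) {
    set.seed(s)
    sc <- data.frame(gene_id = paste0("g", 1:40), p = runif(40))
    go_ks(sc, data.frame(gene_id = sample(sc$gene_id, 8),
                         term = "GO:7"))$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("the permutation threshold is the pooled p-value quantile", {
  universe <- paste0("g", 1:60)
  set.seed(2)
  ann <- data.frame(gene_id = sample(universe, 120, replace = TRUE),
                    term = sample(paste0("GO:", 1:6), 120, replace = TRUE))
  ann <- unique(ann)
  thr <- permutation_threshold(universe, ann, set_size = 8, n_sets = 200,
                               seed = 5)
  # order-statistics oracle on the pooled sample
  expect_equal(thr$threshold,
               stats::quantile(thr$pooled_p, 1e-4, names = FALSE))
  # determinism
  thr2 <- permutation_threshold(universe, ann, set_size = 8, n_sets = 200,
                                seed = 5)
  expect_identical(thr$threshold, thr2$threshold)
  expect_error(permutation_threshold(universe, ann, set_size = 8,
                                     n_sets = 0), "positive")
})

test_that("candidate gene windows follow the LD span and window cap", {
  set.seed(21)
  # 9 markers: 1-4 in tight LD with the focal (3), 5+ independent
  block <- rbinom(50, 1, 0.5) * 2
  flip <- function(x, k) { i <- sample(50, k); x[i] <- 2 - x[i]; x }
  codes <- cbind(flip(block, 2), flip(block, 1), block, flip(block, 3),
                 rbinom(50, 1, 0.5) * 2, rbinom(50, 1, 0.5) * 2,
                 flip(block, 1), rbinom(50, 1, 0.5) * 2,
                 rbinom(50, 1, 0.5) * 2)
  pos <- as.integer(c(1e4, 2e4, 3e4, 4e4, 5e4, 6e4, 7e4, 8e4, 5e5))
  G <- toy_geno(codes, pos = pos)
  genes <- data.frame(gene_id = paste0("g", 1:5), chrom = "chr1",
                      start = c(9000, 35000, 52000, 69000, 495000),
                      end = c(12000, 42000, 56000, 72000, 499000))
  win <- candidate_gene_window("m3", G, genes, max_window = 250e3,
                               r2_min = 0.5)
  # span = contiguous run m1..m4 (m5 breaks it); g1, g2 overlap
  expect_equal(win$span$start, 1e4)
  expect_equal(win$span$end, 4e4)
  expect_setequal(win$genes$gene_id, c("g1", "g2"))
  # interval-overlap oracle
  hit <- genes$start <= win$span$end & genes$end >= win$span$start
  expect_setequal(win$genes$gene_id, genes$gene_id[hit])

  # marker m7 is linked but the contiguous run is broken before it
  expect_false("g4" %in% win$genes$gene_id)

  # window cap: linked markers beyond 125 kb are excluded
  codes2 <- cbind(block, block, block)
  G2 <- toy_geno(codes2, pos = c(1e4, 2e4, 2e5))
  win2 <- candidate_gene_window("m1", G2,
                                data.frame(gene_id = "far", chrom = "chr1",
                                           start = 19e4, end = 21e4),
                                max_window = 250e3)
  expect_equal(nrow(win2$genes), 0)
  expect_error(candidate_gene_window("nope", G, genes), "not genotyped")
})
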