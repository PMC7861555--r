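# Synthetic data: structured selfing populations, polygenic traits, logistic
# growth experiments and loss-of-function matrices. The generator gives every
# downstream stage a ground truth to recover.

#' Configuration for the synthetic-data generator
#'
#' @param n_per_region Integer vector: number of selfing lines per region
#'   (its length sets the number of regions).
#' @param n_snps Number of SNP markers.
#' @param fst_target Target mean per-SNP Nei Fst among regions, in \[0, 1).
#'   The internal Balding-Nichols divergence parameter is calibrated so the
#'   realized estimator mean matches this value.
#' @param n_causal Number of causal SNPs for the polygenic trait.
#' @param causal_fst Optional divergence parameter for the causal loci only
#'   (NULL: causal loci drift like the background). Setting this above
#'   `fst_target` emulates divergent selection: the trait-determining loci
#'   are more differentiated among regions than the neutral background.
#' @param h2 Broad-sense heritability of the replicate-level trait, in (0, 1].
#' @param regional_shift Per-region additive shift of the genotypic value, in
#'   units of the (unshifted) genetic standard deviation. Recycled across
#'   regions; a scalar `s` expands to `c(s, 0, 0, ...)`.
#' @param n_reps Replicate phenotypes per genotype.
#' @param growth_truth List with entries `FS`, `slope`, `t50`, each
#'   `c(mean, genotypic_sd)`. Defaults mimic rosettes under a high-light
#'   regime: final size 8 (1) cm, rate constant 0.25 (0.03) per day,
#'   inflection 15 (1.5) days.
#' @param plant_sd List with per-plant biological SDs of `FS`, `slope`,
#'   `t50` (within-genotype variation between replicate plants, on top of
#'   measurement noise). Defaults give a broad-sense heritability of final
#'   size around 0.6, the magnitude seen in replicated rosette experiments.
#' @param measurement_days Days since sowing at which diameters are recorded.
#' @param noise_sd Measurement noise on diameters, cm.
#' @param block_sd,tray_sd SD of additive block and tray offsets, cm.
#' @param n_blocks Number of complete blocks (one replicate per genotype per
#'   block).
#' @param missing_rate Fraction of genotype calls set to missing.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_region = c(60, 60), n_snps = 2000,
                       fst_target = 0.1, n_causal = 40, causal_fst = NULL,
                       h2 = 0.6,
                       regional_shift = 0, n_reps = 3,
                       growth_truth = list(FS = c(8, 1), slope = c(0.25, 0.03),
                                           t50 = c(15, 1.5)),
                       plant_sd = list(FS = 0.8, slope = 0.02, t50 = 1),
                       measurement_days = c(11, 16, 21, 26, 31, 36, 41, 46),
                       noise_sd = 0.2, block_sd = 0.3, tray_sd = 0.15,
                       n_blocks = 3, missing_rate = 0, seed = 1L) {
  .assert(all(n_per_region > 0) && n_snps > 0 && n_causal > 0 && n_blocks > 0,
          "all counts must be positive")
  .assert(fst_target >= 0 && fst_target < 1, "fst_target must be in [0, 1)")
  .assert(is.null(causal_fst) || (causal_fst >= 0 && causal_fst < 1),
          "causal_fst must be in [0, 1)")
  .assert(h2 > 0 && h2 <= 1, "h2 must be in (0, 1]")
  .assert(n_causal <= n_snps, "n_causal cannot exceed n_snps")
  .assert(missing_rate >= 0 && missing_rate < 1, "missing_rate in [0, 1)")
  shift <- if (length(regional_shift) == 1L && regional_shift != 0)
    c(regional_shift, rep(0, length(n_per_region) - 1L))
  else rep_len(regional_shift, length(n_per_region))
  structure(list(n_per_region = as.integer(n_per_region), n_snps = n_snps,
                 fst_target = fst_target, n_causal = n_causal,
                 causal_fst = causal_fst, h2 = h2,
                 regional_shift = shift, n_reps = n_reps,
                 growth_truth = growth_truth, plant_sd = plant_sd,
                 measurement_days = measurement_days, noise_sd = noise_sd,
                 block_sd = block_sd, tray_sd = tray_sd, n_blocks = n_blocks,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

.bn_cache <- new.env(parent = emptyenv())

# Calibrate the Balding-Nichols divergence parameter so that the realized
# mean per-SNP Nei Fst (the estimator of per_snp_fst, including line
# sampling and the clamp at zero) matches the requested target. The mean of
# per-SNP ratio estimators sits well below the ratio of expectations, so
# the map is inverted by deterministic Monte Carlo: the expectation curve
# is evaluated on a fixed internal seed and root-found with uniroot.
.calibrate_bn <- function(target, n_per_region, B = 40000L) {
  key <- paste(signif(target, 6), paste(n_per_region, collapse = "_"))
  if (!is.null(.bn_cache[[key]])) return(.bn_cache[[key]])
  r <- length(n_per_region)
  realized <- function(f) {
    set.seed(20240101L)
    p <- stats::runif(B, 0.05, 0.95)
    ph <- nn <- matrix(0, r, B)
    for (k in seq_len(r)) {
      pk <- stats::rbeta(B, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      ph[k, ] <- stats::rbinom(B, n_per_region[k], pk) / n_per_region[k]
      nn[k, ] <- n_per_region[k]
    }
    hs <- colMeans(nn / (nn - 1) * 2 * ph * (1 - ph))
    pb <- colMeans(ph)
    ht <- 2 * pb * (1 - pb) + hs / (r * (r / colSums(1 / nn)))
    mean(ifelse(ht > 0, pmax(0, (ht - hs) / ht), 0))
  }
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, globalenv()), add = TRUE)
  upper <- min(0.98, max(0.5, 4 * target))
  f <- stats::uniroot(function(f) realized(f) - target,
                      lower = 1e-4, upper = upper, tol = 1e-4)$root
  .bn_cache[[key]] <- f
  f
}

#' Simulate structured genotypes for selfing lines
#'
#' Ancestral allele frequencies are drawn from Uniform(0.05, 0.95); regional
#' frequencies follow a Balding-Nichols Beta model whose divergence parameter
#' is calibrated so that the realized mean Nei Fst among regions matches
#' `fst_target` in expectation. Lines are fully homozygous (codes 0/2), as
#' in selfing accessions. Markers are laid out on 5 synthetic chromosomes.
#'
#' @param config A [sim_config].
#' @return A [geno_matrix] with region labels `R1`, `R2`, ...
#' @export
simulate_genotypes <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  r <- length(config$n_per_region)
  m <- config$n_snps
  t <- config$fst_target
  f_bn <- if (t == 0) 0 else .calibrate_bn(t, config$n_per_region)
  set.seed(stage_seed(config$seed, "genotypes"))
  p_anc <- stats::runif(m, 0.05, 0.95)
  freq <- matrix(NA_real_, r, m)
  for (k in seq_len(r)) {
    freq[k, ] <- if (f_bn == 0) p_anc else
      stats::rbeta(m, p_anc * (1 - f_bn) / f_bn,
                   (1 - p_anc) * (1 - f_bn) / f_bn)
  }
  causal_idx <- NULL
  if (!is.null(config$causal_fst) && config$causal_fst > 0) {
    f_c <- .calibrate_bn(config$causal_fst, config$n_per_region)
    causal_idx <- sort(sample.int(m, config$n_causal))
    for (k in seq_len(r)) {
      pc <- p_anc[causal_idx]
      freq[k, causal_idx] <- stats::rbeta(length(causal_idx),
                                          pc * (1 - f_c) / f_c,
                                          (1 - pc) * (1 - f_c) / f_c)
    }
  }
  n <- sum(config$n_per_region)
  codes <- matrix(NA_real_, n, m)
  regions <- rep(paste0("R", seq_len(r)), config$n_per_region)
  row0 <- 0L
  for (k in seq_len(r)) {
    nk <- config$n_per_region[k]
    codes[row0 + seq_len(nk), ] <-
      2 * matrix(stats::rbinom(nk * m, 1, rep(freq[k, ], each = nk)), nk, m)
    row0 <- row0 + nk
  }
  if (config$missing_rate > 0)
    codes[stats::runif(length(codes)) < config$missing_rate] <- NA
  n_chr <- 5L
  chrom <- paste0("chr", rep_len(seq_len(n_chr), m))
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(length(ix) * 5000L, length(ix)))), use.names = FALSE)
  map <- data.frame(marker = paste0("snp", seq_len(m)), chrom = chrom,
                    pos = pos)
  G <- geno_matrix(codes, map, lines = sprintf("L%03d", seq_len(n)),
                   regions = regions)
  if (!is.null(causal_idx))
    attr(G, "causal_candidates") <- paste0("snp", causal_idx)
  G
}

#' Simulate a polygenic trait with replicates
#'
#' Causal markers are sampled at random; effect sizes are Gaussian, rescaled
#' so the genotypic values have unit variance before the per-region shift is
#' added. Replicate phenotypes add environmental noise sized so the expected
#' broad-sense heritability equals `h2`.
#'
#' @param G A [geno_matrix] (missing calls are mean-imputed for the genetic
#'   value).
#' @param config A [sim_config].
#' @return List with `pheno` (lines x n_reps matrix), `geno_value` (the
#'   per-line genotypic value) and `truth` (list: `causal_ids`,
#'   `true_effects`, `true_genotypic_values`, `region_labels`).
#' @export
simulate_trait <- function(G, config) {
  .assert(config$n_causal <= ncol(G$codes), "n_causal exceeds marker count")
  set.seed(stage_seed(config$seed, "trait"))
  codes <- G$codes
  if (anyNA(codes)) {
    mu <- colMeans(codes, na.rm = TRUE)
    idx <- which(is.na(codes), arr.ind = TRUE)
    codes[idx] <- mu[idx[, 2]]
  }
  cand <- attr(G, "causal_candidates")
  causal <- if (!is.null(cand) && all(cand %in% colnames(codes)))
    sort(match(cand, colnames(codes)))
  else sort(sample.int(ncol(codes), config$n_causal))
  alpha <- stats::rnorm(length(causal))
  X <- codes[, causal, drop = FALSE]
  g <- drop(X %*% alpha)
  s <- stats::sd(g)
  if (s > 0) { alpha <- alpha / s; g <- g / s }
  shift <- config$regional_shift[match(G$regions,
                                       paste0("R", seq_along(config$regional_shift)))]
  shift[is.na(shift)] <- 0
  # Realize the regional shift through causal allele-frequency divergence
  # aligned with effect signs (true polygenic adaptation), falling back to
  # a constant genetic offset for any remainder the realized frequency
  # divergence cannot support (e.g. fst_target = 0).
  two_groups <- length(unique(shift)) == 2
  if (two_groups && any(shift != 0)) {
    hi <- shift == max(shift)
    target <- max(shift) - min(shift)
    u <- colMeans(X[hi, , drop = FALSE]) / 2 -
      colMeans(X[!hi, , drop = FALSE]) / 2
    if (sum(u^2) > 1e-8) {
      dstd <- function(gamma) {
        gg <- drop(X %*% (alpha + gamma * u))
        (mean(gg[hi]) - mean(gg[!hi])) / stats::sd(gg)
      }
      gmax <- 1
      while (gmax < 4096 && dstd(2 * gmax) > dstd(gmax) + 1e-6) gmax <- 2 * gmax
      if (dstd(0) >= target) {
        gam <- 0
      } else if (dstd(gmax) >= target) {
        gam <- stats::uniroot(function(x) dstd(x) - target, c(0, gmax),
                              tol = 1e-8)$root
      } else gam <- gmax
      alpha <- alpha + gam * u
      g <- drop(X %*% alpha)
      alpha <- alpha / stats::sd(g)
      g <- g / stats::sd(g)
      # residual constant offset for any unachievable remainder
      resid_shift <- target - (mean(g[hi]) - mean(g[!hi]))
      if (abs(resid_shift) > 1e-8) g <- g + ifelse(hi, resid_shift, 0)
      g <- g + min(shift)
    } else g <- g + shift
  } else g <- g + shift
  vg <- stats::var(g)
  .assert(vg > 0 || config$h2 == 0, "degenerate genotypic values")
  sde <- sqrt(vg * (1 - config$h2) / config$h2)
  n <- length(g)
  pheno <- matrix(g, n, config$n_reps) +
    matrix(stats::rnorm(n * config$n_reps, sd = sde), n, config$n_reps)
  rownames(pheno) <- G$lines
  colnames(pheno) <- paste0("rep", seq_len(config$n_reps))
  list(pheno = pheno, geno_value = stats::setNames(g, G$lines),
       truth = list(causal_ids = G$map$marker[causal], true_effects = alpha,
                    true_genotypic_values = stats::setNames(g, G$lines),
                    region_labels = G$regions))
}

#' Simulate a randomized-block growth experiment
#'
#' Each line's diameter trajectory follows the three-parameter logistic
#' `FS / (1 + exp(-slope (t - t50)))` at the configured measurement days,
#' plus additive block and tray offsets and Gaussian measurement noise.
#' Per-line true parameters combine the `growth_truth` population means with
#' genotypic deviations: the final-size deviation is the (standardized)
#' polygenic value in `truth`, slope and t50 deviations are independent.
#' The design is balanced, one replicate per genotype per block, with plants
#' arrayed on trays of 5 rows x 7 columns.
#'
#' @param truth Truth list from [simulate_trait()] (or any list with
#'   `true_genotypic_values`).
#' @param config A [sim_config].
#' @param regime Label stored in the output (`"HL"` by default).
#' @return List with `series` (long data frame: plant_id, genotype_id,
#'   regime, block, tray, row, col, day, diameter), `true_params` (per-plant
#'   FS, slope, t50 including biological deviations),
#'   `true_genotype_params` (genotypic values) and `block_effects`.
#' @export
simulate_growth_experiment <- function(truth, config, regime = "HL") {
  .assert(length(config$measurement_days) > 0, "measurement days empty")
  set.seed(stage_seed(config$seed, paste0("growth_", regime)))
  gv <- truth$true_genotypic_values
  n <- length(gv)
  ids <- names(gv) %||% sprintf("L%03d", seq_len(n))
  z_fs <- as.numeric(scale(gv))
  if (anyNA(z_fs)) z_fs <- rep(0, n)
  gt <- config$growth_truth
  fs <- pmax(gt$FS[1] + gt$FS[2] * z_fs, 0.5)
  sl <- pmax(gt$slope[1] + gt$slope[2] * stats::rnorm(n), 0.02)
  t50 <- pmax(gt$t50[1] + gt$t50[2] * stats::rnorm(n), 1)
  block_eff <- stats::rnorm(config$n_blocks, sd = config$block_sd)
  days <- config$measurement_days
  psd <- config$plant_sd %||% list(FS = 0, slope = 0, t50 = 0)
  out <- truth_rows <- vector("list", config$n_blocks)
  n_tray <- ceiling(n / 35)
  for (b in seq_len(config$n_blocks)) {
    ord <- sample.int(n)            # randomize positions within the block
    slot <- order(ord)              # slot[i] = position of genotype i
    tray <- (slot - 1L) %/% 35L + 1L
    within <- (slot - 1L) %% 35L
    row <- within %/% 7L + 1L
    col <- within %% 7L + 1L
    tray_eff <- stats::rnorm(n_tray, sd = config$tray_sd)
    # per-plant biological deviations around the genotypic parameters
    fs_b <- pmax(fs + stats::rnorm(n, sd = psd$FS), 0.5)
    sl_b <- pmax(sl + stats::rnorm(n, sd = psd$slope), 0.02)
    t50_b <- pmax(t50 + stats::rnorm(n, sd = psd$t50), 1)
    d <- outer(fs_b, rep(1, length(days))) /
      (1 + exp(-outer(sl_b, rep(1, length(days))) *
                 (outer(rep(1, n), days) - outer(t50_b, rep(1, length(days))))))
    d <- d + block_eff[b] + tray_eff[tray] +
      matrix(stats::rnorm(n * length(days), sd = config$noise_sd), n)
    d <- pmax(d, 0)
    out[[b]] <- data.frame(
      plant_id = paste0(ids, "_b", b), genotype_id = rep(ids, length(days)),
      regime = regime, block = b, tray = rep(tray, length(days)),
      row = rep(row, length(days)), col = rep(col, length(days)),
      day = rep(days, each = n), diameter = as.vector(d))
    truth_rows[[b]] <- data.frame(plant_id = paste0(ids, "_b", b),
                                  genotype_id = ids, block = b, FS = fs_b,
                                  slope = sl_b, t50 = t50_b)
  }
  series <- do.call(rbind, out)
  rownames(series) <- NULL
  list(series = series,
       true_params = do.call(rbind, truth_rows),
       true_genotype_params = data.frame(genotype_id = ids, FS = fs,
                                         slope = sl, t50 = t50),
       block_effects = block_eff)
}

#' Simulate a loss-of-function gene-state matrix
#'
#' Generates a binary gene x genotype matrix of LOF states with per-gene
#' carrier frequency `freq`. One designated gene's LOF state shifts a trait
#' by `effect`.
#'
#' @param G A [geno_matrix] (supplies line ids).
#' @param n_genes Number of genes.
#' @param freq LOF carrier frequency, in (0, 1).
#' @param effect Trait shift for carriers of the designated gene's LOF
#'   allele (0 for a pure null).
#' @param seed Integer seed.
#' @param baseline Optional baseline trait per line; standard normal noise
#'   by default.
#' @return List with `lof` (genes x genotypes 0/1 matrix), `trait` (named
#'   per-line phenotype) and `causal_gene`.
#' @export
simulate_lof <- function(G, n_genes = 100, freq = 0.15, effect = 0,
                         seed = 1L, baseline = NULL) {
  .assert(n_genes > 0, "n_genes must be positive")
  .assert(freq > 0 && freq < 1, "freq must be in (0, 1)")
  set.seed(stage_seed(seed, "lof"))
  n <- length(G$lines)
  lof <- matrix(stats::rbinom(n_genes * n, 1, freq), n_genes, n,
                dimnames = list(paste0("gene", seq_len(n_genes)), G$lines))
  causal <- paste0("gene", max(1L, n_genes %/% 2L))
  trait <- (baseline %||% stats::rnorm(n)) + effect * lof[causal, ]
  list(lof = lof, trait = stats::setNames(trait, G$lines),
       causal_gene = causal)
}

#' Simulate gene models and a GO annotation over a marker map
#'
#' Tiles non-overlapping genes along the simulated chromosomes and draws a
#' random gene-to-term annotation (each gene annotated to `terms_per_gene`
#' terms on average). Used to exercise the gene-level stages end to end.
#'
#' @param G A [geno_matrix] whose map defines the chromosomes.
#' @param n_genes Number of genes.
#' @param n_terms Number of GO-like terms.
#' @param terms_per_gene Mean annotations per gene.
#' @param gene_length Gene length in bp.
#' @param seed Integer seed.
#' @return List: `genes` (`gene_id`, `chrom`, `start`, `end`) and
#'   `annotation` (`gene_id`, `term`).
#' @export
simulate_gene_models <- function(G, n_genes = 250, n_terms = 20,
                                 terms_per_gene = 2, gene_length = 2000,
                                 seed = 1L) {
  set.seed(stage_seed(seed, "genes"))
  chrs <- unique(G$map$chrom)
  span <- lapply(chrs, function(ch) range(G$map$pos[G$map$chrom == ch]))
  names(span) <- chrs
  per_chr <- diff(seq(0, n_genes, length.out = length(chrs) + 1))
  per_chr <- diff(round(seq(0, n_genes, length.out = length(chrs) + 1)))
  rows <- list()
  g <- 0L
  for (i in seq_along(chrs)) {
    k <- per_chr[i]
    if (k <= 0) next
    lo <- span[[i]][1]; hi <- max(span[[i]][2], lo + (gene_length + 500) * k)
    starts <- sort(sample.int(hi - lo - gene_length, k)) + lo
    # enforce non-overlap by spreading collisions
    starts <- starts + (seq_len(k) - 1)
    rows[[i]] <- data.frame(gene_id = sprintf("g%04d", g + seq_len(k)),
                            chrom = chrs[i], start = starts,
                            end = starts + gene_length - 1L)
    g <- g + k
  }
  genes <- do.call(rbind, rows)
  n_ann <- stats::rpois(nrow(genes), terms_per_gene)
  ann <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    if (n_ann[i] == 0) return(NULL)
    data.frame(gene_id = genes$gene_id[i],
               term = paste0("GO:", sprintf("%07d",
                                            sample.int(n_terms, min(n_ann[i], n_terms)))))
  }))
  list(genes = genes, annotation = ann)
}

#' Write a phenotype CSV in the raw-measurement layout
#'
#' Wide layout with one row per plant: genotype, block, tray, row, col and
#' one `diam<day>` column per measurement day.
#'
#' @param series Long data frame from [simulate_growth_experiment()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_pheno_csv <- function(series, path) {
  wide <- stats::reshape(
    series[, c("plant_id", "genotype_id", "block", "tray", "row", "col",
               "day", "diameter")],
    idvar = c("plant_id", "genotype_id", "block", "tray", "row", "col"),
    timevar = "day", direction = "wide")
  names(wide) <- sub("^diameter\\.", "diam", names(wide))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype CSV in the raw-measurement layout
#'
#' Inverse of [write_pheno_csv()]: expects columns `plant_id` (or builds one
#' from genotype and block), `genotype_id`, `block`, `tray`, `row`, `col`
#' and `diam<day>` columns.
#'
#' @param path CSV path.
#' @return Long data frame with one row per plant x day.
#' @export
read_pheno_csv <- function(path) {
  wide <- utils::read.csv(path, check.names = FALSE)
  diam_cols <- grep("^diam[0-9]+$", names(wide), value = TRUE)
  .assert(length(diam_cols) > 0, "no diam<day> columns found")
  if (is.null(wide$plant_id))
    wide$plant_id <- paste0(wide$genotype_id, "_b", wide$block)
  long <- stats::reshape(wide, varying = diam_cols, v.names = "diameter",
                         times = as.integer(sub("^diam", "", diam_cols)),
                         timevar = "day", direction = "long")
  long <- long[!is.na(long$diameter),
               c("plant_id", "genotype_id", "block", "tray", "row", "col",
                 "day", "diameter")]
  long <- long[order(long$plant_id, long$day), ]
  rownames(long) <- NULL
  long
}

#' Write a loss-of-function matrix as TSV
#'
#' @param lof Binary genes x genotypes matrix.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_lof_tsv <- function(lof, path) {
  utils::write.table(data.frame(gene = rownames(lof), lof,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
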