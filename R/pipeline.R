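# Pipeline orchestration: configuration, stage order, reporting.

#' Pipeline configuration
#'
#' Bundles input paths (or a synthetic-data configuration), analysis
#' thresholds and resampling counts. Thresholds default to the standard
#' values of the analysis: 5% MAF, 5% missingness, association thresholds
#' 1e-4 (index) and 0.01 (secondary), 1 Mb clump window, 250 kb LD window,
#' 10 kb gene window, 1000 permutations / random sets and 10000
#' Fst resamples / MVN simulations.
#'
#' @param sim A [sim_config] for a synthetic run, or NULL when paths are
#'   given.
#' @param paths Named list of input files (`pheno_csv`, `geno`,
#'   `geno_format`, `gff`, `go`, `lof`); ignored when `sim` is given.
#' @param maf_min,max_missing Marker filters.
#' @param p_index,p_secondary,r2 Clumping parameters.
#' @param clump_window,ld_window,gene_window Window sizes in bp.
#' @param n_perm,n_sims,n_random_sets,n_resamples Resampling counts.
#' @param seed Global seed, expanded into per-stage seeds via [stage_seed()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            maf_min = 0.05, max_missing = 0.05,
                            p_index = 1e-4, p_secondary = 0.01, r2 = 0.5,
                            clump_window = 1e6, ld_window = 250e3,
                            gene_window = 10e3, n_perm = 1000,
                            n_sims = 10000, n_random_sets = 1000,
                            n_resamples = 10000, seed = 1L) {
  .assert(maf_min >= 0 && maf_min <= 0.5, "maf_min must be in [0, 0.5]")
  .assert(max_missing >= 0 && max_missing <= 1, "max_missing in [0, 1]")
  .assert(p_index > 0 && p_index < 1 && p_secondary > 0 && p_secondary < 1,
          "association thresholds must be in (0, 1)")
  .assert(r2 >= 0 && r2 <= 1, "r2 must be in [0, 1]")
  .assert(all(c(n_perm, n_sims, n_random_sets, n_resamples) > 0),
          "resampling counts must be positive")
  if (!is.null(paths)) {
    missing_files <- unlist(paths[vapply(paths, is.character, TRUE)])
    missing_files <- missing_files[!file.exists(missing_files) &
                                     !names(paths) %in% "geno_format"]
    .assert(length(missing_files) == 0,
            paste("input file(s) not found:",
                  paste(missing_files, collapse = ", ")))
  }
  structure(list(sim = sim, paths = paths, maf_min = maf_min,
                 max_missing = max_missing, p_index = p_index,
                 p_secondary = p_secondary, r2 = r2,
                 clump_window = clump_window, ld_window = ld_window,
                 gene_window = gene_window, n_perm = n_perm,
                 n_sims = n_sims, n_random_sets = n_random_sets,
                 n_resamples = n_resamples, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Small stable hash for provenance (FNV-1a over the serialized object).
.config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL))
  h <- 2166136261
  for (v in b) h <- (bitwXor(as.integer(h %% 2^31), v) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stage order growth-curve fitting -> genotypic means, GxE and
#' heritability -> marker filtering, kinship and mixed-model GWAS -> Fst,
#' LOF burden and regional contrasts -> clumping, polygenic scores and Qx
#' -> Qst with permutation and MVN nulls -> gene scores and GO enrichment,
#' and collects every stage output in a run report. The synthetic inputs
#' are generated from `config$sim` (two light regimes; the low-light trial
#' uses a larger final size, a delayed inflection and a slower rate, the
#' classic shade response).
#'
#' @param config A [pipeline_config].
#' @param out_dir Optional directory; when given, stage tables (TSV) and a
#'   JSON summary are written there.
#' @param quiet Suppress progress messages.
#' @return List of class `run_report`; see components in the details.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  .assert(inherits(config, "pipeline_config"), "config must validate")
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  .assert(is.null(config$paths) && !is.null(config$sim),
          "file-based runs are assembled from the module functions; run_pipeline drives the synthetic study")
  sim <- config$sim

  say("stage 1/7: synthetic inputs")
  G <- simulate_genotypes(sim)
  trait <- simulate_trait(G, sim)
  hl <- simulate_growth_experiment(trait$truth, sim, regime = "HL")
  sim_ll <- sim
  sim_ll$growth_truth <- list(
    FS = c(sim$growth_truth$FS[1] * 1.45, sim$growth_truth$FS[2] * 1.2),
    slope = c(sim$growth_truth$slope[1] * 0.55, sim$growth_truth$slope[2] * 0.6),
    t50 = c(sim$growth_truth$t50[1] + 22, sim$growth_truth$t50[2] * 1.3))
  sim_ll$measurement_days <- c(24, 33, 42, 51, 60, 70, 80, 89)
  ll <- simulate_growth_experiment(trait$truth, sim_ll, regime = "LL")
  ann <- simulate_gene_models(G, seed = sim$seed)
  lof_sim <- simulate_lof(G, n_genes = 100, freq = 0.15, effect = -1.5,
                          seed = sim$seed,
                          baseline = trait$truth$true_genotypic_values)

  say("stage 2/7: growth-curve fits, genotypic means, GxE, heritability")
  fits_hl <- fit_growth_curves(hl$series)
  fits_ll <- fit_growth_curves(ll$series)
  means <- list()
  for (p in c("FS", "slope", "t50")) {
    means[[paste0(p, "_HL")]] <- genotypic_means(fits_hl, p)
    means[[paste0(p, "_LL")]] <- genotypic_means(fits_ll, p)
  }
  gxe_fs <- gxe_residuals(means$FS_HL, means$FS_LL)
  h2 <- list(
    FS_HL = broad_sense_h2(data.frame(genotype_id = fits_hl$genotype_id,
                                      block = fits_hl$block,
                                      value = fits_hl$FS)),
    FS_LL = broad_sense_h2(data.frame(genotype_id = fits_ll$genotype_id,
                                      block = fits_ll$block,
                                      value = fits_ll$FS)))

  say("stage 3/7: filtering, kinship, mixed-model GWAS")
  Gf <- filter_markers(G, config$maf_min, config$max_missing)
  K <- compute_kinship(Gf)
  y <- stats::setNames(means$FS_HL$mean, means$FS_HL$genotype_id)[Gf$lines]
  assoc <- mixed_gwas(y, Gf, K)

  say("stage 4/7: Fst, LOF burden, regional contrasts")
  regions <- stats::setNames(Gf$regions, Gf$lines)
  fst <- per_snp_fst(Gf)
  fst95 <- stats::quantile(fst$fst, 0.95, na.rm = TRUE, names = FALSE)
  hits <- assoc$marker[!is.na(assoc$p) & assoc$p < config$p_index]
  fst_hits <- if (length(hits) >= 2)
    fst_set_test(fst, hits, n_resamples = config$n_resamples,
                 seed = stage_seed(sim$seed, "fstset")) else NULL
  burden <- lof_burden_test(lof_sim$lof, lof_sim$trait)
  lof_assoc <- lof_gwas(lof_sim$trait[Gf$lines],
                        lof_sim$lof[, Gf$lines, drop = FALSE], K,
                        maf_min = config$maf_min)
  regional <- region_compare(means$FS_HL,
                             stats::setNames(G$regions, G$lines))

  say("stage 5/7: clumping, polygenic scores, Qx")
  cl <- ld_clump(assoc, Gf, p_index = config$p_index,
                 window = config$clump_window,
                 p_secondary = config$p_secondary, r2 = config$r2)
  qx <- NULL
  if (nrow(cl$index) >= 1) {
    fr <- unit_freqs(Gf, markers = cl$index$marker)
    Fdrift <- drift_covariance(Gf)
    qx <- qx_test(cl$index$effect, fr, Fdrift, G = Gf,
                  n_null = config$n_random_sets,
                  seed = stage_seed(sim$seed, "qx"))
  }
  # replicate-level FS phenotypes (one column per block) for validation
  pheno_rep <- do.call(cbind, lapply(sort(unique(fits_hl$block)), function(b) {
    v <- fits_hl[fits_hl$block == b, ]
    stats::setNames(v$FS, v$genotype_id)[Gf$lines]
  }))
  val <- tryCatch(
    validate_scores(pheno_rep, Gf, K, scheme = "replicate_cv",
                    p_index = config$p_index,
                    seed = stage_seed(sim$seed, "validate")),
    error = function(e) list(scheme = "replicate_cv", rho = NA_real_,
                             p = NA_real_, error = conditionMessage(e)))

  say("stage 6/7: Qst, permutation and MVN nulls")
  qst <- estimate_qst(means$FS_HL, regions)
  qst_pct <- qst_vs_fst(qst$qst, fst)
  qst_perm <- qst_permutation(means$FS_HL, regions, fst95,
                              n_perm = config$n_perm,
                              seed = stage_seed(sim$seed, "perm"))
  mvn <- qst_mvn_null(K, regions, Vg = stats::var(means$FS_HL$mean),
                      n_sims = config$n_sims, observed_qst = qst$qst,
                      seed = stage_seed(sim$seed, "mvn"))

  say("stage 7/7: gene scores and GO enrichment")
  gene_scores <- assign_gene_scores(assoc, ann$genes)
  cand <- unique(unlist(lapply(which(!is.na(assoc$p) &
                                       assoc$p < config$p_index), function(j) {
    sel <- ann$genes$chrom == assoc$chrom[j] &
      ann$genes$start - config$gene_window <= assoc$pos[j] &
      ann$genes$end + config$gene_window >= assoc$pos[j]
    ann$genes$gene_id[sel]
  })))
  enrich <- if (length(cand) >= 1)
    tryCatch(go_fisher(cand, ann$genes$gene_id, ann$annotation),
             error = function(e) NULL) else NULL
  thr <- if (length(cand) >= 1)
    permutation_threshold(ann$genes$gene_id, ann$annotation,
                          set_size = length(cand),
                          n_sets = config$n_random_sets,
                          seed = stage_seed(sim$seed, "gothr")) else NULL

  report <- structure(list(
    provenance = list(config_hash = .config_hash(config), seed = sim$seed,
                      package_version = as.character(
                        utils::packageVersion("polygrowth")),
                      elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                      units = "secs"))),
    genotypes = list(n_lines = nrow(G$codes), n_snps_total = ncol(G$codes),
                     n_snps_filtered = ncol(Gf$codes)),
    truth = trait$truth,
    means = means, gxe_fs = gxe_fs, h2 = h2,
    assoc = assoc, kinship = K,
    fst = fst, fst95 = fst95, fst_hits = fst_hits,
    burden = burden, lof_assoc = lof_assoc, regional = regional,
    clumps = cl, qx = qx, validation = val,
    qst = qst, qst_percentile = qst_pct, qst_perm = qst_perm,
    qst_mvn = mvn,
    gene_scores = gene_scores, enrichment = enrich,
    enrichment_threshold = thr), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("polygrowth run report\n")
  cat(sprintf("  lines: %d  SNPs: %d (filtered %d)\n",
              x$genotypes$n_lines, x$genotypes$n_snps_total,
              x$genotypes$n_snps_filtered))
  cat(sprintf("  H2 FS (HL): %.3f   pseudo-h2: %.3f\n", x$h2$FS_HL$h2,
              attr(x$assoc, "pseudo_h2")))
  cat(sprintf("  Qst = %.3f (Fst percentile %.1f, perm p = %.3g, MVN p = %.3g)\n",
              x$qst$qst, x$qst_percentile$percentile, x$qst_perm$p_perm,
              x$qst_mvn$p))
  if (!is.null(x$qx))
    cat(sprintf("  Qx = %.2f on %d df (p_chi2 = %.3g, p_emp = %.3g)\n",
                x$qx$qx, x$qx$df, x$qx$p_chi2, x$qx$p_empirical))
  invisible(x)
}

#' Write the run report to disk
#'
#' Writes the main stage tables as TSV and a JSON summary of the scalar
#' results.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the JSON path.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(report$assoc, "association.tsv")
  wt(report$fst, "fst.tsv")
  for (nm in names(report$means))
    wt(report$means[[nm]], paste0("means_", nm, ".tsv"))
  if (!is.null(report$enrichment)) wt(report$enrichment, "enrichment.tsv")
  summary <- list(
    provenance = report$provenance,
    h2_fs_hl = report$h2$FS_HL$h2, h2_fs_ll = report$h2$FS_LL$h2,
    pseudo_h2 = attr(report$assoc, "pseudo_h2"),
    n_snps_filtered = report$genotypes$n_snps_filtered,
    fst95 = report$fst95,
    qst = report$qst$qst,
    qst_fst_percentile = report$qst_percentile$percentile,
    qst_perm_p = report$qst_perm$p_perm,
    qst_mvn_p = report$qst_mvn$p,
    qx = report$qx$qx %||% NA, qx_p_chi2 = report$qx$p_chi2 %||% NA,
    qx_p_empirical = report$qx$p_empirical %||% NA,
    validation_rho = report$validation$rho,
    burden_rho = report$burden$rho, burden_p = report$burden$p,
    enrichment_threshold = report$enrichment_threshold$threshold %||% NA)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
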