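# Per-SNP and per-gene Fst, random-set differentiation tests, LOF burden
# and regional trait contrasts.
#
# Fst is the Nei-style 1 - Hs/Ht with sample-size-corrected heterozygosities.
# Lines are treated as haploid-equivalent (selfers): a line contributes
# code/2 to the allele frequency, so heterozygous calls count one half.

# Per-marker Hs/Ht components for a set of region labels.
.fst_components <- function(G, pops) {
  regions <- pops %||% G$regions
  .assert(!is.null(regions), "region labels required")
  lev <- unique(regions[!is.na(regions)])
  r <- length(lev)
  .assert(r >= 2, "need at least two populations")
  m <- ncol(G$codes)
  p <- n <- matrix(NA_real_, r, m)
  for (k in seq_len(r)) {
    rows <- which(regions == lev[k])
    sub <- G$codes[rows, , drop = FALSE] / 2
    p[k, ] <- colMeans(sub, na.rm = TRUE)
    n[k, ] <- colSums(!is.na(sub))
  }
  valid <- colSums(n >= 2) == r
  hs_k <- n / (n - 1) * 2 * p * (1 - p)
  hs <- colMeans(hs_k)
  pbar <- colMeans(p)
  ntil <- r / colSums(1 / n)                   # harmonic mean sample size
  ht <- 2 * pbar * (1 - pbar) + hs / (ntil * r)
  hs[!valid] <- NA; ht[!valid] <- NA
  list(hs = hs, ht = ht, pops = lev)
}

#' Per-SNP Fst between populations
#'
#' Nei estimator `Fst = 1 - Hs/Ht` with sample-size-corrected within- and
#' total heterozygosity (Nei & Chesser correction, haploid-equivalent
#' sample sizes). Negative values are set to zero. Markers monomorphic in
#' all populations get Fst 0; markers with fewer than two non-missing lines
#' in a population get NA.
#'
#' @param G A [geno_matrix].
#' @param pops Per-line population labels (default: `G$regions`).
#' @return Data frame: `marker`, `chrom`, `pos`, `fst`, `hs`, `ht`;
#'   attribute `pops` lists the populations compared.
#' @export
per_snp_fst <- function(G, pops = NULL) {
  cmp <- .fst_components(G, pops)
  fst <- ifelse(cmp$ht > 0, pmax(0, (cmp$ht - cmp$hs) / cmp$ht), 0)
  fst[is.na(cmp$ht)] <- NA
  out <- data.frame(marker = G$map$marker, chrom = G$map$chrom,
                    pos = G$map$pos, fst = fst, hs = cmp$hs, ht = cmp$ht)
  attr(out, "pops") <- cmp$pops
  out
}

#' Per-gene Fst over SNPs in gene intervals
#'
#' Multi-SNP genes are aggregated by ratio of sums,
#' `sum(Ht - Hs) / sum(Ht)` over the SNPs inside the interval (1-based
#' inclusive), with negatives clamped to zero. A single-SNP gene equals the
#' per-SNP value. Genes without SNPs get NA; a gene on a chromosome absent
#' from the marker map is an error.
#'
#' @param G A [geno_matrix].
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (e.g. from [read_gff_genes()]).
#' @param pops Per-line population labels (default: `G$regions`).
#' @return Data frame: `gene_id`, `chrom`, `n_snps`, `fst`.
#' @export
per_gene_fst <- function(G, genes, pops = NULL) {
  .assert(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
          "genes needs gene_id, chrom, start, end")
  missing_chr <- setdiff(unique(genes$chrom), unique(G$map$chrom))
  if (length(missing_chr))
    stop("gene chromosome(s) absent from marker map: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  cmp <- .fst_components(G, pops)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    n_snps = 0L, fst = NA_real_)
  for (i in seq_len(nrow(genes))) {
    in_gene <- G$map$chrom == genes$chrom[i] &
      G$map$pos >= genes$start[i] & G$map$pos <= genes$end[i]
    in_gene <- in_gene & !is.na(cmp$ht)
    out$n_snps[i] <- sum(in_gene)
    if (any(in_gene)) {
      num <- sum(cmp$ht[in_gene] - cmp$hs[in_gene])
      den <- sum(cmp$ht[in_gene])
      out$fst[i] <- if (den > 0) max(0, num / den) else 0
    }
  }
  out
}

#' Differentiation test for a marker set against the genome-wide background
#'
#' Compares the Fst distribution of a hit set to the genome-wide
#' distribution with a Kolmogorov-Smirnov test, and computes an exceedance
#' p-value: the fraction of `n_resamples` random equally-sized marker sets
#' whose 95th percentile is at least the hit set's 95th percentile
#' (with the +1 correction, so p is in `[1/(n+1), 1]`).
#'
#' @param fst Data frame from [per_snp_fst()] (genome-wide).
#' @param hit_ids Marker ids of the hit set (must be a subset).
#' @param n_resamples Number of random sets (default 10000).
#' @param seed Integer seed.
#' @return List: `ks_p`, `exceedance_p`, `hit_q95`, `null_q95` (vector).
#' @export
fst_set_test <- function(fst, hit_ids, n_resamples = 10000, seed = 1L) {
  .assert(length(hit_ids) > 0, "hit set is empty")
  .assert(n_resamples > 0, "n_resamples must be positive")
  vals <- fst$fst[!is.na(fst$fst)]
  ids <- fst$marker[!is.na(fst$fst)]
  .assert(all(hit_ids %in% ids), "hit set must be a subset of the Fst table")
  hit <- fst$fst[match(hit_ids, fst$marker)]
  ks <- suppressWarnings(stats::ks.test(hit, vals))
  set.seed(stage_seed(seed, "fst_set_test"))
  k <- length(hit)
  q95 <- stats::quantile(hit, 0.95, names = FALSE)
  null95 <- replicate(n_resamples,
                      stats::quantile(sample(vals, k), 0.95, names = FALSE))
  list(ks_p = ks$p.value,
       exceedance_p = (1 + sum(null95 >= q95)) / (n_resamples + 1),
       hit_q95 = q95, null_q95 = null95)
}

#' Loss-of-function burden versus phenotype
#'
#' The burden is each line's count of LOF gene states; association with the
#' phenotype is tested by Spearman rank correlation (two-sided).
#'
#' @param lof Binary genes x genotypes matrix.
#' @param phenotype Per-genotype phenotype, aligned with `lof` columns (or
#'   named, in which case names are matched).
#' @return List: `burden` (named counts), `rho`, `p`.
#' @export
lof_burden_test <- function(lof, phenotype) {
  burden <- colSums(lof)
  if (!is.null(names(phenotype)) && !is.null(colnames(lof))) {
    common <- intersect(colnames(lof), names(phenotype))
    .assert(length(common) >= 3, "fewer than 3 genotypes matched")
    burden <- burden[common]; phenotype <- phenotype[common]
  }
  .assert(length(burden) == length(phenotype), "lines not matched")
  .assert(stats::var(burden) > 0, "burden has zero variance")
  ct <- suppressWarnings(stats::cor.test(burden, phenotype,
                                         method = "spearman"))
  list(burden = burden, rho = unname(ct$estimate), p = ct$p.value)
}

#' Compare trait means among regions
#'
#' Linear model `mean ~ region` with all pairwise contrasts, single-step
#' (Tukey-style) family-wise adjustment via `multcomp::glht`, and a compact
#' letter display. Regions with fewer than two genotypes are excluded with
#' a warning.
#'
#' @param means Data frame from [genotypic_means()] (columns `genotype_id`,
#'   `mean`).
#' @param regions Per-genotype region labels: a named vector, or a data
#'   frame with columns `genotype_id` and `region`.
#' @return List: `group_means` (data frame), `contrasts` (estimate, z,
#'   adjusted p per pair), `letters` (compact letter display), `fit`.
#' @export
region_compare <- function(means, regions) {
  if (is.data.frame(regions))
    regions <- stats::setNames(regions$region, regions$genotype_id)
  d <- data.frame(genotype_id = means$genotype_id, y = means$mean,
                  region = as.character(regions[means$genotype_id]))
  d <- d[!is.na(d$region) & is.finite(d$y), ]
  cnt <- table(d$region)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning("region(s) with a single genotype excluded: ",
            paste(small, collapse = ", "))
    d <- d[!d$region %in% small, ]
  }
  .assert(length(unique(d$region)) >= 2, "need at least two regions")
  d$region <- factor(d$region)
  fit <- stats::glm(y ~ region, data = d, family = stats::gaussian())
  gh <- multcomp::glht(fit, linfct = multcomp::mcp(region = "Tukey"))
  sm <- summary(gh)
  contrasts <- data.frame(contrast = names(sm$test$coefficients),
                          estimate = unname(sm$test$coefficients),
                          z = unname(sm$test$tstat),
                          p_adj = unname(sm$test$pvalues))
  letters <- multcomp::cld(gh)$mcletters$Letters
  gm <- stats::aggregate(y ~ region, d, mean)
  names(gm) <- c("region", "mean")
  gm$n <- as.vector(cnt[as.character(gm$region)])
  list(group_means = gm, contrasts = contrasts, letters = letters, fit = fit)
}

#' Read gene intervals from a GFF3 file
#'
#' Imports gene features (1-based inclusive coordinates) via `rtracklayer`.
#'
#' @param path GFF3 file path.
#' @param feature Feature type to keep (default `"gene"`).
#' @return Data frame: `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gff_genes <- function(path, feature = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  g <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  g <- g[as.character(g$type) == feature, ]
  id <- g$ID %||% g$Name
  if (is.null(id)) id <- paste0("gene", seq_len(nrow(g)))
  data.frame(gene_id = as.character(id), chrom = as.character(g$seqnames),
             start = g$start, end = g$end)
}
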