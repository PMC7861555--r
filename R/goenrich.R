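# Gene-level association scores, tandem-duplicate pruning, GO enrichment
# (Fisher and rank-based KS), permutation-calibrated significance threshold
# and LD-defined candidate gene windows.

#' Assign an association p-value to every gene
#'
#' Each gene receives the lowest p-value among SNPs lying inside the gene
#' (1-based inclusive); a gene without internal SNPs receives the p-value of
#' the physically closest SNP, measured from the gene midpoint, with
#' distance ties broken toward the smaller p. Genes on chromosomes absent
#' from the association table are skipped with a warning.
#'
#' @param assoc Association table from [mixed_gwas()] (rows with NA p are
#'   ignored).
#' @param genes Gene intervals: data frame with `gene_id`, `chrom`, `start`,
#'   `end`.
#' @return Data frame: `gene_id`, `p`, `marker` (source SNP), `distance`
#'   (bp; 0 for internal SNPs). Every retained gene appears exactly once.
#' @export
assign_gene_scores <- function(assoc, genes) {
  a <- assoc[!is.na(assoc$p), ]
  skip <- !genes$chrom %in% unique(a$chrom)
  if (any(skip))
    warning(sum(skip), " gene(s) on chromosomes without SNPs skipped")
  genes <- genes[!skip, , drop = FALSE]
  out <- data.frame(gene_id = genes$gene_id, p = NA_real_,
                    marker = NA_character_, distance = NA_real_)
  by_chr <- split(seq_len(nrow(a)), a$chrom)
  for (i in seq_len(nrow(genes))) {
    rows <- by_chr[[genes$chrom[i]]]
    inside <- rows[a$pos[rows] >= genes$start[i] &
                     a$pos[rows] <= genes$end[i]]
    if (length(inside)) {
      j <- inside[which.min(a$p[inside])]
      out$p[i] <- a$p[j]; out$marker[i] <- a$marker[j]; out$distance[i] <- 0
    } else {
      mid <- (genes$start[i] + genes$end[i]) / 2
      dd <- abs(a$pos[rows] - mid)
      near <- rows[dd == min(dd)]
      j <- near[which.min(a$p[near])]
      out$p[i] <- a$p[j]; out$marker[i] <- a$marker[j]
      out$distance[i] <- abs(a$pos[j] - mid)
    }
  }
  out
}

#' Prune tandem duplicated genes
#'
#' Given precomputed all-vs-all similarity pairs (alignment e-values), genes
#' are considered tandem duplicates when their e-value is below `e_cut` and
#' they lie fewer than `max_rank_dist` genes apart on the same chromosome
#' (rank order along the chromosome). The downstream member of each
#' qualifying pair is removed; removal is iterated to a fixed point, so the
#' operation is idempotent and independent of input order.
#'
#' @param genes Gene intervals ordered along the genome (`gene_id`, `chrom`,
#'   `start`, `end`).
#' @param pairs Data frame of similarity pairs: `gene1`, `gene2`, `evalue`.
#' @param e_cut E-value threshold (default 1e-30).
#' @param max_rank_dist Maximum gene-rank distance (default 10, exclusive).
#' @return The pruned `genes` data frame.
#' @export
prune_tandem_duplicates <- function(genes, pairs, e_cut = 1e-30,
                                    max_rank_dist = 10) {
  if (is.null(pairs) || nrow(pairs) == 0) return(genes)
  sig <- pairs[pairs$evalue < e_cut, , drop = FALSE]
  if (nrow(sig) == 0) return(genes)
  cur <- genes
  repeat {
    ord <- order(cur$chrom, cur$start, cur$gene_id)
    cur <- cur[ord, , drop = FALSE]
    rank <- stats::ave(seq_len(nrow(cur)), cur$chrom, FUN = seq_along)
    info <- stats::setNames(seq_len(nrow(cur)), cur$gene_id)
    drop_ids <- character(0)
    for (k in seq_len(nrow(sig))) {
      i <- info[sig$gene1[k]]; j <- info[sig$gene2[k]]
      if (is.na(i) || is.na(j)) next
      if (cur$chrom[i] != cur$chrom[j]) next
      if (abs(rank[i] - rank[j]) >= max_rank_dist) next
      down <- if (cur$start[i] > cur$start[j] ||
                  (cur$start[i] == cur$start[j] &&
                     cur$gene_id[i] > cur$gene_id[j])) i else j
      drop_ids <- c(drop_ids, cur$gene_id[down])
    }
    if (!length(drop_ids)) break
    cur <- cur[!cur$gene_id %in% drop_ids, , drop = FALSE]
  }
  rownames(cur) <- NULL
  cur
}

#' GO over-representation test (one-sided Fisher)
#'
#' One-sided hypergeometric (Fisher exact) test per GO term on the 2x2
#' candidate x term table. Terms annotated to `min_genes` or fewer genes in
#' the universe are suppressed from the report.
#'
#' @param candidates Candidate gene ids (subset of `universe`).
#' @param universe All scored gene ids.
#' @param annotation Data frame mapping `gene_id` to `term` (optionally a
#'   `term_name` column).
#' @param min_genes Report only terms with more than this many annotated
#'   genes (default 5).
#' @return Data frame: `term`, `term_name`, `n_annotated`, `n_candidate`,
#'   `n_expected`, `p`, `test`; sorted by p.
#' @export
go_fisher <- function(candidates, universe, annotation, min_genes = 5) {
  .assert(length(candidates) > 0, "empty candidate set")
  .assert(all(candidates %in% universe),
          "candidates must be a subset of the universe")
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  terms <- split(ann$gene_id, ann$term)
  nm <- if (!is.null(annotation$term_name))
    stats::setNames(annotation$term_name, annotation$term) else NULL
  N <- length(unique(universe)); n <- length(unique(candidates))
  rows <- lapply(names(terms), function(tm) {
    tg <- unique(terms[[tm]])
    K <- length(tg)
    if (K <= min_genes) return(NULL)
    k <- sum(candidates %in% tg)
    data.frame(term = tm,
               term_name = if (is.null(nm)) NA_character_ else
                 unname(nm[tm]),
               n_annotated = K, n_candidate = k, n_expected = n * K / N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               test = "fisher")
  })
  out <- do.call(rbind, rows)
  .assert(!is.null(out), "no term exceeds the reporting size")
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' GO enrichment by gene ranks (one-sided Kolmogorov-Smirnov)
#'
#' Genes are ranked by their assigned score (ascending p or Fst rank; ties
#' broken by gene id, so the order is total). For each term, a one-sided KS
#' test compares the ranks of term genes against non-term genes, sensitive
#' to enrichment at the top of the ranking.
#'
#' @param scores Data frame from [assign_gene_scores()] (or any frame with
#'   `gene_id` and a score column named `p`).
#' @param annotation Gene-to-term mapping as in [go_fisher()].
#' @param min_genes Report only terms with more than this many scored genes
#'   (default 5).
#' @return Data frame: `term`, `term_name`, `n_annotated`, `ks_stat`, `p`,
#'   `test`; sorted by p.
#' @export
go_ks <- function(scores, annotation, min_genes = 5) {
  ord <- order(scores$p, scores$gene_id)
  ranked <- scores$gene_id[ord]
  rk <- stats::setNames(seq_along(ranked), ranked)
  ann <- annotation[annotation$gene_id %in% ranked, , drop = FALSE]
  terms <- split(ann$gene_id, ann$term)
  nm <- if (!is.null(annotation$term_name))
    stats::setNames(annotation$term_name, annotation$term) else NULL
  rows <- lapply(names(terms), function(tm) {
    tg <- unique(terms[[tm]])
    if (length(tg) <= min_genes) return(NULL)
    in_rk <- rk[tg]
    out_rk <- rk[setdiff(ranked, tg)]
    if (!length(out_rk)) return(NULL)
    ks <- suppressWarnings(stats::ks.test(in_rk, out_rk,
                                          alternative = "greater"))
    data.frame(term = tm,
               term_name = if (is.null(nm)) NA_character_ else unname(nm[tm]),
               n_annotated = length(tg), ks_stat = unname(ks$statistic),
               p = ks$p.value, test = "ks")
  })
  out <- do.call(rbind, rows)
  .assert(!is.null(out), "no term exceeds the reporting size")
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Permutation-calibrated enrichment significance threshold
#'
#' Runs the Fisher enrichment on `n_sets` random candidate gene sets of the
#' given size and returns the 0.01% quantile of the pooled enrichment
#' p-value distribution — a conservative threshold below which observed
#' enrichment p-values are unlikely to arise from random sets.
#'
#' @param universe Gene universe.
#' @param annotation Gene-to-term mapping.
#' @param set_size Number of genes per random set.
#' @param n_sets Number of random sets (default 1000).
#' @param quantile_level Quantile of the pooled distribution (default 1e-4,
#'   i.e. 0.01%).
#' @param min_genes Term-size reporting filter passed to [go_fisher()].
#' @param seed Integer seed.
#' @return List: `threshold`, `pooled_p` (vector), `n_sets`.
#' @export
permutation_threshold <- function(universe, annotation, set_size,
                                  n_sets = 1000, quantile_level = 1e-4,
                                  min_genes = 5, seed = 1L) {
  .assert(n_sets > 0, "n_sets must be positive")
  .assert(set_size > 0 && set_size <= length(universe), "bad set_size")
  set.seed(stage_seed(seed, "perm_threshold"))
  pooled <- vector("list", n_sets)
  for (b in seq_len(n_sets)) {
    cand <- sample(universe, set_size)
    res <- tryCatch(go_fisher(cand, universe, annotation,
                              min_genes = min_genes),
                    error = function(e) NULL)
    pooled[[b]] <- if (is.null(res)) numeric(0) else res$p
  }
  pooled <- unlist(pooled)
  .assert(length(pooled) > 0, "no enrichment p-values produced")
  list(threshold = stats::quantile(pooled, quantile_level, names = FALSE),
       pooled_p = pooled, n_sets = n_sets)
}

#' Genes in the LD window around a focal marker
#'
#' Starting from a focal marker, extends a span over the contiguous run of
#' markers whose squared genotype correlation with the focal marker is at
#' least `r2_min`, truncated at `max_window/2` on each side, and returns
#' the genes overlapping that span.
#'
#' @param focal_marker Marker id (must be genotyped in `G`).
#' @param G A [geno_matrix].
#' @param genes Gene intervals (`gene_id`, `chrom`, `start`, `end`).
#' @param max_window Total window size in bp (default 250 kb).
#' @param r2_min LD threshold (default 0.5).
#' @return List: `genes` (data frame of overlapping genes), `span`
#'   (chrom, start, end), `n_markers` in the span.
#' @export
candidate_gene_window <- function(focal_marker, G, genes,
                                  max_window = 250e3, r2_min = 0.5) {
  j <- match(focal_marker, G$map$marker)
  .assert(!is.na(j), paste("focal marker", focal_marker, "not genotyped"))
  chrom <- G$map$chrom[j]; fpos <- G$map$pos[j]
  on_chr <- which(G$map$chrom == chrom &
                    abs(G$map$pos - fpos) <= max_window / 2)
  on_chr <- on_chr[order(G$map$pos[on_chr])]
  r2 <- suppressWarnings(
    stats::cor(G$codes[, j], G$codes[, on_chr, drop = FALSE],
               use = "pairwise.complete.obs"))^2
  r2[is.na(r2)] <- 0
  k <- match(j, on_chr)
  lo <- hi <- k
  while (lo > 1 && r2[lo - 1] >= r2_min) lo <- lo - 1
  while (hi < length(on_chr) && r2[hi + 1] >= r2_min) hi <- hi + 1
  span <- c(G$map$pos[on_chr[lo]], G$map$pos[on_chr[hi]])
  hit <- genes$chrom == chrom & genes$end >= span[1] & genes$start <= span[2]
  list(genes = genes[hit, , drop = FALSE],
       span = list(chrom = chrom, start = span[1], end = span[2]),
       n_markers = hi - lo + 1L)
}

#' Read a gene-to-GO-term annotation TSV
#'
#' Expects at least two columns: gene id and term id (header `gene_id`,
#' `term`; an optional third `term_name`).
#'
#' @param path TSV path.
#' @return Data frame: `gene_id`, `term` (+ `term_name` when present).
#' @export
read_go_annotation <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  .assert(all(c("gene_id", "term") %in% names(d)),
          "annotation needs gene_id and term columns")
  d
}
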