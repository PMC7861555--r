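# Genotype container and file I/O (vcftools 012 dialect and minimal VCF).

#' Construct a genotype matrix object
#'
#' Container for biallelic genotypes of inbred lines: a lines x markers
#' matrix of allele-dose codes in \{0, 1, 2, NA\}, a marker map and optional
#' region labels. Positions are 1-based and sorted within chromosome.
#'
#' @param codes Numeric matrix, lines x markers, entries in \{0, 1, 2, NA\}.
#' @param map Data frame with columns `marker`, `chrom`, `pos` (1-based bp).
#' @param lines Character vector of line identifiers (defaults to rownames).
#' @param regions Optional character/factor vector of per-line region labels.
#' @return An object of class `geno_matrix` with components `codes`, `map`,
#'   `lines`, `regions`.
#' @export
geno_matrix <- function(codes, map, lines = rownames(codes), regions = NULL) {
  codes <- as.matrix(codes)
  .assert(all(codes %in% c(0, 1, 2) | is.na(codes)),
          "genotype codes must be 0, 1, 2 or NA")
  .assert(is.data.frame(map) && all(c("marker", "chrom", "pos") %in% names(map)),
          "map needs columns marker, chrom, pos")
  .assert(nrow(map) == ncol(codes), "map rows must match marker columns")
  if (is.null(lines)) lines <- paste0("line", seq_len(nrow(codes)))
  .assert(length(lines) == nrow(codes), "one line id per row")
  if (!is.null(regions)) {
    .assert(length(regions) == nrow(codes), "one region label per line")
    regions <- as.character(regions)
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  codes <- codes[, ord, drop = FALSE]
  rownames(codes) <- lines
  colnames(codes) <- map$marker
  structure(list(codes = codes, map = map, lines = lines, regions = regions),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d lines x %d markers, %d chromosome(s)\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$map$chrom))))
  if (!is.null(x$regions))
    cat("regions:", paste(sprintf("%s (%d)", names(table(x$regions)),
                                  table(x$regions)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Per-marker minor allele frequency
#'
#' Allele frequencies are computed on non-missing calls, treating each line
#' as contributing `code / 2` (heterozygous calls count one half, matching
#' the haploid-equivalent treatment of selfing lines).
#'
#' @param G A [geno_matrix].
#' @return Named numeric vector of minor allele frequencies in \[0, 0.5\].
#' @export
marker_maf <- function(G) {
  p <- colMeans(G$codes / 2, na.rm = TRUE)
  pmin(p, 1 - p)
}

#' Write genotypes in the vcftools 012 dialect
#'
#' Writes three files: `<prefix>.012` (tab-separated matrix with a leading
#' row-index column, missing as -1), `<prefix>.012.indv` (line ids) and
#' `<prefix>.012.pos` (chromosome, 1-based position).
#'
#' @param G A [geno_matrix].
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_geno_012 <- function(G, prefix) {
  codes <- G$codes
  codes[is.na(codes)] <- -1
  m <- cbind(seq_len(nrow(codes)) - 1L, codes)
  utils::write.table(m, paste0(prefix, ".012"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(G$lines, paste0(prefix, ".012.indv"))
  utils::write.table(G$map[, c("chrom", "pos")], paste0(prefix, ".012.pos"),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(paste0(prefix, c(".012", ".012.indv", ".012.pos")))
}

.read_geno_012 <- function(prefix, regions = NULL) {
  mat_file <- if (file.exists(prefix)) prefix else paste0(prefix, ".012")
  base <- sub("\\.012$", "", mat_file)
  indv <- readLines(paste0(base, ".012.indv"))
  pos <- utils::read.table(paste0(base, ".012.pos"), sep = "\t",
                           col.names = c("chrom", "pos"),
                           colClasses = c("character", "integer"))
  m <- as.matrix(utils::read.table(mat_file, sep = "\t"))
  m <- m[, -1, drop = FALSE]  # vcftools leading row index
  if (nrow(m) != length(indv))
    stop("012 matrix has ", nrow(m), " rows but .indv lists ", length(indv),
         " lines", call. = FALSE)
  if (ncol(m) != nrow(pos))
    stop("012 matrix has ", ncol(m), " markers but .pos lists ", nrow(pos),
         call. = FALSE)
  m[m == -1] <- NA
  map <- data.frame(marker = paste0(pos$chrom, "_", pos$pos),
                    chrom = pos$chrom, pos = pos$pos)
  geno_matrix(m, map, lines = indv, regions = regions)
}

#' Write a minimal VCF for inbred-line genotypes
#'
#' Emits a VCFv4.2 file with GT fields only; code 0 becomes `0/0`, 1 `0/1`,
#' 2 `1/1` and missing `./.`. REF/ALT are placeholder A/T alleles.
#'
#' @param G A [geno_matrix].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(G, path) {
  gt <- matrix(c("0/0", "0/1", "1/1")[G$codes + 1], nrow = nrow(G$codes))
  gt[is.na(G$codes)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", G$lines), collapse = "\t"))
  body <- apply(cbind(G$map$chrom, G$map$pos, G$map$marker, "A", "T", ".",
                      "PASS", ".", "GT", t(gt)), 1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

.read_geno_vcf <- function(path, regions = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
    nchar(fix[, "ALT"]) != 1
  n_skipped <- sum(multi)
  if (n_skipped > 0)
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    ifelse(g %in% c("0/0"), 0,
           ifelse(g %in% c("0/1", "1/0"), 1,
                  ifelse(g %in% c("1/1"), 2, NA)))
  }
  m <- t(apply(gt, 1, code))
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == "."))
    ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  map <- data.frame(marker = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]))
  geno_matrix(t(m), map, lines = colnames(gt), regions = regions)
}

#' Read genotypes from VCF or the vcftools 012 dialect
#'
#' @param path VCF file, or 012 prefix/matrix path (companions `.012.indv`
#'   and `.012.pos` must sit next to it).
#' @param format `"vcf"` or `"012"`.
#' @param regions Optional per-line region labels (in file line order).
#' @return A [geno_matrix]. In VCF mode only biallelic SNP records are kept;
#'   others are skipped with a message. In 012 mode `-1` becomes missing.
#' @export
read_genotypes <- function(path, format = c("012", "vcf"), regions = NULL) {
  format <- match.arg(format)
  switch(format,
         `012` = .read_geno_012(path, regions),
         vcf = .read_geno_vcf(path, regions))
}
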