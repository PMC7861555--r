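# Shared fixtures, built in code.

# Tiny genotype matrix with explicit codes (lines x markers).
toy_geno <- function(codes, chrom = NULL, pos = NULL, regions = NULL) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  map <- data.frame(marker = paste0("m", seq_len(m)),
                    chrom = chrom %||% rep("chr1", m),
                    pos = pos %||% (seq_len(m) * 1000L))
  polygrowth::geno_matrix(codes, map,
                          lines = paste0("L", seq_len(nrow(codes))),
                          regions = regions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free logistic diameter series.
logistic_series <- function(fs, slope, t50, days = seq(5, 60, by = 5),
                            noise = 0) {
  d <- fs / (1 + exp(-slope * (days - t50)))
  if (noise > 0) d <- d + stats::rnorm(length(days), sd = noise)
  data.frame(day = days, diameter = pmax(d, 0))
}

# Direct Nei Fst oracle for two populations of homozygous lines, written
# independently of the package implementation (scalar, loop-based).
fst_oracle <- function(g1, g2) {
  p1 <- mean(g1, na.rm = TRUE) / 2; p2 <- mean(g2, na.rm = TRUE) / 2
  n1 <- sum(!is.na(g1)); n2 <- sum(!is.na(g2))
  hs1 <- n1 / (n1 - 1) * 2 * p1 * (1 - p1)
  hs2 <- n2 / (n2 - 1) * 2 * p2 * (1 - p2)
  hs <- (hs1 + hs2) / 2
  pb <- (p1 + p2) / 2
  ntil <- 2 / (1 / n1 + 1 / n2)
  ht <- 2 * pb * (1 - pb) + hs / (2 * ntil)
  if (ht <= 0) return(0)
  max(0, (ht - hs) / ht)
}

# Balanced one-way ANOVA method-of-moments variance components
# (independent oracle for H2 and Qst recovery checks).
anova_mom <- function(value, group) {
  group <- as.factor(group)
  r <- length(levels(group))
  n_i <- tabulate(group)
  stopifnot(length(unique(n_i)) == 1)
  n0 <- n_i[1]
  gm <- tapply(value, group, mean)
  msb <- n0 * sum((gm - mean(value))^2) / (r - 1)
  msw <- sum((value - gm[as.integer(group)])^2) / (length(value) - r)
  vg <- max(0, (msb - msw) / n0)
  list(vg = vg, ve = msw, ratio = vg / (vg + msw))
}
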