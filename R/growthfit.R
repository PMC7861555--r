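# Logistic growth-curve fitting, design-corrected genotypic means, growth
# plasticity (GxE) residuals and broad-sense heritability.

.logistic3 <- function(day, FS, slope, t50) FS / (1 + exp(-slope * (day - t50)))

#' Fit a three-parameter logistic growth curve to one plant
#'
#' Minimizes the residual sum of squares of
#' `d(t) = FS / (1 + exp(-slope (t - t50)))` by Levenberg-Marquardt with an
#' analytic Jacobian. `slope` is reported as the positive rate constant of an
#' increasing curve; the derivative at the inflection point
#' (`slope * FS / 4`, the fold increase of the linear phase) is also emitted
#' as `slope_linear`. Starting values are `FS0 = max(diameter)`, `t50_0` the
#' first day exceeding half of `FS0`, `slope0 = 4 max(gradient)/FS0`; on
#' failure the fit restarts from a fixed grid of jittered starts.
#'
#' @param day Numeric vector of measurement days (strictly increasing), or a
#'   data frame with columns `day` and `diameter`.
#' @param diameter Numeric vector of diameters (cm), `>= 0`.
#' @return List of class `growth_fit`: `FS`, `slope`, `t50`, `slope_linear`,
#'   `sse`, `converged`, `n`, `message`. Non-convergence (or an unbounded
#'   asymptote) gives `converged = FALSE` with `NA` parameters; such records
#'   are excluded downstream.
#' @export
fit_logistic <- function(day, diameter = NULL) {
  if (is.data.frame(day)) { diameter <- day$diameter; day <- day$day }
  ok <- is.finite(day) & is.finite(diameter)
  day <- day[ok]; diameter <- diameter[ok]
  .assert(length(unique(day)) >= 4, "need at least 4 distinct time points")
  .assert(all(diff(sort(day)) >= 0), "days must be increasing")
  .assert(all(diameter >= 0), "diameters must be non-negative")
  fail <- function(msg) structure(
    list(FS = NA_real_, slope = NA_real_, t50 = NA_real_,
         slope_linear = NA_real_, sse = NA_real_, converged = FALSE,
         n = length(day), message = msg), class = "growth_fit")

  fs0 <- max(diameter)
  if (fs0 <= 0) return(fail("all-zero diameters"))
  t50_0 <- day[which(diameter >= fs0 / 2)[1]]
  grad <- diff(diameter) / diff(day)
  sl0 <- max(4 * max(grad, 0) / fs0, 0.01)
  dat <- data.frame(day = day, diameter = diameter)

  try_fit <- function(start) {
    tryCatch({
      fit <- minpack.lm::nlsLM(
        diameter ~ FS / (1 + exp(-slope * (day - t50))), data = dat,
        start = start, lower = c(FS = 1e-8, slope = 1e-8, t50 = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12))
      cf <- stats::coef(fit)
      list(cf = cf, sse = sum(stats::resid(fit)^2))
    }, error = function(e) NULL, warning = function(w) NULL)
  }

  starts <- c(list(c(FS = fs0, slope = sl0, t50 = t50_0)),
              lapply(list(c(0.8, 1.5, 0.7), c(1.2, 0.5, 1.3), c(1.5, 2, 1),
                          c(1, 0.25, 1.6), c(0.9, 3, 0.5)),
                     function(j) c(FS = fs0 * j[1], slope = sl0 * j[2],
                                   t50 = max(t50_0 * j[3], 1e-3))))
  best <- NULL
  for (s in starts) {
    res <- try_fit(s)
    if (!is.null(res) && (is.null(best) || res$sse < best$sse)) best <- res
  }
  if (is.null(best)) return(fail("Levenberg-Marquardt did not converge"))
  cf <- best$cf
  # An asymptote far beyond the data is unidentified: flag as failed.
  if (cf[["FS"]] > 5 * fs0) return(fail("unbounded final size"))
  structure(list(FS = unname(cf["FS"]), slope = unname(cf["slope"]),
                 t50 = unname(cf["t50"]),
                 slope_linear = unname(cf["slope"] * cf["FS"] / 4),
                 sse = best$sse, converged = TRUE, n = length(day),
                 message = "ok"), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("logistic fit: FS = %.3f cm, slope = %.4f /day, t50 = %.2f d (%s)\n",
              x$FS, x$slope, x$t50,
              if (x$converged) "converged" else x$message))
  invisible(x)
}

#' Fit logistic curves for every plant in a diameter series
#'
#' @param series Long data frame (as produced by
#'   [simulate_growth_experiment()] or [read_pheno_csv()]) with columns
#'   `plant_id`, `genotype_id`, `day`, `diameter` and the design covariates
#'   `block`, `tray`, `row`, `col` (carried through).
#' @param min_timepoints Minimum distinct days required to attempt a fit.
#' @return Data frame with one row per plant: design covariates, `FS`,
#'   `slope`, `t50`, `slope_linear`, `sse`, `converged`. Failed fits are
#'   retained with `converged = FALSE` and `NA` parameters.
#' @export
fit_growth_curves <- function(series, min_timepoints = 4) {
  .assert(all(c("plant_id", "day", "diameter") %in% names(series)),
          "series needs plant_id, day, diameter columns")
  keys <- c("plant_id", intersect(c("genotype_id", "regime", "block", "tray",
                                    "row", "col"), names(series)))
  out <- lapply(split(series, series$plant_id), function(d) {
    meta <- d[1, keys, drop = FALSE]
    if (length(unique(d$day)) < min_timepoints) {
      f <- list(FS = NA_real_, slope = NA_real_, t50 = NA_real_,
                slope_linear = NA_real_, sse = NA_real_, converged = FALSE)
    } else f <- fit_logistic(d$day, d$diameter)
    cbind(meta, data.frame(FS = f$FS, slope = f$slope, t50 = f$t50,
                           slope_linear = f$slope_linear, sse = f$sse,
                           converged = f$converged))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Design-corrected genotypic means
#'
#' Least-squares fit of `parameter ~ genotype + block + tray/(row + col)`
#' (tray effects entered as tray, tray:row and tray:col, with tray labels
#' made unique within block) using sum-to-zero contrasts for the nuisance
#' factors. The genotypic mean is the marginal mean per genotype averaged
#' over the observed design: for genotype g, the model prediction is formed
#' for every plant's design covariates with the genotype set to g, and the
#' predictions are averaged. In a balanced design this equals the estimated
#' marginal mean over the design levels (asserted against `emmeans` in the
#' test suite). Nuisance terms with fewer than two observed levels are
#' dropped, so an intercept-only nuisance model reduces to group means.
#'
#' @param fits Per-plant data frame from [fit_growth_curves()] (only rows
#'   with `converged` are used when that column is present).
#' @param parameter Which column to model (e.g. `"FS"`).
#' @return Data frame: `genotype_id`, `mean`, `se`, `n`, plus attribute
#'   `parameter`. Genotypes with no successful fits are dropped with a
#'   warning.
#' @export
genotypic_means <- function(fits, parameter = "FS") {
  .assert(parameter %in% names(fits), paste("no column", parameter))
  d <- fits
  if ("converged" %in% names(d)) {
    lost <- setdiff(unique(d$genotype_id), unique(d$genotype_id[d$converged]))
    if (length(lost))
      warning(length(lost), " genotype(s) without a successful fit dropped")
    d <- d[d$converged & is.finite(d[[parameter]]), , drop = FALSE]
  }
  .assert(nrow(d) > 0, "no usable fits")
  d$genotype_id <- factor(d$genotype_id)
  d$.y <- d[[parameter]]
  genos <- levels(d$genotype_id)
  n_rep <- as.vector(table(d$genotype_id)[genos])
  if (length(genos) == 1L) {
    out <- data.frame(genotype_id = genos, mean = mean(d$.y),
                      se = stats::sd(d$.y) / sqrt(nrow(d)), n = n_rep)
    attr(out, "parameter") <- parameter
    return(out)
  }
  terms <- "genotype_id"
  if (!is.null(d$block) && length(unique(d$block)) > 1) {
    d$block <- factor(d$block)
    terms <- c(terms, "block")
  }
  has_tray <- !is.null(d$tray) && length(unique(paste(d$block, d$tray))) > 1
  if (has_tray) {
    d$tray <- factor(paste0(if (!is.null(d$block)) as.character(d$block)
                            else "", "_", d$tray))
    terms <- c(terms, "tray")
    if (!is.null(d$row) && length(unique(d$row)) > 1) {
      d$row <- factor(d$row); terms <- c(terms, "tray:row")
    }
    if (!is.null(d$col) && length(unique(d$col)) > 1) {
      d$col <- factor(d$col); terms <- c(terms, "tray:col")
    }
  }
  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  nuis <- intersect(c("block", "tray", "row", "col"), all.vars(fml))
  ctr <- stats::setNames(rep(list("contr.sum"), length(nuis)), nuis)
  fit <- stats::lm(fml, data = d, contrasts = if (length(ctr)) ctr else NULL)
  beta <- stats::coef(fit)
  alias <- is.na(beta)
  # non-aliased coefficients only; summary.lm warns on zero-residual fits
  V <- suppressWarnings(stats::vcov(fit, complete = FALSE))
  tt <- stats::delete.response(stats::terms(fit))
  est <- se <- numeric(length(genos))
  for (i in seq_along(genos)) {
    d2 <- d
    d2$genotype_id <- factor(genos[i], levels = genos)
    mm <- stats::model.matrix(tt, d2, contrasts.arg = fit$contrasts)
    cc <- colMeans(mm)[names(beta)]
    est[i] <- sum(cc[!alias] * beta[!alias])
    se[i] <- sqrt(drop(t(cc[!alias]) %*% V %*% cc[!alias]))
  }
  out <- data.frame(genotype_id = genos, mean = est, se = se, n = n_rep)
  attr(out, "parameter") <- parameter
  out
}

#' Growth plasticity (GxE) residuals between light regimes
#'
#' Ordinary least-squares regression of low-light genotypic means on
#' high-light genotypic means; the residual quantifies each genotype's
#' deviation from the population-average light response.
#'
#' @param means_hl,means_ll Data frames from [genotypic_means()] for the two
#'   regimes (matched on `genotype_id`).
#' @return Data frame: `genotype_id`, `gxe_residual`, plus the fitted
#'   intercept/slope as attributes.
#' @export
gxe_residuals <- function(means_hl, means_ll) {
  m <- merge(means_hl[, c("genotype_id", "mean")],
             means_ll[, c("genotype_id", "mean")],
             by = "genotype_id", suffixes = c("_hl", "_ll"))
  .assert(nrow(m) >= 3, "need at least 3 genotypes shared between regimes")
  fit <- stats::lm(mean_ll ~ mean_hl, data = m)
  out <- data.frame(genotype_id = m$genotype_id,
                    gxe_residual = stats::resid(fit))
  attr(out, "intercept") <- unname(stats::coef(fit)[1])
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  rownames(out) <- NULL
  out
}

#' Broad-sense heritability from replicated phenotypes
#'
#' REML variance components of the model `value ~ block` (fixed) with a
#' random genotype intercept; `H2 = Vg / (Vg + Ve)`, clipped to \[0, 1\].
#' Fitted with `nlme::lme`; if that fails on a degenerate fit (for instance
#' zero residual variance) an internal profiled-REML fallback on
#' block-corrected values is used.
#'
#' @param pheno Data frame with columns `genotype_id`, `value` and
#'   optionally `block`.
#' @return List: `h2`, `var_genetic`, `var_residual`.
#' @export
broad_sense_h2 <- function(pheno) {
  .assert(all(c("genotype_id", "value") %in% names(pheno)),
          "pheno needs genotype_id and value")
  d <- pheno[is.finite(pheno$value), ]
  .assert(stats::var(d$value) > 0, "all phenotypes identical: H2 undefined")
  reps <- table(d$genotype_id)
  .assert(sum(reps >= 2) >= 10, "need >=2 replicates for >=10 genotypes")
  has_block <- !is.null(d$block) && length(unique(d$block)) > 1
  fml <- if (has_block) value ~ factor(block) else value ~ 1
  fit <- tryCatch(
    nlme::lme(fml, random = ~ 1 | genotype_id, data = d, method = "REML"),
    error = function(e) NULL)
  if (!is.null(fit)) {
    vc <- nlme::VarCorr(fit)
    vg <- as.numeric(vc["(Intercept)", "Variance"])
    ve <- as.numeric(vc["Residual", "Variance"])
  } else {
    y <- if (has_block) stats::resid(stats::lm(fml, data = d)) else d$value
    cmp <- .reml_random_intercept(y, d$genotype_id)
    vg <- cmp$var_between; ve <- cmp$var_within
  }
  list(h2 = max(0, min(1, vg / (vg + ve))), var_genetic = vg,
       var_residual = ve)
}
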