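#' Per-site calorie-restriction decomposition model
#'
#' Fits, for every site, the linear model
#' `m = b0 + b_age * age + b_IS * CR + b_TAT * (age - t0) * CR + confounders`,
#' where `CR` is the treatment indicator. `b_IS` is the model's predicted
#' CR-control difference at age exactly `t0` (the initial shift) and `b_TAT`
#' the additional per-month rate under treatment (the cumulative,
#' time-after-treatment effect). The nested F-test compares the full model
#' against the reduced model without the two CR terms; per-coefficient
#' two-sided t-tests and BH-adjusted q-values are reported for each term.
#'
#' @param fractions sites x samples fraction matrix (or vector for one site).
#' @param ages ages in months.
#' @param is_cr logical treatment indicator per sample.
#' @param t0 treatment-start age in months.
#' @param confounders optional per-sample covariate data.frame.
#' @return data.frame (one row per site): `beta_age`, `beta_IS`, `beta_TAT`,
#'   `F_stat`, `p_F`, `p_IS`, `p_TAT`, `q_F`, `q_IS`, `q_TAT`.
#' @export
fit_site_cr <- function(fractions, ages, is_cr, t0, confounders = NULL) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1)
  n <- length(ages)
  is_cr <- as.logical(is_cr)
  if (!any(is_cr) || all(is_cr)) {
    stop("both control and CR samples are required")
  }
  if (any(ages[is_cr] < t0)) stop("CR samples must be at or past t0")
  C <- confounder_matrix(confounders, n)
  X_full <- cbind(`(Intercept)` = 1, age = ages, cr = as.numeric(is_cr),
                  tat = (ages - t0) * as.numeric(is_cr), C)
  X_red <- cbind(`(Intercept)` = 1, age = ages, C)
  Y <- t(fractions)
  fit_full <- ols_multi(X_full, Y)
  fit_red <- ols_multi(X_red, Y)
  df_f <- fit_full$df
  F_stat <- ((fit_red$rss - fit_full$rss) / 2) / (fit_full$rss / df_f)
  p_F <- stats::pf(F_stat, 2, df_f, lower.tail = FALSE)
  out <- data.frame(
    beta_age = fit_full$coef["age", ],
    beta_IS = fit_full$coef["cr", ],
    beta_TAT = fit_full$coef["tat", ],
    F_stat = F_stat, p_F = p_F,
    p_IS = fit_full$p["cr", ],
    p_TAT = fit_full$p["tat", ])
  out$q_F <- adjust_pvalues(out$p_F)
  out$q_IS <- adjust_pvalues(out$p_IS)
  out$q_TAT <- adjust_pvalues(out$p_TAT)
  if (!is.null(rownames(fractions))) {
    out <- cbind(site_id = rownames(fractions), out)
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two site-aligned coefficient vectors
#'
#' Intersects the two vectors on shared site ids (when named) or positions,
#' optionally restricted by a selection, and returns the Pearson correlation
#' with its two-sided p-value.
#'
#' @param coef_a,coef_b numeric vectors (optionally named by site id).
#' @param select optional logical/integer selection applied after alignment.
#' @return list with `r`, `p`, `n`.
#' @export
coefficient_correlation <- function(coef_a, coef_b, select = NULL) {
  if (!is.null(names(coef_a)) && !is.null(names(coef_b))) {
    shared <- intersect(names(coef_a), names(coef_b))
    coef_a <- coef_a[shared]; coef_b <- coef_b[shared]
  } else if (length(coef_a) != length(coef_b)) {
    stop("unnamed coefficient vectors must have equal length")
  }
  if (!is.null(select)) {
    coef_a <- coef_a[select]; coef_b <- coef_b[select]
  }
  ok <- is.finite(coef_a) & is.finite(coef_b)
  coef_a <- coef_a[ok]; coef_b <- coef_b[ok]
  if (length(coef_a) < 3) stop("fewer than 3 shared sites")
  ct <- stats::cor.test(coef_a, coef_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(coef_a))
}

#' Endpoint comparison of the oldest CR and control groups
#'
#' Computes, per site, the difference in mean methylation between CR and
#' age-matched control samples in the oldest age group, and correlates these
#' differences with (a) the control-cohort aging slopes and (b) the CR-cohort
#' aging slopes.
#'
#' @param fractions sites x samples fraction matrix.
#' @param samples sample sheet.
#' @param oldest_age the endpoint age (default: oldest age with both groups).
#' @return list with `delta` (per-site CR - control difference),
#'   `cor_control_slope`, `cor_cr_slope` (each a
#'   [coefficient_correlation()] result, or `NA` when undefined),
#'   `oldest_age`.
#' @export
endpoint_comparison <- function(fractions, samples, oldest_age = NULL) {
  samples <- validate_sample_sheet(samples)
  if (is.null(oldest_age)) {
    shared <- intersect(samples$age[samples$group == "CR"],
                        samples$age[samples$group == "control"])
    if (length(shared) == 0) stop("no age with both CR and control samples")
    oldest_age <- max(shared)
  }
  cr_cols <- which(samples$group == "CR" & samples$age == oldest_age)
  ctrl_cols <- which(samples$group == "control" & samples$age == oldest_age)
  if (length(cr_cols) == 0 || length(ctrl_cols) == 0) {
    stop("both groups must be present at the endpoint age")
  }
  delta <- rowMeans(fractions[, cr_cols, drop = FALSE], na.rm = TRUE) -
    rowMeans(fractions[, ctrl_cols, drop = FALSE], na.rm = TRUE)
  ctrl <- samples$group == "control"
  slopes_ctrl <- fit_site_linear(fractions[, ctrl, drop = FALSE],
                                 samples$age[ctrl])$slope
  cr <- samples$group == "CR"
  slopes_cr <- if (sum(cr) >= 3 && length(unique(samples$age[cr])) >= 2) {
    fit_site_linear(fractions[, cr, drop = FALSE], samples$age[cr])$slope
  } else NULL
  safe_cor <- function(a, b) {
    if (is.null(b) || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(list(r = NA_real_, p = NA_real_, n = length(a)))
    }
    coefficient_correlation(a, b)
  }
  list(delta = delta,
       cor_control_slope = safe_cor(delta, slopes_ctrl),
       cor_cr_slope = safe_cor(delta, slopes_cr),
       oldest_age = oldest_age)
}

#' Full CR analysis of a cohort
#'
#' Runs [fit_site_cr()] over a fraction matrix with its sample sheet, then
#' summarizes the coefficient-correlation structure: control-aging slope vs
#' IS among sites significant for both, control-aging slope vs TAT, and IS vs
#' TAT among sites significant for both CR terms. The aging-coefficient
#' vector comes from a control-only regression by default
#' (`aging_from = "control"`); `"joint"` uses the joint model's age
#' coefficient.
#'
#' @param fractions sites x samples fraction matrix.
#' @param samples sample sheet.
#' @param alpha significance level on adjusted p-values.
#' @param confounders optional covariates.
#' @param aging_from `"control"` or `"joint"`.
#' @return list with `cr_fit` (the [fit_site_cr()] table), `age_fit`
#'   (control aging fit), `overlap` (counts of sites significant for aging,
#'   IS, TAT and their intersections), and `correlations` (age-IS, age-TAT,
#'   IS-TAT).
#' @export
run_cr_analysis <- function(fractions, samples, alpha = 0.05,
                            confounders = NULL,
                            aging_from = c("control", "joint")) {
  aging_from <- match.arg(aging_from)
  samples <- validate_sample_sheet(samples)
  if (is.null(confounders)) confounders <- sample_confounders(samples)
  if (ncol(confounders) == 0) confounders <- NULL
  is_cr <- samples$group == "CR"
  t0 <- unique(samples$t0[is_cr])
  if (length(t0) != 1) stop("a single treatment-start age is required")
  cr_fit <- fit_site_cr(fractions, samples$age, is_cr, t0, confounders)
  ctrl <- !is_cr
  conf_ctrl <- if (!is.null(confounders)) confounders[ctrl, , drop = FALSE] else NULL
  age_fit <- fit_site_linear(fractions[, ctrl, drop = FALSE],
                             samples$age[ctrl], conf_ctrl)
  age_fit$q <- adjust_pvalues(age_fit$p)
  aging_coef <- if (aging_from == "control") age_fit$slope else cr_fit$beta_age
  sig_age <- age_fit$q < alpha
  sig_is <- cr_fit$q_IS < alpha
  sig_tat <- cr_fit$q_TAT < alpha
  corr_or_na <- function(a, b, sel) {
    if (sum(sel) < 3) return(list(r = NA_real_, p = NA_real_, n = sum(sel)))
    coefficient_correlation(a, b, select = which(sel))
  }
  list(cr_fit = cr_fit, age_fit = age_fit,
       overlap = c(n_sites = nrow(cr_fit),
                   sig_F = sum(cr_fit$q_F < alpha),
                   sig_age = sum(sig_age), sig_IS = sum(sig_is),
                   sig_TAT = sum(sig_tat),
                   age_and_IS = sum(sig_age & sig_is),
                   age_and_TAT = sum(sig_age & sig_tat),
                   IS_and_TAT = sum(sig_is & sig_tat)),
       correlations = list(
         age_is = corr_or_na(aging_coef, cr_fit$beta_IS, sig_age & sig_is),
         age_tat = corr_or_na(aging_coef, cr_fit$beta_TAT, sig_age & sig_tat),
         is_tat = corr_or_na(cr_fit$beta_IS, cr_fit$beta_TAT,
                             sig_is & sig_tat)))
}
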