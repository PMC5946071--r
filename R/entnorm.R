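#' Smooth of regression slope against intercept (expected entropy slope)
#'
#' Fits a one-dimensional penalized-spline generalized additive model of the
#' per-site age-regression slope against the per-site intercept, over the
#' significant sites. The fitted curve is the "average entropy" trend: how
#' fast a site with a given baseline methylation is expected to drift with
#' age. Smoothing is selected by generalized cross-validation.
#'
#' @param intercepts per-site regression intercepts (significant sites).
#' @param slopes per-site regression slopes, aligned with `intercepts`.
#' @param basis_dim spline basis dimension (default 20).
#' @param min_sites minimum number of sites required (default 50).
#' @return object of class `expected_slope_fit`; evaluate with
#'   [predict_expected_slope()].
#' @export
fit_expected_slope <- function(intercepts, slopes, basis_dim = 20,
                               min_sites = 50) {
  if (length(intercepts) != length(slopes)) stop("length mismatch")
  ok <- is.finite(intercepts) & is.finite(slopes)
  intercepts <- intercepts[ok]; slopes <- slopes[ok]
  if (length(intercepts) < min_sites) {
    stop("at least ", min_sites, " significant sites required for the smooth")
  }
  k <- min(basis_dim, max(4, length(unique(intercepts)) - 1))
  dat <- data.frame(intercept = intercepts, slope = slopes)
  gam_fit <- mgcv::gam(slope ~ s(intercept, k = k), data = dat,
                       method = "GCV.Cp")
  structure(list(gam = gam_fit,
                 range = range(intercepts)),
            class = "expected_slope_fit")
}

#' Evaluate the expected-slope smooth
#'
#' Predicts the expected slope at any intercept. Inside the fitted intercept
#' range the penalized-spline prediction is used; outside it the curve is
#' continued linearly from the boundary (slope estimated by a small finite
#' difference), avoiding spline extrapolation artifacts.
#'
#' @param fit an `expected_slope_fit` from [fit_expected_slope()].
#' @param intercepts numeric vector of intercepts (typically in `[0, 1]`).
#' @return expected slope per intercept (fraction per month).
#' @export
predict_expected_slope <- function(fit, intercepts) {
  stopifnot(inherits(fit, "expected_slope_fit"))
  lo <- fit$range[1]; hi <- fit$range[2]
  x <- clip_range(intercepts, lo, hi)
  pred <- as.numeric(mgcv::predict.gam(fit$gam,
                                       newdata = data.frame(intercept = x)))
  h <- max(1e-4, (hi - lo) * 1e-3)
  edge <- function(x0, sign) {
    p <- as.numeric(mgcv::predict.gam(fit$gam, newdata = data.frame(
      intercept = c(x0, x0 + sign * h))))
    (p[2] - p[1]) / (sign * h)
  }
  below <- which(intercepts < lo)
  if (length(below) > 0) {
    d <- edge(lo, +1)
    pred[below] <- pred[below] + d * (intercepts[below] - lo)
  }
  above <- which(intercepts > hi)
  if (length(above) > 0) {
    d <- edge(hi, -1)
    pred[above] <- pred[above] + d * (intercepts[above] - hi)
  }
  pred
}

#' Residual methylation fractions
#'
#' Subtracts each site's expected entropy drift from its observed
#' methylation: `RMF[i, j] = OMF[i, j] - age[j] * expected_slope[i]`. Values
#' may leave `[0, 1]` and are deliberately not clipped; the residual is a
#' regression quantity, not a fraction.
#'
#' @param fractions sites x samples matrix of original methylation fractions.
#' @param ages ages in months, one per sample.
#' @param expected_slope expected slope per site.
#' @return matrix of residual methylation fractions, same shape as
#'   `fractions`.
#' @export
compute_rmf <- function(fractions, ages, expected_slope) {
  fractions <- as.matrix(fractions)
  if (length(expected_slope) != nrow(fractions)) {
    stop("expected_slope must have one value per site")
  }
  if (length(ages) != ncol(fractions)) stop("ages must match samples")
  fractions - outer(expected_slope, ages)
}

#' Classify sites relative to the average entropy trajectory
#'
#' Combines the significance of the original (OMF) and entropy-normalized
#' (RMF) age fits into one category per site:
#'
#' * OMF not significant, RMF significant: `resist` (the site holds its
#'   methylation against the entropy drift);
#' * OMF significant, RMF not: `follow_entropy` (its change is fully
#'   explained by the average entropy effect);
#' * neither significant: `stable`;
#' * both significant: `exceed_entropy` when the observed slope has the same
#'   sign as the expected slope and larger magnitude, `slower_than_entropy`
#'   for same sign and smaller magnitude, `counter_entropy` for opposite
#'   sign.
#'
#' @param omf_fit site-fit data.frame for OMF (needs `site_id`, `slope`, `q`).
#' @param rmf_fit site-fit data.frame for RMF, same sites.
#' @param expected_slope expected slope per site (aligned with `omf_fit`).
#' @param alpha significance level applied to both fits.
#' @return data.frame with `site_id`, `omf_significant`, `rmf_significant`,
#'   `category`.
#' @export
classify_entropy_relation <- function(omf_fit, rmf_fit, expected_slope,
                                      alpha = 0.05) {
  if (!identical(as.character(omf_fit$site_id), as.character(rmf_fit$site_id))) {
    stop("OMF and RMF fits must cover the same sites in the same order")
  }
  if (length(expected_slope) != nrow(omf_fit)) {
    stop("expected_slope must align with the site fits")
  }
  omf_sig <- omf_fit$q < alpha
  rmf_sig <- rmf_fit$q < alpha
  same_sign <- sign(omf_fit$slope) == sign(expected_slope)
  larger <- abs(omf_fit$slope) > abs(expected_slope)
  category <- ifelse(!omf_sig & rmf_sig, "resist",
              ifelse(omf_sig & !rmf_sig, "follow_entropy",
              ifelse(!omf_sig & !rmf_sig, "stable",
              ifelse(!same_sign, "counter_entropy",
              ifelse(larger, "exceed_entropy", "slower_than_entropy")))))
  data.frame(site_id = omf_fit$site_id, omf_significant = omf_sig,
             rmf_significant = rmf_sig, category = category,
             stringsAsFactors = FALSE)
}

#' Entropy normalization of a fitted cohort
#'
#' End-to-end wrapper: fits the expected-slope smooth on the significant
#' sites of an OMF site-fit table, evaluates it for all sites, computes the
#' residual methylation fractions, refits the age model on the RMF (same
#' machinery, including the transformation grid and BH adjustment) and
#' classifies every site relative to the entropy trajectory.
#'
#' @param fractions sites x samples OMF matrix.
#' @param samples sample sheet.
#' @param omf_fit OMF site-fit table from [fit_age_models()].
#' @param alpha significance level.
#' @param basis_dim spline basis dimension for the smooth.
#' @param ... passed to [fit_age_models()] for the RMF refit.
#' @return list with `smooth` (the [fit_expected_slope()] fit),
#'   `expected_slope` (per site), `rmf` (matrix), `rmf_fit` (site-fit table),
#'   `classes` (classification table) and `overlap` (OMF/RMF significant-site
#'   two-set counts).
#' @export
run_entropy_normalization <- function(fractions, samples, omf_fit,
                                      alpha = 0.05, basis_dim = 20, ...) {
  samples <- validate_sample_sheet(samples)
  sig <- omf_fit$q < alpha
  smooth <- fit_expected_slope(omf_fit$intercept[sig], omf_fit$slope[sig],
                               basis_dim = basis_dim)
  expected <- predict_expected_slope(smooth, omf_fit$intercept)
  rmf <- compute_rmf(fractions, samples$age, expected)
  rmf_fit <- fit_age_models(rmf, samples, alpha = alpha, ...)
  classes <- classify_entropy_relation(omf_fit, rmf_fit, expected, alpha)
  overlap <- c(omf_only = sum(sig & rmf_fit$q >= alpha),
               rmf_only = sum(!sig & rmf_fit$q < alpha),
               both = sum(sig & rmf_fit$q < alpha),
               neither = sum(!sig & rmf_fit$q >= alpha))
  list(smooth = smooth, expected_slope = expected, rmf = rmf,
       rmf_fit = rmf_fit, classes = classes, overlap = overlap)
}
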