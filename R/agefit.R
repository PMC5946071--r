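#' Per-site linear regression of methylation on age
#'
#' Ordinary least squares of methylation fraction on age plus optional
#' confounder columns, fitted site-by-site (all sites share the design
#' matrix, so the fit is vectorized). Returns the age coefficient, the
#' intercept and the two-sided p-value of the age coefficient.
#'
#' @param fractions numeric matrix (sites x samples) or vector (one site) of
#'   methylation fractions.
#' @param ages ages in months, one per sample.
#' @param confounders optional data.frame of numeric per-sample covariates.
#' @return data.frame with columns `slope`, `intercept`, `se`, `p` (one row
#'   per site).
#' @export
fit_site_linear <- function(fractions, ages, confounders = NULL) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1)
  n <- length(ages)
  if (ncol(fractions) != n) stop("fractions must have one column per sample")
  C <- confounder_matrix(confounders, n)
  if (n < ncol(C) + 3) stop("insufficient samples for the requested model")
  X <- cbind(`(Intercept)` = 1, age = ages, C)
  fit <- ols_multi(X, t(fractions))
  out <- data.frame(slope = fit$coef["age", ],
                    intercept = fit$coef["(Intercept)", ],
                    se = fit$se["age", ],
                    p = fit$p["age", ])
  if (!is.null(rownames(fractions))) out <- cbind(site_id = rownames(fractions), out)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment. Validates the input range and
#' delegates to the standard implementation.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method adjustment method (default `"BH"`).
#' @return vector of adjusted p-values, elementwise `>= p`.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Transformation grid with AIC model selection
#'
#' For every site, fits each candidate model `g(age) ~ m^power + confounders`
#' with `g` in `responses` (identity or natural log of age) and `power` over
#' `grid`, and selects the lowest-AIC model. `AIC = n log(RSS/n) + 2k`; when
#' the response is `ln_age` a Jacobian term `2 * sum(log(age))` is added so
#' AIC values are comparable across response transforms (disable with
#' `naive_aic = TRUE`). Models within `delta_aic` of the minimum are resolved
#' toward the plain linear model `(age, 1)` when it is among them.
#'
#' Fractions are clipped to `[eps, 1 - eps]` before negative powers are taken.
#'
#' @param fractions numeric matrix (sites x samples) or vector (one site).
#' @param ages ages in months.
#' @param confounders optional per-sample covariate data.frame.
#' @param grid powers of the methylation predictor
#'   (default `c(-13, -5, -1, 1, 5, 13)`).
#' @param responses response transforms to consider.
#' @param eps clipping bound for fractions.
#' @param delta_aic tie window for preferring the linear model.
#' @param naive_aic drop the Jacobian correction (raw per-response AICs).
#' @return list with `aic` (sites x models matrix, columns named
#'   `response:power`), `best_response`, `best_power` (vectors per site).
#' @export
fit_transform_grid <- function(fractions, ages, confounders = NULL,
                               grid = c(-13, -5, -1, 1, 5, 13),
                               responses = c("age", "ln_age"),
                               eps = 1e-4, delta_aic = 2, naive_aic = FALSE) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1)
  n <- length(ages)
  if (ncol(fractions) != n) stop("fractions must have one column per sample")
  C <- confounder_matrix(confounders, n)
  k <- 3 + ncol(C)  # intercept + predictor + confounders + sigma
  if (n <= k) stop("too few samples for the transformation-grid fit")
  m <- clip_range(as.matrix(fractions), eps, 1 - eps)
  Z <- cbind(1, C)
  S <- nrow(m)
  models <- expand.grid(power = grid, response = responses,
                        stringsAsFactors = FALSE)
  aic <- matrix(NA_real_, S, nrow(models))
  colnames(aic) <- paste0(models$response, ":", models$power)
  for (j in seq_len(nrow(models))) {
    y <- if (models$response[j] == "age") ages else log(ages)
    y_r <- residualize(matrix(y, ncol = 1), Z)[, 1]
    X_r <- residualize(t(m^models$power[j]), Z)  # n x S
    sxx <- colSums(X_r^2)
    sxy <- colSums(X_r * y_r)
    slope <- ifelse(sxx > 0, sxy / sxx, 0)
    rss <- pmax(sum(y_r^2) - slope^2 * sxx, 1e-300)
    a <- n * log(rss / n) + 2 * k
    if (models$response[j] == "ln_age" && !naive_aic) {
      a <- a + 2 * sum(log(ages))
    }
    aic[, j] <- a
  }
  best <- max.col(-aic, ties.method = "first")
  lin_col <- which(models$response == "age" & models$power == 1)
  if (length(lin_col) == 1) {
    minaic <- aic[cbind(seq_len(S), best)]
    prefer_lin <- aic[, lin_col] - minaic < delta_aic
    best[prefer_lin] <- lin_col
  }
  list(aic = aic,
       best_response = models$response[best],
       best_power = models$power[best])
}

#' Classify the aging dynamics of a significant site
#'
#' Maps the selected model family to a dynamics label: response `age` with
#' predictor power `<= -5` marks late-life-accelerating change (the inverse
#' power law steepens where methylation approaches the regime the regression
#' resolves), response `ln_age` marks early-adulthood change, and everything
#' else is labeled linear.
#'
#' @param best_response,best_power selected model per site
#'   (from [fit_transform_grid()]).
#' @param significant logical per site (`q < alpha` from the linear fit).
#' @return character vector of labels (`late_accelerating`, `early_change`,
#'   `linear`); errors if a non-significant site is classified.
#' @export
classify_dynamics <- function(best_response, best_power, significant) {
  if (!all(significant)) {
    stop("dynamics classification is defined only for significant sites")
  }
  ifelse(best_response == "age" & best_power <= -5, "late_accelerating",
         ifelse(best_response == "ln_age", "early_change", "linear"))
}

#' Fit the full per-site age model table
#'
#' Convenience wrapper producing the complete site-fit table: linear slope,
#' intercept and p-value per site, BH-adjusted q, direction (gain / loss /
#' none at `q < alpha`), and, for significant sites, the best transformation
#' model and its dynamics class. Significance is decided on the untransformed
#' linear model; the grid only characterizes dynamics among significant
#' sites.
#'
#' @param fractions sites x samples fraction matrix.
#' @param samples sample sheet (control samples are used for the age fit
#'   unless `use_all = TRUE`).
#' @param alpha significance level on the BH-adjusted p (default 0.05).
#' @param grid transformation powers, as in [fit_transform_grid()].
#' @param confounders optional confounder data.frame aligned with `samples`;
#'   defaults to the numeric extra columns of the sample sheet.
#' @param use_all include CR samples in the age regression (default: control
#'   only).
#' @param ... passed to [fit_transform_grid()].
#' @return data.frame (one row per site): `site_id`, `slope`, `intercept`,
#'   `se`, `p`, `q`, `direction`, `best_response`, `best_power`, `dynamics`.
#' @export
fit_age_models <- function(fractions, samples, alpha = 0.05,
                           grid = c(-13, -5, -1, 1, 5, 13),
                           confounders = NULL, use_all = FALSE, ...) {
  samples <- validate_sample_sheet(samples)
  if (is.null(confounders)) confounders <- sample_confounders(samples)
  use <- if (use_all) rep(TRUE, nrow(samples)) else samples$group == "control"
  fr <- fractions[, use, drop = FALSE]
  ages <- samples$age[use]
  conf <- if (ncol(confounders) > 0) confounders[use, , drop = FALSE] else NULL
  fit <- fit_site_linear(fr, ages, conf)
  fit$q <- adjust_pvalues(fit$p)
  fit$direction <- ifelse(fit$q < alpha,
                          ifelse(fit$slope > 0, "gain", "loss"), "none")
  fit$best_response <- NA_character_
  fit$best_power <- NA_real_
  fit$dynamics <- "none"
  sig <- which(fit$direction != "none")
  if (length(sig) > 0) {
    gridfit <- fit_transform_grid(fr[sig, , drop = FALSE], ages, conf,
                                  grid = grid, ...)
    fit$best_response[sig] <- gridfit$best_response
    fit$best_power[sig] <- gridfit$best_power
    fit$dynamics[sig] <- classify_dynamics(gridfit$best_response,
                                           gridfit$best_power,
                                           rep(TRUE, length(sig)))
  }
  if (is.null(fit$site_id)) fit <- cbind(site_id = rownames(fractions) %||%
                                           paste0("site", seq_len(nrow(fit))), fit)
  fit
}

#' Global methylome trend with age
#'
#' Regresses the per-sample mean methylation fraction on age (plus optional
#' confounders); a negative slope indicates global hypomethylation with age.
#'
#' @param fractions sites x samples fraction matrix.
#' @param ages ages in months.
#' @param confounders optional per-sample covariates.
#' @return one-row data.frame with `slope`, `intercept`, `se`, `p`.
#' @export
global_trend <- function(fractions, ages, confounders = NULL) {
  if (is.null(dim(fractions))) fractions <- matrix(fractions, nrow = 1)
  sample_means <- colMeans(fractions, na.rm = TRUE)
  out <- fit_site_linear(matrix(sample_means, nrow = 1), ages, confounders)
  out$site_id <- NULL
  out
}

#' Permutation comparison of lifespan-average methylation between site sets
#'
#' The statistic is the difference of the mean (over sites) of the
#' lifespan-average methylation between two site sets. The null is built by
#' randomly reassigning set labels across the union; the p-value uses the
#' add-one estimator `(1 + #{|null| >= |observed|}) / (1 + n_perm)`.
#'
#' @param setA,setB site indices or ids.
#' @param fractions sites x samples fraction matrix (rownames = site ids).
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed for the label shuffles.
#' @return list with `difference`, `p`, `n_perm`.
#' @export
compare_site_set_means <- function(setA, setB, fractions, n_perm = 9999,
                                   seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.character(setA)) setA <- match(setA, rownames(fractions))
  if (is.character(setB)) setB <- match(setB, rownames(fractions))
  if (length(setA) < 1 || length(setB) < 1) stop("site sets must be non-empty")
  site_means <- rowMeans(fractions, na.rm = TRUE)
  obs <- mean(site_means[setA]) - mean(site_means[setB])
  pool <- c(site_means[setA], site_means[setB])
  nA <- length(setA); nTot <- length(pool)
  set.seed(seed)
  null <- replicate(n_perm, {
    idx <- sample.int(nTot, nA)
    mean(pool[idx]) - mean(pool[-idx])
  })
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  list(difference = obs, p = p, n_perm = n_perm)
}
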