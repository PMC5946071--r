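#' Normalized Shannon entropy of a methylation profile
#'
#' Per-sample entropy of the methylome over a site set:
#' `H = 1 / (N * ln(1/2)) * sum_i( m_i ln m_i + (1 - m_i) ln(1 - m_i) )`.
#' The normalization fixes `H = 1` when every site is at 0.5 and `H = 0`
#' when every site is fully methylated or unmethylated. Fractions are clipped
#' to `[1e-6, 1 - 1e-6]` before the logs, so exact 0/1 sites contribute 0 by
#' continuity. The base of the logarithm cancels under the normalization.
#'
#' @param m numeric vector of methylation fractions for one sample (or a
#'   sites x samples matrix; entropy is computed per column).
#' @return scalar entropy in `[0, 1]` (or a vector, one per sample).
#' @export
sample_entropy <- function(m) {
  if (is.null(dim(m))) {
    if (length(m) == 0) stop("entropy of an empty site set is undefined")
    mc <- clip_range(m, 1e-6, 1 - 1e-6)
    return(sum(mc * log(mc) + (1 - mc) * log(1 - mc)) / (length(mc) * log(0.5)))
  }
  if (nrow(m) == 0) stop("entropy of an empty site set is undefined")
  mc <- clip_range(m, 1e-6, 1 - 1e-6)
  colSums(mc * log(mc) + (1 - mc) * log(1 - mc), na.rm = TRUE) /
    (colSums(!is.na(mc)) * log(0.5))
}

#' Entropy trajectory over age
#'
#' Fits the per-sample entropy against age with the same linear model and
#' transformation grid used for per-site methylation, returning the linear
#' slope/p-value and the best-AIC model of the `g(age) ~ H^power` family.
#'
#' @param H per-sample entropy values.
#' @param ages ages in months.
#' @param confounders optional per-sample covariates.
#' @param grid transformation powers (as in [fit_transform_grid()]).
#' @param ... passed to [fit_transform_grid()].
#' @return list with `slope`, `intercept`, `p` (linear fit), `best_response`,
#'   `best_power`.
#' @export
entropy_vs_age <- function(H, ages, confounders = NULL,
                           grid = c(-13, -5, -1, 1, 5, 13), ...) {
  if (length(H) < 8) stop("at least 8 samples required for the entropy fit")
  lin <- fit_site_linear(matrix(H, nrow = 1), ages, confounders)
  gridfit <- fit_transform_grid(matrix(H, nrow = 1), ages, confounders,
                                grid = grid, ...)
  list(slope = lin$slope, intercept = lin$intercept, p = lin$p,
       best_response = gridfit$best_response,
       best_power = gridfit$best_power, aic = gridfit$aic[1, ])
}

#' Permutation comparison of entropy between two site sets
#'
#' The statistic is the mean over samples of `H(set A) - H(set B)`. The null
#' relabels sites across the union of the two sets (site-level permutation:
#' the compared unit is the site set); `perm_unit = "samples"` permutes
#' sample columns instead.
#'
#' @param setA,setB site indices or ids.
#' @param fractions sites x samples fraction matrix.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param perm_unit `"sites"` (default) or `"samples"`.
#' @return list with `delta_H` (mean over samples), `delta_H_by_sample`,
#'   `p`, `n_perm`.
#' @export
entropy_permutation_compare <- function(setA, setB, fractions, n_perm = 9999,
                                        seed = 1L, perm_unit = c("sites", "samples")) {
  perm_unit <- match.arg(perm_unit)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.character(setA)) setA <- match(setA, rownames(fractions))
  if (is.character(setB)) setB <- match(setB, rownames(fractions))
  if (length(setA) < 1 || length(setB) < 1) stop("site sets must be non-empty")
  HA <- sample_entropy(fractions[setA, , drop = FALSE])
  HB <- sample_entropy(fractions[setB, , drop = FALSE])
  delta <- HA - HB
  obs <- mean(delta)
  set.seed(seed)
  nA <- length(setA)
  pool <- c(setA, setB)
  if (perm_unit == "sites") {
    # precompute per-site entropy terms once; permutations only re-pool them
    mc <- clip_range(fractions[pool, , drop = FALSE], 1e-6, 1 - 1e-6)
    E <- mc * log(mc) + (1 - mc) * log(1 - mc)
    nB <- length(setB)
    null <- replicate(n_perm, {
      idx <- sample.int(length(pool), nA)
      mean(colSums(E[idx, , drop = FALSE]) / (nA * log(0.5)) -
             colSums(E[-idx, , drop = FALSE]) / (nB * log(0.5)))
    })
  } else {
    n <- ncol(fractions)
    null <- replicate(n_perm, {
      flip <- sample(c(-1, 1), n, replace = TRUE)
      mean(delta * flip)
    })
  }
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  list(delta_H = obs, delta_H_by_sample = delta, p = p, n_perm = n_perm)
}
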