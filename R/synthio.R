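#' Site trajectory specification
#'
#' Defines the latent mean-methylation trajectory of one CpG site across age.
#' Five trajectory families are supported, mirroring the dynamics observed in
#' aging RRBS methylomes:
#'
#' * `stable`: constant at `m0`.
#' * `linear`: `m(age) = m0 + slope * age`.
#' * `late_accel`: the inverse of the power-law regression family
#'   `age = a + b * m^-13`, i.e. `m(age) = ((age - a) / b)^(-1/13)`; with
#'   `mirror = TRUE` the trajectory is reflected (`1 - m`) so that both gain
#'   and loss directions are representable by the same law.
#' * `early_change`: logarithmic early-adulthood change,
#'   `m(age) = m0 + d * ln(age)`.
#' * `entropy_drift`: exponential shrinkage toward 0.5 at `kappa` per month,
#'   `m(age) = 0.5 + (m0 - 0.5) * exp(-kappa * age)`.
#'
#' @param class_name one of `"stable"`, `"linear"`, `"late_accel"`,
#'   `"early_change"`, `"entropy_drift"`.
#' @param m0 baseline fraction in `[0, 1]` (used by stable/linear/early/drift).
#' @param slope fraction change per month (linear).
#' @param a,b coefficients of `age = a + b * m^-13` (late_accel).
#' @param d coefficient of `m0 + d * ln(age)` (early_change).
#' @param kappa per-month shrinkage rate toward 0.5 (entropy_drift).
#' @param mirror reflect a late_accel trajectory around 0.5 of the unit
#'   interval (`m -> 1 - m`), giving a gaining counterpart of the same law.
#' @return a `site_class_spec` list.
#' @export
site_class_spec <- function(class_name, m0 = NA_real_, slope = NA_real_,
                            a = NA_real_, b = NA_real_, d = NA_real_,
                            kappa = NA_real_, mirror = FALSE) {
  class_name <- match.arg(class_name,
    c("stable", "linear", "late_accel", "early_change", "entropy_drift"))
  spec <- list(class_name = class_name, m0 = m0, slope = slope, a = a, b = b,
               d = d, kappa = kappa, mirror = isTRUE(mirror))
  class(spec) <- "site_class_spec"
  spec
}

#' Calorie-restriction effect specification
#'
#' An instantaneous shift at treatment start plus an additional slope for
#' every month on treatment, applied only to treated samples at or past the
#' treatment-start age.
#'
#' @param t0 treatment-start age in months.
#' @param is_shift instantaneous fraction shift at `t0`.
#' @param tat_slope additional fraction change per month after `t0`
#'   (time-after-treatment slope).
#' @return a `cr_spec` list.
#' @export
cr_spec <- function(t0, is_shift = 0, tat_slope = 0) {
  stopifnot(is.numeric(t0), t0 > 0)
  structure(list(t0 = t0, is_shift = is_shift, tat_slope = tat_slope),
            class = "cr_spec")
}

#' Latent mean methylation trajectory of one site
#'
#' Evaluates the noise-free mean methylation fraction of a site at the given
#' ages, clipped to `[0.001, 0.999]`.
#'
#' @param spec a [site_class_spec()].
#' @param ages positive ages in months.
#' @return numeric vector of fractions, one per age.
#' @export
simulate_trajectory <- function(spec, ages) {
  stopifnot(inherits(spec, "site_class_spec"), all(ages > 0))
  m <- switch(spec$class_name,
    stable = rep(spec$m0, length(ages)),
    linear = spec$m0 + spec$slope * ages,
    late_accel = {
      x <- (ages - spec$a) / spec$b
      if (any(x <= 0)) {
        stop(sprintf(
          "late_accel trajectory undefined at age <= a (a = %g, b = %g): the law age = a + b*m^-13 has no valid methylation value there",
          spec$a, spec$b))
      }
      v <- x^(-1 / 13)
      if (spec$mirror) 1 - v else v
    },
    early_change = spec$m0 + spec$d * log(ages),
    entropy_drift = 0.5 + (spec$m0 - 0.5) * exp(-spec$kappa * ages)
  )
  clip_range(m, 0.001, 0.999)
}

#' Apply a calorie-restriction effect to latent fractions
#'
#' Adds `is_shift + tat_slope * (age - t0)` to the latent fraction of every
#' sample at or past the treatment-start age, then clips to `[0.001, 0.999]`.
#' Samples below `t0` are returned unchanged.
#'
#' @param latent numeric vector of latent fractions, one per sample.
#' @param ages ages in months, aligned with `latent`.
#' @param cr a [cr_spec()].
#' @return adjusted latent fractions.
#' @export
apply_cr <- function(latent, ages, cr) {
  stopifnot(inherits(cr, "cr_spec"), length(latent) == length(ages))
  on_cr <- ages >= cr$t0
  latent[on_cr] <- latent[on_cr] + cr$is_shift + cr$tat_slope * (ages[on_cr] - cr$t0)
  clip_range(latent, 0.001, 0.999)
}

#' Cohort design for the synthetic RRBS generator
#'
#' Defaults emulate an aging mouse blood cohort: 16 age groups spanning
#' 3--35 months with 9 control animals each, plus calorie-restricted animals
#' in four groups between 10 and 27 months treated from 4 months of age.
#' Read depth is negative-binomial, methylated counts binomial around a
#' jittered latent fraction, and the site-class mixture produces a methylome
#' that is bimodal (most fractions near 0 or 1) with a minority of sites
#' gaining or losing methylation with age.
#'
#' @param n_sites number of CpG sites.
#' @param age_groups ages (months) of the control groups.
#' @param n_per_group control samples per age group.
#' @param cr_age_groups ages (months) of the calorie-restricted groups
#'   (empty vector for a control-only cohort).
#' @param n_cr_per_group treated samples per CR age group.
#' @param t0 treatment-start age in months.
#' @param class_mixture named proportions over the trajectory classes;
#'   must sum to 1. Class counts are fixed by largest-remainder rounding so
#'   the realized mixture matches exactly.
#' @param coverage_mean,coverage_dispersion negative-binomial read-depth mean
#'   and size parameter (larger size = less overdispersion).
#' @param noise_sd per-sample Gaussian jitter on the latent fraction.
#' @param is_coupling,tat_coupling couplings of CR effects to each changing
#'   site's linearized aging slope: `is_shift = is_coupling * slope` and
#'   `tat_slope = -tat_coupling * slope` (plus small site-level noise),
#'   giving an initial shift in the direction of aging and a cumulative
#'   effect opposing it.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a `cohort_design` list.
#' @export
cohort_design <- function(n_sites = 10000,
                          age_groups = c(3, 5, 7, 9, 10, 12, 14, 16, 18, 21,
                                         23, 25, 27, 30, 32, 35),
                          n_per_group = 9,
                          cr_age_groups = c(10, 16, 21, 27),
                          n_cr_per_group = 9,
                          t0 = 4,
                          class_mixture = c(stable = 0.72, linear = 0.04,
                                            late_accel = 0.18,
                                            early_change = 0.03,
                                            entropy_drift = 0.03),
                          coverage_mean = 30,
                          coverage_dispersion = 5,
                          noise_sd = 0.02,
                          is_coupling = 6,
                          tat_coupling = 0.4,
                          seed = 1L) {
  if (abs(sum(class_mixture) - 1) > 1e-8) stop("class_mixture must sum to 1")
  if (any(class_mixture < 0)) stop("class_mixture proportions must be >= 0")
  if (coverage_mean <= 0) stop("coverage_mean must be positive")
  if (n_sites < 1 || n_per_group < 1) stop("all counts must be >= 1")
  if (length(cr_age_groups) > 0 && any(cr_age_groups < t0))
    stop("CR age groups must be at or past the treatment-start age t0")
  structure(list(n_sites = as.integer(n_sites), age_groups = age_groups,
                 n_per_group = as.integer(n_per_group),
                 cr_age_groups = cr_age_groups,
                 n_cr_per_group = as.integer(n_cr_per_group), t0 = t0,
                 class_mixture = class_mixture,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 noise_sd = noise_sd, is_coupling = is_coupling,
                 tat_coupling = tat_coupling, seed = as.integer(seed)),
            class = "cohort_design")
}

# Exact class counts by largest-remainder rounding, so the realized mixture
# matches the requested proportions exactly up to integer feasibility.
mixture_counts <- function(mixture, n) {
  raw <- mixture * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(counts), names(mixture))
}

# Draw per-site trajectory parameters for one class, using the current RNG
# stream. Returns a site_class_spec plus bookkeeping (direction, linearized
# slope over the cohort age span) for the truth table.
draw_site_params <- function(class_name, age_min, age_max) {
  dir <- if (stats::runif(1) < 0.5) "gain" else "loss"
  span <- age_max - age_min
  spec <- switch(class_name,
    stable = {
      m0 <- stats::rbeta(1, 0.4, 0.4)
      site_class_spec("stable", m0 = clip_range(m0, 0.02, 0.98))
    },
    linear = {
      if (dir == "gain") {
        m0 <- stats::runif(1, 0.05, 0.30); s <- 0.005
      } else {
        m0 <- stats::runif(1, 0.70, 0.95); s <- -0.005
      }
      site_class_spec("linear", m0 = m0, slope = s)
    },
    late_accel = {
      m_start <- stats::runif(1, 0.60, 0.90)
      m_end <- max(0.15, m_start - stats::runif(1, 0.20, 0.40))
      b <- span / (m_end^-13 - m_start^-13)
      a <- age_min - b * m_start^-13
      site_class_spec("late_accel", a = a, b = b, mirror = (dir == "gain"))
    },
    early_change = {
      d <- stats::runif(1, 0.02, 0.05)
      if (dir == "gain") {
        m0 <- stats::runif(1, 0.05, 0.25)
      } else {
        m0 <- stats::runif(1, 0.75, 0.95); d <- -d
      }
      # m(age) = m0 + d*ln(age); keep within the unit interval over the span
      site_class_spec("early_change", m0 = m0, d = d)
    },
    entropy_drift = {
      m0 <- if (dir == "gain") stats::runif(1, 0.03, 0.25) else stats::runif(1, 0.75, 0.97)
      site_class_spec("entropy_drift", m0 = m0, kappa = stats::runif(1, 0.01, 0.03))
    })
  traj <- simulate_trajectory(spec, c(age_min, age_max))
  lin_slope <- (traj[2] - traj[1]) / span
  if (class_name == "stable") dir <- "none"
  list(spec = spec, direction = dir, lin_slope = lin_slope)
}

#' Sample read counts around latent fractions
#'
#' Draws per-entry coverage from a negative binomial (floored at 1 read) and
#' methylated counts from a binomial around the latent fraction jittered by
#' truncated Gaussian noise. All randomness flows through deterministic
#' per-site substreams of the design seed, so the same seed reproduces the
#' matrix bit-identically and each site's counts do not depend on which other
#' sites are generated.
#'
#' @param latent numeric matrix (sites x samples) of latent fractions in
#'   `[0, 1]`.
#' @param design a [cohort_design()]; only the read-model fields and seed
#'   are used.
#' @param sample_ids optional sample ids (defaults to `S1..Sn`).
#' @param chrom,spacing genomic placement of the synthetic CpGs: site `i`
#'   is a 2-bp CpG at 0-based start `1000 + spacing * (i - 1)`.
#' @return a [methylome_matrix()].
#' @export
sample_counts <- function(latent, design, sample_ids = NULL,
                          chrom = "chr1", spacing = 100L) {
  latent <- as.matrix(latent)
  if (any(latent < 0 | latent > 1)) stop("latent fractions must lie in [0, 1]")
  if (design$coverage_mean <= 0) stop("coverage_mean must be positive")
  S <- nrow(latent); n <- ncol(latent)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  meth <- matrix(0L, S, n)
  total <- matrix(0L, S, n)
  for (i in seq_len(S)) {
    set.seed(site_seed(design$seed, i))
    cov <- pmax(1L, stats::rnbinom(n, mu = design$coverage_mean,
                                   size = design$coverage_dispersion))
    p <- clip_range(latent[i, ] + stats::rnorm(n, 0, design$noise_sd), 0, 1)
    meth[i, ] <- stats::rbinom(n, cov, p)
    total[i, ] <- cov
  }
  starts <- 1000L + spacing * (seq_len(S) - 1L)
  sites <- data.frame(chrom = chrom, start = starts, end = starts + 2L,
                      strand = "*")
  methylome_matrix(sites, meth, total, sample_ids)
}

#' Simulate a full aging / calorie-restriction cohort
#'
#' Builds the sample sheet, draws per-site trajectory classes and parameters,
#' evaluates latent fractions at every sample's age (applying the CR effect to
#' treated samples), and samples read counts. The returned truth table records
#' each site's class, direction, trajectory parameters, linearized slope and
#' CR effect, aligned row-by-row with the count matrix.
#'
#' @param design a [cohort_design()].
#' @return list with elements `matrix` ([methylome_matrix()]),
#'   `samples` (sample sheet data.frame) and `truth` (truth table data.frame).
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  ages_ctrl <- rep(design$age_groups, each = design$n_per_group)
  ids_ctrl <- sprintf("C%02d_%02d", rep(seq_along(design$age_groups),
                                        each = design$n_per_group),
                      rep(seq_len(design$n_per_group),
                          length(design$age_groups)))
  if (length(design$cr_age_groups) > 0) {
    ages_cr <- rep(design$cr_age_groups, each = design$n_cr_per_group)
    ids_cr <- sprintf("R%02d_%02d", rep(seq_along(design$cr_age_groups),
                                        each = design$n_cr_per_group),
                      rep(seq_len(design$n_cr_per_group),
                          length(design$cr_age_groups)))
  } else {
    ages_cr <- numeric(0); ids_cr <- character(0)
  }
  samples <- data.frame(
    sample_id = c(ids_ctrl, ids_cr),
    age = c(ages_ctrl, ages_cr),
    group = c(rep("control", length(ids_ctrl)), rep("CR", length(ids_cr))),
    t0 = c(rep(NA_real_, length(ids_ctrl)), rep(design$t0, length(ids_cr))),
    stringsAsFactors = FALSE)

  counts <- mixture_counts(design$class_mixture, design$n_sites)
  classes <- rep(names(counts), counts)
  set.seed(design$seed)
  classes <- sample(classes)

  age_min <- min(design$age_groups)
  age_max <- max(design$age_groups)
  n <- nrow(samples)
  is_cr <- samples$group == "CR"
  latent <- matrix(NA_real_, design$n_sites, n)
  truth <- vector("list", design$n_sites)
  for (i in seq_len(design$n_sites)) {
    set.seed(site_seed(design$seed, i) %% 2147483646L + 1L)
    ps <- draw_site_params(classes[i], age_min, age_max)
    if (ps$direction == "none") {
      cr_i <- cr_spec(design$t0, 0, 0)
    } else {
      cr_i <- cr_spec(design$t0,
        is_shift = design$is_coupling * ps$lin_slope + stats::rnorm(1, 0, 0.002),
        tat_slope = -design$tat_coupling * ps$lin_slope + stats::rnorm(1, 0, 2e-4))
    }
    lat <- simulate_trajectory(ps$spec, samples$age)
    if (any(is_cr)) {
      lat[is_cr] <- apply_cr(lat[is_cr], samples$age[is_cr], cr_i)
    }
    latent[i, ] <- lat
    truth[[i]] <- data.frame(
      class_name = classes[i], direction = ps$direction,
      m0 = ps$spec$m0, slope = ps$spec$slope, a = ps$spec$a, b = ps$spec$b,
      d = ps$spec$d, kappa = ps$spec$kappa, mirror = ps$spec$mirror,
      lin_slope = ps$lin_slope, is_shift = cr_i$is_shift,
      tat_slope = cr_i$tat_slope, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  mm <- sample_counts(latent, design, sample_ids = samples$sample_id)
  truth <- cbind(site_id = mm$sites$site_id, truth)
  rownames(truth) <- NULL
  list(matrix = mm, samples = samples, truth = truth, latent = latent)
}

#' Synthetic region annotation for a simulated cohort
#'
#' Builds BED-style interval annotations (labels `CGI`, `CGI_shore`,
#' `CGI_shelf`, `promoter`, `intron`) over the synthetic genome so that
#' region-level operations are exercisable end-to-end. CpG islands
#' preferentially cover methylation-gaining sites (reflecting the CGI gain
#' typical of aging methylomes), shores and shelves flank the islands, a
#' promoter covers each island plus margin, and introns cover a sample of the
#' remaining loss-leaning sites. The annotation is synthetic: it carries no
#' biological meaning beyond its overlap structure with the generated sites.
#'
#' @param cohort output of [simulate_cohort()].
#' @param p_cgi_gain probability a gaining site seeds a CGI.
#' @param p_cgi_other probability any other site seeds a CGI.
#' @param seed RNG seed for the annotation draw.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`, `label`.
#' @export
simulate_region_annotation <- function(cohort, p_cgi_gain = 0.6,
                                       p_cgi_other = 0.05, seed = 1L) {
  sites <- cohort$matrix$sites
  truth <- cohort$truth
  set.seed(seed)
  gain <- truth$direction == "gain"
  seed_cgi <- stats::runif(nrow(sites)) < ifelse(gain, p_cgi_gain, p_cgi_other)
  regs <- list()
  if (any(seed_cgi)) {
    s <- sites[seed_cgi, ]
    regs$CGI <- data.frame(chrom = s$chrom, start = s$start - 10L,
                           end = s$end + 10L, strand = "*", label = "CGI")
    regs$shore_l <- data.frame(chrom = s$chrom, start = s$start - 50L,
                               end = s$start - 10L, strand = "*",
                               label = "CGI_shore")
    regs$shore_r <- data.frame(chrom = s$chrom, start = s$end + 10L,
                               end = s$end + 50L, strand = "*",
                               label = "CGI_shore")
    regs$shelf_l <- data.frame(chrom = s$chrom, start = s$start - 90L,
                               end = s$start - 50L, strand = "*",
                               label = "CGI_shelf")
    regs$shelf_r <- data.frame(chrom = s$chrom, start = s$end + 50L,
                               end = s$end + 90L, strand = "*",
                               label = "CGI_shelf")
    regs$promoter <- data.frame(chrom = s$chrom, start = s$start - 30L,
                                end = s$end + 30L, strand = "*",
                                label = "promoter")
  }
  loss_sites <- sites[truth$direction == "loss" & !seed_cgi, ]
  if (nrow(loss_sites) > 0) {
    keep <- stats::runif(nrow(loss_sites)) < 0.5
    s <- loss_sites[keep, ]
    if (nrow(s) > 0) {
      regs$intron <- data.frame(chrom = s$chrom, start = s$start - 5L,
                                end = s$end + 5L, strand = "*",
                                label = "intron")
    }
  }
  out <- do.call(rbind, regs)
  out$start <- pmax(0L, out$start)
  out <- out[out$start < out$end, ]
  rownames(out) <- NULL
  out
}
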