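#' Run the full analysis chain on a synthetic cohort
#'
#' Convenience driver exercising every stage end-to-end: simulate a cohort,
#' write and re-read the per-sample coverage files, run site selection, the
#' per-site age models, entropy analysis, entropy normalization, region-level
#' summaries on a synthetic annotation, and the calorie-restriction
#' decomposition. All randomness derives from the design seed, and result
#' files carry no timestamps, so reruns with the same design are
#' byte-identical.
#'
#' @param design a [cohort_design()].
#' @param out_dir output directory; result TSVs are written beneath it.
#' @param alpha significance level used throughout.
#' @param n_perm permutations for the entropy comparison.
#' @param write_files write coverage/sample/truth files and re-read them
#'   (exercises the IO round trip); if `FALSE` the in-memory matrix is used.
#' @return invisibly, a list with the main result objects (`report`,
#'   `site_fits`, `entropy`, `entnorm`, `regions`, `cr`).
#' @export
run_pipeline <- function(design, out_dir, alpha = 0.05, n_perm = 999,
                         write_files = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(design)
  samples <- cohort$samples
  if (write_files) {
    covdir <- file.path(out_dir, "coverage")
    write_coverage_files(cohort$matrix, covdir)
    utils::write.table(samples, file.path(out_dir, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cohort$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- file.path(covdir, paste0(samples$sample_id, ".cov"))
    mm <- read_coverage_files(paths, samples$sample_id)
  } else {
    mm <- cohort$matrix
  }

  pre <- preprocess_sites(mm, samples)
  fr <- meth_fractions(pre$matrix)
  ctrl <- samples$group == "control"

  fits <- fit_age_models(fr, samples, alpha = alpha)
  glob <- global_trend(fr[, ctrl, drop = FALSE], samples$age[ctrl])

  H_all <- sample_entropy(fr)
  sig <- which(fits$q < alpha)
  ent_fit_all <- entropy_vs_age(H_all[ctrl], samples$age[ctrl])
  ent <- list(H_all = H_all, fit_all = ent_fit_all)
  if (length(sig) >= 1) {
    H_sig <- sample_entropy(fr[sig, , drop = FALSE])
    ent$H_sig <- H_sig
    ent$fit_sig <- entropy_vs_age(H_sig[ctrl], samples$age[ctrl])
    gain <- which(fits$direction == "gain")
    loss <- which(fits$direction == "loss")
    if (length(gain) >= 1 && length(loss) >= 1) {
      ent$gain_vs_loss <- entropy_permutation_compare(
        loss, gain, fr, n_perm = n_perm, seed = design$seed)
    }
  }

  en <- if (length(sig) >= 50) {
    run_entropy_normalization(fr, samples, fits, alpha = alpha)
  } else {
    warning("fewer than 50 significant sites; entropy normalization skipped")
    NULL
  }

  regions_bed <- simulate_region_annotation(
    list(matrix = pre$matrix,
         truth = cohort$truth[match(pre$matrix$sites$site_id,
                                    cohort$truth$site_id), ]),
    seed = design$seed)
  membership <- assign_sites(pre$matrix$sites, regions_bed)
  ages_ctrl <- samples$age[ctrl]
  fr_ctrl <- fr[, ctrl, drop = FALSE]
  reg_rows <- list()
  for (lab in names(membership)) {
    msig <- intersect(membership[[lab]], sig)
    rs <- if (length(msig) >= 2)
      suppressWarnings(region_slope(msig, fr_ctrl, ages_ctrl,
                                    seed = design$seed)) else NULL
    if (!is.null(rs)) {
      reg_rows[[lab]] <- data.frame(label = lab, n_sites = rs$n_sites,
                                    mean_slope = rs$mean_slope,
                                    ci_lo = rs$ci[1], ci_hi = rs$ci[2])
    }
  }
  reg_slopes <- do.call(rbind, reg_rows)
  enr <- enrichment_fisher(membership, fits$direction)
  tiers <- NULL
  if (all(c("promoter", "CGI") %in% names(membership))) {
    msig <- intersect(membership$promoter, sig)
    if (length(msig) >= 2) {
      tiers <- cgi_sensitivity(msig, fr_ctrl, ages_ctrl,
                               cgi_idx = membership$CGI,
                               shore_idx = membership$CGI_shore %||% integer(0),
                               shelf_idx = membership$CGI_shelf %||% integer(0),
                               seed = design$seed)
      tiers <- cbind(label = "promoter", tiers)
    }
  }

  cr <- if (any(samples$group == "CR")) {
    run_cr_analysis(fr, samples, alpha = alpha)
  } else NULL

  meta <- list(seed = design$seed, n_sites = design$n_sites, alpha = alpha)
  tables <- list(
    filter_report = pre$report,
    site_fits = fits,
    global_trend = glob,
    entropy = data.frame(sample_id = samples$sample_id, age = samples$age,
                         group = samples$group, H_all = H_all,
                         H_sig = if (length(sig) >= 1) ent$H_sig else NA_real_),
    region_enrichment = enr)
  if (!is.null(en)) {
    tables$expected_slope <- data.frame(site_id = fits$site_id,
                                        expected_slope = en$expected_slope)
    tables$rmf_fits <- en$rmf_fit
    tables$entropy_classes <- en$classes
  }
  if (!is.null(reg_slopes)) tables$region_slopes <- reg_slopes
  if (!is.null(tiers)) tables$cgi_tiers <- tiers
  if (!is.null(cr)) {
    tables$cr_fits <- cr$cr_fit
    tables$cr_overlap <- data.frame(t(cr$overlap))
  }
  write_results(tables, file.path(out_dir, "results"), meta = meta)

  invisible(list(cohort = cohort, matrix = pre$matrix, report = pre$report,
                 site_fits = fits, global_trend = glob, entropy = ent,
                 entnorm = en, regions = list(bed = regions_bed,
                                              membership = membership,
                                              slopes = reg_slopes,
                                              enrichment = enr, tiers = tiers),
                 cr = cr))
}
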