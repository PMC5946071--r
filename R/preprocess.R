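#' Keep sites observed in every sample
#'
#' A site is common when it has at least one read in every sample (no `NA`
#' and coverage >= 1 everywhere).
#'
#' @param x a [methylome_matrix()].
#' @return logical vector, `TRUE` for sites kept.
#' @export
intersect_common_sites <- function(x) {
  stopifnot(inherits(x, "methylome_matrix"))
  unname(rowSums(is.na(x$total) | x$total < 1) == 0)
}

#' Soft coverage filter by age group
#'
#' Excludes a site if, within any control age group or within the set of
#' treated (CR) samples, the proportion of samples with coverage below
#' `min_cov` exceeds `max_low_frac` (strict inequality).
#'
#' @param x a [methylome_matrix()].
#' @param samples sample sheet aligned with the matrix columns.
#' @param min_cov minimum acceptable coverage (default 10 reads).
#' @param max_low_frac maximum tolerated proportion of low-coverage samples
#'   per group (default 0.5).
#' @return logical vector, `TRUE` for sites kept.
#' @export
coverage_filter <- function(x, samples, min_cov = 10, max_low_frac = 0.5) {
  stopifnot(inherits(x, "methylome_matrix"))
  samples <- validate_sample_sheet(samples)
  if (nrow(samples) != ncol(x$total)) stop("sample sheet does not match matrix")
  ctrl <- samples$group == "control"
  groups <- split(which(ctrl), samples$age[ctrl])
  if (any(samples$group == "CR")) groups$CR <- which(samples$group == "CR")
  if (any(lengths(groups) == 0)) stop("empty sample group")
  low <- is.na(x$total) | x$total < min_cov
  keep <- rep(TRUE, nrow(x$total))
  for (g in groups) {
    frac_low <- rowMeans(low[, g, drop = FALSE])
    keep <- keep & (frac_low <= max_low_frac)
  }
  unname(keep)
}

#' Shorth threshold of a numeric sample
#'
#' The mean of the values inside the shortest interval (in sorted order)
#' containing `ceiling(n/2)` of them. Ties among equally short windows are
#' broken toward the window with the lower mean.
#'
#' @param v numeric vector.
#' @return scalar threshold.
#' @export
shorth_mean <- function(v) {
  v <- sort(v)
  n <- length(v)
  h <- ceiling(n / 2)
  if (h >= n) return(mean(v))
  starts <- seq_len(n - h + 1)
  widths <- v[starts + h - 1] - v[starts]
  # widths within 1e-9 are treated as tied, absorbing floating-point noise
  cand <- starts[widths <= min(widths) + 1e-9]
  means <- vapply(cand, function(s) mean(v[s:(s + h - 1)]), numeric(1))
  min(means)
}

#' Variance filter against the shorth of per-site standard deviations
#'
#' Computes the standard deviation of each site's methylation fractions
#' across samples and drops sites whose SD falls below the mean of the
#' shortest interval covering half of all the SDs. This removes the
#' near-constant sites that RRBS produces in abundance (fully methylated or
#' unmethylated across all samples).
#'
#' @param fractions numeric matrix (sites x samples) of methylation fractions.
#' @return list with `keep` (logical per site) and `threshold` (SD units).
#' @export
shorth_sd_filter <- function(fractions) {
  fractions <- as.matrix(fractions)
  if (ncol(fractions) < 2) stop("at least 2 samples required")
  sds <- apply(fractions, 1, stats::sd, na.rm = TRUE)
  thr <- shorth_mean(sds)
  list(keep = sds >= thr, threshold = thr)
}

#' Aggregate the two strands of each CpG
#'
#' A plus-strand cytosine at position `p` and the minus-strand cytosine at
#' `p + 1` belong to the same CpG; their methylated and total counts are
#' summed into one record covering `[p, p + 2)`. Unpaired stranded records
#' are kept as single-strand CpG records. Records without strand information
#' (`"*"`) pass through unchanged.
#'
#' @param x a [methylome_matrix()] whose sites carry strand information.
#' @return a [methylome_matrix()] with one row per CpG.
#' @export
aggregate_cpg_strands <- function(x) {
  stopifnot(inherits(x, "methylome_matrix"))
  s <- x$sites
  plus <- which(s$strand == "+")
  minus <- which(s$strand == "-")
  if (length(plus) == 0 || length(minus) == 0) return(x)
  key_plus <- paste0(s$chrom[plus], ":", s$start[plus])
  key_minus_partner <- paste0(s$chrom[minus], ":", s$start[minus] - 1)
  if (anyDuplicated(key_plus) || anyDuplicated(key_minus_partner)) {
    stop("three-way position collision while pairing CpG strands")
  }
  hit <- match(key_minus_partner, key_plus)
  paired_minus <- which(!is.na(hit))
  paired_plus <- plus[hit[paired_minus]]
  paired_minus <- minus[paired_minus]

  add_na <- function(a, b) {
    out <- ifelse(is.na(a) & is.na(b), NA_real_,
                  ifelse(is.na(a), b, ifelse(is.na(b), a, a + b)))
    matrix(out, nrow = nrow(a))
  }
  keep <- setdiff(seq_len(nrow(s)), c(paired_plus, paired_minus))
  sites_new <- s[keep, c("chrom", "start", "end", "strand")]
  meth_new <- x$meth[keep, , drop = FALSE]
  total_new <- x$total[keep, , drop = FALSE]
  if (length(paired_plus) > 0) {
    sites_cpg <- data.frame(chrom = s$chrom[paired_plus],
                            start = s$start[paired_plus],
                            end = s$start[paired_plus] + 2,
                            strand = "*")
    meth_cpg <- add_na(x$meth[paired_plus, , drop = FALSE],
                       x$meth[paired_minus, , drop = FALSE])
    total_cpg <- add_na(x$total[paired_plus, , drop = FALSE],
                        x$total[paired_minus, , drop = FALSE])
    sites_new <- rbind(sites_new, sites_cpg)
    meth_new <- rbind(meth_new, meth_cpg)
    total_new <- rbind(total_new, total_cpg)
  }
  ord <- order(sites_new$chrom, sites_new$start, sites_new$end)
  methylome_matrix(sites_new[ord, ], meth_new[ord, , drop = FALSE],
                   total_new[ord, , drop = FALSE], x$samples)
}

#' Mask coverage outliers and drop SNP-overlapping sites
#'
#' Entries whose coverage exceeds the per-sample `cov_quantile` and is more
#' than `min_ratio` times the sample's median coverage are masked (set
#' unobserved), guarding against PCR / mapping artifacts without clipping
#' the tail of an ordinary coverage distribution. Sites whose interval
#' overlaps any SNP region are dropped entirely.
#'
#' @param x a [methylome_matrix()].
#' @param snp_regions optional region data.frame (`chrom`, `start`, `end`).
#' @param cov_quantile per-sample coverage quantile above which entries are
#'   masked (default 0.999).
#' @param min_ratio minimum ratio to the sample median coverage for an entry
#'   to count as an outlier (default 2).
#' @return list with `matrix` (masked [methylome_matrix()]) and
#'   `keep` (logical per site, `FALSE` for SNP overlap).
#' @export
exclude_outliers_and_snps <- function(x, snp_regions = NULL,
                                      cov_quantile = 0.999, min_ratio = 2) {
  stopifnot(inherits(x, "methylome_matrix"))
  total <- x$total
  meth <- x$meth
  for (k in seq_len(ncol(total))) {
    obs <- !is.na(total[, k])
    if (!any(obs)) next
    thr <- max(stats::quantile(total[obs, k], cov_quantile, names = FALSE),
               min_ratio * stats::median(total[obs, k]))
    mask <- obs & total[, k] > thr
    total[mask, k] <- NA_real_
    meth[mask, k] <- NA_real_
  }
  keep <- rep(TRUE, nrow(total))
  if (!is.null(snp_regions) && nrow(snp_regions) > 0) {
    ov <- assign_sites(x$sites, transform(snp_regions, label = "snp"))
    keep <- !(seq_len(nrow(total)) %in% ov$snp)
  }
  masked <- methylome_matrix(x$sites[, c("chrom", "start", "end", "strand")],
                             meth, total, x$samples)
  list(matrix = masked, keep = keep)
}

#' Full site-selection chain
#'
#' Applies, in order: common-site intersection, the soft coverage filter,
#' outlier masking / SNP exclusion (entries masked by the outlier rule make a
#' site non-common, so those sites are dropped too), strand aggregation, and
#' finally the shorth variance filter on CpG-level fractions. Returns the
#' filtered matrix and a report of site counts along the chain.
#'
#' @param x a [methylome_matrix()].
#' @param samples sample sheet aligned with the matrix columns.
#' @param snp_regions optional SNP region data.frame.
#' @param min_cov,max_low_frac coverage-filter parameters.
#' @param cov_quantile outlier-masking quantile.
#' @return list with `matrix` (filtered [methylome_matrix()]) and `report`
#'   (single-row data.frame of counts plus the shorth threshold).
#' @export
preprocess_sites <- function(x, samples, snp_regions = NULL, min_cov = 10,
                             max_low_frac = 0.5, cov_quantile = 0.999) {
  n_input <- nrow(x$meth)
  common <- intersect_common_sites(x)
  x <- x[common, ]
  n_common <- nrow(x$meth)
  covkeep <- coverage_filter(x, samples, min_cov, max_low_frac)
  x <- x[covkeep, ]
  n_cov <- nrow(x$meth)
  out <- exclude_outliers_and_snps(x, snp_regions, cov_quantile)
  x <- out$matrix[out$keep & intersect_common_sites(out$matrix), ]
  n_snp <- nrow(x$meth)
  x <- aggregate_cpg_strands(x)
  if (nrow(x$meth) > 0) {
    sh <- shorth_sd_filter(meth_fractions(x))
    x <- x[sh$keep, ]
  } else {
    sh <- list(threshold = NA_real_)
  }
  report <- data.frame(n_input_sites = n_input, n_after_common = n_common,
                       n_after_coverage = n_cov, n_after_snp = n_snp,
                       n_after_shorth = nrow(x$meth),
                       shorth_threshold = sh$threshold)
  list(matrix = x, report = report)
}
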