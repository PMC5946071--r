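#' Assign sites to labeled genomic regions
#'
#' A site belongs to a region when its interval overlaps the region interval
#' (both 0-based half-open); a site may belong to several labels. Overlap is
#' computed with GenomicRanges.
#'
#' @param sites data.frame with `chrom`, `start`, `end` (a
#'   [methylome_matrix()] `$sites` slot works directly).
#' @param regions data.frame with `chrom`, `start`, `end`, `label`.
#' @return named list (one element per label) of site row indices.
#' @export
assign_sites <- function(sites, regions) {
  if (nrow(regions) == 0) return(list())
  if (length(intersect(unique(sites$chrom), unique(regions$chrom))) == 0) {
    stop("no shared chromosome names between sites and regions ",
         "(check the chromosome naming dialect, e.g. 'chr1' vs '1')")
  }
  gr_sites <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$start + 1, end = sites$end))
  gr_regions <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(start = regions$start + 1,
                                    end = regions$end))
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_regions,
                                      ignore.strand = TRUE)
  lab <- regions$label[S4Vectors::subjectHits(hits)]
  membership <- split(S4Vectors::queryHits(hits), lab)
  lapply(membership, function(v) sort(unique(v)))
}

#' Normalized region-level age slope
#'
#' Each member site's fraction series is z-scored across samples (mean
#' extracted, divided by the SD) and re-regressed on age; the region
#' statistic is the mean of these z-scale slopes, which weights every site
#' equally regardless of its raw effect size. A bootstrap over sites gives
#' the confidence interval.
#'
#' @param site_idx row indices of the member sites (typically significant
#'   sites only).
#' @param fractions sites x samples fraction matrix.
#' @param ages ages in months.
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return list with `mean_slope` (SD units per month), `ci` (two values),
#'   `n_sites`, `site_slopes`; `NULL` (with a warning) when fewer than 2
#'   usable sites.
#' @export
region_slope <- function(site_idx, fractions, ages, n_boot = 1000, seed = 1L,
                         conf = 0.95) {
  f <- fractions[site_idx, , drop = FALSE]
  mu <- rowMeans(f, na.rm = TRUE)
  sdv <- apply(f, 1, stats::sd, na.rm = TRUE)
  usable <- which(sdv > 0)
  if (length(usable) < 2) {
    warning("region skipped: fewer than 2 variable sites")
    return(NULL)
  }
  z <- (f[usable, , drop = FALSE] - mu[usable]) / sdv[usable]
  slopes <- fit_site_linear(z, ages)$slope
  set.seed(seed)
  boots <- replicate(n_boot, mean(slopes[sample.int(length(slopes),
                                                    replace = TRUE)]))
  alpha <- (1 - conf) / 2
  list(mean_slope = mean(slopes),
       ci = stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE),
       n_sites = length(usable), site_slopes = slopes)
}

# Two-sided conditional Fisher p-value by the probability-ordering rule:
# sum of hypergeometric probabilities not exceeding that of the observed
# table (with the customary 1 + 1e-7 relative tolerance for ties).
fisher_p_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  k <- lo:hi
  probs <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher enrichment of site directions in regions
#'
#' For every region label and direction, tests the 2x2 table
#' (in region / not in region) x (direction / not direction) over all tested
#' sites with the two-sided conditional Fisher exact test, reporting the
#' sample (cross-product) odds ratio; p-values are BH-adjusted across
#' regions within each direction. An empty margin leaves the odds ratio
#' undefined (`NA`).
#'
#' @param membership named list of site indices per region label
#'   (from [assign_sites()]).
#' @param directions character vector over all tested sites
#'   (`gain` / `loss` / `none`), the enrichment background.
#' @param test_directions directions to test (default gain and loss).
#' @return data.frame with one row per label x direction: `label`,
#'   `direction`, counts, `odds_ratio`, `p`, `q`.
#' @export
enrichment_fisher <- function(membership, directions,
                              test_directions = c("gain", "loss")) {
  n <- length(directions)
  rows <- list()
  for (dir in test_directions) {
    is_dir <- directions == dir
    for (lab in names(membership)) {
      in_reg <- rep(FALSE, n)
      in_reg[membership[[lab]]] <- TRUE
      a <- sum(in_reg & is_dir); b <- sum(in_reg & !is_dir)
      c_ <- sum(!in_reg & is_dir); d <- sum(!in_reg & !is_dir)
      or <- if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0)
        NA_real_ else (a * d) / (b * c_)
      rows[[length(rows) + 1]] <- data.frame(
        label = lab, direction = dir, in_dir = a, in_other = b,
        out_dir = c_, out_other = d, odds_ratio = or,
        p = fisher_p_two_sided(a, b, c_, d))
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (dir in test_directions) {
    sel <- out$direction == dir
    out$q[sel] <- adjust_pvalues(out$p[sel])
  }
  rownames(out) <- NULL
  out
}

#' CGI-removal sensitivity tiers for region slopes
#'
#' Recomputes a region's normalized slope after cumulatively excluding member
#' sites that overlap (i) CpG islands, (ii) islands + shores, (iii) islands +
#' shores + shelves. A change of sign across tiers indicates that the
#' region's age trend is driven by its overlapping islands rather than the
#' region itself.
#'
#' @param site_idx member site indices of the region.
#' @param fractions,ages as in [region_slope()].
#' @param cgi_idx,shore_idx,shelf_idx site indices overlapping each
#'   annotation tier.
#' @param ... passed to [region_slope()].
#' @return data.frame with one row per tier (`none`, `minus_cgi`,
#'   `minus_cgi_shore`, `minus_cgi_shore_shelf`): `tier`, `mean_slope`,
#'   `ci_lo`, `ci_hi`, `n_sites` (`NA` where the tier leaves < 2 sites).
#' @export
cgi_sensitivity <- function(site_idx, fractions, ages, cgi_idx,
                            shore_idx = integer(0), shelf_idx = integer(0),
                            ...) {
  tiers <- list(none = integer(0),
                minus_cgi = cgi_idx,
                minus_cgi_shore = union(cgi_idx, shore_idx),
                minus_cgi_shore_shelf = Reduce(union, list(cgi_idx, shore_idx,
                                                           shelf_idx)))
  rows <- lapply(names(tiers), function(tn) {
    keep <- setdiff(site_idx, tiers[[tn]])
    rs <- if (length(keep) >= 2) {
      suppressWarnings(region_slope(keep, fractions, ages, ...))
    } else NULL
    if (is.null(rs)) {
      warning("tier ", tn, ": fewer than 2 sites remain; skipped")
      data.frame(tier = tn, mean_slope = NA_real_, ci_lo = NA_real_,
                 ci_hi = NA_real_, n_sites = length(keep))
    } else {
      data.frame(tier = tn, mean_slope = rs$mean_slope, ci_lo = rs$ci[1],
                 ci_hi = rs$ci[2], n_sites = rs$n_sites)
    }
  })
  do.call(rbind, rows)
}

#' Relative gene position of sites
#'
#' Maps a site to the normalized gene coordinate `r`, where 0 is the TSS and
#' 1 the gene end, extended one gene length in both directions
#' (`r` in `[-1, 2]`). On the minus strand the mapping is mirrored.
#'
#' @param site_pos site positions (0-based start coordinates).
#' @param gene_start,gene_end gene interval (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @return numeric vector of relative positions (`NA` outside `[-1, 2]`).
#' @export
relative_gene_position <- function(site_pos, gene_start, gene_end, strand) {
  L <- gene_end - gene_start
  if (L <= 0) stop("zero-length gene")
  r <- if (strand == "-") (gene_end - site_pos) / L else (site_pos - gene_start) / L
  r[r < -1 | r > 2] <- NA_real_
  r
}

#' Metagene methylation profile by age group
#'
#' Maps every (significant) site into the extended relative coordinate of
#' each gene it falls near, averages methylation per age group at each
#' mapped site, and smooths the group means along the relative coordinate
#' with a penalized-spline generalized additive model.
#'
#' @param fractions sites x samples fraction matrix.
#' @param sites site table (`chrom`, `start`).
#' @param genes gene models: data.frame with `chrom`, `start`, `end`,
#'   `strand` (and optionally `gene_id`).
#' @param ages ages per sample; groups are the unique ages.
#' @param site_idx indices of the sites to profile (default: all).
#' @param r_grid evaluation grid of relative positions.
#' @param basis_dim spline basis dimension.
#' @return data.frame with `r`, `age_group`, `mean_methylation` (smoothed).
#' @export
metagene_profile <- function(fractions, sites, genes, ages,
                             site_idx = seq_len(nrow(fractions)),
                             r_grid = seq(-1, 2, by = 0.05),
                             basis_dim = 20) {
  if (any(genes$end <= genes$start)) stop("zero-length gene")
  maps <- list()
  for (g in seq_len(nrow(genes))) {
    on_chr <- which(sites$chrom[site_idx] == genes$chrom[g])
    if (length(on_chr) == 0) next
    idx <- site_idx[on_chr]
    r <- relative_gene_position(sites$start[idx], genes$start[g],
                                genes$end[g], genes$strand[g])
    ok <- which(!is.na(r))
    if (length(ok) > 0) {
      maps[[length(maps) + 1]] <- data.frame(site = idx[ok], r = r[ok])
    }
  }
  if (length(maps) == 0) stop("no sites map into any gene window")
  map <- do.call(rbind, maps)
  out <- list()
  for (ag in sort(unique(ages))) {
    cols <- which(ages == ag)
    y <- rowMeans(fractions[map$site, cols, drop = FALSE], na.rm = TRUE)
    dat <- data.frame(r = map$r, y = y)
    k <- min(basis_dim, max(4, length(unique(dat$r)) - 1))
    fit <- mgcv::gam(y ~ s(r, k = k), data = dat, method = "GCV.Cp")
    pred <- as.numeric(mgcv::predict.gam(fit, newdata = data.frame(r = r_grid)))
    out[[length(out) + 1]] <- data.frame(r = r_grid, age_group = ag,
                                         mean_methylation = pred)
  }
  do.call(rbind, out)
}

#' Compare member-site slopes between two region sets
#'
#' Two-sample t-test of the z-scale member slopes of two site sets within the
#' same region universe (e.g. homologous vs species-specific elements).
#'
#' @param idx_a,idx_b site indices of the two sets.
#' @param fractions,ages as in [region_slope()].
#' @param ... passed to [region_slope()].
#' @return list with the two [region_slope()] results and `t_test`
#'   (an `htest`).
#' @export
compare_region_sets <- function(idx_a, idx_b, fractions, ages, ...) {
  ra <- region_slope(idx_a, fractions, ages, ...)
  rb <- region_slope(idx_b, fractions, ages, ...)
  if (is.null(ra) || is.null(rb)) stop("both sets need >= 2 variable sites")
  list(a = ra, b = rb,
       t_test = stats::t.test(ra$site_slopes, rb$site_slopes))
}
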