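#' Methylome count matrix
#'
#' Container for per-CpG methylated / total read counts across samples.
#' Sites are rows; samples are columns. Coordinates are stored 0-based
#' half-open (`[start, end)`); the bismark coverage dialect (1-based
#' inclusive) is converted at the IO boundary only.
#'
#' @param sites data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand` (one of `"+"`, `"-"`, `"*"`); one row per site.
#' @param meth integer/numeric matrix of methylated read counts
#'   (sites x samples). `NA` marks an unobserved site/sample entry.
#' @param total matrix of total read counts, same shape as `meth`.
#' @param samples character vector of sample ids (column names).
#' @return An object of class `methylome_matrix`.
#' @export
methylome_matrix <- function(sites, meth, total, samples = colnames(meth)) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "start", "end") %in% names(sites)))
  if (is.null(sites$strand)) sites$strand <- "*"
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  if (!all(dim(meth) == dim(total))) stop("meth and total must have identical shape")
  if (nrow(meth) != nrow(sites)) stop("one matrix row per site required")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(meth)))
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (any(sites$start >= sites$end)) stop("site start must be < end (0-based half-open)")
  bad <- !is.na(total) & !is.na(meth) & (meth > total | meth < 0 | total < 0)
  if (any(bad)) stop("counts must satisfy 0 <= meth <= total")
  sites$site_id <- site_ids(sites)
  if (anyDuplicated(sites$site_id)) stop("duplicate sites: ",
    paste(utils::head(sites$site_id[duplicated(sites$site_id)], 3), collapse = ", "))
  dimnames(meth) <- dimnames(total) <- list(sites$site_id, samples)
  structure(list(sites = sites, meth = meth, total = total, samples = samples),
            class = "methylome_matrix")
}

site_ids <- function(sites) {
  if (nrow(sites) == 0) return(character(0))
  # fixed notation: large positions must never render as "1e+05"
  fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
  paste0(sites$chrom, ":", fmt(sites$start), "-", fmt(sites$end),
         ifelse(sites$strand %in% c("+", "-"), paste0(":", sites$strand), ""))
}

#' @export
print.methylome_matrix <- function(x, ...) {
  cat(sprintf("methylome_matrix: %d sites x %d samples\n",
              nrow(x$meth), ncol(x$meth)))
  cat(sprintf("  chrom(s): %s\n", paste(unique(x$sites$chrom), collapse = ", ")))
  obs <- mean(!is.na(x$total))
  cat(sprintf("  observed entries: %.1f%%\n", 100 * obs))
  invisible(x)
}

#' @export
dim.methylome_matrix <- function(x) dim(x$meth)

#' Subset a methylome matrix by sites and/or samples
#' @param x a [methylome_matrix()]
#' @param i site index (logical, integer or site-id character)
#' @param j sample index (logical, integer or sample-id character)
#' @param ... unused
#' @export
`[.methylome_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$meth))
  if (missing(j)) j <- seq_len(ncol(x$meth))
  if (is.character(i)) i <- match(i, x$sites$site_id)
  if (is.character(j)) j <- match(j, x$samples)
  methylome_matrix(x$sites[i, c("chrom", "start", "end", "strand"), drop = FALSE],
                   x$meth[i, j, drop = FALSE],
                   x$total[i, j, drop = FALSE],
                   x$samples[j])
}

#' Methylation fractions of a methylome matrix
#'
#' Fraction = methylated reads / total reads per site and sample
#' (`NA` where a site is unobserved or has zero coverage).
#'
#' @param x a [methylome_matrix()]
#' @return numeric matrix (sites x samples) of values in `[0, 1]`
#' @export
meth_fractions <- function(x) {
  stopifnot(inherits(x, "methylome_matrix"))
  f <- x$meth / x$total
  f[!is.finite(f)] <- NA_real_
  f
}

#' Per-entry read coverage
#' @param x a [methylome_matrix()]
#' @return matrix of total read counts (NA = unobserved)
#' @export
meth_coverage <- function(x) x$total
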