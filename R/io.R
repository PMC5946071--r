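#' Read bismark-style coverage files into a methylome matrix
#'
#' Each file is a tab-separated table with columns chrom, start, end,
#' methylation percent, methylated count, unmethylated count, with 1-based
#' inclusive positions (the bismark coverage dialect). Positions are converted
#' to 0-based half-open coordinates on input; this is the only place the
#' conversion happens. Sites absent from a sample are `NA` in that column.
#'
#' @param paths character vector of file paths, one per sample.
#' @param sample_ids sample ids; default is the file name without extension.
#' @return a [methylome_matrix()] over the union of sites.
#' @export
read_coverage_files <- function(paths, sample_ids = NULL) {
  if (length(paths) == 0) stop("at least one coverage file required")
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  tabs <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    tab <- data.table::fread(paths[k], header = FALSE, sep = "\t",
                             colClasses = list(character = 1),
                             data.table = TRUE, showProgress = FALSE)
    if (ncol(tab) != 6) {
      stop(sprintf("%s: expected 6 tab-separated columns, found %d",
                   paths[k], ncol(tab)))
    }
    data.table::setnames(tab, c("chrom", "start1", "end1", "pct", "M", "U"))
    for (col in c("start1", "end1", "pct", "M", "U")) {
      v <- suppressWarnings(as.numeric(tab[[col]]))
      bad <- which(is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("%s: malformed line %d (non-numeric %s field)",
                     paths[k], bad[1], col))
      }
      data.table::set(tab, j = col, value = v)
    }
    if (any(tab$M < 0 | tab$U < 0)) {
      bad <- which(tab$M < 0 | tab$U < 0)[1]
      stop(sprintf("%s: malformed line %d (negative count)", paths[k], bad))
    }
    key <- paste0(tab$chrom, ":", tab$start1, "-", tab$end1)
    if (anyDuplicated(key)) {
      dupline <- which(duplicated(key))[1]
      stop(sprintf("%s: duplicate site %s at line %d",
                   paths[k], key[dupline], dupline))
    }
    tab$key <- key
    tabs[[k]] <- tab
  }
  all_keys <- unique(unlist(lapply(tabs, `[[`, "key")))
  first <- do.call(rbind, lapply(tabs, function(t)
    data.frame(key = t$key, chrom = t$chrom, start1 = t$start1, end1 = t$end1)))
  first <- first[!duplicated(first$key), ]
  first <- first[match(all_keys, first$key), ]
  # bismark 1-based inclusive -> internal 0-based half-open: start-1, end kept
  sites <- data.frame(chrom = first$chrom, start = first$start1 - 1,
                      end = first$end1, strand = "*")
  ord <- order(sites$chrom, sites$start, sites$end)
  sites <- sites[ord, ]
  all_keys <- all_keys[ord]
  S <- length(all_keys)
  meth <- matrix(NA_real_, S, length(paths))
  total <- matrix(NA_real_, S, length(paths))
  for (k in seq_along(tabs)) {
    idx <- match(tabs[[k]]$key, all_keys)
    meth[idx, k] <- tabs[[k]]$M
    total[idx, k] <- tabs[[k]]$M + tabs[[k]]$U
  }
  methylome_matrix(sites, meth, total, sample_ids)
}

#' Write a methylome matrix as per-sample coverage files
#'
#' Inverse of [read_coverage_files()]: one bismark-dialect file per sample
#' (1-based inclusive positions), skipping unobserved entries. Writing then
#' reading reproduces the counts exactly.
#'
#' @param x a [methylome_matrix()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_coverage_files <- function(x, dir) {
  stopifnot(inherits(x, "methylome_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(x$samples, ".cov"))
  for (k in seq_along(x$samples)) {
    obs <- which(!is.na(x$total[, k]))
    M <- x$meth[obs, k]
    U <- x$total[obs, k] - M
    tab <- data.table::data.table(
      chrom = x$sites$chrom[obs],
      start = x$sites$start[obs] + 1,  # internal 0-based -> 1-based inclusive
      end = x$sites$end[obs],
      pct = round(100 * M / (M + U), 6),
      M = M, U = U)
    data.table::fwrite(tab, paths[k], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}

#' Read a BED file as a region set
#'
#' BED is already 0-based half-open, so intervals are kept verbatim. A strand
#' column (BED6) is honored when present.
#'
#' @param path BED3+ file path.
#' @param label region-class label attached to every interval (default: file
#'   stem).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`, `label`.
#' @export
read_bed_regions <- function(path, label = NULL) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      label = character(0)))
  }
  tab <- data.table::fread(path, header = FALSE, sep = "\t",
                           data.table = FALSE, showProgress = FALSE)
  if (ncol(tab) < 3) stop(path, ": BED requires at least 3 columns")
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.numeric(tab[[2]]),
                    end = as.numeric(tab[[3]]),
                    strand = if (ncol(tab) >= 6) as.character(tab[[6]]) else "*",
                    label = label, stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) {
    bad <- which(out$start >= out$end)[1]
    stop(sprintf("%s: interval with start >= end at line %d", path, bad))
  }
  out
}

#' Read a sample sheet TSV
#'
#' Expected columns: `sample_id`, `age` (months), `group` (`control` or `CR`),
#' `t0` (treatment-start age, CR rows only); any additional numeric columns
#' are treated as confounders.
#'
#' @param path TSV file path.
#' @return validated sample-sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t",
                           data.table = FALSE, showProgress = FALSE)
  validate_sample_sheet(tab)
}

#' Validate a sample sheet
#'
#' Checks id uniqueness, positive ages, known groups and that the
#' treatment-start age precedes every treated sample's age.
#'
#' @param samples data.frame with at least `sample_id`, `age`, `group`.
#' @return the sample sheet, invisibly validated (with `t0` column present).
#' @export
validate_sample_sheet <- function(samples) {
  req <- c("sample_id", "age", "group")
  if (!all(req %in% names(samples))) {
    stop("sample sheet requires columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  if (any(samples$age <= 0)) stop("ages must be positive")
  if (!all(samples$group %in% c("control", "CR"))) {
    stop("group must be 'control' or 'CR'")
  }
  if (is.null(samples$t0)) samples$t0 <- NA_real_
  cr <- samples$group == "CR"
  if (any(cr)) {
    if (any(is.na(samples$t0[cr]))) stop("CR samples require t0")
    if (any(samples$t0[cr] >= samples$age[cr])) {
      stop("t0 must precede the age of every CR sample")
    }
  }
  samples
}

#' Confounder columns of a sample sheet
#' @param samples sample sheet data.frame.
#' @return data.frame of the numeric confounder columns (may be empty).
#' @export
sample_confounders <- function(samples) {
  known <- c("sample_id", "age", "group", "t0")
  extra <- setdiff(names(samples), known)
  extra <- extra[vapply(samples[extra], is.numeric, logical(1))]
  samples[, extra, drop = FALSE]
}

#' Read a generic fraction matrix
#'
#' Sites x samples TSV of methylation fractions in `[0, 1]` with a site-id
#' first column and sample ids as header, for array-style data without read
#' counts. Count-dependent filters do not apply to such input.
#'
#' @param path TSV file path.
#' @return numeric matrix with site-id rownames.
#' @export
read_fraction_matrix <- function(path) {
  tab <- data.table::fread(path, header = TRUE, sep = "\t",
                           data.table = FALSE, showProgress = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop("fractions must lie in [0, 1]")
  m
}

#' Write result tables with a reproducibility header
#'
#' Writes each table as TSV with stable column order, prefixed by comment
#' lines recording the package version, the run seed and a configuration
#' hash. Output contains no timestamps, so a rerun on identical inputs is
#' byte-identical.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param meta named list echoed into the header (e.g. seed, parameters).
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, meta = list()) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta_str <- paste(names(meta), vapply(meta, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = "; ")
  header <- c(
    sprintf("# methyldrift %s",
            as.character(utils::packageVersion("methyldrift"))),
    sprintf("# config_hash=%s", config_hash(meta_str)),
    if (nzchar(meta_str)) sprintf("# %s", meta_str))
  paths <- file.path(out_dir, paste0(names(tables), ".tsv"))
  for (k in seq_along(tables)) {
    tab <- as.data.frame(tables[[k]])
    con <- file(paths[k], open = "wt")
    writeLines(header, con)
    numcols <- vapply(tab, is.numeric, logical(1))
    tab[numcols] <- lapply(tab[numcols], function(v) format(v, digits = 15))
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    close(con)
  }
  invisible(paths)
}

#' Read a YAML run configuration
#'
#' Returns the configuration as a named list; the `cohort` section (if any)
#' can be passed to [cohort_design()] via [cohort_design_from_config()].
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Build a cohort design from a configuration list
#' @param config named list (e.g. the `cohort` section of [read_config()]).
#' @return a [cohort_design()].
#' @export
cohort_design_from_config <- function(config) {
  allowed <- names(formals(cohort_design))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("unknown cohort configuration fields: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(config$class_mixture)) {
    config$class_mixture <- unlist(config$class_mixture)
  }
  do.call(cohort_design, config)
}
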