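make_mm <- function(total, meth = NULL, samples = NULL) {
  S <- nrow(total)
  if (is.null(meth)) meth <- pmin(total, matrix(1, S, ncol(total)))
  starts <- 100 * seq_len(S)
  methylome_matrix(data.frame(chrom = "chr1", start = starts,
                              end = starts + 2),
                   meth, total, samples %||% paste0("s", seq_len(ncol(total))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("common-site intersection requires a read in every sample", {
  total <- rbind(c(5, 3, 2), c(4, NA, 2), c(1, 0, 2))
  mm <- make_mm(total, matrix(0, 3, 3))
  expect_equal(intersect_common_sites(mm), c(TRUE, FALSE, FALSE))
  one <- make_mm(matrix(c(2, 3), 2, 1), matrix(0, 2, 1))
  expect_equal(intersect_common_sites(one), c(TRUE, TRUE))
})

test_that("coverage filter applies the strict majority rule per group", {
  sheet <- data.frame(sample_id = paste0("s", 1:5),
                      age = c(3, 3, 3, 10, 10),
                      group = "control")
  # group1 coverages 12,8,9: 2/3 low -> excluded
  total <- rbind(c(12, 8, 9, 30, 30),
                 c(15, 12, 10, 30, 30),
                 c(30, 30, 30, 9, 15))  # group2 1/2 = 0.5, not > 0.5 -> kept
  mm <- make_mm(total, matrix(0, 3, 5))
  expect_equal(coverage_filter(mm, sheet), c(FALSE, TRUE, TRUE))
})

test_that("CR samples form one extra evaluation group", {
  sheet <- data.frame(sample_id = paste0("s", 1:6),
                      age = c(3, 3, 3, 20, 20, 20),
                      group = c(rep("control", 3), rep("CR", 3)),
                      t0 = c(NA, NA, NA, 4, 4, 4))
  total <- rbind(c(30, 30, 30, 9, 8, 30),   # CR set 2/3 low -> excluded
                 c(30, 30, 30, 30, 9, 30))
  mm <- make_mm(total, matrix(0, 2, 6))
  expect_equal(coverage_filter(mm, sheet), c(FALSE, TRUE))
})

test_that("shorth threshold matches the worked example and the scan oracle", {
  sds <- c(0, 0.01, 0.011, 0.012, 0.5)
  expect_equal(shorth_mean(sds), 0.011)
  set.seed(14)
  for (trial in 1:200) {
    v <- switch(1 + trial %% 4,
                runif(sample(2:500, 1)),
                rexp(sample(2:100, 1)),
                rep(0.3, sample(2:50, 1)),
                round(runif(sample(3:80, 1)), 2)) # heavy ties
    expect_equal(shorth_mean(v), shorth_oracle(v))
  }
})

test_that("variance filter keeps sites at or above the shorth threshold", {
  set.seed(1)
  base <- matrix(runif(5 * 20), 5, 20)
  fr <- rbind(base * c(0, 0.02, 0.022, 0.024, 1) + 0.4, 0.4)
  out <- shorth_sd_filter(fr)
  expect_false(out$keep[1])          # constant site always dropped
  expect_false(out$keep[6])
  expect_true(out$keep[5])
  flat <- matrix(rep(c(0.1, 0.9), 10), 4, 20, byrow = TRUE)
  outf <- shorth_sd_filter(flat)
  expect_true(all(outf$keep))        # identical SDs: all kept at threshold
  expect_error(shorth_sd_filter(matrix(1, 3, 1)), "2 samples")
})

test_that("strand aggregation merges CpG pairs and keeps orphans", {
  mm <- aggregate_cpg_strands(stranded_matrix())
  # pair at 100/101 merges into [100,102) with summed counts
  cpg <- which(mm$sites$start == 100)
  expect_equal(mm$sites$end[cpg], 102)
  expect_equal(unname(mm$meth[cpg, ]), c(5, 2))
  expect_equal(unname(mm$total[cpg, ]), c(10, 5))
  # orphan plus-strand site at 200 is kept as-is
  expect_true(200 %in% mm$sites$start)
  expect_equal(nrow(mm$meth), 3)
  # fraction of a merged all-unmethylated pair is 0
  sites0 <- data.frame(chrom = "chr1", start = c(10, 11), end = c(11, 12),
                       strand = c("+", "-"))
  mm0 <- aggregate_cpg_strands(methylome_matrix(sites0, matrix(0, 2, 1),
                                                matrix(c(4, 6), 2, 1), "a"))
  expect_equal(unname(meth_fractions(mm0)[1, 1]), 0)
})

test_that("three-way strand collisions are rejected", {
  sites <- data.frame(chrom = "chr1", start = c(10, 10, 11),
                      end = c(11, 12, 12), strand = c("+", "+", "-"))
  mm <- methylome_matrix(sites, matrix(1, 3, 1), matrix(2, 3, 1), "a")
  expect_error(aggregate_cpg_strands(mm), "collision")
})

test_that("coverage outliers are masked and SNP sites dropped", {
  set.seed(3)
  total <- matrix(rpois(100 * 2, 20) + 1, 100, 2)
  total[7, 1] <- 5000
  mm <- make_mm(total, matrix(0, 100, 2))
  out <- exclude_outliers_and_snps(mm, cov_quantile = 0.99)
  expect_true(is.na(out$matrix$total[7, 1]))
  expect_false(is.na(out$matrix$total[7, 2]))
  snp <- data.frame(chrom = "chr1", start = 100 * 5, end = 100 * 5 + 1)
  out2 <- exclude_outliers_and_snps(mm, snp_regions = snp)
  expect_false(out2$keep[5])
  expect_true(all(out2$keep[-5]))
})

test_that("filter chain report is non-increasing and order-stable", {
  d <- cohort_design(n_sites = 300, n_per_group = 3, n_cr_per_group = 2,
                     coverage_mean = 15, seed = 6)
  co <- simulate_cohort(d)
  pre <- preprocess_sites(co$matrix, co$samples)
  r <- pre$report
  expect_true(r$n_after_common <= r$n_input_sites)
  expect_true(r$n_after_coverage <= r$n_after_common)
  expect_true(r$n_after_snp <= r$n_after_coverage)
  expect_true(r$n_after_shorth <= r$n_after_snp)
  expect_gt(r$n_after_shorth, 0)
  # permuting sample order never changes the kept-site set
  perm <- sample(nrow(co$samples))
  pre2 <- preprocess_sites(co$matrix[, perm], co$samples[perm, ])
  expect_setequal(pre$matrix$sites$site_id, pre2$matrix$sites$site_id)
})
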