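test_that("site-region assignment follows the half-open convention", {
  sites <- data.frame(chrom = "chr1", start = c(100, 200, 150),
                      end = c(101, 201, 151))
  regions <- data.frame(chrom = "chr1", start = c(100, 100),
                        end = c(200, 160), label = c("CGI", "promoter"))
  mem <- assign_sites(sites, regions)
  expect_equal(mem$CGI, c(1, 3))          # 200 is outside [100, 200)
  expect_equal(mem$promoter, c(1, 3))     # overlap with both labels allowed
  expect_error(assign_sites(data.frame(chrom = "1", start = 1, end = 2),
                            regions), "chromosome naming")
})

test_that("assignment agrees with the quadratic-scan oracle", {
  set.seed(22)
  sites <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                      start = sample(1e4, 300))
  sites$end <- sites$start + sample(1:3, 300, TRUE)
  regions <- data.frame(chrom = sample(c("chr1", "chr2"), 150, TRUE),
                        start = sample(1e4, 150))
  regions$end <- regions$start + sample(5:500, 150, TRUE)
  regions$label <- sample(c("a", "b", "c"), 150, TRUE)
  got <- assign_sites(sites, regions)
  want <- overlap_oracle(sites, regions)
  for (lab in names(want)) expect_equal(got[[lab]], want[[lab]])
})

test_that("region slope is scale-invariant and averages member slopes", {
  ages <- rep(seq(3, 35, length.out = 16), each = 3)
  set.seed(30)
  base <- outer(rep(0.004, 10), ages) + 0.2 +
    matrix(rnorm(10 * length(ages), 0, 0.01), 10)
  rescaled <- base * 7 + 3   # affine rescale must not change z-scored slopes
  r1 <- region_slope(1:10, base, ages, seed = 2)
  r2 <- region_slope(1:10, rescaled, ages, seed = 2)
  expect_equal(r1$mean_slope, r2$mean_slope, tolerance = 1e-12)
  expect_gt(r1$mean_slope, 0)
  mirror <- rbind(base, 1 - base)
  rm <- region_slope(1:20, mirror, ages, seed = 2)
  expect_lt(abs(rm$mean_slope), 1e-10)
  expect_warning(expect_null(region_slope(1, base, ages)), "fewer than 2")
})

test_that("Fisher enrichment matches the cross-product OR and the oracle", {
  membership <- list(CGI = 1:10)
  directions <- c(rep("gain", 8), rep("none", 2),   # in region: 8 gain, 2 not
                  rep("gain", 20), rep("none", 70)) # outside: 20 gain, 70 not
  enr <- enrichment_fisher(membership, directions, "gain")
  expect_equal(enr$odds_ratio, 14)
  expect_equal(enr$p, fisher_oracle(8, 2, 20, 70), tolerance = 1e-12)
  expect_equal(enr$p, fisher.test(matrix(c(8, 2, 20, 70), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # independence: proportional table gives OR 1
  dirs2 <- c(rep("gain", 5), rep("none", 5), rep("gain", 20), rep("none", 20))
  enr2 <- enrichment_fisher(list(r = 1:10), dirs2, "gain")
  expect_equal(enr2$odds_ratio, 1)
  # empty margin: undefined OR
  enr3 <- enrichment_fisher(list(r = integer(0)), dirs2, "gain")
  expect_true(is.na(enr3$odds_ratio))
})

test_that("Fisher p equals the enumeration oracle over sampled tables", {
  set.seed(40)
  for (trial in 1:300) {
    tab <- sample(0:30, 4, replace = TRUE)
    got <- methyldrift:::fisher_p_two_sided(tab[1], tab[2], tab[3], tab[4])
    expect_equal(got, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
})

test_that("CGI-tier removal flips a region driven by island gain", {
  ages <- rep(seq(3, 35, length.out = 16), each = 3)
  set.seed(33)
  gain_cgi <- outer(rep(0.006, 12), ages) + 0.15
  loss_other <- outer(rep(-0.004, 12), ages) + 0.85
  fr <- rbind(gain_cgi, loss_other) +
    matrix(rnorm(24 * length(ages), 0, 0.01), 24)
  tiers <- cgi_sensitivity(1:24, fr, ages, cgi_idx = 1:12, seed = 3)
  base <- tiers$mean_slope[tiers$tier == "none"]
  t1 <- tiers$mean_slope[tiers$tier == "minus_cgi"]
  expect_gt(base, 0)      # gain sites dominate the mixed region
  expect_lt(t1, 0)        # removing CGI members flips the sign
  # a region with no CGI overlap is unchanged across tiers
  tiers2 <- cgi_sensitivity(13:24, fr, ages, cgi_idx = 1:12, seed = 3)
  expect_equal(tiers2$mean_slope[1], tiers2$mean_slope[2])
  expect_warning(cgi_sensitivity(1:12, fr, ages, cgi_idx = 1:12, seed = 3),
                 "fewer than 2")
})

test_that("relative gene positions honor strand and the extended window", {
  expect_equal(relative_gene_position(100, 100, 200, "+"), 0)
  expect_equal(relative_gene_position(200, 100, 200, "+"), 1)
  expect_equal(relative_gene_position(50, 100, 200, "+"), -0.5)
  expect_equal(relative_gene_position(200, 100, 200, "-"), 0)
  expect_equal(relative_gene_position(100, 100, 200, "-"), 1)
  expect_true(is.na(relative_gene_position(1000, 100, 200, "+")))
  expect_error(relative_gene_position(5, 100, 100, "+"), "zero-length")
})

test_that("metagene profile recovers a TSS-centered methylation bump", {
  ages <- rep(c(5, 30), each = 10)
  set.seed(44)
  pos <- seq(0, 2999, by = 20)
  sites <- data.frame(chrom = "chr1", start = pos, end = pos + 2)
  genes <- data.frame(chrom = "chr1", start = 1000, end = 2000, strand = "+")
  r_true <- (pos - 1000) / 1000
  bump <- 0.3 + 0.4 * exp(-((r_true - 0) / 0.3)^2)
  fr <- matrix(rep(bump, length(ages)), length(pos)) +
    matrix(rnorm(length(pos) * length(ages), 0, 0.02), length(pos))
  prof <- metagene_profile(fr, sites, genes, ages)
  expect_setequal(unique(prof$age_group), c(5, 30))
  young <- prof[prof$age_group == 5, ]
  peak_r <- young$r[which.max(young$mean_methylation)]
  expect_lt(abs(peak_r), 0.2)
  expect_error(metagene_profile(fr, sites,
                                data.frame(chrom = "chr1", start = 5,
                                           end = 5, strand = "+"), ages),
               "zero-length")
})

test_that("homolog-style set comparison detects opposite slopes", {
  ages <- rep(seq(3, 35, length.out = 16), each = 3)
  set.seed(55)
  up <- outer(rep(0.004, 15), ages) + 0.2
  dn <- outer(rep(-0.004, 15), ages) + 0.8
  fr <- rbind(up, dn) + matrix(rnorm(30 * length(ages), 0, 0.01), 30)
  cmp <- compare_region_sets(1:15, 16:30, fr, ages, seed = 4)
  expect_gt(cmp$a$mean_slope, 0)
  expect_lt(cmp$b$mean_slope, 0)
  expect_lt(cmp$t_test$p.value, 1e-6)
})
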