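# Designed-cohort builders shared by the unit and acceptance tests.

ages_16x9 <- function() rep(seq(3, 35, length.out = 16), each = 9)

control_sheet <- function(ages) {
  data.frame(sample_id = sprintf("x%03d", seq_along(ages)), age = ages,
             group = "control", stringsAsFactors = FALSE)
}

# Bimodal intercepts away from 0.5, as in a real methylome where most sites
# sit near fully methylated or unmethylated.
bimodal_intercepts <- function(S) {
  ifelse(runif(S) < 0.5, runif(S, 0.05, 0.35), runif(S, 0.65, 0.95))
}

# Cohort whose per-site slopes relate to intercepts through a known
# expected-slope law e(i), scaled per site by a category multiplier:
# follow = 1, exceed = 2, slower = 0.5, counter = -1, resist = 0.
# The category weights are chosen so the multipliers average to 1 among the
# slope-significant categories, keeping the fitted smooth centered on e(i).
entropy_class_cohort <- function(S = 2000, ages = ages_16x9(),
                                 noise_sd = 0.02, seed = 43,
                                 e_law = function(i) 0.01 * (0.5 - i),
                                 weights = c(follow = 0.3, exceed = 0.3,
                                             slower = 0.2, counter = 0.1,
                                             resist = 0.1)) {
  set.seed(seed)
  cls <- sample(rep(names(weights), round(weights * S)))[seq_len(S)]
  i0 <- bimodal_intercepts(S)
  e <- e_law(i0)
  mult <- c(follow = 1, exceed = 2, slower = 0.5, counter = -1, resist = 0)[cls]
  lat <- outer(e * unname(mult), ages) + i0
  fr <- pmin(pmax(lat + matrix(rnorm(S * length(ages), 0, noise_sd), S), 0), 1)
  rownames(fr) <- paste0("s", seq_len(S))
  list(fractions = fr, classes = cls, intercepts = i0, expected = e,
       samples = control_sheet(ages))
}

# Cohort whose per-sample entropy follows the inverse power law
# age = a + b * H^-13 (drift of every site toward 0.5, accelerating late in
# life). Fractions are placed at the value solving the entropy equation.
entropy_law_cohort <- function(n_sites = 400, ages = ages_16x9(),
                               H_start = 0.55, H_end = 0.80,
                               noise_sd = 0.01, seed = 42) {
  set.seed(seed)
  span <- max(ages) - min(ages)
  b <- span / (H_end^-13 - H_start^-13)
  a <- min(ages) - b * H_start^-13
  Ht <- ((ages - a) / b)^(-1 / 13)
  m_for_H <- function(H) {
    uniroot(function(m) (m * log(m) + (1 - m) * log(1 - m)) / log(0.5) - H,
            c(1e-6, 0.5))$root
  }
  mt <- vapply(Ht, m_for_H, numeric(1))
  fr <- matrix(rep(mt, each = n_sites), n_sites) +
    matrix(rnorm(n_sites * length(ages), 0, noise_sd), n_sites)
  fr <- pmin(pmax(fr, 0), 1)
  rownames(fr) <- paste0("s", seq_len(n_sites))
  list(fractions = fr, ages = ages, H_target = Ht)
}

# Small stranded matrix for CpG aggregation tests.
stranded_matrix <- function() {
  sites <- data.frame(
    chrom = "chr1",
    start = c(100, 101, 200, 300, 301),
    end = c(101, 102, 201, 301, 302),
    strand = c("+", "-", "+", "+", "-"))
  meth <- matrix(c(3, 2, 1, 4, 0,
                   1, 1, 0, 2, 2), ncol = 2)
  total <- matrix(c(5, 5, 2, 6, 3,
                    2, 3, 1, 4, 4), ncol = 2)
  methylome_matrix(sites, meth, total, c("A", "B"))
}
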