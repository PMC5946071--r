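# Independent brute-force oracles used to cross-check package computations.
# These deliberately use naive algorithms (exhaustive scans, closed forms,
# direct enumeration) and never share code with the implementation.

# Benjamini-Hochberg by the step-up definition: q_(i) = min_{j >= i} p_(j)*n/j
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- q
  out
}

# Shorth threshold by exhaustive O(n^2) window scan over the sorted values.
shorth_oracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  h <- ceiling(n / 2)
  if (h >= n) return(mean(v))
  best_w <- Inf
  best_mean <- Inf
  for (s in 1:(n - h + 1)) {
    w <- v[s + h - 1] - v[s]
    m <- sum(v[s:(s + h - 1)]) / h
    if (w < best_w - 1e-9 || (abs(w - best_w) <= 1e-9 && m < best_mean)) {
      best_w <- w
      best_mean <- m
    }
  }
  best_mean
}

# Two-sided Fisher p by direct enumeration of the conditional distribution,
# with table probabilities computed from log-binomial coefficients.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  logp <- function(k) {
    lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  }
  p_obs <- exp(logp(a))
  tot <- 0
  for (k in lo:hi) {
    pk <- exp(logp(k))
    if (pk <= p_obs * (1 + 1e-7)) tot <- tot + pk
  }
  min(1, tot)
}

# Simple-regression closed form with the two-sided t p-value for the slope.
simple_reg_oracle <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept, se = se,
       p = 2 * pt(abs(t), n - 2, lower.tail = FALSE))
}

# Quadratic-scan interval overlap (0-based half-open on both sides).
overlap_oracle <- function(sites, regions) {
  out <- list()
  for (r in seq_len(nrow(regions))) {
    hits <- integer(0)
    for (s in seq_len(nrow(sites))) {
      if (sites$chrom[s] == regions$chrom[r] &&
          sites$start[s] < regions$end[r] &&
          regions$start[r] < sites$end[s]) {
        hits <- c(hits, s)
      }
    }
    lab <- regions$label[r]
    out[[lab]] <- sort(unique(c(out[[lab]], hits)))
  }
  out
}

# All permutations of 1..n (recursive insertion), for small-n oracle sweeps.
combinat_perms <- function(n) {
  if (n == 1) return(list(1))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos)
    }
  }
  out
}
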