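# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clip values into a closed interval
#' @param x numeric vector or matrix
#' @param lo,hi interval bounds
#' @return `x` with values forced into `[lo, hi]`
#' @keywords internal
clip_range <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Deterministic per-site seed substream. Keeps every value strictly below
# 2^31 so it is a valid R integer seed.
site_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 69069 + as.numeric(i) * 7919) %% 2147483647)
}

# Deterministic 31-bit rolling hash of a character vector, as 8 hex digits.
# Used to stamp result files with a configuration fingerprint without extra
# dependencies; not cryptographic.
config_hash <- function(s) {
  bytes <- as.numeric(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261 %% 2147483647
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Multi-response ordinary least squares on a shared design matrix.
# X: n x k design, Y: n x S response matrix (one column per site/sample unit).
# Returns coefficients, standard errors, t statistics and two-sided p-values
# per response column, plus residual sums of squares and degrees of freedom.
ols_multi <- function(X, Y) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    stop("rank-deficient design matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qrX, Y)
  if (is.null(dim(coef))) coef <- matrix(coef, ncol = ncol(Y))
  fitted <- X %*% coef
  res <- Y - fitted
  rss <- colSums(res^2)
  df <- n - ncol(X)
  XtXinv <- chol2inv(qr.R(qrX))
  sigma2 <- rss / df
  se <- sqrt(outer(diag(XtXinv), sigma2)) # k x S
  tstat <- coef / se
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  rownames(coef) <- rownames(se) <- rownames(tstat) <- rownames(pval) <- colnames(X)
  list(coef = coef, se = se, t = tstat, p = pval, rss = rss, df = df,
       residuals = res)
}

# Residualize the columns of M (n x S) against the column space of Z (n x q).
residualize <- function(M, Z) {
  qrZ <- qr(Z)
  M - qr.fitted(qrZ, M)
}

# Build the confounder part of a design matrix from an optional data frame.
confounder_matrix <- function(confounders, n) {
  if (is.null(confounders) || length(confounders) == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  M <- as.matrix(as.data.frame(confounders))
  if (!is.numeric(M)) stop("confounder columns must be numeric")
  if (nrow(M) != n) stop("confounders must have one row per sample")
  M
}
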