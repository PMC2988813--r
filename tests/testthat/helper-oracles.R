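# Independent brute-force oracles used to validate the statistical
# primitives. These stay deliberately naive: direct combinatorial sums
# with choose(), no shared code with the package internals.

# upper-tail hypergeometric by direct enumeration of the sample space
hyper_enum <- function(N, K, n, k) {
  kk <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(probs[kk >= k])
}

# two-sided Fisher exact p by the probability-mass method: sum of all
# tables at the observed margins whose point probability does not
# exceed the observed table's (with the standard relative tolerance
# for floating-point ties)
fisher_enum <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  K <- a + b          # row 1 margin
  n <- a + c_         # col 1 margin
  N <- a + b + c_ + d
  kk <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  p_obs <- probs[kk == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# plain two-sample t with per-group variances (the nu0 = 0 limit of
# the regularized test), df = n1 + n2 - 2
welch_style_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  t <- (mean(x1) - mean(x2)) / sqrt(var(x1) / n1 + var(x2) / n2)
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# closed-form regularized t, written independently from the formula
reg_t_oracle <- function(x1, x2, s01, s02, nu0) {
  n1 <- length(x1); n2 <- length(x2)
  v1 <- (nu0 * s01^2 + (n1 - 1) * var(x1)) / (nu0 + n1 - 2)
  v2 <- (nu0 * s02^2 + (n2 - 1) * var(x2)) / (nu0 + n2 - 2)
  t <- (mean(x1) - mean(x2)) / sqrt(v1 / n1 + v2 / n2)
  df <- n1 + n2 - 2 + 2 * nu0
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# tiny array_scan builder for I/O-free screen tests
make_scan <- function(id, values, channel = "Cy5", flags = 0L) {
  n <- length(values)
  feat <- data.frame(feature_id = names(values),
                     spot_index = 1L,
                     flag = rep_len(flags, n),
                     stringsAsFactors = FALSE)
  feat[[paste0("net.", channel)]] <- unname(values)
  structure(list(array_id = id, features = feat, channel_names = channel),
            class = "array_scan")
}
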