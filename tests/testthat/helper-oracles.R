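# Independent oracles used by the unit tests. These are deliberately
# naive re-implementations (loops, direct formulas, enumeration) kept
# separate from the package code paths they check.

# Brute-force moderated t: per-gene loops, uniroot-based trigamma
# inversion (the package uses vectorized code and bisection).
oracle_moderated_t <- function(mat, cols_a, cols_b) {
  G <- nrow(mat)
  na <- length(cols_a); nb <- length(cols_b)
  dg <- na + nb - 2
  s2 <- numeric(G); beta <- numeric(G)
  for (g in seq_len(G)) {
    xa <- as.numeric(mat[g, cols_a]); xb <- as.numeric(mat[g, cols_b])
    beta[g] <- mean(xa) - mean(xb)
    s2[g] <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / dg
  }
  e <- log(pmax(s2, 1e-300)) - digamma(dg / 2) + log(dg / 2)
  ebar <- mean(e)
  rhs <- mean((e - ebar)^2 * G / (G - 1) - trigamma(dg / 2))
  if (!is.finite(rhs) || rhs <= 0) {
    d0 <- Inf
    s02 <- exp(ebar)
    s2post <- rep(s02, G)
    dft <- Inf
  } else {
    half <- stats::uniroot(function(x) trigamma(x) - rhs,
                           lower = 1e-8, upper = 1e8, tol = 1e-12)$root
    d0 <- 2 * half
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    s2post <- (d0 * s02 + dg * s2) / (d0 + dg)
    dft <- d0 + dg
  }
  tst <- beta / sqrt(s2post * (1 / na + 1 / nb))
  p <- 2 * stats::pt(abs(tst), df = dft, lower.tail = FALSE)
  list(t = tst, p = p, d0 = d0, s02 = s02, s2_post = s2post)
}

# Exact one-sample signed-rank p by enumeration over all sign vectors;
# alternative "greater" means the observed mu exceeds the sample
# location, i.e. small W = sum of ranks where x > mu.
oracle_signrank_greater <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  total <- 0L; count <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[1:n]
    w <- sum(r[signs == 1])
    total <- total + 1L
    if (w <= W) count <- count + 1L
  }
  count / total
}

# Running-mean detrend oracle via stats::filter (package uses cumsum).
oracle_detrend <- function(t, y, window_h) {
  dt <- mean(diff(t))
  k <- round(window_h / dt)
  if (k %% 2 == 0) k <- k + 1
  rm <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  keep <- !is.na(rm)
  list(t = t[keep], y = y[keep] / rm[keep])
}

make_planted_study <- function(seed = 42, n_genes = 5000, planted = 30,
                               effect = 2.0, n_test = 0) {
  gen_expression(n_genes = n_genes, planted = planted,
                 effect_sd = effect, n_test_lines = n_test, seed = seed)
}
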