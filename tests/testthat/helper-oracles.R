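# Independent oracles used across test files.

# Discrete Wright-Fisher sojourn-time oracle: 2N haploid copies,
# semidominant selection with heterozygote coefficient s = S/(4N),
# binomial resampling. Returns the expected sampled SFS (class 1..2n-1)
# of a single new mutation, from the fundamental matrix of the transient
# chain (expected visits to each frequency before absorption).
wfSampledSFS <- function(S, twoN = 2000, nChrom = 8) {
  s <- S / (2 * twoN)
  j <- seq_len(twoN - 1L)
  p <- j / twoN
  wbar <- p^2 * (1 + 2 * s) + 2 * p * (1 - p) * (1 + s) + (1 - p)^2
  pp <- (p^2 * (1 + 2 * s) + p * (1 - p) * (1 + s)) / wbar
  Q <- matrix(0, twoN - 1L, twoN - 1L)
  for (a in j) Q[a, ] <- dbinom(j, twoN, pp[a])
  visits <- solve(t(diag(twoN - 1L) - Q), as.numeric(j == 1L))
  vapply(seq_len(nChrom - 1L),
         function(i) sum(visits * dbinom(i, nChrom, p)), 0)
}

# Dense-grid Riemann sum of int Phi(S) f(S) dS for a purely continuous
# DFE, on a trapezoid log-spaced grid per sign; independent of the
# package's quantile-based Gauss-Legendre scheme.
riemannDFEIntegral <- function(dfe, f, nGrid = 2e4) {
  tot <- 0
  for (sgn in c(-1, 1)) {
    S <- sgn * exp(seq(log(1e-12), log(1e7), length.out = nGrid))
    dens <- dfeDensity(dfe, S)
    if (all(dens == 0)) next
    val <- dens * f(S)
    h <- abs(diff(S))
    tot <- tot + sum((val[-1] + val[-nGrid]) / 2 * h)
  }
  tot
}

# Hand-rolled Pearson r (textbook formula), independent of cor().
pearsonR <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
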