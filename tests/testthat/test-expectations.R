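test_that("sojourn density has the neutral 2/x limit and matches the diffusion form", {
  expect_equal(sojournDensity(0, 0.5), 4)
  expect_equal(sojournDensity(0, 0.1), 20)
  # direct evaluation of the closed form as an independent oracle
  for (S in c(-2, -0.5, 0.5, 3)) for (x in c(0.1, 0.5, 0.9)) {
    oracle <- 2 * (1 - exp(-S * (1 - x))) / (x * (1 - x) * (1 - exp(-S)))
    expect_equal(sojournDensity(S, x), oracle, tolerance = 1e-10)
  }
  # continuity across the S = 0 branch
  expect_equal(sojournDensity(1e-9, 0.3), sojournDensity(0, 0.3),
               tolerance = 1e-6)
  # overflow guard far in the tails
  expect_true(is.finite(sojournDensity(-2000, 0.01)))
  expect_true(is.finite(sojournDensity(2000, 0.99)))
  expect_error(sojournDensity(0, 1), "strictly")
})

test_that("binomial sampling probabilities behave", {
  expect_equal(samplingProb(1, 2, 0.5), 0.5)
  expect_equal(samplingProb(0, 8, 0.3), 0.7^8)
  expect_equal(sum(samplingProb(0:8, 8, 0.37)), 1)
})

test_that("segregation factor reduces to 2/i near S = 0 and converges in nodes", {
  expect_equal(segFactor(1e-10, 2, 8), 1, tolerance = 1e-6)
  expect_equal(segFactor(1e-10, 5, 12), 0.4, tolerance = 1e-6)
  for (i in c(1, 3, 7)) {
    g256 <- segFactor(-7.3, i, 8, xNodes = 256L)
    g512 <- segFactor(-7.3, i, 8, xNodes = 512L)
    expect_equal(g256, g512, tolerance = 1e-9)
  }
  expect_error(segFactor(0, 8, 8), "i must lie")
})

test_that("fixation factor has the neutral limit and the reflection identity", {
  expect_equal(fixationFactor(0), 1)
  expect_equal(fixationFactor(2), 2 / (1 - exp(-2)), tolerance = 1e-12)
  S <- c(-700, -50, -3, -1e-4, 1e-4, 3, 50, 700)
  expect_equal(fixationFactor(S) - fixationFactor(-S), S, tolerance = 1e-10)
})

test_that("fully neutral expectations recover the theta L / i closed form", {
  par <- ModelParams(theta = 0.01, r = rep(1, 7), Tdiv = 0.05,
                     dfe = DFEModel("neutral", f_neutral = 1))
  shp <- list(nChrom = 8L, folded = FALSE, LN = 1000, LS = 1000,
              LdivN = 1000, LdivS = 1000)
  ex <- expectedData(par, shp)
  expect_equal(ex$expPS, 10 / (1:7), tolerance = 1e-12)
  expect_equal(ex$expPN, 10 / (1:7), tolerance = 1e-9)
  expect_equal(ex$expDS, 50)
  expect_equal(ex$expDN, 50, tolerance = 1e-12)
  # non-synonymous / synonymous ratio is L_N / L_S at every class
  shp2 <- list(nChrom = 8L, folded = FALSE, LN = 3000, LS = 1000,
               LdivN = 3000, LdivS = 1000)
  ex2 <- expectedData(par, shp2)
  expect_equal(ex2$expPN / ex2$expPS, rep(3, 7), tolerance = 1e-9)
})

test_that("gamma DFE suppresses the non-synonymous SFS, more so for stronger selection", {
  shp <- list(nChrom = 8L, folded = FALSE, LN = 1000, LS = 1000,
              LdivN = 1000, LdivS = 1000)
  prev <- NULL
  for (md in c(10, 100, 1000)) {
    par <- ModelParams(0.01, rep(1, 7), 0.05,
                       DFEModel("gamma", shape = 0.4, mean_del = md))
    ex <- expectedData(par, shp)
    ratio <- ex$expPN / ex$expPS
    expect_true(all(ratio < 1))
    if (!is.null(prev)) expect_true(all(ratio < prev))
    prev <- ratio
  }
})

test_that("DFE quadrature agrees with a dense Riemann-sum oracle", {
  n2 <- 8L
  for (dfe in list(DFEModel("gamma", shape = 0.4, mean_del = 500),
                   DFEModel("gammaexpo", shape = 0.4, mean_del = 500,
                            p_pos = 0.02, mean_adv = 10))) {
    psi <- adaptiveMK:::.dfePolyIntegrals(dfe, n2)
    oracle <- sapply(seq_len(n2 - 1L), function(i)
      riemannDFEIntegral(dfe, function(S) segFactor(S, i, n2)))
    expect_equal(psi, oracle, tolerance = 1e-4)
    Ifix <- adaptiveMK:::.dfeDivIntegral(dfe)
    expect_equal(Ifix, riemannDFEIntegral(dfe, fixationFactor),
                 tolerance = 1e-4)
  }
})

test_that("expected dN/dS responds monotonically to the DFE (A = 0)", {
  dnds <- function(p_pos, mean_del) {
    dfe <- DFEModel("gammaexpo", shape = 0.4, mean_del = mean_del,
                    p_pos = p_pos, mean_adv = 10)
    adaptiveMK:::.dfeDivIntegral(dfe)   # = expected dN/dS at A = 0
  }
  grid <- c(0.001, 0.01, 0.05)
  expect_true(all(diff(sapply(grid, dnds, mean_del = 500)) > 0))
  expect_true(all(diff(sapply(c(50, 500, 5000), function(md)
    dnds(0.01, md))) < 0))
})

test_that("folded expectations are sums of mirror unfolded classes", {
  dfe <- DFEModel("gamma", shape = 0.4, mean_del = 300)
  parU <- ModelParams(0.02, rep(1, 7), 0.1, dfe)
  shpU <- list(nChrom = 8L, folded = FALSE, LN = 2000, LS = 1000,
               LdivN = 2000, LdivS = 1000)
  exU <- expectedData(parU, shpU)
  parF <- ModelParams(0.02, rep(1, 4), 0.1, dfe)
  shpF <- shpU; shpF$folded <- TRUE
  exF <- expectedData(parF, shpF)
  foldv <- function(u) c(u[1:3] + u[7:5], u[4])
  expect_equal(exF$expPS, foldv(exU$expPS))
  expect_equal(exF$expPN, foldv(exU$expPN))
})

test_that("r multipliers scale both spectra class-wise", {
  dfe <- DFEModel("gamma", shape = 0.4, mean_del = 300)
  r <- c(1, 1.4, 0.7, 2, 1.1, 0.9, 1.3)
  shp <- list(nChrom = 8L, folded = FALSE, LN = 2000, LS = 1000,
              LdivN = 2000, LdivS = 1000)
  ex1 <- expectedData(ModelParams(0.02, rep(1, 7), 0.1, dfe), shp)
  exr <- expectedData(ModelParams(0.02, r, 0.1, dfe), shp)
  expect_equal(exr$expPS, r * ex1$expPS)
  expect_equal(exr$expPN, r * ex1$expPN)
  expect_equal(exr$expDN, ex1$expDN)
})

test_that("Poisson terms generalize to fractional counts and zero expectations", {
  expect_equal(adaptiveMK:::.poisTerm(1, 1), -1)
  expect_equal(adaptiveMK:::.poisTerm(0, 2.5), -2.5)
  expect_equal(adaptiveMK:::.poisTerm(0, 0), 0)
  expect_equal(adaptiveMK:::.poisTerm(2, 0), -Inf)
  # fractional counts: continuous in a, matches lgamma form
  a <- 2.3; b <- 1.7
  expect_equal(adaptiveMK:::.poisTerm(a, b),
               -b + a * log(b) - lgamma(a + 1))
})

test_that("the synonymous-only Poisson MLE of theta is recovered by the likelihood", {
  # all-lethal DFE: non-synonymous cells are exactly zero, so only the
  # synonymous SFS informs theta, with closed form sum(PS)/(LS sum(1/i))
  set.seed(11)
  n2 <- 8L
  PS <- rpois(n2 - 1L, 50 / (1:7))
  d <- PolyDivData("t", Spectrum(numeric(7), n2), Spectrum(PS, n2),
                   DN = 0, DS = 20, LN = 1000, LS = 1000)
  llTheta <- function(th)
    logLikelihood(d, ModelParams(th, rep(1, 7), 0.02,
                                 DFEModel("neutral", f_neutral = 0)))
  opt <- optimize(llTheta, c(1e-4, 1), maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, sum(PS) / (1000 * sum(1 / (1:7))),
               tolerance = 1e-5)
})
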