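test_that("a simulated neutral DFE is recovered within tight bounds", {
  truth <- ModelParams(theta = 0.02, r = rep(1, 7), Tdiv = 0.1,
                       dfe = DFEModel("neutral", f_neutral = 0.4))
  sc <- SimScenario(truth, nChrom = 8, LN = 1e6, LS = 3e5)
  d <- sampleDataset(sc, 1, seed = 21)
  f <- fitModel(d, "neutral", restarts = 2, seed = 1)
  expect_true(f@converged)
  expect_equal(dfeParams(f@params@dfe)[["f_neutral"]], 0.4,
               tolerance = 0.02 / 0.4)
  expect_equal(f@params@theta, 0.02, tolerance = 0.03)
  expect_equal(f@params@Tdiv, 0.1, tolerance = 0.03)
})

test_that("the Poisson score equation holds at the neutral-family optimum", {
  truth <- ModelParams(theta = 0.02, r = rep(1, 7), Tdiv = 0.1,
                       dfe = DFEModel("neutral", f_neutral = 0.4))
  sc <- SimScenario(truth, nChrom = 8, LN = 1e5, LS = 5e4)
  d <- sampleDataset(sc, 1, seed = 22)
  f <- fitModel(d, "neutral", restarts = 2, seed = 1)
  # with the non-synonymous scale free (f_neutral), the synonymous
  # expected total must match the observed synonymous total
  expTotS <- f@params@theta * d@LS * sum(f@params@r / (1:7))
  expect_equal(expTotS, sum(sfsCounts(d@sfsSyn)), tolerance = 1e-3)
})

test_that("refitting from the optimum is a fixed point of the likelihood", {
  f1 <- smallGammaFit()
  p <- f1@params
  f2 <- fitModel(smallGammaData(), "gamma", restarts = 1, seed = 3,
                 init = list(list(theta = p@theta, Tdiv = p@Tdiv, A = p@A,
                                  dfe = p@dfe)))
  expect_gte(f2@loglik, f1@loglik - 1e-6)
  expect_equal(f2@loglik, f1@loglik, tolerance = 1e-4)
})

test_that("fits are deterministic given the seed", {
  d <- smallGammaData()
  f1 <- fitModel(d, "gamma", restarts = 2, seed = 5)
  f2 <- fitModel(d, "gamma", restarts = 2, seed = 5)
  expect_identical(f1@loglik, f2@loglik)
  expect_identical(f1@params@theta, f2@params@theta)
})

test_that("free-parameter accounting matches the model structure", {
  f <- smallGammaFit()
  expect_equal(f@nFree, 2L + 6L + 2L + 1L)   # theta,T + r + gamma + A
  expect_equal(f@aic, 2 * f@nFree - 2 * f@loglik)
  fm <- fitMinusA(smallGammaData(), "gammaexpo", restarts = 1, seed = 3,
                  init = warmFromGamma(f))
  expect_equal(fm@nFree, 2L + 6L + 4L)       # no A
})

test_that("the minus_A variant is rejected for purely deleterious families", {
  expect_error(fitMinusA(smallGammaData(), "gamma"), "positive")
  expect_error(fitModel(smallGammaData(), "neutral", variant = "minus_A"),
               "positive")
})

test_that("pinning A to zero can only lower the likelihood", {
  d <- smallGammaData()
  fm <- fitMinusA(d, "gammaexpo", restarts = 1, seed = 3,
                  init = warmFromGamma(smallGammaFit()))
  # warm-start the richer model from the constrained optimum (A ~ 0)
  p <- fm@params
  fs <- fitModel(d, "gammaexpo", restarts = 1, seed = 3,
                 init = c(warmFromGamma(smallGammaFit()),
                          list(list(theta = p@theta, Tdiv = p@Tdiv,
                                    A = 1e-9, dfe = p@dfe))))
  expect_lte(fm@loglik, fs@loglik + 1e-6)
})

test_that("likelihood-ratio tests validate nesting and match the chi-square", {
  mkFit <- function(fam, variant, ll, nclass = 7L) {
    dfe <- switch(fam,
      neutral = DFEModel("neutral", f_neutral = 0.5),
      gamma = DFEModel("gamma", shape = 0.4, mean_del = 100),
      gammaexpo = DFEModel("gammaexpo", shape = 0.4, mean_del = 100,
                           p_pos = 0.01, mean_adv = 5),
      scaledbeta = DFEModel("scaledbeta", a = 1, b = 1, w_mild = 0.5))
    nF <- 2L + (nclass - 1L) + nFreeParams(dfe) +
      (variant == "standard")
    new("FitResult", params = ModelParams(0.01, rep(1, nclass), 0.1, dfe),
        loglik = ll, aic = 2 * nF - 2 * ll, nFree = as.integer(nF),
        converged = TRUE, nRestartsUsed = 1L, variant = variant,
        label = "x")
  }
  # equal logliks: statistic 0, p = 1
  t0 <- lrt(mkFit("gamma", "standard", -50), mkFit("gammaexpo", "standard", -50))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  expect_equal(t0$df, 2L)
  # statistic 3.84 on 1 df sits at p ~ 0.05
  t1 <- lrt(mkFit("neutral", "standard", -51.92),
            mkFit("gamma", "standard", -50))
  expect_equal(t1$df, 1L)
  expect_equal(t1$p, pchisq(3.84, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(t1$p, 0.05, tolerance = 0.01)
  # a better null than alternative floors at zero
  expect_equal(lrt(mkFit("gamma", "standard", -49),
                   mkFit("gammaexpo", "standard", -50))$statistic, 0)
  # invalid pairs are refused
  expect_error(lrt(mkFit("scaledbeta", "standard", -50),
                   mkFit("gammaexpo", "standard", -49)), "not nested")
  expect_error(lrt(mkFit("gamma", "standard", -50),
                   mkFit("gammaexpo", "minus_A", -49)), "not nested")
  # minus_A within standard, same family
  t2 <- lrt(mkFit("gammaexpo", "minus_A", -52),
            mkFit("gammaexpo", "standard", -50))
  expect_equal(t2$df, 1L)
  expect_equal(t2$statistic, 4)
})

test_that("model scan ranks by AIC, reproducibly, with nested LRTs", {
  d <- smallGammaData()
  s1 <- modelScan(d, families = c("neutral", "gamma", "gammaexpo"),
                  restarts = 1, seed = 13)
  s2 <- modelScan(d, families = c("neutral", "gamma", "gammaexpo"),
                  restarts = 1, seed = 13)
  expect_identical(s1$table$family, s2$table$family)
  expect_identical(s1$table$aic, s2$table$aic)
  expect_true(all(diff(s1$table$aic) >= 0))
  # warm-started chain: likelihood non-decreasing with model complexity
  lls <- sapply(s1$fits, function(f) f@loglik)
  expect_gte(lls[["gamma"]], lls[["neutral"]] - 1e-3)
  expect_gte(lls[["gammaexpo"]], lls[["gamma"]] - 1e-3)
  expect_setequal(paste(s1$lrt$null, s1$lrt$alt),
                  c("neutral gamma", "neutral gammaexpo", "gamma gammaexpo"))
  expect_true(all(s1$lrt$p >= 0 & s1$lrt$p <= 1))
})

test_that("estimates are invariant to a common rescaling of counts and sites", {
  d <- smallGammaData()
  d10 <- PolyDivData(d@label, Spectrum(10 * sfsCounts(d@sfsNonsyn), 8),
                     Spectrum(10 * sfsCounts(d@sfsSyn), 8),
                     DN = 10 * d@DN, DS = 10 * d@DS, LN = 10 * d@LN,
                     LS = 10 * d@LS, LdivN = 10 * d@LdivN,
                     LdivS = 10 * d@LdivS)
  f1 <- fitModel(d, "gamma", restarts = 2, seed = 5)
  f10 <- fitModel(d10, "gamma", restarts = 2, seed = 5)
  expect_equal(f10@params@theta, f1@params@theta, tolerance = 0.01)
  expect_equal(f10@params@Tdiv, f1@params@Tdiv, tolerance = 0.01)
  a1 <- adaptiveRates(d, f1@params)@alpha
  a10 <- adaptiveRates(d10, f10@params)@alpha
  expect_equal(a10, a1, tolerance = 0.02)
})

test_that("alpha estimation error shrinks with the amount of data", {
  truth <- referenceParams("neutral")
  err <- sapply(c(1e5, 1e7), function(L) {
    mean(sapply(1:5, function(r) {
      d <- sampleDataset(SimScenario(truth, 8, LN = L, LS = L / 3), r,
                         seed = 31)
      abs(adaptiveRates(d, fitModel(d, "neutral", restarts = 2,
                                    seed = 1)@params)@alpha)
    }))
  })
  expect_lt(err[2], err[1])
})

test_that("profile CI for alpha collapses at drop 0 and brackets the estimate", {
  d <- smallGammaData()
  f <- smallGammaFit()
  ahat <- adaptiveRates(d, f@params)@alpha
  c0 <- profileCIAlpha(d, f, drop = 0)
  expect_equal(c0$lower, ahat)
  expect_equal(c0$upper, ahat)
  ci <- profileCIAlpha(d, f, drop = 2, step = 0.05, tol = 0.02)
  expect_lte(ci$lower, ahat)
  expect_gte(ci$upper, ahat)
  expect_lt(ci$lower, ci$upper)
})

test_that("fit results serialize to a readable key=value file", {
  f <- smallGammaFit()
  path <- withr::local_tempfile(fileext = ".txt")
  writeFitResult(f, path)
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- setNames(vapply(kv, `[`, "", 2L), keys)
  expect_equal(as.numeric(vals[["loglik"]]), f@loglik, tolerance = 1e-8)
  expect_equal(vals[["family"]], "gamma")
  expect_equal(as.numeric(vals[["r_1"]]), 1)
})
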