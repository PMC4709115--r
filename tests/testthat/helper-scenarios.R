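# Shared simulation scenarios and lazily-built fit fixtures.

refScenario <- function(family, LN = 1e6, LS = 3e5, nChrom = 8L, ...) {
  SimScenario(referenceParams(family, nChrom = nChrom), nChrom = nChrom,
              LN = LN, LS = LS, ...)
}

# gammaexpo start embedded at the gamma optimum (p_pos ~ 0), used to keep
# likelihoods monotone along the nested chain.
warmFromGamma <- function(gammaFit, family = "gammaexpo") {
  g <- gammaFit@params
  dfe <- if (family == "gammaexpo")
    DFEModel("gammaexpo", shape = dfeParams(g@dfe)[["shape"]],
             mean_del = dfeParams(g@dfe)[["mean_del"]],
             p_pos = 1e-8, mean_adv = 10)
  else
    DFEModel("displgamma", shape = dfeParams(g@dfe)[["shape"]],
             mean_del = dfeParams(g@dfe)[["mean_del"]],
             displacement = 1e-8)
  list(list(theta = g@theta, Tdiv = g@Tdiv, A = g@A, dfe = dfe))
}

# One small gamma-truth dataset and fit, computed once per test run.
.fixtures <- new.env(parent = emptyenv())

smallGammaData <- function() {
  if (is.null(.fixtures$gd)) {
    sc <- refScenario("gamma", LN = 5e4, LS = 2e4)
    .fixtures$gd <- sampleDataset(sc, 1, seed = 42)
  }
  .fixtures$gd
}

smallGammaFit <- function() {
  if (is.null(.fixtures$gf))
    .fixtures$gf <- fitModel(smallGammaData(), "gamma", restarts = 2,
                             seed = 7)
  .fixtures$gf
}
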