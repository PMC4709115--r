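# Model-based Poisson simulator: every SFS class and divergence count is
# drawn Poisson around its model expectation (the sampling distribution
# the likelihood assumes), with optional mis-orientation moving sampled
# SNPs to the mirror frequency class. No forward population simulation.

#' Reference generating parameters
#'
#' Default study conditions used by the package's validation simulations:
#' theta = 0.01 (a typical invertebrate synonymous diversity), T = 0.1
#' (synonymous divergence of 10 percent, mid-range for closely related
#' species pairs), flat r at 2n = 8 chromosomes, A = 0, and per-family DFE
#' defaults (Gamma shape 0.4 and mean scaled effect 1000 for the
#' deleterious branch, matching DFE estimates typical of animal data; 1
#' percent of weakly advantageous mutations of mean scaled effect 10 for
#' gammaexpo).
#'
#' @param family DFE family name.
#' @param theta,Tdiv,A,nChrom overrides of the default conditions.
#' @return A [ModelParams-class] with an unfolded flat r vector.
#' @export
referenceParams <- function(family = "gammaexpo", theta = 0.01, Tdiv = 0.1,
                            A = 0, nChrom = 8L) {
  dfe <- switch(family,
    neutral    = DFEModel("neutral", f_neutral = 0.4),
    gamma      = DFEModel("gamma", shape = 0.4, mean_del = 1000),
    gammaexpo  = DFEModel("gammaexpo", shape = 0.4, mean_del = 1000,
                          p_pos = 0.01, mean_adv = 10),
    scaledbeta = DFEModel("scaledbeta", a = 0.3, b = 1.2, w_mild = 0.3),
    displgamma = DFEModel("displgamma", shape = 0.4, mean_del = 1000,
                          displacement = 0.5),
    stop("unknown family: ", family))
  ModelParams(theta = theta, r = rep(1, nChrom - 1L), Tdiv = Tdiv,
              dfe = dfe, A = A)
}

#' Demographic distortion presets for the r vector
#'
#' Named generators of per-class nuisance multipliers (r\[1\] = 1 always):
#' \describe{
#'   \item{flat}{all ones (constant-size Wright-Fisher).}
#'   \item{expansion-like}{\eqn{r_i = 1 + \sin(\pi (i-1)/(2n-2))}: rises
#'     to 2 at intermediate frequencies and returns to 1.}
#'   \item{bottleneck-like}{\eqn{r_i = \sqrt{i}}: monotone excess of
#'     intermediate- and high-frequency variants relative to singletons.}
#' }
#' These are package-defined shapes for validation, not fits to any
#' particular demographic history.
#'
#' @param name preset name.
#' @param nChrom number of chromosomes (2n); the vector has 2n - 1
#'   entries.
#' @return Numeric r vector of length \code{nChrom - 1} with first entry 1.
#' @examples
#' distortionPresets("flat", 8)
#' @export
distortionPresets <- function(name = c("flat", "expansion-like",
                                       "bottleneck-like"), nChrom) {
  name <- match.arg(name)
  i <- seq_len(nChrom - 1L)
  switch(name,
    "flat" = rep(1, nChrom - 1L),
    "expansion-like" = 1 + sin(pi * (i - 1) / (nChrom - 2L)),
    "bottleneck-like" = sqrt(i))
}

#' Alpha implied by the generating model
#'
#' The proportion of adaptive non-synonymous substitutions implied by a
#' scenario's parameters, computed from expectations with no sampling
#' noise: \code{(expDN - expDNna) / expDN}.
#'
#' @param scenario a [SimScenario-class].
#' @param Sadv non-adaptive threshold (default 5).
#' @return Numeric scalar (0 for a neutral DFE with A = 0).
#' @export
trueAlpha <- function(scenario, Sadv = 5) {
  shape <- list(nChrom = scenario@nChrom, folded = FALSE,
                LN = scenario@LN, LS = scenario@LS,
                LdivN = scenario@LdivN, LdivS = scenario@LdivS)
  ex <- expectedData(scenario@params, shape)
  dNna <- expectedNonadaptiveDivergence(scenario@params, scenario@LdivN,
                                        Sadv)
  (ex$expDN - dNna) / ex$expDN
}

#' Draw one replicate dataset from a scenario
#'
#' Each SFS class and each divergence count is Poisson with its model
#' expectation. With a positive mis-orientation rate, each sampled
#' non-divergence SNP is moved to the mirror class 2n - i with that
#' probability (binomial thinning between mirror classes), emulating
#' ancestral-state errors. Deterministic given (scenario, replicate,
#' seed).
#'
#' @param scenario a [SimScenario-class].
#' @param replicate replicate index (>= 1), part of the random stream.
#' @param seed integer base seed.
#' @return An unfolded [PolyDivData-class] labelled
#'   \code{sim_r<replicate>}.
#' @export
sampleDataset <- function(scenario, replicate = 1, seed = 1) {
  shape <- list(nChrom = scenario@nChrom, folded = FALSE,
                LN = scenario@LN, LS = scenario@LS,
                LdivN = scenario@LdivN, LdivS = scenario@LdivS)
  ex <- expectedData(scenario@params, shape)
  n2 <- scenario@nChrom
  .withSeed(seed + 104729L * (replicate - 1L), {
    PN <- rpois(n2 - 1L, ex$expPN)
    PS <- rpois(n2 - 1L, ex$expPS)
    DN <- rpois(1L, ex$expDN)
    DS <- rpois(1L, ex$expDS)
    mis <- scenario@misorientationRate
    if (mis > 0) {
      PN <- .misorient(PN, n2, mis)
      PS <- .misorient(PS, n2, mis)
    }
    PolyDivData(label = sprintf("sim_r%03d", replicate),
                sfsNonsyn = Spectrum(PN, n2), sfsSyn = Spectrum(PS, n2),
                DN = DN, DS = DS, LN = scenario@LN, LS = scenario@LS,
                LdivN = scenario@LdivN, LdivS = scenario@LdivS)
  })
}

# Move a binomial share of each class to its mirror class.
.misorient <- function(counts, nChrom, rate) {
  moved <- rbinom(length(counts), counts, rate)
  out <- counts - moved
  for (i in seq_along(counts)) {
    j <- nChrom - i
    out[j] <- out[j] + moved[i]
  }
  out
}

#' Draw all replicates of a scenario
#'
#' @param scenario a [SimScenario-class].
#' @param seed integer base seed.
#' @return List of [PolyDivData-class], length \code{nReplicates}.
#' @export
sampleReplicates <- function(scenario, seed = 1) {
  lapply(seq_len(scenario@nReplicates), function(r)
    sampleDataset(scenario, r, seed))
}
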