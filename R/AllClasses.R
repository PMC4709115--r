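# Central S4 classes: site frequency spectra, polymorphism/divergence
# datasets, DFE models, full parameter sets, fit results, simulation
# scenarios.

.DFE_FAMILIES <- c("neutral", "gamma", "gammaexpo", "scaledbeta", "displgamma")

.DFE_PARAM_NAMES <- list(
  neutral    = "f_neutral",
  gamma      = c("shape", "mean_del"),
  gammaexpo  = c("shape", "mean_del", "p_pos", "mean_adv"),
  scaledbeta = c("a", "b", "w_mild"),
  displgamma = c("shape", "mean_del", "displacement")
)

#' Site frequency spectrum
#'
#' An SFS is a vector of SNP counts indexed by allele frequency class:
#' classes 1..2n-1 of derived-allele counts for an unfolded spectrum, or
#' classes 1..n of minor/merged-allele counts for a folded spectrum, where
#' 2n is the number of sampled chromosomes. Counts may be fractional
#' because hypergeometric projection produces expected (real-valued)
#' counts.
#'
#' @slot counts numeric vector of non-negative class counts.
#' @slot nChrom integer, number of sampled chromosomes (2n, even).
#' @slot folded logical scalar.
#' @export
setClass("Spectrum",
  representation(counts = "numeric", nChrom = "integer", folded = "logical"))

setValidity("Spectrum", function(object) {
  n2 <- object@nChrom
  if (length(n2) != 1L || is.na(n2) || n2 < 2L || n2 %% 2L != 0L)
    return("nChrom must be a single positive even integer")
  if (length(object@folded) != 1L || is.na(object@folded))
    return("folded must be TRUE or FALSE")
  k <- if (object@folded) n2 %/% 2L else n2 - 1L
  if (length(object@counts) != k)
    return(sprintf("counts must have length %d (%s, nChrom = %d)", k,
                   if (object@folded) "folded" else "unfolded", n2))
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    return("counts must be finite and non-negative")
  TRUE
})

#' Construct a site frequency spectrum
#'
#' @param counts numeric vector of class counts (length 2n-1 unfolded,
#'   n folded).
#' @param nChrom number of sampled chromosomes (2n; positive even integer).
#' @param folded logical; is the spectrum folded?
#' @return A [Spectrum-class] object.
#' @examples
#' Spectrum(c(5, 2, 1), nChrom = 4)           # unfolded, 2n = 4
#' Spectrum(c(7, 1), nChrom = 4, folded = TRUE)
#' @export
Spectrum <- function(counts, nChrom, folded = FALSE) {
  new("Spectrum", counts = as.numeric(counts), nChrom = as.integer(nChrom),
      folded = folded)
}

#' @describeIn nChrom number of chromosomes of a spectrum
#' @export
setMethod("nChrom", "Spectrum", function(x) x@nChrom)

#' @describeIn isFolded folded flag of a spectrum
#' @export
setMethod("isFolded", "Spectrum", function(x) x@folded)

#' @describeIn sfsCounts class counts of a spectrum
#' @export
setMethod("sfsCounts", "Spectrum", function(x) x@counts)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("%s Spectrum: 2n = %d, %d classes, %.6g SNPs\n",
              if (object@folded) "folded" else "unfolded",
              object@nChrom, length(object@counts), sum(object@counts)))
  print(object@counts)
  invisible(NULL)
})

#' Polymorphism and divergence data for one species pair
#'
#' Holds the non-synonymous and synonymous SFS of the focal species, the
#' counts of fixed non-synonymous (\eqn{D_N}) and synonymous (\eqn{D_S})
#' differences to the outgroup, and the numbers of non-synonymous and
#' synonymous sites in the polymorphism (\eqn{L_N}, \eqn{L_S}) and
#' divergence (\eqn{L^{div}_N}, \eqn{L^{div}_S}) alignments.
#'
#' @slot label character, dataset identifier.
#' @slot sfsNonsyn,sfsSyn [Spectrum-class] objects sharing \code{nChrom}
#'   and \code{folded}.
#' @slot DN,DS non-negative numeric divergence counts.
#' @slot LN,LS positive numeric polymorphism site counts.
#' @slot LdivN,LdivS positive numeric divergence site counts.
#' @export
setClass("PolyDivData",
  representation(label = "character", sfsNonsyn = "Spectrum",
                 sfsSyn = "Spectrum", DN = "numeric", DS = "numeric",
                 LN = "numeric", LS = "numeric",
                 LdivN = "numeric", LdivS = "numeric"))

setValidity("PolyDivData", function(object) {
  if (object@sfsNonsyn@nChrom != object@sfsSyn@nChrom)
    return("non-synonymous and synonymous SFS must share nChrom")
  if (object@sfsNonsyn@folded != object@sfsSyn@folded)
    return("non-synonymous and synonymous SFS must share the folded flag")
  for (s in c("DN", "DS", "LN", "LS", "LdivN", "LdivS")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) return(sprintf("%s must be a finite scalar", s))
  }
  if (object@DN < 0 || object@DS < 0) return("divergence counts must be non-negative")
  if (object@LN <= 0 || object@LS <= 0 || object@LdivN <= 0 || object@LdivS <= 0)
    return("site counts must be positive")
  TRUE
})

#' Construct a polymorphism/divergence dataset
#'
#' @param label dataset identifier.
#' @param sfsNonsyn,sfsSyn non-synonymous and synonymous [Spectrum-class]
#'   objects (same \code{nChrom} and folded flag).
#' @param DN,DS counts of fixed non-synonymous / synonymous differences.
#' @param LN,LS numbers of non-synonymous / synonymous sites in the
#'   polymorphism data.
#' @param LdivN,LdivS numbers of sites in the divergence alignment;
#'   default to \code{LN} and \code{LS}.
#' @return A [PolyDivData-class] object.
#' @export
PolyDivData <- function(label, sfsNonsyn, sfsSyn, DN, DS, LN, LS,
                        LdivN = LN, LdivS = LS) {
  new("PolyDivData", label = as.character(label), sfsNonsyn = sfsNonsyn,
      sfsSyn = sfsSyn, DN = as.numeric(DN), DS = as.numeric(DS),
      LN = as.numeric(LN), LS = as.numeric(LS),
      LdivN = as.numeric(LdivN), LdivS = as.numeric(LdivS))
}

#' @describeIn nChrom number of chromosomes of a dataset
#' @export
setMethod("nChrom", "PolyDivData", function(x) x@sfsSyn@nChrom)

#' @describeIn isFolded folded flag of a dataset
#' @export
setMethod("isFolded", "PolyDivData", function(x) x@sfsSyn@folded)

setMethod("show", "PolyDivData", function(object) {
  cat(sprintf("PolyDivData '%s': 2n = %d (%s)\n", object@label,
              nChrom(object), if (isFolded(object)) "folded" else "unfolded"))
  cat(sprintf("  P_N = %.6g SNPs over L_N = %.6g sites\n",
              sum(object@sfsNonsyn@counts), object@LN))
  cat(sprintf("  P_S = %.6g SNPs over L_S = %.6g sites\n",
              sum(object@sfsSyn@counts), object@LS))
  cat(sprintf("  D_N = %.6g (Ldiv_N = %.6g), D_S = %.6g (Ldiv_S = %.6g)\n",
              object@DN, object@LdivN, object@DS, object@LdivS))
  invisible(NULL)
})

#' Distribution of fitness effects (DFE) model
#'
#' A parametric distribution over scaled selection coefficients
#' \eqn{S = 4 N_e s} of new non-synonymous mutations, possibly including
#' point masses (a neutral class at S = 0 and/or a strongly deleterious
#' class contributing neither polymorphism nor divergence). Families:
#' \describe{
#'   \item{neutral}{mass \code{f_neutral} at S = 0, the rest strongly
#'     deleterious.}
#'   \item{gamma}{\eqn{-S} Gamma-distributed with shape \code{shape} and
#'     mean \code{mean_del} (all mutations deleterious).}
#'   \item{gammaexpo}{mixture: with probability \code{1 - p_pos} the gamma
#'     family above; with probability \code{p_pos} advantageous, S
#'     exponential with mean \code{mean_adv}.}
#'   \item{scaledbeta}{weight \code{w_mild} on a Beta(\code{a}, \code{b})
#'     distribution linearly mapped to \eqn{[-S_{max}, S_{max}]}; the
#'     remaining mass strongly deleterious.}
#'   \item{displgamma}{\eqn{d - S} Gamma-distributed (shape, mean
#'     \code{mean_del}) so S ranges below the displacement
#'     \code{d = displacement}.}
#' }
#'
#' @slot family character, one of the five family names.
#' @slot params named numeric vector of family parameters.
#' @slot Smax numeric, half-range of the scaledbeta family (default 25).
#' @export
setClass("DFEModel",
  representation(family = "character", params = "numeric", Smax = "numeric"))

setValidity("DFEModel", function(object) {
  fam <- object@family
  if (length(fam) != 1L || !fam %in% .DFE_FAMILIES)
    return(sprintf("family must be one of: %s", paste(.DFE_FAMILIES, collapse = ", ")))
  want <- .DFE_PARAM_NAMES[[fam]]
  if (!identical(sort(names(object@params)), sort(want)))
    return(sprintf("params for '%s' must be named: %s", fam,
                   paste(want, collapse = ", ")))
  p <- object@params
  if (any(!is.finite(p))) return("params must be finite")
  bad <- switch(fam,
    neutral    = p[["f_neutral"]] < 0 || p[["f_neutral"]] > 1,
    gamma      = p[["shape"]] <= 0 || p[["mean_del"]] <= 0,
    gammaexpo  = p[["shape"]] <= 0 || p[["mean_del"]] <= 0 ||
                 p[["p_pos"]] < 0 || p[["p_pos"]] > 1 || p[["mean_adv"]] <= 0,
    scaledbeta = p[["a"]] <= 0 || p[["b"]] <= 0 ||
                 p[["w_mild"]] < 0 || p[["w_mild"]] > 1,
    displgamma = p[["shape"]] <= 0 || p[["mean_del"]] <= 0 ||
                 p[["displacement"]] < 0)
  if (bad) return(sprintf("invalid parameter values for family '%s'", fam))
  if (length(object@Smax) != 1L || !is.finite(object@Smax) || object@Smax <= 0)
    return("Smax must be a positive scalar")
  TRUE
})

#' Construct a DFE model
#'
#' @param family family name: \code{"neutral"}, \code{"gamma"},
#'   \code{"gammaexpo"}, \code{"scaledbeta"} or \code{"displgamma"}.
#' @param ... named family parameters (see [DFEModel-class]).
#' @param Smax half-range of the scaledbeta support; default 25.
#' @return A [DFEModel-class] object.
#' @examples
#' DFEModel("gamma", shape = 0.4, mean_del = 1000)
#' DFEModel("gammaexpo", shape = 0.4, mean_del = 1000,
#'          p_pos = 0.01, mean_adv = 10)
#' @export
DFEModel <- function(family, ..., Smax = 25) {
  params <- unlist(list(...))
  new("DFEModel", family = family, params = params, Smax = as.numeric(Smax))
}

#' @describeIn dfeFamily family of a DFE model
#' @export
setMethod("dfeFamily", "DFEModel", function(object) object@family)

#' @describeIn dfeParams parameters of a DFE model
#' @export
setMethod("dfeParams", "DFEModel", function(object) object@params)

setMethod("show", "DFEModel", function(object) {
  cat(sprintf("DFEModel '%s': %s\n", object@family,
              paste(sprintf("%s = %.4g", names(object@params), object@params),
                    collapse = ", ")))
  if (object@family == "scaledbeta")
    cat(sprintf("  Smax = %g\n", object@Smax))
  invisible(NULL)
})

#' Full parameter set of the polymorphism/divergence likelihood
#'
#' Bundles the population-scaled mutation rate \eqn{\theta = 4 N_e \mu}
#' per site, the per-frequency-class nuisance multipliers \eqn{r_i}
#' (\eqn{r_1 = 1}), the scaled divergence time \eqn{T = \mu t}, the
#' divergence excess \eqn{A} (count-scale contribution of strongly
#' advantageous substitutions) and a [DFEModel-class].
#'
#' @slot theta positive numeric.
#' @slot r positive numeric vector, one entry per SFS class, \code{r[1] = 1}.
#' @slot Tdiv positive numeric.
#' @slot A non-negative numeric.
#' @slot dfe a [DFEModel-class].
#' @export
setClass("ModelParams",
  representation(theta = "numeric", r = "numeric", Tdiv = "numeric",
                 A = "numeric", dfe = "DFEModel"))

setValidity("ModelParams", function(object) {
  if (length(object@theta) != 1L || !is.finite(object@theta) || object@theta <= 0)
    return("theta must be a positive scalar")
  if (length(object@r) < 1L || any(!is.finite(object@r)) || any(object@r <= 0))
    return("r must be a vector of positive values")
  if (object@r[1] != 1) return("r[1] must equal 1 exactly")
  if (length(object@Tdiv) != 1L || !is.finite(object@Tdiv) || object@Tdiv <= 0)
    return("Tdiv must be a positive scalar")
  if (length(object@A) != 1L || !is.finite(object@A) || object@A < 0)
    return("A must be a non-negative scalar")
  TRUE
})

#' Construct a model parameter set
#'
#' @param theta population-scaled mutation rate per site (\eqn{4 N_e \mu}).
#' @param r per-frequency-class nuisance multipliers; \code{r[1]} must be 1.
#'   Length 2n-1 for unfolded data, n for folded data.
#' @param Tdiv scaled divergence time (\eqn{\mu t}).
#' @param dfe a [DFEModel-class].
#' @param A divergence count excess from strongly advantageous
#'   substitutions (default 0).
#' @return A [ModelParams-class] object.
#' @export
ModelParams <- function(theta, r, Tdiv, dfe, A = 0) {
  new("ModelParams", theta = as.numeric(theta), r = as.numeric(r),
      Tdiv = as.numeric(Tdiv), A = as.numeric(A), dfe = dfe)
}

setMethod("show", "ModelParams", function(object) {
  cat(sprintf("ModelParams: theta = %.4g, T = %.4g, A = %.4g, %d r-classes\n",
              object@theta, object@Tdiv, object@A, length(object@r)))
  show(object@dfe)
  invisible(NULL)
})

#' Result of a maximum-likelihood fit
#'
#' @slot params the fitted [ModelParams-class].
#' @slot loglik maximized Poisson log-likelihood.
#' @slot aic Akaike information criterion, \code{2 nFree - 2 loglik}.
#' @slot nFree integer, number of free parameters.
#' @slot converged logical.
#' @slot nRestartsUsed integer, number of optimization starts run.
#' @slot variant \code{"standard"} (A free) or \code{"minus_A"} (A pinned
#'   to zero).
#' @slot label dataset label the fit refers to.
#' @export
setClass("FitResult",
  representation(params = "ModelParams", loglik = "numeric", aic = "numeric",
                 nFree = "integer", converged = "logical",
                 nRestartsUsed = "integer", variant = "character",
                 label = "character"))

setValidity("FitResult", function(object) {
  if (!object@variant %in% c("standard", "minus_A"))
    return("variant must be 'standard' or 'minus_A'")
  if (abs(object@aic - (2 * object@nFree - 2 * object@loglik)) > 1e-6)
    return("aic must equal 2*nFree - 2*loglik")
  TRUE
})

#' @describeIn nFreeParams free-parameter count of a fit
#' @export
setMethod("nFreeParams", "FitResult", function(object) object@nFree)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s, %s]: loglik = %.4f, AIC = %.4f, k = %d%s\n",
              dfeFamily(object@params@dfe), object@variant, object@loglik,
              object@aic, object@nFree,
              if (object@converged) "" else " (NOT converged)"))
  show(object@params)
  invisible(NULL)
})

#' Adaptive substitution rate estimate
#'
#' Holds \eqn{\omega_{na}} (non-adaptive non-synonymous rate relative to
#' neutral), \eqn{\omega_a = d_N/d_S - \omega_{na}} and
#' \eqn{\alpha = \omega_a / (d_N/d_S)}, together with the threshold
#' \eqn{S_{adv}} below which substitutions are counted as non-adaptive.
#'
#' @slot omegaNa,omegaA,alpha,dnds numeric scalars.
#' @slot Sadv numeric threshold (default 5).
#' @slot ciAlpha numeric length-2 vector (may be \code{NA}).
#' @slot note character; non-empty when alpha is undefined or clipped.
#' @export
setClass("AdaptiveRateEstimate",
  representation(omegaNa = "numeric", omegaA = "numeric", alpha = "numeric",
                 dnds = "numeric", Sadv = "numeric", ciAlpha = "numeric",
                 note = "character"))

setMethod("show", "AdaptiveRateEstimate", function(object) {
  cat(sprintf(
    "AdaptiveRateEstimate (S_adv = %g):\n  dN/dS = %.4g, omega_na = %.4g, omega_a = %.4g, alpha = %.4g\n",
    object@Sadv, object@dnds, object@omegaNa, object@omegaA, object@alpha))
  if (!all(is.na(object@ciAlpha)))
    cat(sprintf("  alpha CI: [%.4g, %.4g]\n", object@ciAlpha[1], object@ciAlpha[2]))
  if (length(object@note) && nzchar(object@note))
    cat("  note:", object@note, "\n")
  invisible(NULL)
})

#' Simulation scenario
#'
#' Defines the generating model and sampling frame for the Poisson
#' simulator: every SFS class and divergence count is drawn Poisson around
#' its model expectation, optionally followed by mis-orientation of a
#' fraction of SNPs (moved to the mirror frequency class).
#'
#' @slot params generating [ModelParams-class] (unfolded r vector).
#' @slot nChrom integer, 2n.
#' @slot LN,LS,LdivN,LdivS positive numeric site counts.
#' @slot misorientationRate numeric in [0, 1).
#' @slot nReplicates positive integer.
#' @export
setClass("SimScenario",
  representation(params = "ModelParams", nChrom = "integer", LN = "numeric",
                 LS = "numeric", LdivN = "numeric", LdivS = "numeric",
                 misorientationRate = "numeric", nReplicates = "integer"))

setValidity("SimScenario", function(object) {
  if (object@nChrom < 2L || object@nChrom %% 2L != 0L)
    return("nChrom must be a positive even integer")
  if (length(object@params@r) != object@nChrom - 1L)
    return("params@r must have length nChrom - 1 (unfolded)")
  if (object@misorientationRate < 0 || object@misorientationRate >= 1)
    return("misorientationRate must lie in [0, 1)")
  if (any(c(object@LN, object@LS, object@LdivN, object@LdivS) <= 0))
    return("site counts must be positive")
  if (object@nReplicates < 1L) return("nReplicates must be >= 1")
  TRUE
})

#' Construct a simulation scenario
#'
#' @param params generating [ModelParams-class]; its \code{r} vector must
#'   have length \code{nChrom - 1}.
#' @param nChrom number of sampled chromosomes (2n).
#' @param LN,LS polymorphism site counts.
#' @param LdivN,LdivS divergence site counts (default: same as LN, LS).
#' @param misorientationRate probability that a sampled SNP is assigned to
#'   the mirror frequency class (ancestral state error); default 0.
#' @param nReplicates number of replicate datasets; default 1.
#' @return A [SimScenario-class] object.
#' @export
SimScenario <- function(params, nChrom, LN, LS, LdivN = LN, LdivS = LS,
                        misorientationRate = 0, nReplicates = 1) {
  new("SimScenario", params = params, nChrom = as.integer(nChrom),
      LN = as.numeric(LN), LS = as.numeric(LS), LdivN = as.numeric(LdivN),
      LdivS = as.numeric(LdivS),
      misorientationRate = as.numeric(misorientationRate),
      nReplicates = as.integer(nReplicates))
}

setMethod("show", "SimScenario", function(object) {
  cat(sprintf(
    "SimScenario: 2n = %d, L_N = %.3g, L_S = %.3g, misorientation = %g, %d replicate(s)\n",
    object@nChrom, object@LN, object@LS, object@misorientationRate,
    object@nReplicates))
  show(object@params)
  invisible(NULL)
})
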