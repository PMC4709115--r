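#' @import methods
#' @importFrom stats dbinom dhyper dgamma dexp dbeta qgamma qexp qbeta
#'   pgamma pexp pbeta plogis qlogis optim rpois rbinom runif rnorm
#'   pchisq cor.test lm coef setNames splinefun
#' @importFrom utils write.table read.delim
NULL

#' Number of sampled chromosomes
#'
#' Accessor for the number of chromosomes (2n, twice the number of diploid
#' individuals) underlying a site frequency spectrum or dataset.
#'
#' @param x a \code{Spectrum} or \code{PolyDivData} object.
#' @return A positive even integer.
#' @export
setGeneric("nChrom", function(x) standardGeneric("nChrom"))

#' Folded status of a spectrum
#'
#' @param x a \code{Spectrum} or \code{PolyDivData} object.
#' @return \code{TRUE} if the SFS is folded (mirror frequency classes
#'   merged), \code{FALSE} if it is unfolded (derived-allele classes).
#' @export
setGeneric("isFolded", function(x) standardGeneric("isFolded"))

#' SFS class counts
#'
#' @param x a \code{Spectrum} object.
#' @return Numeric vector of per-frequency-class SNP counts. Counts may be
#'   fractional after hypergeometric projection.
#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))

#' DFE family name
#'
#' @param object a \code{DFEModel}.
#' @return Character scalar: one of \code{"neutral"}, \code{"gamma"},
#'   \code{"gammaexpo"}, \code{"scaledbeta"}, \code{"displgamma"}.
#' @export
setGeneric("dfeFamily", function(object) standardGeneric("dfeFamily"))

#' DFE parameter vector
#'
#' @param object a \code{DFEModel}.
#' @return Named numeric vector of family parameters.
#' @export
setGeneric("dfeParams", function(object) standardGeneric("dfeParams"))

#' Continuous DFE density
#'
#' Density of the continuous part of the distribution of fitness effects at
#' scaled selection coefficient \code{S = 4 Ne s}. Point masses (the neutral
#' and strongly deleterious classes of some families) are reported
#' separately by [pointMasses()].
#'
#' @param object a \code{DFEModel}.
#' @param S numeric vector of scaled selection coefficients.
#' @return Numeric vector of densities, same length as \code{S}.
#' @export
setGeneric("dfeDensity", function(object, S) standardGeneric("dfeDensity"))

#' DFE point masses
#'
#' @param object a \code{DFEModel}.
#' @return A data.frame with columns \code{S} (numeric location, \code{NA}
#'   for the strongly deleterious "lethal" class) and \code{mass}. Zero-row
#'   data.frame for purely continuous families.
#' @export
setGeneric("pointMasses", function(object) standardGeneric("pointMasses"))

#' Number of free DFE parameters
#'
#' Used for AIC and likelihood-ratio-test degrees of freedom.
#'
#' @param object a \code{DFEModel} or \code{FitResult}.
#' @return Integer count of free parameters.
#' @export
setGeneric("nFreeParams", function(object) standardGeneric("nFreeParams"))
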