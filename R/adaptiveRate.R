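# Convert a fitted model into omega_na, omega_a and alpha.
#
# The estimators deliberately mix fitted expectations with observed
# counts: the expected non-adaptive divergence D_Nna comes from the model,
# while d_N and d_S in the ratios are observed. alpha < 0 is possible and
# is reported as such.

#' Expected non-adaptive non-synonymous divergence
#'
#' \eqn{\hat D_N^{na} = L^{div}_N \, T \, [\sum_{S_m < S_{adv}} mass_m
#' F(S_m) + \int_{-\infty}^{S_{adv}} \Phi(S) F(S) dS]}: the expected count
#' of non-synonymous substitutions whose scaled selection coefficient lies
#' below the threshold \code{Sadv}. The divergence excess A and DFE mass
#' at or above the threshold are excluded; strongly deleterious point
#' masses contribute nothing.
#'
#' @param params a fitted [ModelParams-class].
#' @param LdivN non-synonymous divergence site count.
#' @param Sadv threshold scaled selection coefficient (default 5).
#' @param sNodes quadrature node count for the truncated DFE integral.
#' @return Non-negative expected count.
#' @export
expectedNonadaptiveDivergence <- function(params, LdivN, Sadv = 5,
                                          sNodes = 64L) {
  LdivN * params@Tdiv * .dfeDivIntegral(params@dfe, sNodes, Sadv = Sadv)
}

#' Adaptive and non-adaptive substitution rates from a fit
#'
#' Computes \eqn{\omega_{na} = (\hat D_N^{na}/L^{div}_N)/(D_S/L^{div}_S)}
#' using the observed synonymous divergence, then
#' \eqn{\omega_a = (d_N - \hat d_N^{na})/d_S} and
#' \eqn{\alpha = (d_N - \hat d_N^{na})/d_N} with observed \eqn{d_N, d_S}.
#' By construction \eqn{\omega_a = d_N/d_S - \omega_{na}} and
#' \eqn{\alpha = \omega_a/(d_N/d_S)} hold exactly. A negative alpha
#' (observed divergence below the nearly-neutral expectation) is reported,
#' not clipped; alpha is \code{NA} with a note when \eqn{D_N = 0}.
#'
#' @param dataset the [PolyDivData-class] the model was fitted to
#'   (\code{DS > 0} required).
#' @param params the fitted [ModelParams-class] (e.g. from a
#'   [FitResult-class] \code{@params} slot).
#' @param Sadv non-adaptive threshold (default 5).
#' @param ciAlpha optional length-2 numeric from [profileCIAlpha()].
#' @param sNodes quadrature node count.
#' @return An [AdaptiveRateEstimate-class].
#' @export
adaptiveRates <- function(dataset, params, Sadv = 5, ciAlpha = c(NA, NA),
                          sNodes = 64L) {
  if (dataset@DS <= 0) stop("D_S must be positive to compute rates")
  dN <- dataset@DN / dataset@LdivN
  dS <- dataset@DS / dataset@LdivS
  dNna <- expectedNonadaptiveDivergence(params, dataset@LdivN, Sadv,
                                        sNodes) / dataset@LdivN
  omegaNa <- dNna / dS
  dnds <- dN / dS
  omegaA <- dnds - omegaNa
  note <- ""
  if (dataset@DN <= 0) {
    alpha <- NA_real_
    note <- "alpha undefined: D_N = 0"
  } else {
    alpha <- omegaA / dnds
  }
  new("AdaptiveRateEstimate", omegaNa = omegaNa, omegaA = omegaA,
      alpha = alpha, dnds = dnds, Sadv = Sadv,
      ciAlpha = as.numeric(ciAlpha), note = note)
}

#' One-row per-dataset results summary
#'
#' The tab-separated report row written by the command-line interface:
#' label, model, variant, fit statistics, key parameter estimates and the
#' adaptive-rate quantities.
#'
#' @param dataset a [PolyDivData-class].
#' @param fit the corresponding [FitResult-class].
#' @param rates an [AdaptiveRateEstimate-class] (computed from the fit if
#'   omitted).
#' @param Sadv threshold used when \code{rates} must be computed.
#' @return A one-row data.frame.
#' @export
resultsRow <- function(dataset, fit, rates = NULL, Sadv = 5) {
  if (is.null(rates)) rates <- adaptiveRates(dataset, fit@params, Sadv)
  p <- fit@params@dfe@params
  data.frame(
    label = dataset@label,
    model = dfeFamily(fit@params@dfe),
    variant = fit@variant,
    loglik = fit@loglik,
    aic = fit@aic,
    converged = fit@converged,
    theta = fit@params@theta,
    T = fit@params@Tdiv,
    A = fit@params@A,
    shape = if ("shape" %in% names(p)) p[["shape"]] else NA_real_,
    p_pos = if ("p_pos" %in% names(p)) p[["p_pos"]] else NA_real_,
    dnds = rates@dnds,
    omega_na = rates@omegaNa,
    omega_a = rates@omegaA,
    alpha = rates@alpha,
    alpha_low = rates@ciAlpha[1],
    alpha_high = rates@ciAlpha[2],
    stringsAsFactors = FALSE)
}
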