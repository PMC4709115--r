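# DFE families: continuous densities over S = 4*Ne*s, point masses,
# free-parameter counts. The Gamma branches are parametrized by (shape,
# mean), not (shape, scale).

#' @describeIn dfeDensity density of the continuous DFE part
#' @export
setMethod("dfeDensity", "DFEModel", function(object, S) {
  p <- object@params
  fam <- object@family
  d <- numeric(length(S))
  if (fam == "neutral") {
    # purely discrete: neutral mass at 0 + strongly deleterious class
  } else if (fam == "gamma") {
    neg <- S < 0
    d[neg] <- dgamma(-S[neg], shape = p[["shape"]],
                     scale = p[["mean_del"]] / p[["shape"]])
  } else if (fam == "gammaexpo") {
    neg <- S < 0
    pos <- S > 0
    d[neg] <- (1 - p[["p_pos"]]) * dgamma(-S[neg], shape = p[["shape"]],
                                          scale = p[["mean_del"]] / p[["shape"]])
    d[pos] <- p[["p_pos"]] * dexp(S[pos], rate = 1 / p[["mean_adv"]])
  } else if (fam == "scaledbeta") {
    Smax <- object@Smax
    inside <- S >= -Smax & S <= Smax
    d[inside] <- p[["w_mild"]] *
      dbeta(S[inside] / (2 * Smax) + 0.5, p[["a"]], p[["b"]]) / (2 * Smax)
  } else if (fam == "displgamma") {
    below <- S < p[["displacement"]]
    d[below] <- dgamma(p[["displacement"]] - S[below], shape = p[["shape"]],
                       scale = p[["mean_del"]] / p[["shape"]])
  }
  d
})

#' @describeIn pointMasses point masses of a DFE model
#' @export
setMethod("pointMasses", "DFEModel", function(object) {
  p <- object@params
  switch(object@family,
    neutral = data.frame(S = c(0, NA), mass = c(p[["f_neutral"]],
                                                1 - p[["f_neutral"]])),
    scaledbeta = data.frame(S = NA_real_, mass = 1 - p[["w_mild"]]),
    data.frame(S = numeric(), mass = numeric()))
})

#' @describeIn nFreeParams free-parameter count of a DFE family
#' @export
setMethod("nFreeParams", "DFEModel", function(object) {
  length(.DFE_PARAM_NAMES[[object@family]])
})
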