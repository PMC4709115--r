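# Expected SFS and divergence under a DFE, and the Poisson log-likelihood.
#
# Scaling conventions: S = 4*Ne*s is advantageous when positive. The
# sojourn density H(S, x) is the standard diffusion form with neutral
# limit 2/x, so the segregation factor G(S, i, n) = int H q dx equals 2/i
# at S = 0 exactly and the fully neutral expected SFS is theta*L/i.

# Gauss-Legendre nodes/weights on (0, 1), computed once per node count
# via the Golub-Welsch eigenvalue method and cached.
.quadCache <- new.env(parent = emptyenv())

.glNodes <- function(n) {
  key <- paste0("gl", n)
  got <- .quadCache[[key]]
  if (!is.null(got)) return(got)
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- (e$values + 1) / 2                 # map [-1,1] -> [0,1]
  w <- as.numeric(e$vectors[1L, ])^2      # weights sum to 2, halved by map
  ord <- order(x)
  out <- list(x = x[ord], w = w[ord])
  .quadCache[[key]] <- out
  out
}

# Per-(2n, xNodes) kernel: frequency nodes, weights, and the binomial
# sampling matrix Q[i, k] = C(2n,i) x_k^i (1-x_k)^(2n-i), i = 1..2n-1.
.sfsKernel <- function(nChrom, xNodes = 256L) {
  key <- paste0("k", nChrom, "_", xNodes)
  got <- .quadCache[[key]]
  if (!is.null(got)) return(got)
  gl <- .glNodes(xNodes)
  i <- seq_len(nChrom - 1L)
  Q <- outer(i, gl$x, function(ii, xx) dbinom(ii, nChrom, xx))
  out <- list(nChrom = as.integer(nChrom), x = gl$x, w = gl$w, Q = Q)
  .quadCache[[key]] <- out
  out
}

# H(S, x) for a vector of S and a vector of x: nS x nx matrix. Branches
# guard against overflow at |S| > 650 and take the analytic S -> 0 limit.
.sojournMatrix <- function(S, x) {
  nS <- length(S)
  nx <- length(x)
  out <- matrix(0, nS, nx)
  x1 <- x * (1 - x)
  for (b in seq_len(nS)) {
    s <- S[b]
    out[b, ] <-
      if (s == 0) 2 / x
      else if (s < -650) 2 * exp(s * x) / x1
      else if (s > 650) -2 * expm1(-s * (1 - x)) / x1
      else 2 * expm1(-s * (1 - x)) / (x1 * expm1(-s))
  }
  out
}

#' Relative sojourn-time density of a selected mutation
#'
#' H(S, x) = 2 (1 - exp(-S (1 - x))) / (x (1 - x) (1 - exp(-S))): the
#' diffusion expectation of the time a new semidominant mutation of scaled
#' selection coefficient S = 4 Ne s spends at population frequency x,
#' relative to the scaling in which the neutral case gives 2/x. S > 0 is
#' advantageous. At S = 0 the analytic limit 2/x is returned.
#'
#' @param S scaled selection coefficient (finite scalar).
#' @param x population allele frequency, in (0, 1); may be a vector.
#' @return Positive numeric vector, same length as \code{x}.
#' @examples
#' sojournDensity(0, 0.5)   # 4
#' sojournDensity(0, 0.1)   # 20
#' @export
sojournDensity <- function(S, x) {
  stopifnot(length(S) == 1L, is.finite(S))
  if (any(x <= 0 | x >= 1)) stop("x must lie strictly in (0, 1)")
  as.numeric(.sojournMatrix(S, x))
}

#' Binomial sampling probability
#'
#' Probability that an allele at population frequency x is observed i
#' times in a sample of \code{nChrom} chromosomes.
#'
#' @param i observed derived-allele count (0..nChrom).
#' @param nChrom sample size in chromosomes (2n).
#' @param x population frequency in [0, 1]; may be a vector.
#' @return Numeric vector of probabilities.
#' @export
samplingProb <- function(i, nChrom, x) dbinom(i, nChrom, x)

#' Segregation factor G(S, i, n)
#'
#' Expected contribution of a mutation of scaled selection coefficient S
#' to SFS class i in a sample of \code{nChrom} chromosomes:
#' \eqn{G(S,i,n) = \int_0^1 H(S,x) \, q(i,n,x) \, dx}, computed by
#' Gauss-Legendre quadrature. G(0, i, n) = 2/i.
#'
#' @param S scaled selection coefficient(s); vectorized.
#' @param i SFS class, 1 <= i <= nChrom - 1 (scalar).
#' @param nChrom sample size in chromosomes.
#' @param xNodes number of quadrature nodes on (0, 1); default 256.
#' @return Positive numeric vector, one value per element of \code{S}.
#' @examples
#' segFactor(1e-10, 2, 8)   # ~ 2/2 = 1
#' @export
segFactor <- function(S, i, nChrom, xNodes = 256L) {
  i <- as.integer(i)
  nChrom <- as.integer(nChrom)
  if (i < 1L || i > nChrom - 1L) stop("i must lie in 1..nChrom-1")
  kern <- .sfsKernel(nChrom, xNodes)
  H <- .sojournMatrix(S, kern$x)
  g <- as.numeric(H %*% (kern$w * kern$Q[i, ]))
  if (any(!is.finite(g)))
    stop(sprintf("quadrature failure in segFactor (S in [%g, %g], i = %d, 2n = %d, %d nodes)",
                 min(S), max(S), i, nChrom, xNodes))
  g
}

#' Scaled fixation factor F(S)
#'
#' F(S) = S / (1 - exp(-S)): the fixation probability of a semidominant
#' mutation of scaled selection coefficient S relative to a neutral one
#' (2 Ne times the diffusion fixation probability). F(0) = 1 by
#' continuity; F(S) - F(-S) = S for all S.
#'
#' @param S scaled selection coefficient(s); vectorized.
#' @return Positive numeric vector.
#' @examples
#' fixationFactor(0)  # 1
#' fixationFactor(2)  # 2 / (1 - exp(-2))
#' @export
fixationFactor <- function(S) {
  out <- numeric(length(S))
  zero <- S == 0
  lo <- S < -650
  hi <- S > 650
  mid <- !zero & !lo & !hi
  out[zero] <- 1
  out[lo] <- -S[lo] * exp(S[lo])
  out[hi] <- S[hi]
  out[mid] <- S[mid] / (-expm1(-S[mid]))
  out
}

# --- DFE quadrature ----------------------------------------------------
#
# Each continuous DFE branch is integrated through its own quantile
# function: int f(S) Phi(S) dS = weight * int_0^1 f(S(u)) du, with S(u)
# the branch quantile at probability u, evaluated at Gauss-Legendre
# u-nodes. Truncation at S < Sadv restricts the u-interval through the
# branch CDF (branches are monotone in u).

# Point masses as a plain list (no data.frame overhead): hot path of the
# likelihood. `S = NA` marks the strongly deleterious class.
.pointMassList <- function(dfe) {
  p <- dfe@params
  switch(dfe@family,
    neutral = list(S = c(0, NA), mass = c(p[["f_neutral"]],
                                          1 - p[["f_neutral"]])),
    scaledbeta = list(S = NA_real_, mass = 1 - p[["w_mild"]]),
    list(S = numeric(), mass = numeric()))
}

# list of branches: weight, quant(u); uBelow(Sadv) gives the u-interval
# on which S(u) < Sadv.
.dfeBranches <- function(dfe) {
  p <- dfe@params
  fam <- dfe@family
  if (fam == "neutral") return(list())
  if (fam %in% c("gamma", "gammaexpo")) {
    sc <- p[["mean_del"]] / p[["shape"]]
    neg <- list(weight = if (fam == "gamma") 1 else 1 - p[["p_pos"]],
                quant = function(u) -qgamma(u, shape = p[["shape"]], scale = sc),
                uBelow = function(Sadv) {
                  if (Sadv >= 0) c(0, 1)
                  else c(pgamma(-Sadv, shape = p[["shape"]], scale = sc), 1)
                })
    if (fam == "gamma") return(list(neg))
    pos <- list(weight = p[["p_pos"]],
                quant = function(u) qexp(u, rate = 1 / p[["mean_adv"]]),
                uBelow = function(Sadv) {
                  if (Sadv <= 0) c(0, 0)
                  else c(0, pexp(Sadv, rate = 1 / p[["mean_adv"]]))
                })
    return(list(neg, pos))
  }
  if (fam == "scaledbeta") {
    Smax <- dfe@Smax
    return(list(list(weight = p[["w_mild"]],
                     quant = function(u) 2 * Smax * (qbeta(u, p[["a"]], p[["b"]]) - 0.5),
                     uBelow = function(Sadv) {
                       c(0, pbeta(min(max(Sadv / (2 * Smax) + 0.5, 0), 1),
                                  p[["a"]], p[["b"]]))
                     })))
  }
  # displgamma: S = d - X, X ~ Gamma, S decreasing in u
  sc <- p[["mean_del"]] / p[["shape"]]
  d0 <- p[["displacement"]]
  list(list(weight = 1,
            quant = function(u) d0 - qgamma(u, shape = p[["shape"]], scale = sc),
            uBelow = function(Sadv) {
              if (Sadv >= d0) c(0, 1)
              else c(pgamma(d0 - Sadv, shape = p[["shape"]], scale = sc), 1)
            }))
}

# Integrate f over the continuous DFE (optionally truncated to S < Sadv):
# f takes a vector of S and returns a vector (scalar integrand) or a
# matrix with one column per SFS class. Point masses are NOT included.
.dfeIntegrate <- function(dfe, f, sNodes = 64L, Sadv = NULL) {
  gl <- .glNodes(sNodes)
  total <- NULL
  for (b in .dfeBranches(dfe)) {
    if (b$weight == 0) next
    iv <- if (is.null(Sadv)) c(0, 1) else b$uBelow(Sadv)
    len <- iv[2] - iv[1]
    if (len <= 0) next
    u <- iv[1] + gl$x * len
    S <- b$quant(u)
    val <- f(S)
    wt <- b$weight * len * gl$w
    piece <- if (is.matrix(val)) colSums(wt * val) else sum(wt * val)
    total <- if (is.null(total)) piece else total + piece
  }
  if (is.null(total)) 0 else total
}

# Spline interpolator of G(S, i, n) over S, one set of splines per
# (2n, xNodes): exact quadrature on a dense fixed S-grid once, then fast
# monotone-cubic evaluation in log|S| at arbitrary S. Used inside the
# likelihood optimizer; expectation accessors use exact quadrature.
.segInterp <- function(nChrom, xNodes = 256L) {
  key <- paste0("gi", nChrom, "_", xNodes)
  got <- .quadCache[[key]]
  if (!is.null(got)) return(got)
  kern <- .sfsKernel(nChrom, xNodes)
  Qw <- t(kern$w * t(kern$Q))
  lneg <- seq(log(1e-6), log(1e10), length.out = 220)
  lpos <- seq(log(1e-6), log(1e5), length.out = 160)
  Gneg <- .sojournMatrix(-exp(lneg), kern$x) %*% t(Qw)   # decreasing in |S|
  Gpos <- .sojournMatrix(exp(lpos), kern$x) %*% t(Qw)    # increasing in S
  i <- seq_len(nChrom - 1L)
  negSp <- lapply(i, function(k) splinefun(lneg, log(Gneg[, k]),
                                           method = "monoH.FC"))
  posSp <- lapply(i, function(k) splinefun(lpos, Gpos[, k],
                                           method = "monoH.FC"))
  g0 <- 2 / i
  fn <- function(S) {
    out <- matrix(0, length(S), nChrom - 1L)
    l <- log(pmax(abs(S), 1e-6))
    tiny <- abs(S) < 1e-6
    neg <- S < 0 & !tiny
    pos <- S > 0 & !tiny
    if (any(tiny)) out[tiny, ] <- rep(g0, each = sum(tiny))
    ln <- pmin(l[neg], log(1e10))
    lp <- pmin(l[pos], log(1e5))
    for (k in i) {
      if (any(neg)) out[neg, k] <- exp(negSp[[k]](ln))
      if (any(pos)) out[pos, k] <- posSp[[k]](lp)
    }
    out
  }
  .quadCache[[key]] <- fn
  fn
}

# Per-class polymorphism integrals Psi_i = sum_masses mass*G(S0,i) +
# int Phi(S) G(S,i,n) dS over unfolded classes i = 1..2n-1. `gfun`
# switches the integrand to the spline interpolator (optimizer path).
.dfePolyIntegrals <- function(dfe, nChrom, xNodes = 256L, sNodes = 64L,
                              gfun = NULL) {
  if (is.null(gfun)) {
    kern <- .sfsKernel(nChrom, xNodes)
    Qw <- t(kern$w * t(kern$Q))
    gfun <- function(S) .sojournMatrix(S, kern$x) %*% t(Qw)
  }
  psi <- .dfeIntegrate(dfe, gfun, sNodes = sNodes)
  if (identical(psi, 0)) psi <- numeric(nChrom - 1L)
  pm <- .pointMassList(dfe)
  for (k in seq_along(pm$mass)) {
    if (is.na(pm$S[k])) next                    # strongly deleterious class
    psi <- psi + pm$mass[k] *
      if (pm$S[k] == 0) 2 / seq_len(nChrom - 1L)
      else vapply(seq_len(nChrom - 1L),
                  function(i) segFactor(pm$S[k], i, nChrom, xNodes), 0)
  }
  psi
}

# Divergence integral: sum_masses mass*F(S0) + int Phi(S) F(S) dS,
# optionally truncated to S < Sadv. Lethal masses contribute 0. The
# integrand is scalar and cheap, and F through the exponential quantile
# has a logarithmic endpoint: 4x the node budget costs nothing and
# restores fast convergence.
.dfeDivIntegral <- function(dfe, sNodes = 64L, Sadv = NULL) {
  val <- .dfeIntegrate(dfe, fixationFactor, sNodes = 4L * sNodes,
                       Sadv = Sadv)
  pm <- .pointMassList(dfe)
  for (k in seq_along(pm$mass)) {
    if (is.na(pm$S[k])) next
    if (is.null(Sadv) || pm$S[k] < Sadv)
      val <- val + pm$mass[k] * fixationFactor(pm$S[k])
  }
  val
}

# Shape of a dataset: what expectedData needs besides the parameters.
.dataShape <- function(x) {
  if (is(x, "PolyDivData"))
    list(nChrom = nChrom(x), folded = isFolded(x), LN = x@LN, LS = x@LS,
         LdivN = x@LdivN, LdivS = x@LdivS)
  else x
}

.foldVector <- function(u, nChrom) {
  n <- nChrom %/% 2L
  f <- numeric(n)
  for (k in seq_len(n - 1L)) f[k] <- u[k] + u[nChrom - k]
  f[n] <- u[n]
  f
}

#' Expected SFS and divergence under a fitted model
#'
#' Computes the model expectations of every data cell: synonymous SFS
#' class i has expectation \eqn{\theta L_S r_i / i}; non-synonymous class
#' i has expectation \eqn{(\theta/2) L_N r_i [\sum_m mass_m G(S_m,i,n) +
#' \int \Phi(S) G(S,i,n) dS]}; expected divergence counts are
#' \eqn{L^{div}_S T} and \eqn{L^{div}_N T [\sum_m mass_m F(S_m) + \int
#' \Phi(S) F(S) dS] + A}. Folded expectations are sums of the mirror
#' unfolded classes (the r multipliers then apply per folded class).
#'
#' @param params a [ModelParams-class]; \code{r} length must match the
#'   number of SFS classes of the target shape.
#' @param shape a [PolyDivData-class], or a list with elements
#'   \code{nChrom}, \code{folded}, \code{LN}, \code{LS}, \code{LdivN},
#'   \code{LdivS}.
#' @param xNodes,sNodes quadrature node counts for the frequency and
#'   selection-coefficient integrals.
#' @return List with elements \code{expPN}, \code{expPS} (numeric vectors)
#'   and \code{expDN}, \code{expDS} (scalars).
#' @examples
#' par <- ModelParams(theta = 0.01, r = rep(1, 7), Tdiv = 0.05,
#'                    dfe = DFEModel("neutral", f_neutral = 1))
#' shp <- list(nChrom = 8L, folded = FALSE, LN = 1000, LS = 1000,
#'             LdivN = 1000, LdivS = 1000)
#' expectedData(par, shp)$expPS   # 10/i
#' @export
expectedData <- function(params, shape, xNodes = 256L, sNodes = 64L) {
  shape <- .dataShape(shape)
  n2 <- shape$nChrom
  nclass <- if (shape$folded) n2 %/% 2L else n2 - 1L
  if (length(params@r) != nclass)
    stop(sprintf("r has length %d but the data have %d SFS classes",
                 length(params@r), nclass))
  iu <- seq_len(n2 - 1L)
  psU <- params@theta * shape$LS / iu
  psi <- .dfePolyIntegrals(params@dfe, n2, xNodes, sNodes)
  pnU <- (params@theta / 2) * shape$LN * psi
  if (shape$folded) {
    psU <- .foldVector(psU, n2)
    pnU <- .foldVector(pnU, n2)
  }
  Ifix <- .dfeDivIntegral(params@dfe, sNodes)
  list(expPN = pnU * params@r,
       expPS = psU * params@r,
       expDN = shape$LdivN * params@Tdiv * Ifix + params@A,
       expDS = shape$LdivS * params@Tdiv)
}

# Poisson log-density generalized to fractional observations through the
# log-Gamma function: -b + a log b - lgamma(a + 1), with 0 log 0 = 0.
.poisTerm <- function(a, b) {
  t <- -b - lgamma(a + 1)
  pos <- a > 0
  t[pos] <- t[pos] + a[pos] * log(b[pos])   # -Inf when b = 0, a > 0
  t
}

#' Poisson log-likelihood of a polymorphism/divergence dataset
#'
#' Sum over all data cells (every SFS class of both spectra, plus the two
#' divergence counts) of the Poisson log-density of the observed count at
#' the model expectation. Factorials are generalized through the
#' log-Gamma function so fractional (projected) counts are handled
#' smoothly. Returns \code{-Inf} when any cell has zero expectation but a
#' positive observed count.
#'
#' @param dataset a [PolyDivData-class].
#' @param params a [ModelParams-class] with matching \code{r} length.
#' @param xNodes,sNodes quadrature node counts.
#' @return Log-likelihood (numeric scalar).
#' @export
logLikelihood <- function(dataset, params, xNodes = 256L, sNodes = 64L) {
  ex <- expectedData(params, dataset, xNodes, sNodes)
  sum(.poisTerm(sfsCounts(dataset@sfsNonsyn), ex$expPN)) +
    sum(.poisTerm(sfsCounts(dataset@sfsSyn), ex$expPS)) +
    .poisTerm(dataset@DN, ex$expDN) +
    .poisTerm(dataset@DS, ex$expDS)
}
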