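# Maximum-likelihood fitting, model comparison, profile confidence
# intervals.
#
# Optimization runs in an unconstrained transformed space (log for theta,
# T, A and positive DFE parameters; logit for proportions; the Gamma shape
# is logit-mapped onto (0, 100), its allowed range). The nuisance
# multipliers r_2..r_k are profiled out analytically: conditional on the
# remaining parameters the Poisson score gives
#   r_i = (P_S[i] + P_N[i]) / (expPS_base[i] + expPN_base[i]),
# so the numeric optimizer only sees theta, T, A and the DFE parameters.

.BIG <- 1e12   # penalty for invalid/non-finite likelihood evaluations

.tf <- list(
  log   = list(fwd = log, bwd = exp),
  logit = list(fwd = qlogis, bwd = plogis),
  shape100 = list(fwd = function(x) qlogis(x / 100),
                  bwd = function(z) 100 * plogis(z))
)

.DFE_TRANSFORMS <- list(
  neutral    = c(f_neutral = "logit"),
  gamma      = c(shape = "shape100", mean_del = "log"),
  gammaexpo  = c(shape = "shape100", mean_del = "log", p_pos = "logit",
                 mean_adv = "log"),
  scaledbeta = c(a = "log", b = "log", w_mild = "logit"),
  displgamma = c(shape = "shape100", mean_del = "log", displacement = "log")
)

.packDFE <- function(dfe) {
  tr <- .DFE_TRANSFORMS[[dfe@family]]
  vapply(names(tr), function(nm) .tf[[tr[[nm]]]]$fwd(dfe@params[[nm]]), 0)
}

.unpackDFE <- function(z, family, Smax = 25) {
  tr <- .DFE_TRANSFORMS[[family]]
  p <- vapply(seq_along(tr), function(k) .tf[[tr[[k]]]]$bwd(z[k]), 0)
  names(p) <- names(tr)
  # keep strictly inside the validity domain
  eps <- 1e-12
  p[names(tr)[tr == "shape100"]] <- pmin(pmax(p[names(tr)[tr == "shape100"]], eps), 100 - eps)
  p[names(tr)[tr == "log"]] <- pmax(p[names(tr)[tr == "log"]], eps)
  new("DFEModel", family = family, params = p, Smax = Smax)
}

.packOuter <- function(theta, Tdiv, A, dfe, variant) {
  c(log(theta), log(Tdiv), if (variant == "standard") log(max(A, 1e-12)),
    .packDFE(dfe))
}

.unpackOuter <- function(v, family, variant, Smax = 25) {
  v <- unname(v)
  theta <- exp(v[1])
  Tdiv <- exp(v[2])
  if (variant == "standard") {
    A <- exp(v[3])
    z <- v[-(1:3)]
  } else {
    A <- 0
    z <- v[-(1:2)]
  }
  list(theta = theta, Tdiv = Tdiv, A = A, dfe = .unpackDFE(z, family, Smax))
}

# Observed-data summary reused across likelihood evaluations. The
# optimizer path evaluates G through the cached spline interpolator.
.fitContext <- function(dataset, xNodes, sNodes, interpolate = TRUE) {
  shape <- .dataShape(dataset)
  list(shape = shape,
       PN = sfsCounts(dataset@sfsNonsyn), PS = sfsCounts(dataset@sfsSyn),
       DN = dataset@DN, DS = dataset@DS,
       iu = seq_len(shape$nChrom - 1L),
       xNodes = xNodes, sNodes = sNodes,
       gfun = if (interpolate) .segInterp(shape$nChrom, xNodes))
}

# Expected per-class base counts (before the r multipliers) and the
# profiled r-hat, given natural-scale parameters.
.profileR <- function(ctx, theta, LNpsi) {
  bSu <- theta * ctx$shape$LS / ctx$iu
  bNu <- (theta / 2) * LNpsi
  if (ctx$shape$folded) {
    bSu <- .foldVector(bSu, ctx$shape$nChrom)
    bNu <- .foldVector(bNu, ctx$shape$nChrom)
  }
  tot_obs <- ctx$PN + ctx$PS
  tot_exp <- bNu + bSu
  r <- rep(1, length(tot_exp))
  idx <- seq_along(r)[-1]
  ok <- tot_exp[idx] > 0
  r[idx][ok] <- pmax(tot_obs[idx][ok] / tot_exp[idx][ok], 1e-12)
  list(bS = bSu, bN = bNu, r = r)
}

.profiledLoglik <- function(ctx, up) {
  psi <- .dfePolyIntegrals(up$dfe, ctx$shape$nChrom, ctx$xNodes, ctx$sNodes,
                           gfun = ctx$gfun)
  pr <- .profileR(ctx, up$theta, ctx$shape$LN * psi)
  Ifix <- .dfeDivIntegral(up$dfe, ctx$sNodes)
  expDN <- ctx$shape$LdivN * up$Tdiv * Ifix + up$A
  expDS <- ctx$shape$LdivS * up$Tdiv
  ll <- sum(.poisTerm(ctx$PN, pr$r * pr$bN)) +
    sum(.poisTerm(ctx$PS, pr$r * pr$bS)) +
    .poisTerm(ctx$DN, expDN) + .poisTerm(ctx$DS, expDS)
  list(ll = ll, r = pr$r)
}

.makeObjective <- function(ctx, family, variant, Smax = 25) {
  function(v) {
    out <- tryCatch(suppressWarnings({
      up <- .unpackOuter(v, family, variant, Smax)
      if (any(!is.finite(c(up$theta, up$Tdiv, up$A, up$dfe@params)))) return(.BIG)
      ll <- .profiledLoglik(ctx, up)$ll
      if (!is.finite(ll)) .BIG else -ll
    }), error = function(e) .BIG)
    out
  }
}

# Coarse DFE starting grids (natural scale), one list per family.
.initGrid <- function(family) {
  g <- function(...) {
    df <- expand.grid(..., KEEP.OUT.ATTRS = FALSE)
    lapply(seq_len(nrow(df)), function(k) unlist(df[k, , drop = FALSE]))
  }
  switch(family,
    neutral    = g(f_neutral = c(0.1, 0.3, 0.6, 0.9)),
    gamma      = g(shape = c(0.1, 0.3, 1), mean_del = c(10, 100, 1000, 1e4)),
    gammaexpo  = g(shape = c(0.1, 0.3, 1), mean_del = c(100, 1000, 1e4),
                   p_pos = c(0.002, 0.02), mean_adv = c(2, 10)),
    scaledbeta = g(a = c(0.2, 1, 2), b = c(0.5, 1, 3), w_mild = c(0.2, 0.8)),
    displgamma = g(shape = c(0.1, 0.3, 1), mean_del = c(10, 100, 1000, 1e4),
                   displacement = c(1e-4, 0.5)))
}

# Method-of-moments style initial scales for theta and T.
.momentInit <- function(ctx) {
  n2 <- ctx$shape$nChrom
  if (ctx$shape$folded) {
    denom <- 1 + 1 / (n2 - 1)
    theta0 <- ctx$PS[1] / (ctx$shape$LS * denom)
  } else {
    theta0 <- ctx$PS[1] / ctx$shape$LS
  }
  if (!is.finite(theta0) || theta0 <= 0)
    theta0 <- sum(ctx$PS) / (ctx$shape$LS * sum(1 / ctx$iu))
  theta0 <- max(theta0, 1e-8)
  T0 <- max(ctx$DS / ctx$shape$LdivS, 1e-8)
  list(theta = theta0, Tdiv = T0, A = max(1e-3 * ctx$DN, 1e-6))
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Fit a DFE model to polymorphism and divergence data by maximum
#' likelihood
#'
#' Maximizes the Poisson likelihood of the full dataset (both SFS and both
#' divergence counts) over theta, T, A (standard variant), the DFE
#' parameters of the chosen family, and the per-class nuisance multipliers
#' r (r\[1\] fixed at 1; profiled out analytically). Optimization is
#' multi-start quasi-Newton (BFGS) in unconstrained transformed space: the
#' first start combines method-of-moments initialization of theta and T
#' with the best point of a coarse DFE grid, the remaining starts are
#' seeded random perturbations of it. Deterministic given \code{seed}.
#'
#' @param dataset a [PolyDivData-class].
#' @param family DFE family name (see [DFEModel-class]).
#' @param variant \code{"standard"} (divergence excess A estimated) or
#'   \code{"minus_A"} (A pinned to 0; only meaningful for families with
#'   positive-effect mass: gammaexpo, scaledbeta).
#' @param restarts number of optimization starts (>= 1).
#' @param seed integer seed for the randomized restarts.
#' @param init optional list of additional starting points, each a list
#'   with elements \code{theta}, \code{Tdiv}, \code{A} and \code{dfe} (a
#'   [DFEModel-class]); useful for warm-starting nested models.
#' @param xNodes,sNodes quadrature node counts (see [expectedData()]).
#' @param maxit maximum BFGS iterations per start.
#' @param Smax scaledbeta half-range.
#' @return A [FitResult-class].
#' @examples
#' \donttest{
#' truth <- ModelParams(theta = 0.01, r = rep(1, 7), Tdiv = 0.05,
#'                      dfe = DFEModel("neutral", f_neutral = 0.4))
#' sc <- SimScenario(truth, nChrom = 8, LN = 1e5, LS = 1e5)
#' d <- sampleDataset(sc, 1, seed = 1)
#' fitModel(d, "neutral", restarts = 2)
#' }
#' @export
fitModel <- function(dataset, family, variant = c("standard", "minus_A"),
                     restarts = 5, seed = 1, init = NULL,
                     xNodes = 256L, sNodes = 64L, maxit = 400, Smax = 25) {
  variant <- match.arg(variant)
  family <- match.arg(family, .DFE_FAMILIES)
  if (variant == "minus_A" && !family %in% c("gammaexpo", "scaledbeta"))
    stop("the minus_A variant requires a DFE family with positive-effect mass ",
         "(gammaexpo or scaledbeta)")
  nclass <- length(sfsCounts(dataset@sfsSyn))
  if (nclass < 2L) stop("at least 2 SFS classes are required")
  ctx <- .fitContext(dataset, xNodes, sNodes)
  obj <- .makeObjective(ctx, family, variant, Smax)
  mom <- .momentInit(ctx)

  # best coarse-grid DFE start
  gridStarts <- lapply(.initGrid(family), function(p)
    .packOuter(mom$theta, mom$Tdiv, mom$A,
               new("DFEModel", family = family, params = p, Smax = Smax),
               variant))
  gridVals <- vapply(gridStarts, obj, 0)
  s1 <- gridStarts[[which.min(gridVals)]]

  starts <- list(s1)
  if (restarts > 1) {
    pert <- .withSeed(seed, lapply(seq_len(restarts - 1L), function(k)
      s1 + rnorm(length(s1), sd = 0.7)))
    starts <- c(starts, pert)
  }
  for (ini in init) {
    A0 <- if (is.null(ini$A)) 0 else ini$A
    starts <- c(starts, list(.packOuter(ini$theta, ini$Tdiv, A0, ini$dfe,
                                        variant)))
  }

  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      optim(st, obj, method = "BFGS",
            control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("all optimization starts failed for family '", family, "'")

  up <- .unpackOuter(best$par, family, variant, Smax)
  # report the exact-quadrature likelihood at the optimum
  pl <- .profiledLoglik(.fitContext(dataset, xNodes, sNodes,
                                    interpolate = FALSE), up)
  params <- ModelParams(theta = up$theta, r = pl$r, Tdiv = up$Tdiv,
                        dfe = up$dfe, A = up$A)
  nFree <- 2L + (nclass - 1L) + nFreeParams(up$dfe) +
    (variant == "standard")
  new("FitResult", params = params, loglik = pl$ll,
      aic = 2 * nFree - 2 * pl$ll, nFree = as.integer(nFree),
      converged = best$convergence == 0 && best$value < .BIG,
      nRestartsUsed = length(starts), variant = variant,
      label = dataset@label)
}

#' Fit with the divergence excess pinned to zero
#'
#' The \[-A\] variant: identical to [fitModel()] but with A = 0, testing
#' whether the continuous DFE alone accounts for the observed divergence.
#' Only families that model positive selection coefficients (gammaexpo,
#' scaledbeta) are accepted.
#'
#' @inheritParams fitModel
#' @param ... passed to [fitModel()].
#' @return A [FitResult-class] with \code{variant = "minus_A"}.
#' @export
fitMinusA <- function(dataset, family, ...) {
  fitModel(dataset, family, variant = "minus_A", ...)
}

# Is `nullFit` nested within `altFit`?
.isNested <- function(nullFit, altFit) {
  famN <- dfeFamily(nullFit@params@dfe)
  famA <- dfeFamily(altFit@params@dfe)
  sameVariant <- nullFit@variant == altFit@variant
  famChain <- list(c("neutral", "gamma"), c("neutral", "gammaexpo"),
                   c("gamma", "gammaexpo"))
  (sameVariant && any(vapply(famChain, function(p)
      identical(p, c(famN, famA)), TRUE))) ||
    (famN == famA && nullFit@variant == "minus_A" &&
       altFit@variant == "standard")
}

#' Likelihood-ratio test between nested fits
#'
#' Valid pairs: neutral within gamma, neutral within gammaexpo, gamma
#' within gammaexpo (same variant), and minus_A within standard (same
#' family). The statistic 2 (loglik_alt - loglik_null) is floored at zero
#' and referred to a chi-square with df equal to the free-parameter
#' difference; for boundary nulls (p_pos = 0, A = 0) this is conservative.
#'
#' @param nullFit,altFit [FitResult-class] objects, null nested in
#'   alternative.
#' @return List with \code{statistic}, \code{df}, \code{p}.
#' @export
lrt <- function(nullFit, altFit) {
  if (!.isNested(nullFit, altFit))
    stop("fits are not nested (", dfeFamily(nullFit@params@dfe), "/",
         nullFit@variant, " vs ", dfeFamily(altFit@params@dfe), "/",
         altFit@variant, ")")
  df <- altFit@nFree - nullFit@nFree
  if (df < 1L) stop("alternative must have more free parameters than the null")
  stat <- max(2 * (altFit@loglik - nullFit@loglik), 0)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Fit and rank several DFE families on one dataset
#'
#' Fits each family once (warm-starting gammaexpo from the gamma optimum
#' when both are requested, so likelihood never decreases along the nested
#' chain), ranks fits by AIC with ties broken toward fewer parameters, and
#' reports likelihood-ratio tests for every nested pair present.
#'
#' @param dataset a [PolyDivData-class].
#' @param families character vector of family names.
#' @param ... passed to [fitModel()] (variant, restarts, seed, ...).
#' @return List with elements \code{fits} (named list of
#'   [FitResult-class]), \code{table} (data.frame ranked by AIC) and
#'   \code{lrt} (data.frame of nested-pair tests).
#' @export
modelScan <- function(dataset, families = c("neutral", "gamma", "gammaexpo",
                                            "scaledbeta", "displgamma"),
                      ...) {
  fits <- list()
  for (fam in families) {
    init <- list()
    if (fam == "gammaexpo" && "gamma" %in% names(fits)) {
      g <- fits[["gamma"]]@params
      init <- c(init, list(list(
        theta = g@theta, Tdiv = g@Tdiv, A = g@A,
        dfe = DFEModel("gammaexpo",
                       shape = g@dfe@params[["shape"]],
                       mean_del = g@dfe@params[["mean_del"]],
                       p_pos = 1e-6, mean_adv = 10))))
    }
    if (fam == "displgamma" && "gamma" %in% names(fits)) {
      g <- fits[["gamma"]]@params
      init <- c(init, list(list(
        theta = g@theta, Tdiv = g@Tdiv, A = g@A,
        dfe = DFEModel("displgamma",
                       shape = g@dfe@params[["shape"]],
                       mean_del = g@dfe@params[["mean_del"]],
                       displacement = 1e-6))))
    }
    fits[[fam]] <- fitModel(dataset, fam, init = init, ...)
  }
  tab <- data.frame(
    family = names(fits),
    loglik = vapply(fits, function(f) f@loglik, 0),
    aic = vapply(fits, function(f) f@aic, 0),
    nFree = vapply(fits, function(f) f@nFree, 0L),
    converged = vapply(fits, function(f) f@converged, TRUE),
    row.names = NULL)
  tab <- tab[order(tab$aic, tab$nFree), ]
  tests <- list()
  fams <- names(fits)
  for (a in fams) for (b in fams) {
    if (a == b) next
    ok <- tryCatch(.isNested(fits[[a]], fits[[b]]), error = function(e) FALSE)
    if (!ok) next
    t <- lrt(fits[[a]], fits[[b]])
    tests[[length(tests) + 1L]] <- data.frame(
      null = a, alt = b, statistic = t$statistic, df = t$df, p = t$p)
  }
  list(fits = fits, table = tab,
       lrt = if (length(tests)) do.call(rbind, tests)
             else data.frame(null = character(), alt = character(),
                             statistic = numeric(), df = integer(),
                             p = numeric()))
}

# Constrained maximum of the log-likelihood subject to alpha fixed:
# alpha determines T through Ldiv_N * T * I_na(dfe) = (1 - alpha) * D_N,
# so the optimizer runs over theta, A and the DFE parameters only.
.profileLoglikAtAlpha <- function(ctx, family, variant, alpha, start,
                                  Sadv = 5, Smax = 25, maxit = 200) {
  if (ctx$DN <= 0) stop("alpha profiling requires D_N > 0")
  strip <- function(v) v[-2]                       # drop log T
  restore <- function(v2, Tdiv) append(v2, log(Tdiv), after = 1)
  objA <- function(v2) {
    tryCatch(suppressWarnings({
      upT <- .unpackOuter(restore(v2, 1), family, variant, Smax)
      Ina <- .dfeDivIntegral(upT$dfe, ctx$sNodes, Sadv = Sadv)
      Tdiv <- (1 - alpha) * ctx$DN / (ctx$shape$LdivN * Ina)
      if (!is.finite(Tdiv) || Tdiv <= 0) return(.BIG)
      up <- .unpackOuter(restore(v2, Tdiv), family, variant, Smax)
      ll <- .profiledLoglik(ctx, up)$ll
      if (!is.finite(ll)) .BIG else -ll
    }), error = function(e) .BIG)
  }
  opt <- tryCatch(
    optim(strip(start), objA, method = "BFGS",
          control = list(maxit = maxit, reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(opt)) return(list(loglik = -Inf, par = start))
  upT <- .unpackOuter(restore(opt$par, 1), family, variant, Smax)
  Ina <- .dfeDivIntegral(upT$dfe, ctx$sNodes, Sadv = Sadv)
  Tdiv <- (1 - alpha) * ctx$DN / (ctx$shape$LdivN * Ina)
  list(loglik = -opt$value, par = restore(opt$par, Tdiv))
}

#' Profile-likelihood confidence interval for alpha
#'
#' Bounds of the set of alpha values whose constrained maximum
#' log-likelihood lies within \code{drop} units of the global maximum
#' (default 2, the conventional "two units of support" interval). The
#' constraint is imposed by solving the non-adaptive divergence identity
#' for T given alpha and the DFE, and re-maximizing over the remaining
#' free parameters, stepping outward from the point estimate with warm
#' starts and refining each bound by bisection.
#'
#' @param dataset the fitted [PolyDivData-class].
#' @param fit a converged [FitResult-class] for this dataset.
#' @param drop log-likelihood drop defining the interval (default 2).
#' @param Sadv non-adaptive threshold used in the alpha definition.
#' @param step initial alpha step (default 0.02).
#' @param tol bisection tolerance on alpha (default 0.005).
#' @return List with \code{lower}, \code{upper}, \code{alphaHat} and
#'   \code{clipped} (TRUE when a bound hit the alpha = 1 boundary).
#' @export
profileCIAlpha <- function(dataset, fit, drop = 2, Sadv = 5, step = 0.02,
                           tol = 0.005) {
  family <- dfeFamily(fit@params@dfe)
  variant <- fit@variant
  Smax <- fit@params@dfe@Smax
  ctx <- .fitContext(dataset, 256L, 64L)
  rates <- adaptiveRates(dataset, fit@params, Sadv = Sadv)
  ahat <- rates@alpha
  if (!is.finite(ahat)) stop("alpha is undefined for this fit (D_N = 0?)")
  # reference level on the same (interpolated) surface the profile uses
  llmax <- .profiledLoglik(ctx, list(theta = fit@params@theta,
                                     Tdiv = fit@params@Tdiv,
                                     A = fit@params@A,
                                     dfe = fit@params@dfe))$ll
  if (drop <= 0) return(list(lower = ahat, upper = ahat, alphaHat = ahat,
                             clipped = FALSE))
  start0 <- .packOuter(fit@params@theta, fit@params@Tdiv, fit@params@A,
                       fit@params@dfe, variant)
  clipped <- FALSE

  sweep <- function(dir) {
    a_in <- ahat
    st <- start0
    repeat {
      a_out <- a_in + dir * step
      if (dir > 0 && a_out >= 1 - 1e-6) {
        clipped <<- TRUE
        return(1)
      }
      pr <- .profileLoglikAtAlpha(ctx, family, variant, a_out, st,
                                  Sadv = Sadv, Smax = Smax)
      if (llmax - pr$loglik > drop) {
        lo <- a_in; hi <- a_out
        while (abs(hi - lo) > tol) {
          mid <- (lo + hi) / 2
          pm <- .profileLoglikAtAlpha(ctx, family, variant, mid, st,
                                      Sadv = Sadv, Smax = Smax)
          if (llmax - pm$loglik > drop) hi <- mid else { lo <- mid; st <- pm$par }
        }
        return((lo + hi) / 2)
      }
      a_in <- a_out
      st <- pr$par
    }
  }
  lower <- sweep(-1)
  upper <- sweep(+1)
  list(lower = lower, upper = upper, alphaHat = ahat, clipped = clipped)
}

#' Write a fit result as a key=value file
#'
#' @param fit a [FitResult-class].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeFitResult <- function(fit, path) {
  p <- fit@params
  kv <- c(label = fit@label, family = dfeFamily(p@dfe),
          variant = fit@variant,
          loglik = sprintf("%.10g", fit@loglik),
          aic = sprintf("%.10g", fit@aic),
          n_free = fit@nFree, converged = fit@converged,
          n_restarts = fit@nRestartsUsed,
          theta = sprintf("%.10g", p@theta),
          T = sprintf("%.10g", p@Tdiv),
          A = sprintf("%.10g", p@A),
          setNames(sprintf("%.10g", p@dfe@params),
                   paste0("dfe_", names(p@dfe@params))),
          setNames(sprintf("%.10g", p@r), paste0("r_", seq_along(p@r))))
  writeLines(paste(names(kv), kv, sep = "="), path)
  invisible(path)
}
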