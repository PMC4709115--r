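# Cross-species comparative layer: per-species summary rows and the
# regression structure relating alpha, omega_a, omega_na and dN/dS to
# (log-transformed) synonymous diversity or life-history covariates.

#' Per-species summary row
#'
#' Combines diversity summaries of a dataset with the adaptive-rate
#' quantities of its fit into one comparative-table row.
#'
#' @param dataset a [PolyDivData-class].
#' @param fit the corresponding [FitResult-class].
#' @param rates an [AdaptiveRateEstimate-class]; computed from the fit if
#'   omitted.
#' @param Sadv threshold used when \code{rates} must be computed.
#' @return A one-row data.frame with columns \code{label}, \code{pi_S},
#'   \code{pi_N}, \code{dnds}, \code{omega_na}, \code{omega_a},
#'   \code{alpha}.
#' @export
speciesSummary <- function(dataset, fit, rates = NULL, Sadv = 5) {
  if (is.null(rates)) rates <- adaptiveRates(dataset, fit@params, Sadv)
  data.frame(
    label = dataset@label,
    pi_S = piFromSFS(dataset@sfsSyn, dataset@LS),
    pi_N = piFromSFS(dataset@sfsNonsyn, dataset@LN),
    dnds = rates@dnds,
    omega_na = rates@omegaNa,
    omega_a = rates@omegaA,
    alpha = rates@alpha,
    stringsAsFactors = FALSE)
}

#' Correlate a rate estimate with a species covariate
#'
#' Pearson correlation and least-squares regression of column \code{y} on
#' column \code{x} (natural-log-transformed when \code{logX}), across the
#' rows of a species summary table. Raw p-values are reported (no
#' multiple-testing correction).
#'
#' @param table data.frame of per-species rows (see [speciesSummary()]),
#'   possibly merged with a covariate table.
#' @param y,x column names.
#' @param logX log-transform x before correlating? (x must then be
#'   positive).
#' @return List with \code{r}, \code{r2}, \code{p}, \code{slope},
#'   \code{intercept}, \code{n}.
#' @examples
#' tab <- data.frame(a = c(1, 2, 3), b = c(2, 4, 6))
#' correlateSummaries(tab, "b", "a")$r   # 1
#' @export
correlateSummaries <- function(table, y, x, logX = FALSE) {
  yv <- table[[y]]
  xv <- table[[x]]
  keep <- is.finite(yv) & is.finite(xv)
  yv <- yv[keep]; xv <- xv[keep]
  if (length(yv) < 3L) stop("need at least 3 complete observations")
  if (logX) {
    if (any(xv <= 0)) stop("x must be positive for log transformation")
    xv <- log(xv)
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero variance in x or y: correlation undefined")
  ct <- cor.test(xv, yv, method = "pearson")
  fitlm <- lm(yv ~ xv)
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, slope = unname(coef(fitlm)[2]),
       intercept = unname(coef(fitlm)[1]), n = length(yv))
}

#' Log-log slope of non-synonymous on synonymous diversity
#'
#' Under a Gamma DFE of shape beta with scaled effects proportional to the
#' effective population size, log(pi_N) is linear in log(pi_S) with slope
#' 1 - beta, so the regression slope across species implies a DFE shape
#' estimate \code{beta_implied = 1 - slope}.
#'
#' @param table data.frame with positive columns \code{pi_N} and
#'   \code{pi_S}.
#' @return List with \code{slope}, \code{beta_implied}, \code{r2},
#'   \code{n}.
#' @examples
#' tab <- data.frame(pi_S = c(0.001, 0.01, 0.1),
#'                   pi_N = 0.2 * c(0.001, 0.01, 0.1)^0.6)
#' piNpiSSlope(tab)$beta_implied   # 0.4
#' @export
piNpiSSlope <- function(table) {
  keep <- is.finite(table$pi_N) & is.finite(table$pi_S)
  piN <- table$pi_N[keep]; piS <- table$pi_S[keep]
  if (any(piN <= 0) || any(piS <= 0))
    stop("pi_N and pi_S must be positive")
  fitlm <- lm(log(piN) ~ log(piS))
  slope <- unname(coef(fitlm)[2])
  list(slope = slope, beta_implied = 1 - slope,
       r2 = stats::cor(log(piN), log(piS))^2, n = length(piN))
}

#' Merge a covariate table into a species summary table
#'
#' @param table species summary data.frame (keyed by \code{label}).
#' @param covariates data.frame with a \code{label} column and numeric
#'   covariates (e.g. longevity, propagule size).
#' @return Merged data.frame (left join on \code{label}).
#' @export
addCovariates <- function(table, covariates) {
  stopifnot("label" %in% names(covariates))
  merge(table, covariates, by = "label", all.x = TRUE, sort = FALSE)
}
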