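## Statistical layer: Pearson correlations, linear mixed-effects models with
## a per-subject random intercept (fellow eyes are not independent), the
## light/dark group comparison, and the bias summary.
##
## LMMs are estimated by REML (lme4) with a Wald z-test on the fixed-effect
## slope. A collapsed random-intercept variance is flagged as a singular
## fit, not treated as an error; in that case the slope coincides with the
## ordinary least-squares estimate.

#' Pearson correlation with a two-sided t-test
#'
#' Standard product-moment correlation, with the two-sided p-value from the
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return List with `r`, `p`, `n`.
#' @section Errors: `LengthMismatch`; `DegenerateVariance`.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y))
    .err("LengthMismatch", "x and y must have equal length")
  if (length(x) < 3)
    .err("DegenerateVariance", "need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .err("DegenerateVariance", "zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

.lmmFit <- function(records, response, predictor) {
  fml <- stats::as.formula(
    sprintf("%s ~ %s + (1 | subjectId)", response, predictor))
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = records, REML = TRUE, control = ctrl)))
  co <- summary(fit)$coefficients
  beta <- co[predictor, "Estimate"]
  se <- co[predictor, "Std. Error"]
  z <- beta / se
  list(fit = fit, beta = beta, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       singular = lme4::isSingular(fit))
}

#' Association between two per-eye variables with a subject random intercept
#'
#' Fits `response ~ predictor + (1 | subjectId)` by REML; the fixed-effect
#' coefficient (beta) is the expected change in the response per unit
#' increase of the predictor after adjusting for between-subject
#' differences. The pooled Pearson r is reported alongside for comparison
#' (it ignores the fellow-eye correlation).
#'
#' @param records `data.frame` with columns `subjectId` plus the response
#'   and predictor variables; one row per eye.
#' @param response,predictor Column names.
#' @return List with `response`, `predictor`, `n`, `nSubjects`, `beta`,
#'   `se`, `pBeta`, `r`, `pR` and `singular` (TRUE when the random-intercept
#'   variance collapsed to zero; the fit is then equivalent to OLS and is
#'   flagged, not failed).
#' @section Errors: `TooFewSubjects` (< 3 subjects).
#' @export
fitLmm <- function(records, response, predictor) {
  stopifnot(all(c("subjectId", response, predictor) %in% names(records)))
  nSub <- length(unique(records$subjectId))
  if (nSub < 3) .err("TooFewSubjects", "need at least 3 subjects")
  fit <- .lmmFit(records, response, predictor)
  pe <- pearsonCorrelation(records[[predictor]], records[[response]])
  list(response = response, predictor = predictor,
       n = nrow(records), nSubjects = nSub,
       beta = fit$beta, se = fit$se, pBeta = fit$p,
       r = pe$r, pR = pe$p, singular = fit$singular)
}

#' Compare densitometry outcomes between light- and dark-iris eyes
#'
#' Groupwise comparison of corneal densitometry and artefact percentages
#' between eyes classified light (`pigmentClass == "light"`) and dark by the
#' IrisColor sign rule; indeterminate eyes are excluded. Per-group mean and
#' SD are plain per-eye statistics; the per-outcome p-value comes from an
#' LMM with the group indicator as fixed effect and a subject random
#' intercept. The corneal-densitometry bias is summarized as
#' `deltaCd = meanLight - meanDark` and its relative size in percent of the
#' dark-group mean (the dark group serves as the unbiased reference).
#'
#' @param records `data.frame` with `subjectId`, `pigmentClass` and the
#'   outcome columns.
#' @param outcomes Outcome columns to compare (default `cd`, `pctIris`,
#'   `pctLateral`, `pctOverall`, reduced to those present).
#' @return List with `table` (per-outcome group means, SDs and LMM p),
#'   `nLight`, `nDark`, `deltaCd`, `relativeBias`.
#' @section Errors: `EmptyGroup` when either strict-sign class is empty.
#' @export
compareGroups <- function(records,
                          outcomes = c("cd", "pctIris", "pctLateral",
                                       "pctOverall")) {
  stopifnot(all(c("subjectId", "pigmentClass") %in% names(records)))
  outcomes <- intersect(outcomes, names(records))
  stopifnot(length(outcomes) > 0)
  rec <- records[records$pigmentClass %in% c("light", "dark"), , drop = FALSE]
  nLight <- sum(rec$pigmentClass == "light")
  nDark <- sum(rec$pigmentClass == "dark")
  if (nLight == 0 || nDark == 0)
    .err("EmptyGroup", "both light and dark groups must be non-empty")
  rec$lightGroup <- as.numeric(rec$pigmentClass == "light")

  rows <- lapply(outcomes, function(oc) {
    byg <- split(rec[[oc]], rec$pigmentClass)
    p <- if (length(unique(rec$subjectId)) >= 3 &&
             stats::sd(rec$lightGroup) > 0) {
      .lmmFit(rec, oc, "lightGroup")$p
    } else NA_real_
    data.frame(outcome = oc,
               meanLight = mean(byg$light), sdLight = stats::sd(byg$light),
               meanDark = mean(byg$dark), sdDark = stats::sd(byg$dark),
               p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  bias <- if ("cd" %in% outcomes) {
    biasSummary(tab$meanLight[tab$outcome == "cd"],
                tab$meanDark[tab$outcome == "cd"])
  } else list(delta = NA_real_, relative = NA_real_)

  list(table = tab, nLight = nLight, nDark = nDark,
       deltaCd = bias$delta, relativeBias = bias$relative)
}

#' Absolute and relative corneal-densitometry bias between groups
#'
#' The light-minus-dark difference in group mean CD, and the same difference
#' expressed in percent of the dark-group mean (overestimation of the light
#' group relative to the dark reference).
#'
#' @param meanLight,meanDark Group mean CD values, a.u.; `meanDark` must be
#'   positive.
#' @return List with `delta` (a.u.) and `relative` (%).
#' @section Errors: `NonpositiveReference` when `meanDark <= 0`.
#' @examples
#' biasSummary(50.3, 47.2) # delta 3.1 a.u., relative approx. 6.6%
#' @export
biasSummary <- function(meanLight, meanDark) {
  if (meanDark <= 0)
    .err("NonpositiveReference", "dark-group mean must be positive")
  delta <- meanLight - meanDark
  list(delta = delta, relative = 100 * delta / meanDark)
}
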