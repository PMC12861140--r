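## Seeded synthetic cohorts with planted effect sizes.
##
## The default cohort emulates the structure of a realistic densitometry
## study: 47 subjects contributing 91 eyes (44 both eyes, 3 one eye), 39
## light- and 52 dark-iris eyes, a planted light-minus-dark corneal
## densitometry difference of 3.1 a.u. over a dark-group mean of 47.2 a.u.,
## per-eye residual SD 2.9 a.u. and per-subject random intercepts.
## Pigmentation levels are drawn bimodally (light eyes below, dark eyes
## above the gradient midpoint, with a gap), matching the strongly bimodal
## distribution of iris color in European cohorts.
##
## The generator is a statistical emulator: the light/dark CD difference is
## planted directly in the table. The image bundles optionally attached to
## each eye provide the mechanistic variant, where lighter eyes receive a
## diffuse glare veil and more planted artefact pixels, so CD inflation
## emerges through the image-analysis pipeline rather than by construction.

#' Specification for a synthetic study cohort
#'
#' @param nSubjects Number of subjects (>= 4).
#' @param nEyes Total eyes, between `nSubjects` and `2 * nSubjects`; the
#'   first `nEyes - nSubjects` subjects contribute both eyes.
#' @param nLightEyes Planted number of light-iris eyes (the rest are dark).
#' @param deltaCd Planted light-minus-dark CD difference, a.u.
#' @param cdDarkMean Dark-group mean CD, a.u.
#' @param cdSd Per-eye residual SD of CD, a.u. (> 0).
#' @param subjectSd Between-subject SD of the random intercept, a.u.
#' @param pigmentRange Range of pigmentation levels spanned by the cohort.
#' @param labNoiseSd Per-component SD of the eye-level CIELAB summaries
#'   around the gradient line, `c(L, a, b)`.
#' @param glareGain Mechanistic-mode diffuse glare at level 0, a.u.
#' @param seed Integer seed.
#' @return Named list of class `"cohortSpec"`.
#' @export
cohortSpec <- function(nSubjects = 47L, nEyes = 91L, nLightEyes = 39L,
                       deltaCd = 3.1, cdDarkMean = 47.2, cdSd = 2.9,
                       subjectSd = 1.5,
                       pigmentRange = c(0.05, 0.95),
                       labNoiseSd = c(L = 1.5, a = 0.8, b = 1.0),
                       glareGain = 6,
                       seed = 1L) {
  spec <- list(nSubjects = as.integer(nSubjects), nEyes = as.integer(nEyes),
               nLightEyes = as.integer(nLightEyes),
               deltaCd = deltaCd, cdDarkMean = cdDarkMean, cdSd = cdSd,
               subjectSd = subjectSd, pigmentRange = pigmentRange,
               labNoiseSd = labNoiseSd, glareGain = glareGain,
               seed = as.integer(seed))
  class(spec) <- c("cohortSpec", "list")
  .validateCohortSpec(spec)
  spec
}

.validateCohortSpec <- function(s) {
  if (s$nSubjects < 4L) .err("SpecInvalid", "need at least 4 subjects")
  if (s$nEyes < s$nSubjects || s$nEyes > 2L * s$nSubjects)
    .err("SpecInvalid", "nEyes must lie in [nSubjects, 2 * nSubjects]")
  if (s$nLightEyes < 1L || s$nLightEyes >= s$nEyes)
    .err("SpecInvalid", "nLightEyes must leave both groups non-empty")
  if (s$cdSd <= 0) .err("SpecInvalid", "cdSd must be positive")
  if (s$cdDarkMean <= 0) .err("SpecInvalid", "cdDarkMean must be positive")
  if (s$pigmentRange[1] < 0 || s$pigmentRange[2] > 1 ||
      s$pigmentRange[1] >= s$pigmentRange[2])
    .err("SpecInvalid", "pigmentRange must be an increasing range in [0, 1]")
  invisible(TRUE)
}

# Artefact-percentage gradient: affine in the pigmentation level, anchored
# so that group means land at realistic values (iris approx. 2.3% light /
# 0.8% dark, lateral 3.9/3.4, overall 6.5/4.3 at mean levels 0.25 / 0.75).
.pctGradients <- list(
  pctIris = c(intercept = 3.05, slope = -3.0, sd = 0.45),
  pctLateral = c(intercept = 4.15, slope = -1.0, sd = 0.60),
  pctOverall = c(intercept = 7.60, slope = -4.4, sd = 0.70)
)

#' Generate a synthetic study cohort with planted ground truth
#'
#' Builds the per-eye study table: subject structure, bimodal pigmentation
#' levels, planted CD difference between light and dark eyes (with subject
#' random intercepts and residual noise), artefact percentages decreasing
#' affinely with pigmentation, and eye-level CIELAB summaries along the
#' gradient which are scored through [scoreIrisCohort()] to obtain the
#' continuous IrisColor column. The `pigmentClass` column records the
#' *planted* class (level below/above the gradient midpoint); the
#' cohort-relative IrisColor sign reproduces it except possibly for eyes
#' nearest the midpoint.
#'
#' With `images = TRUE` each eye also receives an image bundle: a phantom
#' frame (mechanistic mode: corneal mean without the planted class
#' difference, plus a diffuse glare veil `glareGain * (1 - level)` and
#' planted artefact fractions `pctIris/100`, `pctLateral/100`) and a
#' synthetic iris photograph at the eye's pigmentation level, so the full
#' image -> statistics pipeline can be exercised end to end.
#'
#' @param spec A [cohortSpec()].
#' @param images Attach per-eye image bundles (default `FALSE`; table-only
#'   generation is what the statistical simulations use).
#' @return List with `table` (one row per eye: `subjectId`, `eyeId`,
#'   `pigmentLevel`, `cd`, `pctIris`, `pctLateral`, `pctOverall`, `L`, `a`,
#'   `b`, `Ln`, `an`, `bn`, `irisColor`, `pigmentClass`), `truth` (spec,
#'   subject intercepts, planted class and per-eye planted values) and,
#'   when requested, `bundles` (per-eye list of `frame`, `masks`,
#'   `iris`).
#' @section Errors: `SpecInvalid` on an invalid spec.
#' @export
makeCohort <- function(spec = cohortSpec(), images = FALSE) {
  if (!inherits(spec, "cohortSpec")) spec <- do.call(cohortSpec, spec)
  .validateCohortSpec(spec)

  out <- .withSeed(spec$seed, {
    nBoth <- spec$nEyes - spec$nSubjects
    subjectId <- sprintf("S%03d", c(seq_len(spec$nSubjects),
                                    seq_len(nBoth)))
    side <- c(rep("OD", spec$nSubjects), rep("OS", nBoth))
    ord <- order(subjectId, side)
    subjectId <- subjectId[ord]; side <- side[ord]
    eyeIds <- paste0(subjectId, "-", side)

    isLight <- rep(FALSE, spec$nEyes)
    isLight[sample.int(spec$nEyes, spec$nLightEyes)] <- TRUE
    lo <- spec$pigmentRange[1]; hi <- spec$pigmentRange[2]
    level <- ifelse(isLight, stats::runif(spec$nEyes, lo, 0.45),
                    stats::runif(spec$nEyes, 0.55, hi))

    intercepts <- stats::rnorm(spec$nSubjects, 0, spec$subjectSd)
    names(intercepts) <- sprintf("S%03d", seq_len(spec$nSubjects))
    u <- intercepts[subjectId]

    cd <- spec$cdDarkMean + spec$deltaCd * isLight + u +
      stats::rnorm(spec$nEyes, 0, spec$cdSd)

    pct <- lapply(.pctGradients, function(g) {
      pmax(0, g["intercept"] + g["slope"] * level +
             stats::rnorm(spec$nEyes, 0, g["sd"]))
    })

    labTrue <- t(vapply(level, .irisLabAt, numeric(3)))
    lab <- labTrue + cbind(stats::rnorm(spec$nEyes, 0, spec$labNoiseSd["L"]),
                           stats::rnorm(spec$nEyes, 0, spec$labNoiseSd["a"]),
                           stats::rnorm(spec$nEyes, 0, spec$labNoiseSd["b"]))

    summaries <- data.frame(eyeId = eyeIds, L = lab[, 1], a = lab[, 2],
                            b = lab[, 3], stringsAsFactors = FALSE)
    scored <- scoreIrisCohort(summaries)

    tab <- data.frame(
      subjectId = subjectId, eyeId = eyeIds, pigmentLevel = level,
      cd = unname(cd),
      pctIris = unname(pct$pctIris), pctLateral = unname(pct$pctLateral),
      pctOverall = unname(pct$pctOverall),
      stringsAsFactors = FALSE)
    tab <- cbind(tab, scored[c("L", "a", "b", "Ln", "an", "bn", "irisColor")])
    tab$pigmentClass <- ifelse(isLight, "light", "dark")

    bundleSeeds <- sample.int(2^30, spec$nEyes)
    list(table = tab,
         truth = list(spec = spec, subjectIntercepts = intercepts,
                      isLight = isLight, level = level,
                      normalization = attr(scored, "normalization"),
                      bundleSeeds = bundleSeeds))
  })

  if (images) {
    out$bundles <- lapply(seq_len(spec$nEyes), function(i) {
      row <- out$table[i, ]
      ph <- makePhantom(phantomSpec(
        corneaMean = spec$cdDarkMean +
          out$truth$subjectIntercepts[row$subjectId] +
          spec$glareGain * (1 - row$pigmentLevel),
        artefactFractionIris = min(0.95, row$pctIris / 100),
        artefactFractionLateral = min(0.95, row$pctLateral / 100),
        seed = out$truth$bundleSeeds[i]))
      iris <- makeIrisImage(row$pigmentLevel,
                            seed = out$truth$bundleSeeds[i])
      list(eyeId = row$eyeId, frame = ph$frame, masks = ph$masks,
           phantomTruth = ph$truth, iris = iris)
    })
    names(out$bundles) <- out$table$eyeId
  }
  out
}
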