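#' Synthetic cohort specification constructor
#'
#' Defaults emulate the packaged study table of overweight adults: 16
#' analysable subjects, PDFF spanning 1-28 percent, and a linear decreasing
#' conductivity map \code{sigma = 0.346 - 0.0021 * PDFF} (S/m) with 0.009
#' S/m measurement noise -- the ordinary least-squares fit of the printed
#' liver conductivities against PDFF and its residual SD. Demographics are
#' drawn independently of PDFF, matching the study's null findings.
#'
#' @param nSubjects number of subjects (default 16)
#' @param pdffRange PDFF range in percent (default \code{c(1, 28)})
#' @param mapIntercept intercept a of \code{sigma = a - b * PDFF} (S/m)
#' @param mapSlope slope b > 0 (S/m per percent)
#' @param noiseSD SD of conductivity measurement noise (S/m)
#' @param exclusionRate expected fraction flagged with confounders
#'   (default 3/19, the study's rate)
#' @param seed integer seed
#' @return a \code{\link{CohortSpec}}
#' @export
cohortSpec <- function(nSubjects = 16L, pdffRange = c(1, 28),
                       mapIntercept = 0.346, mapSlope = 0.0021,
                       noiseSD = 0.009, exclusionRate = 3 / 19, seed = 1L) {
  new("CohortSpec", nSubjects = as.integer(nSubjects), pdffRange = pdffRange,
      mapIntercept = mapIntercept, mapSlope = mapSlope, noiseSD = noiseSD,
      exclusionRate = exclusionRate, seed = as.integer(seed))
}

#' The cohort's PDFF-to-conductivity map
#'
#' @param spec a \code{\link{CohortSpec}}
#' @param pdff fat fraction(s) in percent
#' @return liver conductivity (S/m)
#' @export
conductivityMap <- function(spec, pdff) {
  spec@mapIntercept - spec@mapSlope * pdff
}

#' Generate a synthetic overweight cohort
#'
#' Draws per-subject PDFF uniformly over the spec range, liver EIT
#' conductivity from the monotone-decreasing map plus Gaussian noise, and
#' demographics (sex, age, height, BMI > 25, weight = BMI x height^2, waist
#' tracking BMI) independent of PDFF. A fraction of subjects is flagged with
#' a confounding condition. Reproducible: identical seeds give identical
#' cohorts.
#'
#' @param spec a \code{\link{CohortSpec}}
#' @return an \code{\link{EITCohort}} with policy \code{"none"}
#' @examples
#' cohort <- generateCohort(cohortSpec(nSubjects = 12, seed = 42))
#' head(cohortRecords(cohort))
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(spec@seed)
  n <- spec@nSubjects
  pdff <- stats::runif(n, spec@pdffRange[1], spec@pdffRange[2])
  eit <- conductivityMap(spec, pdff) + stats::rnorm(n, 0, spec@noiseSD)
  if (any(eit <= 0))
    stop("cohort spec produced non-positive conductivity; reduce noiseSD ",
         "or adjust the map", call. = FALSE)
  sex <- ifelse(stats::runif(n) < 4 / 19, "M", "F")
  age <- round(stats::runif(n, 26, 74))
  height <- round(stats::rnorm(n, 166, 9), 1)
  bmi <- round(25.1 + stats::rexp(n, rate = 1 / 9), 1)    # overweight: BMI > 25
  weight <- round(bmi * (height / 100)^2, 1)
  waist <- round(59 + 1.45 * bmi + stats::rnorm(n, 0, 6), 1)
  current <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  excluded <- stats::runif(n) < spec@exclusionRate
  reason <- ifelse(excluded,
                   sample(c("electrode_malfunction", "renal_failure", "leukemia"),
                          n, replace = TRUE), "")
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  rec <- data.frame(
    subject = seq_len(n), sex = sex, bmi = bmi, age = age, waist = waist,
    height = height, weight = weight, pdff = pdff, eit_mean = eit,
    eit_sd = rep(NA_real_, n), injection_current = current,
    excluded = excluded, exclusion_reason = reason,
    stringsAsFactors = FALSE)
  new("EITCohort", records = rec, exclusionPolicy = "none")
}

#' Derive a subject-specific phantom from a cohort record
#'
#' Returns the base phantom with its liver conductivity set by the cohort's
#' conductivity map evaluated at the subject's PDFF, and the whole geometry
#' scaled isotropically so the outline perimeter equals the subject's waist
#' circumference.
#'
#' @param record one row of \code{\link{cohortRecords}} (a list or
#'   single-row data.frame with \code{pdff} and \code{waist})
#' @param base a \code{\link{PhantomSpec}} with a liver region
#' @param spec the \code{\link{CohortSpec}} supplying the conductivity map
#' @return a \code{\link{PhantomSpec}}
#' @export
subjectToPhantom <- function(record, base, spec = cohortSpec()) {
  labs <- vapply(base@regions, `[[`, character(1), "label")
  if (!"liver" %in% labs)
    stop("base phantom has no liver region", call. = FALSE)
  sigma <- conductivityMap(spec, record$pdff)
  if (sigma <= 0) stop("conductivity map gives non-positive sigma", call. = FALSE)
  scalePhantom(base, waist = record$waist, liverConductivity = sigma)
}

setMethod("cohortRecords", "EITCohort", function(x, applyPolicy = TRUE) {
  rec <- x@records
  if (!applyPolicy) return(rec)
  switch(x@exclusionPolicy,
    none = rec,
    study_n16 = rec[!(rec$exclusion_reason %in%
                        c("electrode_malfunction", "renal_failure", "leukemia") &
                        rec$excluded), , drop = FALSE],
    study_n18 = rec[!(rec$exclusion_reason == "electrode_malfunction" &
                        rec$excluded), , drop = FALSE])
})

#' Set the exclusion policy of a cohort
#' @param cohort an \code{\link{EITCohort}}
#' @param policy \code{"none"}, \code{"study_n16"} or \code{"study_n18"}
#' @return the cohort with the policy set
#' @export
setExclusionPolicy <- function(cohort, policy) {
  policy <- match.arg(policy, c("none", "study_n16", "study_n18"))
  new("EITCohort", records = cohort@records, exclusionPolicy = policy)
}

setMethod("show", "EITCohort", function(object) {
  rec <- cohortRecords(object)
  cat(sprintf("EITCohort: %d subjects (%d after policy '%s'), %d flagged\n",
              nrow(object@records), nrow(rec), object@exclusionPolicy,
              sum(object@records$excluded)))
})

#' Write / read a cohort as CSV
#'
#' Column layout mirrors the packaged study tables: subject, sex, bmi, age,
#' waist, height, weight, pdff, eit_mean, eit_sd, injection_current,
#' excluded, exclusion_reason. Numeric columns are written at full precision
#' so the round trip is lossless.
#'
#' @param cohort an \code{\link{EITCohort}}
#' @param path CSV path
#' @return \code{readCohort} returns an \code{EITCohort} with policy
#'   \code{"none"}; \code{writeCohort} returns \code{path} invisibly.
#' @export
writeCohort <- function(cohort, path) {
  rec <- cohort@records
  for (cc in c("pdff", "eit_mean", "eit_sd"))
    rec[[cc]] <- fmtG(rec[[cc]])
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(rec)) stop("cohort file is empty", call. = FALSE)
  rec$excluded <- as.logical(rec$excluded)
  for (cc in c("pdff", "eit_mean", "eit_sd"))
    if (cc %in% names(rec)) rec[[cc]] <- as.numeric(rec[[cc]])
  new("EITCohort", records = rec, exclusionPolicy = "none")
}
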