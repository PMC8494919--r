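#' Load the packaged study tables
#'
#' Reads the two per-subject tables shipped with the package (typed from the
#' study's printed tables: BMI, liver EIT conductivity mean and spatial SD,
#' MRI PDFF and injection current; and sex, age, waist circumference, height
#' and weight), merges them on subject id and applies an exclusion policy.
#' Three subjects carry confounding-condition flags: subject 4 (electrode
#' malfunction), 14 (renal failure), 18 (leukemia). Policy
#' \code{"study_n16"} removes all three (the study's demographic-analysis
#' sample), \code{"study_n18"} removes only subject 4, \code{"none"} keeps
#' all 19.
#'
#' @param policy exclusion policy, default \code{"study_n16"}
#' @return an \code{\link{EITCohort}}
#' @examples
#' cohort <- loadStudyTables("study_n16")
#' nrow(cohortRecords(cohort))
#' @export
loadStudyTables <- function(policy = c("study_n16", "study_n18", "none")) {
  policy <- match.arg(policy)
  t1 <- utils::read.csv(system.file("extdata", "cohort_table1.csv",
                                    package = "liverEIT"),
                        stringsAsFactors = FALSE)
  t2 <- utils::read.csv(system.file("extdata", "cohort_table2.csv",
                                    package = "liverEIT"),
                        stringsAsFactors = FALSE)
  rec <- merge(t1, t2[, c("subject", "sex", "age", "waist", "height", "weight")],
               by = "subject")
  rec$exclusion_reason[is.na(rec$exclusion_reason)] <- ""
  rec <- rec[order(rec$subject),
             c("subject", "sex", "bmi", "age", "waist", "height", "weight",
               "pdff", "eit_mean", "eit_sd", "injection_current", "excluded",
               "exclusion_reason")]
  rownames(rec) <- NULL
  cohort <- new("EITCohort", records = rec, exclusionPolicy = "none")
  setExclusionPolicy(cohort, policy)
}
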