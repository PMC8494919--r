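#' Pearson correlation with a two-sided t test
#'
#' Standard product-moment correlation; the two-sided p-value comes from the
#' t distribution with n - 2 degrees of freedom (via \code{stats::cor.test}).
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite, each with
#'   nonzero variance
#' @return list with \code{r}, \code{p}, \code{n}
#' @examples
#' pearsonCorr(c(1, 2, 3, 4), c(1, 3, 2, 4))
#' @export
pearsonCorr <- function(x, y) {
  checkPair(x, y)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

checkPair <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  invisible(TRUE)
}

#' Confidence interval of the linear slope
#'
#' Ordinary least-squares slope of y on x with a t-based confidence interval
#' (the interval shown as the shaded band in the study's scatter plots).
#'
#' @param x,y numeric vectors (as \code{\link{pearsonCorr}})
#' @param level confidence level (default 0.95)
#' @return list with \code{slope}, \code{lower}, \code{upper}
#' @export
slopeCI <- function(x, y, level = 0.95) {
  checkPair(x, y)
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  b <- sum(xc * yc) / sxx
  res <- yc - b * xc
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 2)
  list(slope = b, lower = b - tq * se, upper = b + tq * se)
}

#' Run the study's correlation grid on a cohort
#'
#' Computes Pearson correlations, slope confidence intervals and
#' Bonferroni-corrected significance for the study's comparison grid: each
#' outcome (MRI PDFF and liver EIT conductivity) against BMI and the four
#' demographic/anthropometric variables (age, waist, height, weight), plus
#' the headline EIT-versus-PDFF test. The Bonferroni family size applies to
#' the demographic variables per outcome (default m = 4; the BMI comparison
#' and the primary EIT-PDFF hypothesis are single pre-specified tests,
#' m = 1). Set \code{mPerOutcome = 8} to pool both outcome families.
#'
#' @param cohort an \code{\link{EITCohort}}; its exclusion policy is applied
#' @param mPerOutcome Bonferroni family size for the demographic tests
#'   (default 4)
#' @param level confidence level for slope intervals (default 0.95)
#' @return data.frame with one row per variable pair: \code{outcome},
#'   \code{variable}, \code{n}, \code{r}, \code{p}, \code{slope},
#'   \code{slope_lo}, \code{slope_hi}, \code{bonferroni_m},
#'   \code{significant_nominal}, \code{significant_corrected}
#' @examples
#' reports <- runStudyAnalysis(loadStudyTables("study_n16"))
#' reports[reports$outcome == "eit_mean" & reports$variable == "pdff", ]
#' @export
runStudyAnalysis <- function(cohort, mPerOutcome = 4L, level = 0.95) {
  rec <- cohortRecords(cohort)
  if (!nrow(rec)) stop("cohort is empty after exclusions", call. = FALSE)
  demo <- c("age", "waist", "height", "weight")
  need <- c("pdff", "eit_mean", "bmi", demo)
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pairs <- rbind(
    data.frame(outcome = "pdff", variable = c("bmi", demo), m = c(1L, rep(mPerOutcome, 4L))),
    data.frame(outcome = "eit_mean", variable = c("bmi", demo), m = c(1L, rep(mPerOutcome, 4L))),
    data.frame(outcome = "eit_mean", variable = "pdff", m = 1L))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    xo <- rec[[pairs$outcome[i]]]; xv <- rec[[pairs$variable[i]]]
    pc <- pearsonCorr(xv, xo)
    ci <- slopeCI(xv, xo, level)
    m <- pairs$m[i]
    data.frame(outcome = pairs$outcome[i], variable = pairs$variable[i],
               n = pc$n, r = pc$r, p = pc$p, slope = ci$slope,
               slope_lo = ci$lower, slope_hi = ci$upper, bonferroni_m = m,
               significant_nominal = pc$p < 0.05,
               significant_corrected = pc$p < 0.05 / m)
  })
  do.call(rbind, out)
}

#' Write correlation reports as CSV and JSON
#' @param reports data.frame from \code{\link{runStudyAnalysis}}
#' @param csvPath,jsonPath output paths (either may be NULL)
#' @return invisibly, the report data.frame
#' @export
writeReports <- function(reports, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath)) utils::write.csv(reports, csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(reports, jsonPath, dataframe = "rows", digits = NA)
  invisible(reports)
}
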