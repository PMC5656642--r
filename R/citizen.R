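# Citizen-science corroboration statistics: vehicle-report share among
# validated reports, and the in-car sighting survey breakdown.

#' Citizen-science count container
#'
#' @param n_reports_total Total validated (possible or definite) reports.
#' @param n_vehicle_possible,n_vehicle_definite Vehicle reports judged
#'   possible / definite by the entomology team.
#' @param survey Named list or vector with \code{n_respondents},
#'   \code{n_yes}, \code{n_no}, \code{n_blank}; the three answer counts
#'   must sum to \code{n_respondents}.
#' @return A \code{citizen_counts} object.
#' @export
citizen_counts <- function(n_reports_total, n_vehicle_possible,
                           n_vehicle_definite,
                           survey = c(n_respondents = 0, n_yes = 0,
                                      n_no = 0, n_blank = 0)) {
  survey <- as.list(survey)
  cc <- list(
    n_reports_total = n_reports_total,
    n_vehicle_possible = n_vehicle_possible,
    n_vehicle_definite = n_vehicle_definite,
    survey = survey
  )
  if (n_vehicle_possible + n_vehicle_definite > n_reports_total) {
    stop("vehicle reports cannot exceed the report total", call. = FALSE)
  }
  if (any(unlist(cc[1:3]) < 0) || any(unlist(survey) < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  s <- survey
  if (s$n_yes + s$n_no + s$n_blank != s$n_respondents) {
    stop("survey answers must sum to the respondent count", call. = FALSE)
  }
  class(cc) <- "citizen_counts"
  cc
}

#' Summary proportions of the citizen-science evidence
#'
#' Vehicle-report share = (possible + definite vehicle reports) / total
#' reports, as a percentage rounded to one decimal; survey percentages
#' rounded to whole percent, matching the reporting precision of the
#' source counts.
#'
#' @param counts A \code{\link{citizen_counts}} object.
#' @return List with \code{vehicle_share_pct} and, when survey respondents
#'   are present, \code{survey_yes_pct}, \code{survey_no_pct},
#'   \code{survey_blank_pct}.
#' @examples
#' citizen_summary(citizen_counts(2002, 11, 16,
#'   c(n_respondents = 1673, n_yes = 386, n_no = 1220, n_blank = 67)))
#' @export
citizen_summary <- function(counts) {
  stopifnot(inherits(counts, "citizen_counts"))
  if (counts$n_reports_total == 0) {
    stop("zero report total", call. = FALSE)
  }
  out <- list(
    vehicle_share_pct = round(
      100 * (counts$n_vehicle_possible + counts$n_vehicle_definite) /
        counts$n_reports_total, 1)
  )
  s <- counts$survey
  if (s$n_respondents > 0) {
    out$survey_yes_pct <- round(100 * s$n_yes / s$n_respondents)
    out$survey_no_pct <- round(100 * s$n_no / s$n_respondents)
    out$survey_blank_pct <- round(100 * s$n_blank / s$n_respondents)
  }
  out
}
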