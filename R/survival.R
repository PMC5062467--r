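#' Clinical follow-up table
#'
#' Normalizes a TCGA-style clinical table into the per-patient fields the
#' stratification needs: vital status, an observed time in years (death
#' time for deceased patients, last follow-up for the living — death time
#' is authoritative when both exist), and a cohort label.
#'
#' @param df data.frame with columns `patient`, `vital_status`
#'   (alive/dead, case-insensitive), `days_to_death`,
#'   `days_to_last_followup`, and optionally `cohort`.
#' @param days_per_year conversion constant (default 365.25).
#' @return data.frame of class `clinical_table`: `patient`, `status`
#'   (`"alive"`/`"dead"`/`NA`), `time_years`, `cohort`.
#' @export
clinical_table <- function(df, days_per_year = 365.25) {
  need <- c("patient", "vital_status")
  if (!all(need %in% names(df)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  status <- tolower(trimws(as.character(df$vital_status)))
  status[!(status %in% c("alive", "dead"))] <- NA_character_
  d2d <- suppressWarnings(as.numeric(df$days_to_death %||% rep(NA, nrow(df))))
  d2f <- suppressWarnings(as.numeric(df$days_to_last_followup %||% rep(NA, nrow(df))))
  time <- ifelse(!is.na(status) & status == "dead", d2d, d2f)
  time <- time / days_per_year
  time[!is.na(time) & time < 0] <- NA_real_
  out <- data.frame(patient = as.character(df$patient), status = status,
                    time_years = time,
                    cohort = as.character(df$cohort %||% rep("cohort1", nrow(df))),
                    stringsAsFactors = FALSE)
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Stratify patients into high and low survival groups
#'
#' The threshold is the `q`-th quantile (default the 75th percentile,
#' linear-interpolation type 7) of all patients' observed times. The high
#' survival group contains patients censored alive strictly beyond the
#' threshold; the low survival group contains patients who died strictly
#' before it. Everyone else is excluded with a reason
#' (`alive-short-followup`, `dead-late`, `boundary`, `missing-status`,
#' `missing-time`).
#'
#' @param clin a [clinical_table()] (one cohort).
#' @param q quantile defining the threshold (default 0.75).
#' @param quantile_type passed to [stats::quantile()] (default 7).
#' @return list of class `survival_groups`: `high` and `low` patient id
#'   vectors, `threshold_years`, and `excluded` (patient, reason).
#' @export
stratify <- function(clin, q = 0.75, quantile_type = 7) {
  stopifnot(inherits(clin, "data.frame"))
  valid <- !is.na(clin$status) & !is.na(clin$time_years)
  if (!any(!is.na(clin$time_years))) stop("all observation times are missing")
  if (sum(valid) < 4L) stop("need >= 4 patients with valid status and time")
  thr <- unname(stats::quantile(clin$time_years[valid], probs = q,
                                type = quantile_type))
  high <- clin$patient[valid & clin$status == "alive" & clin$time_years > thr]
  low <- clin$patient[valid & clin$status == "dead" & clin$time_years < thr]
  reason <- rep(NA_character_, nrow(clin))
  reason[is.na(clin$status)] <- "missing-status"
  reason[!is.na(clin$status) & is.na(clin$time_years)] <- "missing-time"
  at_thr <- valid & clin$time_years == thr
  reason[valid & clin$status == "alive" & clin$time_years < thr] <- "alive-short-followup"
  reason[valid & clin$status == "dead" & clin$time_years > thr] <- "dead-late"
  reason[at_thr] <- "boundary"
  excl <- data.frame(patient = clin$patient[!is.na(reason)],
                     reason = reason[!is.na(reason)], stringsAsFactors = FALSE)
  structure(list(high = high, low = low, threshold_years = thr,
                 excluded = excl),
            class = "survival_groups")
}

#' @export
print.survival_groups <- function(x, ...) {
  cat("survival_groups: high n=", length(x$high), ", low n=", length(x$low),
      ", threshold=", signif(x$threshold_years, 4), " years, excluded n=",
      nrow(x$excluded), "\n", sep = "")
  invisible(x)
}

#' Stratify every cohort of a clinical table
#'
#' @param clin a [clinical_table()] spanning one or more cohorts.
#' @inheritParams stratify
#' @return named list of [stratify()] results, one per cohort.
#' @export
stratify_cohorts <- function(clin, q = 0.75, quantile_type = 7) {
  lapply(split(clin, clin$cohort), stratify, q = q, quantile_type = quantile_type)
}

#' Drop cohorts with too few patients in either survival group
#'
#' @param groups named list of `survival_groups` (per cohort).
#' @param min_n minimum group size (default 5).
#' @return the retained sublist; dropped cohorts are logged.
#' @export
exclude_cohorts <- function(groups, min_n = 5L) {
  ok <- vapply(groups, function(g)
    length(g$high) >= min_n && length(g$low) >= min_n, TRUE)
  if (any(!ok))
    log_note("cohort(s) dropped for n < ", min_n, " in a survival group: ",
             paste(names(groups)[!ok], collapse = ", "))
  groups[ok]
}
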