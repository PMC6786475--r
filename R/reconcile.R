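#' Reconcile fixation presence across timepoints with validation data
#'
#' In a clonal serial-passage experiment a fixation observed once is assumed
#' retained at every later timepoint, so a mutation is *verified* when the
#' validation assay (e.g. Sanger resequencing) confirms it at any timepoint;
#' presence is then imputed as monotone from the earliest evidence onward.
#' Mutations confirmed nowhere are *unverifiable* and must be excluded from
#' all downstream statistics. Verified mutations whose appearance passage
#' cannot be ordered (every timepoint before the first confirmation has a
#' missing assay result) are *time_unknown*: they count in totals but carry
#' `first_seen_timepoint = NA` and drop out of the accumulation regression.
#'
#' @param presence Tibble of sequencing-based presence: `mutation_id`,
#'   `population`, `timepoint`, `present` (logical). Timepoints are passage
#'   numbers.
#' @param validation Tibble of assay results: `mutation_id`, `timepoint`,
#'   `confirmed` (TRUE = confirmed, FALSE = confirmed absent, NA = assay
#'   uninformative).
#' @return Tibble with one row per mutation: `mutation_id`, `population`,
#'   `validation_status` (`verified` / `unverifiable` / `time_unknown`),
#'   `first_seen_timepoint`, `present_at` (list of timepoints with imputed
#'   presence), and `monotonicity_warning` (TRUE when the sequencing presence
#'   pattern shows a loss after first appearance).
#' @export
reconcile_timepoints <- function(presence, validation) {
  timepoints <- sort(unique(c(presence$timepoint, validation$timepoint)))
  per_mut <- presence |>
    group_by(.data$mutation_id, .data$population) |>
    summarise(ngs_seen = list(sort(unique(.data$timepoint[.data$present]))),
              .groups = "drop")
  per_mut |>
    mutate(res = map2(.data$mutation_id, .data$ngs_seen, function(id, seen) {
      v <- validation[validation$mutation_id == id, , drop = FALSE]
      confirmed_at <- sort(v$timepoint[!is.na(v$confirmed) & v$confirmed])
      if (length(confirmed_at) == 0) {
        return(tibble(validation_status = "unverifiable",
                      first_seen_timepoint = NA_real_,
                      present_at = list(numeric(0)),
                      monotonicity_warning = FALSE))
      }
      # earliest evidence from either sequencing or the validation assay
      first_seen <- min(c(confirmed_at, seen))
      warn_flag <- length(seen) > 0 &&
        any(setdiff(timepoints[timepoints >= min(seen)], seen) < max(seen))
      if (warn_flag) {
        warn(paste0("presence of ", id,
                    " is non-monotone across timepoints (loss after appearance)"))
      }
      earlier <- timepoints[timepoints < first_seen]
      informative_earlier <- v$timepoint[!is.na(v$confirmed)]
      status <- if (length(earlier) > 0 &&
                    !any(earlier %in% c(informative_earlier, seen))) {
        "time_unknown"
      } else {
        "verified"
      }
      tibble(validation_status = status,
             first_seen_timepoint = if (status == "verified") first_seen else NA_real_,
             present_at = list(timepoints[timepoints >= first_seen]),
             monotonicity_warning = warn_flag)
    })) |>
    tidyr::unnest("res") |>
    select("mutation_id", "population", "validation_status",
           "first_seen_timepoint", "present_at", "monotonicity_warning")
}
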