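# Classification of runs and participants. The class boundaries come from
# the Gaussian Mixture Model fitted over the original reference cohort's
# PLV distribution and are taken as printed constants (refitting is out of
# scope); a config escape hatch allows alternative thresholds.

#' The printed PLV classification thresholds
#'
#' Unreliable: PLV < 0.1 or PLV > 0.9. Low: 0.1 <= PLV < 0.4014.
#' Border: 0.4014 <= PLV <= 0.4113. High: 0.4113 < PLV <= 0.9.
#'
#' @return named list with `unreliable_low`, `border_low`, `border_high`,
#'   `unreliable_high`.
#' @export
plv_thresholds <- function() {
  list(unreliable_low = 0.1, border_low = 0.4014,
       border_high = 0.4113, unreliable_high = 0.9)
}

#' Classify a single task run from its PLV
#'
#' Exact application of the printed inequalities, including the closed/open
#' endpoints: 0.1 itself is low, 0.4113 itself is border, 0.9 itself is
#' high. The four classes partition \[0, 1\].
#'
#' @param plv a PLV in \[0, 1\].
#' @param thresholds threshold list (default [plv_thresholds()]).
#' @return object of class `run_classification`: `plv` and `label`, one of
#'   `"unreliable"`, `"low"`, `"border"`, `"high"`.
#' @export
classify_run <- function(plv, thresholds = plv_thresholds()) {
  stop_if_not_scalar_prob(plv)
  th <- thresholds
  label <-
    if (plv < th$unreliable_low || plv > th$unreliable_high) "unreliable"
    else if (plv < th$border_low) "low"
    else if (plv <= th$border_high) "border"
    else "high"
  structure(list(plv = plv, label = label), class = "run_classification")
}

classes_ordered <- c("low", "border", "high")

#' Combine two run classifications into a participant decision
#'
#' A participant is retained only when both runs fall into the same (low or
#' high) class after applying any manual border-case overrides; either run
#' being unreliable excludes the participant. Overrides are explicit records
#' (run number, new label, note) and may only move a label to an adjacent
#' class (e.g. border -> low); unreliable runs cannot be overridden. A
#' border case in both runs without an override is reported as excluded
#' pending override.
#'
#' @param run1,run2 [classify_run()] results.
#' @param overrides optional list of lists with fields `run` (1 or 2),
#'   `label` (new label) and `note`.
#' @return object of class `participant_decision`: `run1`, `run2`,
#'   `excluded`, `reasons` (character), `final_label` (`"low"`, `"high"` or
#'   `"none"`), `overrides_applied`.
#' @export
decide_participant <- function(run1, run2, overrides = NULL) {
  stopifnot(inherits(run1, "run_classification"),
            inherits(run2, "run_classification"))
  runs <- list(run1, run2)
  applied <- list()
  for (ov in overrides %||% list()) {
    r <- ov$run
    if (!r %in% 1:2) stop("override run must be 1 or 2")
    old <- runs[[r]]$label
    if (old == "unreliable")
      stop("cannot override an unreliable run")
    if (abs(match(ov$label, classes_ordered) - match(old, classes_ordered)) > 1)
      stop("override moves the label more than one adjacent class")
    runs[[r]]$label <- ov$label
    applied[[length(applied) + 1L]] <- ov
  }
  l1 <- runs[[1]]$label; l2 <- runs[[2]]$label
  reasons <- character(0)
  if (l1 == "unreliable" || l2 == "unreliable")
    reasons <- c(reasons, "unreliable_plv")
  if (!length(reasons) && l1 == "border" && l2 == "border")
    reasons <- c(reasons, "border_pending_override")
  if (!length(reasons) && (l1 != l2 || l1 == "border"))
    reasons <- c(reasons, "run_inconsistency")
  excluded <- length(reasons) > 0
  structure(list(run1 = runs[[1]], run2 = runs[[2]], excluded = excluded,
                 reasons = reasons,
                 final_label = if (excluded) "none" else l1,
                 overrides_applied = applied),
            class = "participant_decision")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Report which legacy exclusion criteria would fire
#'
#' Evaluates the original exclusion rules for comparison with the refined
#' pipeline (which removes gaps instead of excluding, and estimates an
#' articulation rate instead of applying the spoken-rate cutoff). Returned
#' for reporting only; the refined pipeline does not act on these.
#'
#' @param run_data list with elements `plv` (scalar), `spoken_rate` (Hz,
#'   onsets per second including silences) and `gaps` (a [gap_set()] of
#'   detected silent gaps).
#' @return character vector of triggered criterion names (possibly empty):
#'   `"plv_out_of_bounds"`, `"spoken_rate_le_2hz"`, `"silent_gap_gt_3s"`.
#' @export
legacy_exclusions <- function(run_data) {
  fired <- character(0)
  if (!is.null(run_data$plv) &&
      (run_data$plv > 0.9 || run_data$plv < 0.1))
    fired <- c(fired, "plv_out_of_bounds")
  if (!is.null(run_data$spoken_rate) && run_data$spoken_rate <= 2)
    fired <- c(fired, "spoken_rate_le_2hz")
  if (!is.null(run_data$gaps) && nrow(run_data$gaps$intervals) &&
      any(run_data$gaps$intervals$end - run_data$gaps$intervals$start > 3))
    fired <- c(fired, "silent_gap_gt_3s")
  fired
}
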