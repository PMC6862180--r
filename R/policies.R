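#' EDWIN-C diversion threshold for the persuasion factor
#'
#' Factor A is continuous on \[1, 3\]; its three integer levels anchor the
#' lower bounds of the published crowding intervals (1.5, 2.0, 2.5) and
#' intermediate values interpolate linearly:
#' `threshold = 1.5 + (A - 1) * 0.5`.
#'
#' @param factor_A persuasion level, real in \[1, 3\].
#' @return EDWIN-C threshold above which triage-4/5 arrivals are persuaded.
#' @export
diversion_threshold <- function(factor_A) {
  if (any(!is.finite(factor_A)) || any(factor_A < 1 | factor_A > 3))
    stop("factor_A must lie in [1, 3]")
  1.5 + (factor_A - 1) * 0.5
}

#' Decide whether an arriving patient is diverted to outpatient care
#'
#' Only triage-4/5 patients are candidates; they are persuaded when the
#' previous day's EDWIN-C reached [diversion_threshold()] for the scenario's
#' factor-A level, and persuasion succeeds with probability `p_divert`.
#'
#' @param triage triage level(s) 1..5.
#' @param prev_day_edwinc previous day's aggregated EDWIN-C (>= 0).
#' @param factor_A persuasion level in \[1, 3\].
#' @param p_divert persuasion success probability.
#' @param u optional uniform draw(s) (defaults to fresh draws); exposed so
#'   the event engine can use pre-drawn randomness.
#' @return logical: diverted?
#' @export
apply_diversion_policy <- function(triage, prev_day_edwinc, factor_A,
                                   p_divert = 1.0, u = NULL) {
  stopifnot(all(triage %in% 1:5), prev_day_edwinc >= 0)
  n <- max(length(triage), length(prev_day_edwinc))
  if (is.null(u)) u <- stats::runif(n)
  triage >= 4 &
    prev_day_edwinc >= diversion_threshold(factor_A) &
    u < p_divert
}

#' Plan a patient's checkup-room visiting order (factor B)
#'
#' Level 1 enforces the urine, CT, X-ray sequence. Level 2 puts currently
#' free rooms (scanned in the urine, CT, X-ray order) ahead of occupied
#' ones, so the patient visits the first free room still needed and
#' revisits skipped rooms later. Level 3 visits the needed rooms in a
#' uniformly random order.
#'
#' @param needed character vector, subset of `c("urine", "ct", "xray")`.
#' @param factor_B checkup-process level 1, 2 or 3.
#' @param occupied character vector of rooms currently occupied (used by
#'   level 2 only).
#' @return character vector: the planned visiting order of `needed`.
#' @export
route_checkup <- function(needed, factor_B, occupied = character()) {
  rooms <- c("urine", "ct", "xray")
  if (!all(needed %in% rooms)) stop("unknown exam room in `needed`")
  if (!factor_B %in% 1:3) stop("factor_B must be 1, 2 or 3")
  needed <- rooms[rooms %in% needed]  # canonical scan order
  switch(as.character(factor_B),
    "1" = needed,
    "2" = c(setdiff(needed, occupied), intersect(needed, occupied)),
    "3" = if (length(needed) > 1) sample(needed) else needed)
}

#' Internal-medicine bed-release quota (factor C)
#'
#' When the fraction of ED patients waiting for a sickbed exceeds the
#' level's threshold (15/20/25\%), the internal-medicine department releases
#' up to the level's quota of empty beds (5/10/15) to the ED.
#'
#' @param waiting_fraction fraction of ED patients boarding, in \[0, 1\].
#' @param factor_C bed-release level 1, 2 or 3.
#' @return integer quota (0 when the threshold is not exceeded).
#' @export
bed_release_quota <- function(waiting_fraction, factor_C) {
  if (any(waiting_fraction < 0 | waiting_fraction > 1))
    stop("waiting_fraction must lie in [0, 1]")
  if (!all(factor_C %in% 1:3)) stop("factor_C must be 1, 2 or 3")
  thr <- c(0.15, 0.20, 0.25)[factor_C]
  quota <- c(5L, 10L, 15L)[factor_C]
  ifelse(waiting_fraction > thr, quota, 0L)
}

#' Select the next triage-4/5 patient for physician exam (factor D)
#'
#' Triage 1-3 patients are dispatched by strict triage priority before this
#' rule is consulted; it orders only the non-urgent queue. Level 1 takes the
#' shortest expected exam first (ties by registration order), level 2 the
#' earliest registration, level 3 all triage-4 before any triage-5, within
#' class by registration order.
#'
#' @param queue data.frame of waiting triage-4/5 patients with columns
#'   `triage`, `reg_time` (queue-entry time) and `expected_exam` (minutes).
#' @param factor_D sequencing level 1, 2 or 3.
#' @return integer: the row index of the selected patient.
#' @export
next_patient <- function(queue, factor_D) {
  if (!NROW(queue)) stop("next_patient: queue is empty")
  stopifnot(all(queue$triage %in% 4:5), factor_D %in% 1:3)
  ord <- switch(as.character(factor_D),
    "1" = order(queue$expected_exam, queue$reg_time),
    "2" = order(queue$reg_time),
    "3" = order(queue$triage, queue$reg_time))
  ord[1]
}
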