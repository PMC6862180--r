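#' Emergency Department Work Index (EDWIN)
#'
#' EDWIN summarizes crowding as patient acuity load per physician per free
#' treatment bed: \deqn{EDWIN = \sum_i n_i t_i / (N_a (B_t - B_A))} where
#' \eqn{n_i} is the number of patients at triage level \eqn{i}, \eqn{t_i} the
#' acuity weight of that level, \eqn{N_a} the physicians on duty, \eqn{B_t}
#' the registered treatment beds and \eqn{B_A} the admitted (boarding)
#' patients occupying beds.
#'
#' @param counts integer vector of length 5, patients present at triage
#'   levels 1..5.
#' @param weights acuity weights \eqn{t_1..t_5}. The classic index weights
#'   level 5 as most urgent.
#' @param physicians_Na number of physicians on duty (>= 1).
#' @param beds_Bt registered ED treatment beds (>= 1).
#' @param admitted_BA admitted patients occupying ED beds (boarders).
#' @return non-negative numeric scalar.
#' @seealso [edwin_c()] for the Taiwan Triage and Acuity Scale variant.
#' @export
edwin <- function(counts, weights = 1:5, physicians_Na, beds_Bt, admitted_BA) {
  stopifnot(length(counts) == 5L, length(weights) == 5L)
  if (any(counts < 0) || physicians_Na < 1 || beds_Bt < 1 || admitted_BA < 0)
    stop("invalid EDWIN snapshot: counts/BA must be >= 0, Na and Bt >= 1")
  free <- beds_Bt - admitted_BA
  if (free <= 0)
    stop("degenerate denominator: no free treatment beds (Bt - BA <= 0)")
  sum(counts * weights) / (physicians_Na * free)
}

#' EDWIN transformed for the Taiwan Triage and Acuity Scale
#'
#' Under TTAS triage level 1 is the most urgent, the reverse of the original
#' EDWIN weighting, so the acuity weight of level \eqn{i} becomes
#' \eqn{6 - i}: \deqn{EDWIN^C = \sum_i n_i (6 - i) / (N_a (B_t - B_A))}
#'
#' @inheritParams edwin
#' @return non-negative numeric scalar.
#' @export
edwin_c <- function(counts, physicians_Na, beds_Bt, admitted_BA) {
  edwin(counts, weights = 6 - (1:5), physicians_Na = physicians_Na,
        beds_Bt = beds_Bt, admitted_BA = admitted_BA)
}

#' Classify an EDWIN-type index value into crowding states
#'
#' Values below 1.5 indicate a good state, values in [1.5, 2] a busy state
#' and values above 2 emergency department crowding. Both cutpoints are
#' assigned to "busy" (the published interval is closed at both ends).
#'
#' @param index_value non-negative numeric vector of index values.
#' @return factor with levels `good`, `busy`, `crowded`.
#' @export
classify_crowding <- function(index_value) {
  if (any(!is.finite(index_value)) || any(index_value < 0))
    stop("index values must be finite and >= 0")
  lab <- ifelse(index_value < 1.5, "good",
                ifelse(index_value <= 2, "busy", "crowded"))
  factor(lab, levels = c("good", "busy", "crowded"))
}

#' Per-patient system time
#'
#' Total time a patient spends in the ED: the sum of all waiting-room waits
#' \eqn{W_i} and all service-station times \eqn{S_j},
#' \deqn{ST = \sum_i W_i + \sum_j S_j} in minutes.
#'
#' @param waits numeric vector of waiting times (minutes), possibly empty.
#' @param services numeric vector of service times (minutes), possibly empty.
#' @return numeric scalar, minutes.
#' @export
system_time <- function(waits = numeric(), services = numeric()) {
  w <- as.numeric(waits); s <- as.numeric(services)
  if (any(!is.finite(c(w, s))) || any(c(w, s) < 0))
    stop("waits and services must be finite and >= 0")
  sum(w) + sum(s)
}
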