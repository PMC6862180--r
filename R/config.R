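#' Scenario configuration for one ED simulation replication
#'
#' Bundles every parameter of one EMS simulation run: the signal factor
#' (physicians on duty), the noise factor (daily arrival rate), the four
#' control-factor policy levels, resources, the triage mix, per-station
#' service-time distributions and the run horizon.
#'
#' Control factors:
#' \describe{
#'   \item{A (persuasion, continuous in \[1,3\])}{Triage-4/5 arrivals are
#'     persuaded to outpatient care when the previous day's EDWIN-C reaches
#'     a threshold of `1.5 + (A - 1) * 0.5` (levels 1/2/3 anchor the
#'     thresholds 1.5/2.0/2.5).}
#'   \item{B (checkup process, 1..3)}{1 = enforced urine - CT - X-ray
#'     sequence; 2 = visit the first free room still needed; 3 = random room
#'     order.}
#'   \item{C (bed release, 1..3)}{release 5/10/15 internal-medicine beds
#'     when more than 15/20/25\% of ED patients wait for a sickbed.}
#'   \item{D (triage-4/5 sequencing, 1..3)}{1 = shortest expected exam
#'     first; 2 = registration order; 3 = all triage 4 before triage 5.}
#' }
#'
#' @param signal_M physicians on duty, 1 or 2.
#' @param noise_lambda arrival rate, patients/day (study levels 350 and 425).
#' @param factor_A persuasion level, real in \[1, 3\].
#' @param factor_B,factor_C,factor_D policy levels in \{1, 2, 3\}.
#' @param beds_Bt registered ED treatment beds.
#' @param registration_servers parallel registration/triage desks.
#' @param exam_rooms named integer vector: rooms for `urine`, `ct`, `xray`.
#' @param triage_mix probability vector over triage levels 1..5 (sums to 1).
#' @param service_dists named list of per-station distribution specs, each
#'   `list(family, mean, sd)` with family one of `"lognormal"`,
#'   `"exponential"`, `"deterministic"`; stations `registration`,
#'   `physician`, `urine`, `ct`, `xray`. Minutes.
#' @param checkup_probs probability that a patient needs each checkup
#'   (named: urine, ct, xray).
#' @param admit_probs admission probability by triage level 1..5.
#' @param p_divert probability a persuaded triage-4/5 patient actually
#'   leaves (persuasion success).
#' @param horizon_days simulated days contributing arrivals and metrics.
#' @param warmup_days initial days excluded from response summaries.
#' @param edwinc_agg how hourly EDWIN-C values aggregate into the "previous
#'   day" value driving diversion: `"mean"`, `"max"` or `"last"`.
#' @param seed integer RNG seed for the replication.
#' @return an object of class `scenario_config` (a validated named list).
#' @export
scenario_config <- function(signal_M = 1L,
                            noise_lambda = 350,
                            factor_A = 1,
                            factor_B = 1L,
                            factor_C = 1L,
                            factor_D = 2L,
                            beds_Bt = 30L,
                            registration_servers = 2L,
                            exam_rooms = c(urine = 1L, ct = 1L, xray = 1L),
                            triage_mix = c(0.02, 0.08, 0.45, 0.35, 0.10),
                            service_dists = default_service_dists(),
                            checkup_probs = c(urine = 0.50, ct = 0.35, xray = 0.45),
                            admit_probs = c(0.90, 0.70, 0.40, 0.15, 0.05),
                            p_divert = 1.0,
                            horizon_days = 3L,
                            warmup_days = 1L,
                            edwinc_agg = c("mean", "max", "last"),
                            seed = 1L) {
  edwinc_agg <- match.arg(edwinc_agg)
  cfg <- list(
    signal_M = as.integer(signal_M), noise_lambda = as.numeric(noise_lambda),
    factor_A = as.numeric(factor_A), factor_B = as.integer(factor_B),
    factor_C = as.integer(factor_C), factor_D = as.integer(factor_D),
    beds_Bt = as.integer(beds_Bt),
    registration_servers = as.integer(registration_servers),
    exam_rooms = exam_rooms, triage_mix = as.numeric(triage_mix),
    service_dists = service_dists, checkup_probs = checkup_probs,
    admit_probs = as.numeric(admit_probs), p_divert = as.numeric(p_divert),
    horizon_days = as.integer(horizon_days),
    warmup_days = as.integer(warmup_days),
    edwinc_agg = edwinc_agg, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

#' Fixture defaults for per-station service-time distributions (minutes)
#'
#' The study hospital's service-time data is not published; these lognormal
#' mean/sd pairs are fixture values chosen to be plausible for an
#' internal-medicine ED and are fully configurable.
#' @return named list of distribution specs.
#' @export
default_service_dists <- function() {
  list(registration = list(family = "lognormal", mean = 5,  sd = 2),
       physician    = list(family = "lognormal", mean = 15, sd = 8),
       urine        = list(family = "lognormal", mean = 10, sd = 5),
       ct           = list(family = "lognormal", mean = 20, sd = 10),
       xray         = list(family = "lognormal", mean = 10, sd = 4))
}

validate_scenario_config <- function(cfg) {
  if (!cfg$signal_M %in% c(1L, 2L))
    stop("signal_M (physicians) must be 1 or 2")
  if (!is.finite(cfg$noise_lambda) || cfg$noise_lambda <= 0)
    stop("noise_lambda (arrival rate) must be > 0")
  if (cfg$factor_A < 1 || cfg$factor_A > 3)
    stop("factor_A must lie in [1, 3]")
  for (f in c("factor_B", "factor_C", "factor_D"))
    if (!cfg[[f]] %in% 1:3) stop(f, " must be one of 1, 2, 3")
  if (cfg$beds_Bt <= 0) stop("beds_Bt must be > 0")
  if (cfg$registration_servers <= 0) stop("registration_servers must be > 0")
  if (!all(c("urine", "ct", "xray") %in% names(cfg$exam_rooms)) ||
      any(cfg$exam_rooms <= 0))
    stop("exam_rooms must give positive counts for urine, ct and xray")
  if (length(cfg$triage_mix) != 5L || any(cfg$triage_mix < 0) ||
      abs(sum(cfg$triage_mix) - 1) > 1e-9)
    stop("triage_mix must be 5 non-negative probabilities summing to 1")
  stations <- c("registration", "physician", "urine", "ct", "xray")
  if (!all(stations %in% names(cfg$service_dists)))
    stop("service_dists must cover: ", paste(stations, collapse = ", "))
  for (st in stations) check_dist_spec(cfg$service_dists[[st]], st)
  if (!all(c("urine", "ct", "xray") %in% names(cfg$checkup_probs)) ||
      any(cfg$checkup_probs < 0 | cfg$checkup_probs > 1))
    stop("checkup_probs must be probabilities named urine, ct, xray")
  if (length(cfg$admit_probs) != 5L ||
      any(cfg$admit_probs < 0 | cfg$admit_probs > 1))
    stop("admit_probs must be 5 probabilities (triage 1..5)")
  if (cfg$p_divert < 0 || cfg$p_divert > 1) stop("p_divert must be in [0, 1]")
  if (cfg$horizon_days < 1) stop("horizon_days must be >= 1")
  if (cfg$warmup_days < 0 || cfg$warmup_days >= cfg$horizon_days)
    stop("warmup_days must be in [0, horizon_days)")
  cfg
}

check_dist_spec <- function(spec, station) {
  fam <- spec$family
  if (is.null(fam) || !fam %in% c("lognormal", "exponential", "deterministic"))
    stop("service_dists$", station,
         ": family must be lognormal, exponential or deterministic")
  if (is.null(spec$mean) || spec$mean < 0)
    stop("service_dists$", station, ": mean must be >= 0")
  if (fam == "lognormal" && (is.null(spec$sd) || spec$sd <= 0))
    stop("service_dists$", station, ": lognormal needs sd > 0")
  invisible(spec)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("ED scenario: M =", x$signal_M, "physicians, lambda =", x$noise_lambda,
      "patients/day\n")
  cat("  control factors A/B/C/D:", x$factor_A, x$factor_B, x$factor_C,
      x$factor_D, "\n")
  cat("  beds =", x$beds_Bt, "| horizon =", x$horizon_days, "d (warmup",
      x$warmup_days, "d) | seed =", x$seed, "\n")
  invisible(x)
}

#' Read and validate a scenario configuration from a YAML file
#'
#' Every field of [scenario_config()] is addressable by its argument name;
#' omitted keys take the defaults, unknown keys are rejected. Nested keys
#' (`service_dists`, `exam_rooms`, `checkup_probs`) follow the same names.
#'
#' @param path path to a YAML file (an empty file yields all defaults).
#' @param overrides named list applied on top of the file contents, e.g.
#'   `list(signal_M = 2, seed = 7)`.
#' @return a validated `scenario_config`.
#' @export
read_scenario_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  raw[names(overrides)] <- overrides
  allowed <- names(formals(scenario_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (nm in c("exam_rooms", "checkup_probs"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(scenario_config, raw)
}
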