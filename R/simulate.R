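#' Draw service times from a station's distribution spec
#'
#' Lognormal specs are parameterized by their natural-scale mean and sd
#' (converted internally to meanlog/sdlog); exponential by its mean;
#' deterministic returns the mean exactly.
#'
#' @param n number of draws.
#' @param spec `list(family, mean, sd)` as in [scenario_config()].
#' @return numeric vector of minutes, length `n`.
#' @export
draw_service_times <- function(n, spec) {
  check_dist_spec(spec, "spec")
  if (n == 0L) return(numeric(0))
  switch(spec$family,
    deterministic = rep(spec$mean, n),
    exponential = if (spec$mean == 0) rep(0, n) else
      stats::rexp(n, rate = 1 / spec$mean),
    lognormal = {
      if (spec$mean == 0) return(rep(0, n))
      sdlog2 <- log(1 + (spec$sd / spec$mean)^2)
      stats::rlnorm(n, meanlog = log(spec$mean) - sdlog2 / 2,
                    sdlog = sqrt(sdlog2))
    })
}

#' Run one replication of the ED discrete-event simulation
#'
#' Seeds the RNG from `config$seed`, generates the arrival population and
#' all stochastic quantities (service times, checkup needs, persuasion and
#' admission draws, random room orders), then executes the event-driven
#' patient flow: arrivals, optional diversion of triage-4/5 patients based
#' on the previous day's EDWIN-C (factor A), registration, physician exam
#' with strict triage 1-3 priority and factor-D ordering among triage 4/5,
#' checkup routing (factor B), and admission with boarding and hourly
#' factor-C bed releases. Arrivals stop at the horizon; the system then
#' drains so every patient has a disposition. Hourly EDWIN-C is recorded up
#' to the horizon only.
#'
#' @param config a [scenario_config()].
#' @param patients optional pre-built arrival table (columns `id`,
#'   `arrival_min`, `triage`) overriding the generated one; useful for
#'   hand-constructed scenarios.
#' @return an `ems_sim` object: list with `patients` (per-patient trace:
#'   waits, services, disposition, system time `st`), `hourly_edwinc`,
#'   `daily_edwinc`, `mean_ST`, `mean_EDWINC`, `config`.
#' @export
run_simulation <- function(config, patients = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  if (is.null(patients)) patients <- generate_patients(config)
  stopifnot(all(c("id", "arrival_min", "triage") %in% names(patients)))
  n <- nrow(patients)
  ord <- order(patients$arrival_min)
  patients <- patients[ord, , drop = FALSE]

  sd_ <- config$service_dists
  t_reg <- draw_service_times(n, sd_$registration)
  t_phys <- draw_service_times(n, sd_$physician)
  t_exam <- cbind(draw_service_times(n, sd_$urine),
                  draw_service_times(n, sd_$ct),
                  draw_service_times(n, sd_$xray))
  cp <- config$checkup_probs[c("urine", "ct", "xray")]
  need <- if (n) matrix(stats::runif(3 * n) <
                          rep(cp, each = n), nrow = n) else
    matrix(logical(0), nrow = 0, ncol = 3)
  u_divert <- stats::runif(n)
  u_admit <- stats::runif(n)
  perm <- matrix(rep(1:3, each = max(n, 1L)), nrow = max(n, 1L))[seq_len(n), ,
                                                                drop = FALSE]
  if (config$factor_B == 3L && n > 0) {
    keys <- matrix(stats::runif(3 * n), nrow = n)
    perm <- t(apply(keys, 1, order))
  }

  params <- list(
    signal_M = config$signal_M,
    registration_servers = config$registration_servers,
    exam_rooms = as.integer(config$exam_rooms[c("urine", "ct", "xray")]),
    beds_Bt = config$beds_Bt,
    factor_A = config$factor_A, factor_B = config$factor_B,
    factor_C = config$factor_C, factor_D = config$factor_D,
    p_divert = config$p_divert, admit_probs = config$admit_probs,
    horizon_min = config$horizon_days * 1440,
    edwinc_agg_code = match(config$edwinc_agg, c("mean", "max", "last")) - 1L)

  res <- .sim_engine_cpp(patients$arrival_min, as.integer(patients$triage),
                         t_reg, t_phys, t_exam, need, u_divert, u_admit,
                         perm, params)

  dispo <- c("diverted", "discharged", "admitted")[res$disposition + 1L]
  pt <- data.frame(
    id = patients$id, triage = patients$triage,
    arrival_min = patients$arrival_min,
    wait_registration = res$wait_reg, serv_registration = res$serv_reg,
    wait_physician = res$wait_phys, serv_physician = res$serv_phys,
    wait_urine = res$wait_exam[, 1], serv_urine = res$serv_exam[, 1],
    wait_ct = res$wait_exam[, 2], serv_ct = res$serv_exam[, 2],
    wait_xray = res$wait_exam[, 3], serv_xray = res$serv_exam[, 3],
    wait_bed = res$wait_bed,
    physician_start = res$phys_start,
    departure_min = res$departure,
    diverted = res$disposition == 0L,
    admitted = res$disposition == 2L,
    disposition = dispo)
  pt$st <- pt$departure_min - pt$arrival_min

  hr <- data.frame(time_min = res$hourly_time, edwinc = res$hourly_edwinc)
  hr$day <- ceiling(hr$time_min / 1440)
  daily <- if (nrow(hr)) stats::aggregate(edwinc ~ day, data = hr, FUN = mean)
           else data.frame(day = integer(0), edwinc = numeric(0))

  warm_min <- config$warmup_days * 1440
  keep_p <- !pt$diverted & pt$arrival_min >= warm_min
  keep_h <- hr$time_min > warm_min
  out <- list(
    patients = pt,
    hourly_edwinc = hr,
    daily_edwinc = daily,
    mean_ST = if (any(keep_p)) mean(pt$st[keep_p]) else NA_real_,
    mean_EDWINC = if (any(keep_h)) mean(hr$edwinc[keep_h]) else NA_real_,
    config = config)
  class(out) <- "ems_sim"
  out
}

#' @export
print.ems_sim <- function(x, ...) {
  n <- nrow(x$patients)
  cat("ED simulation:", n, "arrivals over", x$config$horizon_days, "days\n")
  cat(sprintf("  diverted %d | discharged %d | admitted %d\n",
              sum(x$patients$diverted),
              sum(x$patients$disposition == "discharged"),
              sum(x$patients$admitted)))
  cat(sprintf("  mean ST = %.1f min | mean EDWIN-C = %.3f (post warm-up)\n",
              x$mean_ST, x$mean_EDWINC))
  invisible(x)
}
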