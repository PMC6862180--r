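#' Inverse-transform exponential interarrival time
#'
#' Maps a uniform draw \eqn{\theta \in [0, 1)} to an interarrival time by
#' inverting the exponential CDF: \eqn{x = -\ln(1 - \theta) / \lambda}. With
#' \eqn{\theta \sim U(0,1)} this yields Poisson daily arrival counts at rate
#' `rate_per_day`.
#'
#' @param theta uniform draw(s) in \[0, 1).
#' @param rate_per_day arrival rate, patients/day.
#' @return interarrival time(s) in minutes.
#' @export
interarrival_from_uniform <- function(theta, rate_per_day) {
  if (rate_per_day <= 0) stop("rate_per_day must be > 0")
  if (any(theta < 0 | theta >= 1)) stop("theta must lie in [0, 1)")
  -log(1 - theta) / (rate_per_day / 1440)
}

#' Sample a stream of Poisson arrival times
#'
#' Successive interarrival gaps are drawn by [interarrival_from_uniform()]
#' from the current RNG stream and accumulated until the horizon is reached.
#'
#' @param rate_per_day arrival rate, patients/day (> 0).
#' @param horizon_days length of the arrival window in days (> 0).
#' @return strictly increasing arrival times in minutes, all within
#'   `[0, horizon_days * 1440)`.
#' @export
sample_interarrivals <- function(rate_per_day, horizon_days) {
  if (!is.finite(rate_per_day) || rate_per_day <= 0)
    stop("rate_per_day must be > 0")
  if (!is.finite(horizon_days) || horizon_days <= 0)
    stop("horizon_days must be > 0")
  horizon_min <- horizon_days * 1440
  # draw in blocks: expected count + 6 sd, then top up if the stream is short
  times <- numeric(0)
  last <- 0
  expected <- rate_per_day * horizon_days
  repeat {
    n_block <- max(64L, ceiling(expected + 6 * sqrt(expected)))
    gaps <- interarrival_from_uniform(stats::runif(n_block), rate_per_day)
    new <- last + cumsum(gaps)
    times <- c(times, new)
    last <- times[length(times)]
    if (last >= horizon_min) break
    expected <- rate_per_day * (horizon_min - last) / 1440
  }
  times[times < horizon_min]
}

#' Generate the arrival population for one scenario
#'
#' One patient per arrival event; triage levels are sampled i.i.d. from the
#' configured triage mix. Uses the current RNG stream ([run_simulation()]
#' seeds it from the scenario's `seed`).
#'
#' @param config a [scenario_config()].
#' @return data.frame with columns `id`, `arrival_min`, `triage`.
#' @export
generate_patients <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  arr <- sample_interarrivals(config$noise_lambda, config$horizon_days)
  n <- length(arr)
  triage <- if (n) sample.int(5L, n, replace = TRUE, prob = config$triage_mix)
            else integer(0)
  data.frame(id = seq_len(n), arrival_min = arr, triage = triage)
}
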