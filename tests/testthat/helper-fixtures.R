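# Shared fixtures, built in code at test time.

# A single-class stable queueing scenario: all-exponential physician
# service, instantaneous registration, no checkups, no admissions, no
# diversion candidates -- the physician station is then an M/M/c queue.
mmc_config <- function(lambda_day = 100, mean_service = 20, physicians = 2L,
                       horizon_days = 400L, warmup_days = 40L, seed = 1L) {
  scenario_config(
    signal_M = physicians, noise_lambda = lambda_day,
    triage_mix = c(0, 0, 1, 0, 0),
    service_dists = list(
      registration = list(family = "deterministic", mean = 0),
      physician = list(family = "exponential", mean = mean_service),
      urine = list(family = "deterministic", mean = 0),
      ct = list(family = "deterministic", mean = 0),
      xray = list(family = "deterministic", mean = 0)),
    checkup_probs = c(urine = 0, ct = 0, xray = 0),
    admit_probs = rep(0, 5),
    horizon_days = horizon_days, warmup_days = warmup_days, seed = seed)
}

# Erlang-C mean waiting time for an M/M/c queue (minutes).
mmc_wq <- function(lambda_day, mean_service, c_servers) {
  lam <- lambda_day / 1440
  mu <- 1 / mean_service
  a <- lam / mu
  rho <- a / c_servers
  stopifnot(rho < 1)
  p0_inv <- sum(a^(0:(c_servers - 1)) / factorial(0:(c_servers - 1))) +
    a^c_servers / (factorial(c_servers) * (1 - rho))
  erlang_c <- (a^c_servers / (factorial(c_servers) * (1 - rho))) / p0_inv
  erlang_c / (c_servers * mu - lam)
}

# Fast all-deterministic scenario used for engine-policy tests.
det_config <- function(..., exam_mean = 10) {
  scenario_config(
    service_dists = list(
      registration = list(family = "deterministic", mean = 0),
      physician = list(family = "deterministic", mean = exam_mean),
      urine = list(family = "deterministic", mean = 5),
      ct = list(family = "deterministic", mean = 5),
      xray = list(family = "deterministic", mean = 5)),
    ...)
}

# Synthetic dynamic-response generator with planted factor effects: the
# ideal-function slope grows at the planted A/B/C levels while the
# noise-factor sensitivity of the response shrinks at the planted D level,
# so the setting with maximal dynamic SN (printed beta/MSE form) is known
# by construction.
planted_response_table <- function(n_rep = 1000, seed = 1,
                                   planted = c(A = 3, B = 1, C = 2, D = 2)) {
  set.seed(seed)
  plan <- build_plan(replications = 1L)
  cells <- plan$cells
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    beta <- 1 + 0.4 * (cl$A == planted[["A"]]) + 0.3 * (cl$B == planted[["B"]]) +
      0.3 * (cl$C == planted[["C"]])
    delta <- ifelse(cl$D == planted[["D"]], 0.05, 0.15)  # noise sensitivity
    z <- ifelse(cl$Z == 425, 1, -1)
    y <- (beta + delta * z) * cl$M + rnorm(n_rep, 0, 0.3)
    data.frame(cl, rep = seq_len(n_rep), mean_ST = y, mean_EDWINC = y,
               row.names = NULL)
  })
  do.call(rbind, out)
}

# Exhaustive-grid oracle for the mixed-space fitness maximization.
grid_oracle <- function(fitness, a_step = 0.01) {
  grid <- expand.grid(A = seq(1, 3, by = a_step), B = 1:3, C = 1:3, D = 1:3,
                      KEEP.OUT.ATTRS = FALSE)
  f <- fitness(grid)
  grid[which.max(f), ]
}

# Planted mixed-space test fitness: maximized at A = 2.5, B = 1, C = 2,
# D = 2 (additive penalties force the discrete genes).
planted_fitness <- function(pop) {
  -(pop$A - 2.5)^2 - 0.3 * (pop$B != 1) - 0.3 * (pop$C != 2) -
    0.3 * (pop$D != 2)
}
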