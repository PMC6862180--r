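test_that("a lone patient's system time is the sum of its services", {
  cfg <- scenario_config(
    service_dists = list(
      registration = list(family = "deterministic", mean = 10),
      physician = list(family = "deterministic", mean = 20),
      urine = list(family = "deterministic", mean = 0),
      ct = list(family = "deterministic", mean = 0),
      xray = list(family = "deterministic", mean = 0)),
    checkup_probs = c(urine = 0, ct = 0, xray = 0),
    admit_probs = rep(0, 5),
    horizon_days = 1L, warmup_days = 0L, seed = 1L)
  one <- data.frame(id = 1L, arrival_min = 100, triage = 3L)
  sim <- run_simulation(cfg, patients = one)
  p <- sim$patients
  expect_equal(p$st, 30)  # 10 + 20, no queueing
  expect_equal(p$wait_registration + p$wait_physician, 0)
  expect_equal(p$departure_min, 130)
  expect_equal(sim$mean_ST, 30)
})

test_that("identical seeds give identical simulation results", {
  cfg <- scenario_config(horizon_days = 2L, warmup_days = 0L, seed = 77L)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$patients, s2$patients)
  expect_identical(s1$hourly_edwinc, s2$hourly_edwinc)
  s3 <- run_simulation(scenario_config(horizon_days = 2L, warmup_days = 0L,
                                       seed = 78L))
  expect_false(identical(s1$patients$st, s3$patients$st))
})

test_that("patient accounting is conserved and traces are consistent", {
  cfg <- scenario_config(horizon_days = 2L, warmup_days = 0L, seed = 42L)
  sim <- run_simulation(cfg)
  p <- sim$patients
  expect_true(all(p$disposition %in% c("diverted", "discharged", "admitted")))
  expect_equal(sum(table(p$disposition)), nrow(p))
  wait_cols <- grep("^wait_", names(p), value = TRUE)
  serv_cols <- grep("^serv_", names(p), value = TRUE)
  expect_true(all(as.matrix(p[c(wait_cols, serv_cols)]) >= 0))
  expect_true(all(p$departure_min >= p$arrival_min))
  # per-patient ST equals total waits + services along the trace
  tot <- rowSums(p[wait_cols]) + rowSums(p[serv_cols])
  expect_equal(p$st[!p$diverted], tot[!p$diverted], tolerance = 1e-9)
  # diverted patients receive no service and leave on arrival
  expect_true(all(tot[p$diverted] == 0))
  expect_true(all(p$st[p$diverted] == 0))
  expect_true(all(sim$hourly_edwinc$edwinc >= 0))
  expect_equal(nrow(sim$hourly_edwinc), cfg$horizon_days * 24)
})

test_that("adding a physician does not worsen mean system time", {
  for (sd in c(1L, 2L, 3L)) {
    s1 <- run_simulation(scenario_config(signal_M = 1L, horizon_days = 2L,
                                         warmup_days = 0L, seed = sd))
    s2 <- run_simulation(scenario_config(signal_M = 2L, horizon_days = 2L,
                                         warmup_days = 0L, seed = sd))
    expect_lte(s2$mean_ST, s1$mean_ST + 1)
  }
})

test_that("a stable single-class scenario reproduces M/M/c waiting times", {
  cfg <- mmc_config(lambda_day = 100, mean_service = 20, physicians = 2L,
                    horizon_days = 400L, warmup_days = 40L, seed = 9L)
  sim <- run_simulation(cfg)
  p <- sim$patients
  keep <- p$arrival_min >= 40 * 1440
  wq_sim <- mean(p$wait_physician[keep])
  wq_theory <- mmc_wq(100, 20, 2)
  expect_equal(wq_sim, wq_theory, tolerance = 0.08)
  # and the service-time mean is as configured
  expect_equal(mean(p$serv_physician[keep]), 20, tolerance = 0.05)
})

test_that("factor D orders the triage-4/5 physician queue in the engine", {
  pats <- data.frame(id = 1:3, arrival_min = c(0, 1, 2),
                     triage = c(3L, 5L, 4L))
  base <- function(D) det_config(signal_M = 1L, factor_D = D,
                                 checkup_probs = c(urine = 0, ct = 0, xray = 0),
                                 admit_probs = rep(0, 5),
                                 horizon_days = 1L, warmup_days = 0L,
                                 exam_mean = 50)
  s2 <- run_simulation(base(2L), patients = pats)  # registration order
  expect_lt(s2$patients$physician_start[s2$patients$id == 2],
            s2$patients$physician_start[s2$patients$id == 3])
  s3 <- run_simulation(base(3L), patients = pats)  # triage 4 first
  expect_lt(s3$patients$physician_start[s3$patients$id == 3],
            s3$patients$physician_start[s3$patients$id == 2])
})

test_that("factor D level 1 serves the shortest expected exam first", {
  # direct engine call so per-patient exam durations can differ
  n <- 3L
  params <- list(signal_M = 1L, registration_servers = 2L,
                 exam_rooms = c(1L, 1L, 1L), beds_Bt = 30L,
                 factor_A = 1, factor_B = 1L, factor_C = 1L, factor_D = 1L,
                 p_divert = 1, admit_probs = rep(0, 5),
                 horizon_min = 1440, edwinc_agg_code = 0L)
  res <- emsopt:::.sim_engine_cpp(
    arr = c(0, 1, 2), triage = c(3L, 4L, 5L),
    t_reg = rep(0, n), t_phys = c(50, 30, 12),
    t_exam = matrix(0, n, 3), need_exam = matrix(FALSE, n, 3),
    u_divert = rep(1, n), u_admit = rep(1, n),
    perm = matrix(rep(1:3, each = n), n), params = params)
  expect_lt(res$phys_start[3], res$phys_start[2])
  expect_equal(res$phys_start[1], 0)
})

test_that("diversion activates from the second day via previous-day EDWIN-C", {
  cfg <- det_config(noise_lambda = 400, triage_mix = c(0, 0, 0, 0, 1),
                    factor_A = 1, horizon_days = 2L, warmup_days = 0L,
                    checkup_probs = c(urine = 0, ct = 0, xray = 0),
                    admit_probs = rep(0, 5), exam_mean = 30, seed = 12L)
  sim <- run_simulation(cfg)
  p <- sim$patients
  day2 <- p$arrival_min >= 1440
  expect_true(all(!p$diverted[!day2]))  # day 1: no previous-day signal
  expect_gt(sim$daily_edwinc$edwinc[1], 1.5)
  expect_true(all(p$diverted[day2]))    # overloaded day 1 triggers persuasion
})

test_that("admitted patients board and leave at hourly bed releases", {
  cfg <- det_config(noise_lambda = 200, admit_probs = rep(1, 5),
                    factor_C = 2L, horizon_days = 1L, warmup_days = 0L,
                    checkup_probs = c(urine = 0, ct = 0, xray = 0),
                    exam_mean = 5, seed = 4L)
  sim <- run_simulation(cfg)
  p <- sim$patients
  adm <- p[p$admitted, ]
  expect_gt(nrow(adm), 0)
  expect_true(all(adm$departure_min %% 60 == 0))
  expect_true(all(adm$wait_bed >= 0))
  expect_true(all(!p$diverted))
})
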