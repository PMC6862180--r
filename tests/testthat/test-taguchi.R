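test_that("the L9 array is balanced and orthogonal", {
  m <- l9_array()
  expect_equal(dim(m), c(9L, 4L))
  expect_equal(unname(m[1, ]), c(1, 1, 1, 1))
  for (j in 1:4) expect_equal(as.vector(table(m[, j])), rep(3L, 3))
  for (j1 in 1:3) for (j2 in (j1 + 1):4) {
    pairs <- paste(m[, j1], m[, j2])
    expect_setequal(pairs, paste(rep(1:3, each = 3), rep(1:3, 3)))
  }
})

test_that("the crossed plan has 36 unique cells and degenerates correctly", {
  plan <- build_plan(replications = 5L)
  expect_equal(nrow(plan$cells), 36L)
  expect_equal(anyDuplicated(plan$cells[c("row", "M", "Z")]), 0L)
  # factor columns agree with the inner array
  expect_equal(unname(as.matrix(plan$cells[c("A", "B", "C", "D")])),
               unname(l9_array()[plan$cells$row, ]))
  p9 <- build_plan(signal_levels = 1, noise_levels = 350)
  expect_equal(nrow(p9$cells), 9L)
  expect_error(build_plan(signal_levels = c(1, 1)), "distinct")
  # plan construction is deterministic (no RNG involved)
  expect_identical(build_plan(replications = 3L)$cells,
                   build_plan(replications = 3L)$cells)
})

test_that("the zero-intercept fit matches hand and grid-search results", {
  ft <- fit_ideal_function(c(1, 1, 2, 2), c(1.1, 0.9, 2.2, 1.8))
  expect_equal(ft$beta, 1.0)
  expect_equal(ft$mse, 0.1 / 3, tolerance = 1e-12)
  perfect <- fit_ideal_function(c(1, 2, 3), 2 * c(1, 2, 3))
  expect_equal(perfect$beta, 2)
  expect_equal(perfect$mse, 0)
  # brute-force SSE minimization oracle (iterated grid refinement)
  grid_min <- function(M, y) {
    lo <- -10; hi <- 10
    for (pass in 1:8) {
      b <- seq(lo, hi, length.out = 401)
      sse <- vapply(b, function(bb) sum((y - bb * M)^2), numeric(1))
      i <- which.min(sse)
      lo <- b[max(1, i - 1)]; hi <- b[min(401, i + 1)]
    }
    (lo + hi) / 2
  }
  set.seed(2024)
  for (k in 1:25) {
    M <- sample(c(1, 2), 6, replace = TRUE)
    y <- rnorm(6, 1.5 * M, 0.4)
    expect_equal(fit_ideal_function(M, y)$beta, grid_min(M, y),
                 tolerance = 1e-6)
  }
  expect_error(fit_ideal_function(1, 2), "at least 2")
  expect_error(fit_ideal_function(c(0, 0), c(1, 2)), "zero")
})

test_that("the dynamic SN ratio follows the printed decibel form", {
  expect_equal(sn_ratio(1, 1)$sn_db, 0)
  expect_equal(sn_ratio(1, 0.1 / 3)$sn_db, 10 * log10(30))
  expect_equal(round(sn_ratio(1, 0.1 / 3)$sn_db, 2), 14.77)
  # a decade in MSE is exactly 10 dB
  expect_equal(sn_ratio(2, 0.5)$sn_db - sn_ratio(2, 5)$sn_db, 10)
  # negative slopes enter by magnitude, with the sign reported
  expect_equal(sn_ratio(-2, 0.5)$sn_db, sn_ratio(2, 0.5)$sn_db)
  expect_equal(sn_ratio(-2, 0.5)$beta_sign, -1)
  # conventional variant uses beta^2
  expect_equal(sn_ratio(3, 0.5, variant = "conventional")$sn_db,
               10 * log10(9 / 0.5))
  expect_error(sn_ratio(1, 0), "mse")
  expect_error(sn_ratio(0, 1), "beta")
})

test_that("main effects aggregate by L9 balance and predict additively", {
  m <- l9_array()
  tab <- data.frame(row = 1:9, A = m[, 1], B = m[, 2], C = m[, 3],
                    D = m[, 4], beta = 1, mse = 1, sn_db = as.numeric(m[, 1]),
                    beta_sign = 1)
  eff <- main_effects(tab)
  expect_equal(eff$mean_sn[eff$factor == "A"], c(1, 2, 3))
  for (f in c("B", "C", "D"))
    expect_equal(eff$mean_sn[eff$factor == f], rep(2, 3))
  # partition identity: level means x 3 sum to the total per factor
  for (f in c("A", "B", "C", "D"))
    expect_equal(sum(eff$mean_sn[eff$factor == f] * 3), sum(tab$sn_db))
  sel <- select_optimal_levels(eff)
  expect_equal(unname(sel$levels["A"]), 3L)
  expect_setequal(sel$ties, c("B", "C", "D"))  # flat factors tie at level 1
  expect_equal(unname(sel$levels[c("B", "C", "D")]), rep(1L, 3))
  # constant table: any level optimal, prediction equals the constant
  tabc <- tab; tabc$sn_db <- 5
  selc <- select_optimal_levels(main_effects(tabc))
  expect_equal(unname(selc$levels), rep(1L, 4))
  expect_equal(selc$predicted_sn_db, 5)
})

test_that("level selection recovers planted factor effects", {
  hits <- 0L
  n_trials <- 20L
  for (tr in seq_len(n_trials)) {
    resp <- planted_response_table(n_rep = 1000, seed = 1000 + tr)
    tab <- sn_table(resp, response = "mean_ST")
    sel <- select_optimal_levels(main_effects(tab))
    if (identical(unname(sel$levels), c(3L, 1L, 2L, 2L))) hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.95)
})
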