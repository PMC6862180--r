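constant_model <- function(d1, d2) {
  # a degenerate fitness standing in for a surrogate with constant output
  function(pop) rep(total_performance(d1, d2), nrow(pop))
}

test_that("fitness composes surrogate predictions into TP", {
  f1 <- constant_model(1, 1)
  expect_equal(f1(data.frame(A = c(1, 2.5), B = 1, C = 1, D = 1)), c(1, 1))
  f2 <- constant_model(0.5, 0.8)
  expect_equal(f2(data.frame(A = 2, B = 1, C = 2, D = 3)), 0.32)
})

test_that("surrogate fitness aggregates over signal/noise combinations", {
  cells <- build_plan(replications = 1L)$cells
  cells$d1 <- d_ramp_up(cells$M + cells$Z / 1000, 1, 3)
  cells$d2 <- 0.8
  tt <- build_training_table(cells, seed = 1)
  model <- train_surrogate(tt, hidden_nodes = 4, iterations = 2000, seed = 2)
  pop <- data.frame(A = c(1, 2, 3), B = 1, C = 2, D = 2)
  tp_mean <- evaluate_fitness(pop, model, aggregation = "mean")
  tp_worst <- evaluate_fitness(pop, model, aggregation = "worst")
  expect_true(all(tp_worst <= tp_mean + 1e-12))
  expect_true(all(tp_mean >= 0 & tp_mean <= 1))
  # nominal fixes one (M, Z) combination
  tp_nom <- evaluate_fitness(pop, model, aggregation = "nominal",
                             nominal = c(M = 2, Z = 350))
  expect_length(tp_nom, 3L)
})

test_that("the GA recovers a planted mixed-space optimum vs a grid oracle", {
  oracle <- grid_oracle(planted_fitness)
  expect_equal(oracle$A, 2.5, tolerance = 1e-9)
  expect_equal(c(oracle$B, oracle$C, oracle$D), c(1, 2, 2))
  hits <- 0L
  for (sd in 1:20) {
    opt <- optimize_factors(planted_fitness,
                            ga_config(generations = 150, population = 40,
                                      seed = sd))
    ok <- abs(opt$setting$A - oracle$A) <= 0.1 &&
      opt$setting$B == oracle$B && opt$setting$C == oracle$C &&
      opt$setting$D == oracle$D
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.95)
})

test_that("the best-so-far trace is non-decreasing and bounds hold", {
  opt <- optimize_factors(planted_fitness,
                          ga_config(generations = 100, population = 30,
                                    seed = 3))
  expect_true(all(diff(opt$history) >= 0))
  expect_true(opt$setting$A >= 1 && opt$setting$A <= 3)
  expect_true(all(unlist(opt$setting[c("B", "C", "D")]) %in% 1:3))
})

test_that("the GA is seed-deterministic and dominates random search", {
  o1 <- optimize_factors(planted_fitness,
                         ga_config(generations = 60, population = 30,
                                   seed = 11))
  o2 <- optimize_factors(planted_fitness,
                         ga_config(generations = 60, population = 30,
                                   seed = 11))
  expect_identical(o1$setting, o2$setting)
  expect_identical(o1$history, o2$history)
  set.seed(99)
  rand <- data.frame(A = runif(1000, 1, 3),
                     B = sample.int(3, 1000, TRUE),
                     C = sample.int(3, 1000, TRUE),
                     D = sample.int(3, 1000, TRUE))
  expect_gte(o1$tp, max(planted_fitness(rand)))
})

test_that("with no variation operators the initial best is returned", {
  flat <- function(pop) -(pop$A - 2)^2
  opt <- optimize_factors(flat, ga_config(generations = 30, population = 20,
                                          crossover_rate = 0,
                                          mutation_rate = 0, seed = 5))
  set.seed(5)
  init <- data.frame(A = runif(20, 1, 3), B = sample.int(3, 20, TRUE),
                     C = sample.int(3, 20, TRUE), D = sample.int(3, 20, TRUE))
  expect_equal(opt$tp, max(flat(init)))
})
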