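make_cells_with_targets <- function(target_fun, noise_sd = 0, seed = 1) {
  set.seed(seed)
  cells <- build_plan(replications = 1L)$cells
  x <- data.frame(
    m = (cells$M - 1), z = (cells$Z - 350) / 75, a = (cells$A - 1) / 2,
    b = (cells$B - 1) / 2, cc = (cells$C - 1) / 2, d = (cells$D - 1) / 2)
  tg <- target_fun(x)
  cells$d1 <- pmin(1, pmax(0, tg$d1 + rnorm(nrow(cells), 0, noise_sd)))
  cells$d2 <- pmin(1, pmax(0, tg$d2 + rnorm(nrow(cells), 0, noise_sd)))
  cells$mean_EDWINC <- cells$d1
  cells$mean_ST <- cells$d2
  cells
}

smooth_targets <- function(x) {
  list(d1 = 0.15 + 0.7 * plogis(2 * (x$a + x$b - x$m - 0.5)),
       d2 = 0.15 + 0.7 * plogis(2 * (x$d + 0.5 * x$cc - x$z)))
}

test_that("the train/test split uses the round-half-up rule and is seeded", {
  cells <- make_cells_with_targets(smooth_targets)
  tt <- build_training_table(cells, split = 0.8, seed = 5)
  expect_equal(sum(tt$is_train), 29L)  # round-half-up(0.8 * 36)
  expect_equal(sum(!tt$is_train), 7L)
  tt2 <- build_training_table(cells, split = 0.8, seed = 5)
  expect_identical(tt$is_train, tt2$is_train)
  tt3 <- build_training_table(cells, split = 0.8, seed = 6)
  expect_false(identical(tt$is_train, tt3$is_train))
  # inputs scaled into [0,1] with recorded affine maps
  expect_true(all(tt$X >= 0 & tt$X <= 1))
  expect_equal(unname(tt$scalers$lo), c(1, 350, 1, 1, 1, 1))
})

test_that("training is deterministic and can overfit an easy table", {
  cells <- make_cells_with_targets(smooth_targets)
  tt <- build_training_table(cells, seed = 1)
  m1 <- train_surrogate(tt, hidden_nodes = 5, iterations = 3000, seed = 2)
  m2 <- train_surrogate(tt, hidden_nodes = 5, iterations = 3000, seed = 2)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_lt(m1$rmse_train, 0.05)
  pred <- predict(m1, cells)
  expect_true(all(pred >= 0 & pred <= 1))
})

test_that("the surrogate recovers a planted smooth response (3-sigma rule)", {
  sigma <- 0.02
  cells <- make_cells_with_targets(smooth_targets, noise_sd = sigma, seed = 9)
  tt <- build_training_table(cells, seed = 3)
  model <- train_surrogate(tt, hidden_nodes = 5, iterations = 10000, seed = 4)
  expect_lte(model$rmse_test, 3 * sigma)
})

test_that("architecture search returns the test-RMSE argmin over 2..8", {
  cells <- make_cells_with_targets(smooth_targets, noise_sd = 0.02, seed = 11)
  tt <- build_training_table(cells, seed = 7)
  out <- architecture_search(tt, hidden_range = 2:8, iterations = 2000,
                             seed = 13)
  expect_equal(nrow(out$comparison), 7L)
  expect_equal(out$comparison$structure[1], "6-2-2")
  expect_equal(out$comparison$structure[7], "6-8-2")
  expect_true(all(out$comparison$rmse_train >= 0))
  best_h <- out$comparison$hidden[which.min(out$comparison$rmse_test)]
  expect_equal(unname(out$best$structure["hidden"]), best_h)
  # reproducible under the same seeds
  out2 <- architecture_search(tt, hidden_range = 2:8, iterations = 2000,
                              seed = 13)
  expect_equal(out$comparison$rmse_test, out2$comparison$rmse_test)
})

test_that("predictions are continuous in factor A and clamp out-of-range", {
  cells <- make_cells_with_targets(smooth_targets)
  tt <- build_training_table(cells, seed = 1)
  model <- train_surrogate(tt, hidden_nodes = 4, iterations = 1500, seed = 2)
  nd <- data.frame(M = 2, Z = 350, A = 2.3, B = 1, C = 2, D = 2)
  nd2 <- nd; nd2$A <- 2.3 + 1e-6
  expect_lt(max(abs(predict(model, nd) - predict(model, nd2))), 1e-4)
  nd_out <- nd; nd_out$A <- 5
  expect_warning(p_out <- predict(model, nd_out), "clamped")
  nd_edge <- nd; nd_edge$A <- 3
  expect_equal(p_out, predict(model, nd_edge))
})

test_that("surrogate models survive a JSON round trip", {
  cells <- make_cells_with_targets(smooth_targets)
  tt <- build_training_table(cells, seed = 1)
  model <- train_surrogate(tt, hidden_nodes = 3, iterations = 500, seed = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_surrogate(model, f)
  back <- read_surrogate(f)
  nd <- cells[c(1, 10, 30), ]
  expect_equal(predict(back, nd), predict(model, nd), tolerance = 1e-12)
  expect_equal(back$rmse_test, model$rmse_test, tolerance = 1e-12)
})
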