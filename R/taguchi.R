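#' The standard L9(3^4) orthogonal array
#'
#' Nine runs accommodating four three-level factors; each level appears
#' three times per column and any two columns form the full 3 x 3 grid of
#' ordered level pairs.
#'
#' @return 9 x 4 integer matrix with columns `A`, `B`, `C`, `D`.
#' @export
l9_array <- function() {
  m <- matrix(c(1, 1, 1, 1,
                1, 2, 2, 2,
                1, 3, 3, 3,
                2, 1, 2, 3,
                2, 2, 3, 1,
                2, 3, 1, 2,
                3, 1, 3, 2,
                3, 2, 1, 3,
                3, 3, 2, 1), ncol = 4, byrow = TRUE)
  colnames(m) <- c("A", "B", "C", "D")
  m
}

#' Build the crossed simulation plan: L9 inner array x signal x noise
#'
#' Crosses the 9 inner-array control settings with the signal levels
#' (physicians) and noise levels (arrival rates), yielding the 36-cell
#' plan each simulated `replications` times.
#'
#' @param signal_levels physicians on duty, default `c(1, 2)`.
#' @param noise_levels arrival rates (patients/day), default `c(350, 425)`.
#' @param replications replications per cell (>= 1).
#' @param base_config a [scenario_config()] supplying everything the plan
#'   does not vary.
#' @return a `design_plan`: list with `cells` (data.frame: `cell`, `row`,
#'   `M`, `Z`, `A`..`D`), `inner_rows`, `replications`, `base_config`.
#' @export
build_plan <- function(signal_levels = c(1L, 2L),
                       noise_levels = c(350, 425),
                       replications = 20L,
                       base_config = scenario_config()) {
  if (anyDuplicated(signal_levels) || anyDuplicated(noise_levels))
    stop("signal and noise levels must be distinct")
  if (replications < 1) stop("replications must be >= 1")
  inner <- l9_array()
  grid <- expand.grid(row = seq_len(nrow(inner)),
                      M = signal_levels, Z = noise_levels,
                      KEEP.OUT.ATTRS = FALSE)
  cells <- data.frame(cell = seq_len(nrow(grid)), grid,
                      inner[grid$row, , drop = FALSE])
  plan <- list(cells = cells, inner_rows = inner,
               replications = as.integer(replications),
               base_config = base_config)
  class(plan) <- "design_plan"
  plan
}

#' Simulate every cell of a design plan
#'
#' Runs `replications` independent simulation replications per cell;
#' replication seeds are derived deterministically from `seed` by a counter
#' scheme (`seed + cell * 1000 + rep`), so individual cells can be re-run
#' in isolation.
#'
#' @param plan a [build_plan()] object.
#' @param seed master seed for the whole plan.
#' @return data.frame with one row per (cell, replication): the cell tags
#'   plus responses `mean_ST` (minutes) and `mean_EDWINC`.
#' @export
simulate_plan <- function(plan, seed = 1L) {
  stopifnot(inherits(plan, "design_plan"))
  cells <- plan$cells
  out <- vector("list", nrow(cells) * plan$replications)
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    cl <- cells[ci, ]
    for (r in seq_len(plan$replications)) {
      cfg <- plan$base_config
      cfg$signal_M <- as.integer(cl$M)
      cfg$noise_lambda <- as.numeric(cl$Z)
      cfg$factor_A <- as.numeric(cl$A)
      cfg$factor_B <- as.integer(cl$B)
      cfg$factor_C <- as.integer(cl$C)
      cfg$factor_D <- as.integer(cl$D)
      cfg$seed <- as.integer((seed + cl$cell * 1000 + r) %% .Machine$integer.max)
      cfg <- validate_scenario_config(cfg)
      sim <- run_simulation(cfg)
      k <- k + 1L
      out[[k]] <- data.frame(cl, rep = r, seed = cfg$seed,
                             mean_ST = sim$mean_ST,
                             mean_EDWINC = sim$mean_EDWINC)
    }
  }
  do.call(rbind, out)
}

#' Average replicate responses to cell means
#'
#' @param responses output of [simulate_plan()].
#' @return data.frame with one row per cell: tags plus `mean_ST`,
#'   `mean_EDWINC` averaged over replications.
#' @export
cell_means <- function(responses) {
  stats::aggregate(cbind(mean_ST, mean_EDWINC) ~ cell + row + M + Z +
                     A + B + C + D,
                   data = responses, FUN = mean)
}

#' Zero-intercept ideal-function fit
#'
#' Fits the dynamic ideal function \eqn{y_{ij} = \beta M_j} by least
#' squares through the origin: \eqn{\beta = \sum M y / \sum M^2}. MSE is
#' the mean squared distance of the responses from the fitted line, with
#' denominator `n - 1` by default (`n` optionally).
#'
#' @param M_values signal-level values.
#' @param y_values responses, same length.
#' @param mse_denominator `"n-1"` (default) or `"n"`.
#' @return list with `beta`, `mse`, `n`.
#' @export
fit_ideal_function <- function(M_values, y_values,
                               mse_denominator = c("n-1", "n")) {
  mse_denominator <- match.arg(mse_denominator)
  M <- as.numeric(M_values); y <- as.numeric(y_values)
  if (length(M) != length(y)) stop("M and y must have equal length")
  if (length(M) < 2) stop("need at least 2 points to fit the ideal function")
  if (all(M == 0)) stop("signal values must not all be zero")
  beta <- sum(M * y) / sum(M^2)
  denom <- if (mse_denominator == "n-1") length(M) - 1 else length(M)
  mse <- sum((y - beta * M)^2) / denom
  list(beta = beta, mse = mse, n = length(M))
}

#' Dynamic signal-to-noise ratio (decibels)
#'
#' The printed form is \eqn{SN = 10 \log_{10}(\beta / MSE)}; the
#' conventional dynamic SN uses \eqn{\beta^2}. Since the slope may be
#' negative, its absolute value enters the numerator and the sign is
#' returned alongside.
#'
#' @param beta fitted slope (non-zero).
#' @param mse mean squared error (> 0).
#' @param variant `"printed"` (beta/MSE) or `"conventional"` (beta^2/MSE).
#' @return list with `sn_db`, `beta_sign`.
#' @export
sn_ratio <- function(beta, mse, variant = c("printed", "conventional")) {
  variant <- match.arg(variant)
  if (!is.finite(mse) || mse <= 0)
    stop("mse must be > 0 (zero MSE gives an infinite SN ratio)")
  if (!is.finite(beta) || beta == 0) stop("beta must be non-zero")
  num <- if (variant == "printed") abs(beta) else beta^2
  list(sn_db = 10 * log10(num / mse), beta_sign = sign(beta))
}

#' Per-row dynamic SN table for one response
#'
#' For each L9 inner row, the responses entering the zero-intercept fit are
#' the cell means over replications at each (signal, noise) cell; pooling
#' across noise lets noise variation contribute to the MSE (the robustness
#' reading of the dynamic design). `pool_noise = FALSE` instead fits per
#' noise level and averages the SN ratios.
#'
#' @param responses output of [simulate_plan()].
#' @param response `"mean_ST"` or `"mean_EDWINC"`.
#' @param variant passed to [sn_ratio()].
#' @param pool_noise pool noise levels into one fit per row (default TRUE).
#' @return data.frame: one row per inner row with factor levels, `beta`,
#'   `mse`, `sn_db`, `beta_sign`.
#' @export
sn_table <- function(responses, response = c("mean_EDWINC", "mean_ST"),
                     variant = c("printed", "conventional"),
                     pool_noise = TRUE) {
  response <- match.arg(response)
  variant <- match.arg(variant)
  cm <- cell_means(responses)
  rows <- sort(unique(cm$row))
  if (length(rows) != 9) stop("SN table needs the complete 9-row inner array")
  res <- lapply(rows, function(r) {
    d <- cm[cm$row == r, ]
    if (pool_noise) {
      ft <- fit_ideal_function(d$M, d[[response]])
      sn <- sn_ratio(ft$beta, ft$mse, variant)
      beta <- ft$beta; mse <- ft$mse; sn_db <- sn$sn_db
    } else {
      per <- lapply(split(d, d$Z), function(dz) {
        ft <- fit_ideal_function(dz$M, dz[[response]])
        c(ft$beta, ft$mse, sn_ratio(ft$beta, ft$mse, variant)$sn_db)
      })
      per <- do.call(rbind, per)
      beta <- mean(per[, 1]); mse <- mean(per[, 2]); sn_db <- mean(per[, 3])
    }
    data.frame(row = r, A = d$A[1], B = d$B[1], C = d$C[1], D = d$D[1],
               beta = beta, mse = mse, sn_db = sn_db,
               beta_sign = sign(beta))
  })
  out <- do.call(rbind, res)
  attr(out, "response") <- response
  out
}

#' Main effects of the control factors on the SN ratio
#'
#' L9 balance guarantees each (factor, level) pair is visited by exactly
#' three rows; the main effect is the mean SN over those rows.
#'
#' @param sn_tab output of [sn_table()] (9 complete rows).
#' @return data.frame with columns `factor`, `level`, `mean_sn`.
#' @export
main_effects <- function(sn_tab) {
  if (nrow(sn_tab) != 9 || anyNA(sn_tab$sn_db))
    stop("main_effects needs a complete 9-row SN table")
  out <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(f) {
    data.frame(factor = f, level = 1:3,
               mean_sn = vapply(1:3, function(l)
                 mean(sn_tab$sn_db[sn_tab[[f]] == l]), numeric(1)))
  }))
  attr(out, "overall_mean") <- mean(sn_tab$sn_db)
  out
}

#' Select the SN-optimal level per factor and predict the optimum SN
#'
#' Picks, per factor, the level with the largest mean SN (ties toward the
#' lower level index) and predicts the SN at the combined setting by the
#' standard additive model: overall mean plus the sum of chosen-level
#' deviations.
#'
#' @param effects output of [main_effects()].
#' @return list with `levels` (named vector A..D), `predicted_sn_db`,
#'   `ties` (factors whose optimum was tied).
#' @export
select_optimal_levels <- function(effects) {
  overall <- attr(effects, "overall_mean")
  if (is.null(overall)) overall <- mean(effects$mean_sn)
  facs <- c("A", "B", "C", "D")
  lv <- integer(length(facs)); names(lv) <- facs
  ties <- character(0)
  pred <- overall
  for (f in facs) {
    e <- effects[effects$factor == f, ]
    best <- e$level[which.max(e$mean_sn)]  # which.max: lowest index on ties
    if (sum(e$mean_sn == max(e$mean_sn)) > 1) ties <- c(ties, f)
    lv[f] <- best
    pred <- pred + (max(e$mean_sn) - overall)
  }
  list(levels = lv, predicted_sn_db = pred, ties = ties)
}
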