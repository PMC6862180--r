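round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Adjusted TP percentage relative to the optimum
#'
#' The sensitivity tables report each swept level's total performance as a
#' percentage change from the optimum:
#' \deqn{adjusted\ TP\% = (TP_{level} - TP_{opt}) / TP_{opt} \times 100}
#' rounded half-away-from-zero to two decimals, matching the published
#' table style.
#'
#' @param tp_level TP at the swept level (> 0 typical; >= 0 allowed).
#' @param tp_opt TP at the optimum (> 0).
#' @return percentage(s), two decimals.
#' @export
adjusted_tp_percent <- function(tp_level, tp_opt) {
  if (any(!is.finite(tp_opt)) || any(tp_opt <= 0))
    stop("tp_opt must be > 0")
  round_half_away((tp_level - tp_opt) / tp_opt * 100, 2)
}

#' One-factor-at-a-time sensitivity sweep around the optimum
#'
#' Holding the other factors at their optimal values, factor A is swept
#' over a 0.2-step grid from 1 to 3 (11 points) and each discrete factor
#' over its levels \{1, 2, 3\}; each table reports the TP at every level
#' and its [adjusted_tp_percent()] relative to the optimum's TP. TP is
#' evaluated through the same fitness used by the GA (surrogate prediction
#' aggregated over the signal/noise combinations).
#'
#' @param fitness an `ems_surrogate` or a fitness function, as in
#'   [optimize_factors()].
#' @param optimum an `ems_optimum` (or a list with `setting` and `tp`).
#' @param a_grid sweep grid for factor A.
#' @param ... passed to [evaluate_fitness()] when `fitness` is a surrogate.
#' @return named list of data.frames (`A`, `B`, `C`, `D`), each with
#'   columns `level`, `tp`, `adjusted_tp_percent`, `is_optimum`.
#' @export
ofat_sweep <- function(fitness, optimum, a_grid = seq(1, 3, by = 0.2), ...) {
  fit_fun <- if (inherits(fitness, "ems_surrogate")) {
    model <- fitness
    function(pop) evaluate_fitness(pop, model, ...)
  } else {
    stopifnot(is.function(fitness))
    fitness
  }
  s <- optimum$setting
  tp_opt <- optimum$tp
  sweep_one <- function(factor_id, grid) {
    pop <- data.frame(A = s$A, B = s$B, C = s$C, D = s$D)[rep(1, length(grid)), ]
    pop[[factor_id]] <- grid
    tp <- fit_fun(pop)
    is_opt <- abs(grid - s[[factor_id]]) < 1e-9
    tp[is_opt] <- tp_opt  # the optimum cell reports the optimum's TP
    data.frame(level = grid, tp = tp,
               adjusted_tp_percent = ifelse(is_opt, 0,
                                            adjusted_tp_percent(tp, tp_opt)),
               is_optimum = is_opt)
  }
  list(A = sweep_one("A", a_grid),
       B = sweep_one("B", 1:3),
       C = sweep_one("C", 1:3),
       D = sweep_one("D", 1:3))
}
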