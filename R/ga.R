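#' GA configuration
#'
#' Defaults follow the study settings: 1000 generations, population 80,
#' crossover rate 0.5, mutation rate 0.08.
#'
#' @param generations number of generations (>= 1).
#' @param population population size (>= 2).
#' @param crossover_rate probability a selected pair is recombined.
#' @param mutation_rate per-gene mutation probability.
#' @param sigma_A standard deviation of the Gaussian perturbation applied
#'   to factor A on mutation (clamped back to \[1, 3\]).
#' @param seed RNG seed.
#' @return a `ga_config` list.
#' @export
ga_config <- function(generations = 1000L, population = 80L,
                      crossover_rate = 0.5, mutation_rate = 0.08,
                      sigma_A = 0.1, seed = 1L) {
  if (generations < 1 || population < 2)
    stop("need generations >= 1 and population >= 2")
  if (any(c(crossover_rate, mutation_rate) < 0) ||
      any(c(crossover_rate, mutation_rate) > 1))
    stop("rates must lie in [0, 1]")
  structure(list(generations = as.integer(generations),
                 population = as.integer(population),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 sigma_A = sigma_A, seed = as.integer(seed)),
            class = "ga_config")
}

#' Total-performance fitness of factor settings under a surrogate
#'
#' The GA optimizes only the control factors; the surrogate also takes the
#' signal and noise levels, so predictions are aggregated over the four
#' (M, Z) study combinations — by their mean (default), worst case, or a
#' fixed nominal combination — before TP = d1 * d2^2 is formed.
#'
#' @param chromosomes data.frame with columns `A`, `B`, `C`, `D` (one row
#'   per chromosome).
#' @param model an `ems_surrogate`.
#' @param aggregation `"mean"`, `"worst"` or `"nominal"`.
#' @param signal_levels,noise_levels the study levels to aggregate over.
#' @param nominal `c(M, Z)` used when `aggregation = "nominal"`.
#' @return numeric vector of TP values, one per chromosome.
#' @export
evaluate_fitness <- function(chromosomes, model,
                             aggregation = c("mean", "worst", "nominal"),
                             signal_levels = c(1, 2),
                             noise_levels = c(350, 425),
                             nominal = c(M = 2, Z = 350)) {
  aggregation <- match.arg(aggregation)
  n <- nrow(chromosomes)
  combos <- if (aggregation == "nominal")
    data.frame(M = nominal[["M"]], Z = nominal[["Z"]])
  else expand.grid(M = signal_levels, Z = noise_levels,
                   KEEP.OUT.ATTRS = FALSE)
  k <- nrow(combos)
  newdata <- data.frame(
    M = rep(combos$M, each = n), Z = rep(combos$Z, each = n),
    A = rep(chromosomes$A, k), B = rep(chromosomes$B, k),
    C = rep(chromosomes$C, k), D = rep(chromosomes$D, k))
  pred <- predict(model, newdata)
  d1 <- matrix(pred[, "d1"], nrow = n)
  d2 <- matrix(pred[, "d2"], nrow = n)
  if (aggregation == "worst") {
    a1 <- apply(d1, 1, min); a2 <- apply(d2, 1, min)
  } else {
    a1 <- rowMeans(d1); a2 <- rowMeans(d2)
  }
  total_performance(a1, a2)
}

clamp_A <- function(a) pmin(3, pmax(1, a))

#' Genetic-algorithm search for the TP-optimal factor setting
#'
#' Chromosomes mix a continuous gene (factor A in \[1, 3\]) with three
#' discrete genes (factors B, C, D in \{1, 2, 3\}). Operators: binary
#' tournament selection; arithmetic (blend) crossover on A and uniform
#' level swap on B/C/D, applied to a pair with probability
#' `crossover_rate`; mutation perturbs A by a clamped Gaussian and
#' re-draws discrete genes uniformly, per gene with probability
#' `mutation_rate`; one elite survives unconditionally, so the best-so-far
#' trace is non-decreasing.
#'
#' @param fitness either an `ems_surrogate` (fitness is then
#'   [evaluate_fitness()] with `...` forwarded) or a function taking a
#'   chromosome data.frame (`A`, `B`, `C`, `D`) and returning a numeric
#'   vector.
#' @param config a [ga_config()].
#' @param ... passed to [evaluate_fitness()] when `fitness` is a surrogate.
#' @return an `ems_optimum`: list with `setting` (named list A..D), `tp`,
#'   `history` (best fitness per generation), `config`.
#' @export
optimize_factors <- function(fitness, config = ga_config(), ...) {
  stopifnot(inherits(config, "ga_config"))
  fit_fun <- if (inherits(fitness, "ems_surrogate")) {
    model <- fitness
    function(pop) evaluate_fitness(pop, model, ...)
  } else {
    stopifnot(is.function(fitness))
    fitness
  }
  set.seed(config$seed)
  P <- config$population
  pop <- data.frame(A = stats::runif(P, 1, 3),
                    B = sample.int(3, P, replace = TRUE),
                    C = sample.int(3, P, replace = TRUE),
                    D = sample.int(3, P, replace = TRUE))
  history <- numeric(config$generations)
  fit <- fit_fun(pop)
  for (g in seq_len(config$generations)) {
    elite_i <- which.max(fit)
    # binary tournament selection
    cand <- matrix(sample.int(P, 2 * P, replace = TRUE), ncol = 2)
    winners <- ifelse(fit[cand[, 1]] >= fit[cand[, 2]],
                      cand[, 1], cand[, 2])
    nxt <- pop[winners, , drop = FALSE]
    rownames(nxt) <- NULL
    # pairwise crossover
    for (j in seq(1, P - 1, by = 2)) {
      if (stats::runif(1) < config$crossover_rate) {
        u <- stats::runif(1)
        a1 <- nxt$A[j]; a2 <- nxt$A[j + 1]
        nxt$A[j] <- u * a1 + (1 - u) * a2
        nxt$A[j + 1] <- (1 - u) * a1 + u * a2
        for (f in c("B", "C", "D")) if (stats::runif(1) < 0.5) {
          tmp <- nxt[[f]][j]
          nxt[[f]][j] <- nxt[[f]][j + 1]
          nxt[[f]][j + 1] <- tmp
        }
      }
    }
    # mutation (per gene)
    mutA <- stats::runif(P) < config$mutation_rate
    if (any(mutA))
      nxt$A[mutA] <- clamp_A(nxt$A[mutA] +
                               stats::rnorm(sum(mutA), 0, config$sigma_A))
    for (f in c("B", "C", "D")) {
      mutf <- stats::runif(P) < config$mutation_rate
      if (any(mutf)) nxt[[f]][mutf] <- sample.int(3, sum(mutf), replace = TRUE)
    }
    # elitism: carry the incumbent best into slot 1
    nxt[1, ] <- pop[elite_i, ]
    pop <- nxt
    fit <- fit_fun(pop)
    history[g] <- max(fit)
    if (g > 1) history[g] <- max(history[g], history[g - 1])
  }
  best <- which.max(fit)
  out <- list(setting = list(A = pop$A[best], B = pop$B[best],
                             C = pop$C[best], D = pop$D[best]),
              tp = fit[best], history = history, config = config)
  class(out) <- "ems_optimum"
  out
}

#' @export
print.ems_optimum <- function(x, ...) {
  cat(sprintf("GA optimum: A = %.2f, B = %d, C = %d, D = %d | TP = %.3f\n",
              x$setting$A, x$setting$B, x$setting$C, x$setting$D, x$tp))
  invisible(x)
}
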