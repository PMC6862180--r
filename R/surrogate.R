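sigmoid <- function(x) 1 / (1 + exp(-x))

#' Assemble the surrogate training table from the 36-cell responses
#'
#' One row per design cell: the six inputs (signal M, noise Z, factors
#' A..D) are scaled to \[0, 1\] by affine maps recorded in the table, and
#' the targets are the cell's desirabilities (d1, d2). Rows are split into
#' train/test by a seeded shuffle; the train count is
#' `round-half-up(split * n)`.
#'
#' @param cells output of [add_desirabilities()] on the cell means (must
#'   contain `M`, `Z`, `A`..`D`, `d1`, `d2`).
#' @param split train fraction (default 0.8).
#' @param seed seed for the shuffle.
#' @return a `training_table`: list with `X` (scaled inputs), `Y`
#'   (targets), `is_train`, `scalers`, `cells`.
#' @export
build_training_table <- function(cells, split = 0.8, seed = 1L) {
  req <- c("M", "Z", "A", "B", "C", "D", "d1", "d2")
  if (!all(req %in% names(cells)) || anyNA(cells[req]))
    stop("cells must contain complete columns ", paste(req, collapse = ", "))
  n <- nrow(cells)
  raw <- as.matrix(cells[, c("M", "Z", "A", "B", "C", "D")])
  lo <- apply(raw, 2, min); hi <- apply(raw, 2, max)
  rng <- ifelse(hi > lo, hi - lo, 1)
  X <- sweep(sweep(raw, 2, lo), 2, rng, "/")
  Y <- as.matrix(cells[, c("d1", "d2")])
  n_train <- min(n, max(1L, floor(split * n + 0.5)))  # round half up
  set.seed(seed)
  ord <- sample.int(n)
  is_train <- logical(n)
  is_train[ord[seq_len(n_train)]] <- TRUE
  out <- list(X = X, Y = Y, is_train = is_train,
              scalers = list(lo = lo, range = rng), cells = cells)
  class(out) <- "training_table"
  out
}

#' Train the feed-forward neural-network surrogate
#'
#' A single-hidden-layer perceptron with sigmoid activations on the hidden
#' and output layers (outputs therefore live in \[0, 1\] like the
#' desirability targets). Training is full-batch backpropagation on the
#' joint mean-squared error of both outputs, with momentum and a
#' bold-driver adaptive learning rate (multiplied by 1.05 after an
#' improving iteration, halved after a worsening one, clamped to
#' `[lr_min, lr_max]`).
#'
#' @param table a [build_training_table()] object.
#' @param hidden_nodes hidden-layer width (>= 1).
#' @param iterations training iterations (default 10000).
#' @param momentum momentum coefficient (default 0.65).
#' @param lr_min,lr_max learning-rate clamp (defaults 0.01 and 0.5).
#' @param seed seed for the weight initialization.
#' @return an `ems_surrogate`: weights, scalers, `rmse_train`, `rmse_test`,
#'   training metadata.
#' @export
train_surrogate <- function(table, hidden_nodes = 5L, iterations = 10000L,
                            momentum = 0.65, lr_min = 0.01, lr_max = 0.5,
                            seed = 1L) {
  stopifnot(inherits(table, "training_table"), hidden_nodes >= 1)
  Xtr <- table$X[table$is_train, , drop = FALSE]
  Ytr <- table$Y[table$is_train, , drop = FALSE]
  if (!nrow(Xtr)) stop("empty training set")
  p <- ncol(Xtr); q <- ncol(Ytr); h <- as.integer(hidden_nodes)
  set.seed(seed)
  W1 <- matrix(stats::runif(p * h, -0.5, 0.5), p, h)
  b1 <- stats::runif(h, -0.5, 0.5)
  W2 <- matrix(stats::runif(h * q, -0.5, 0.5), h, q)
  b2 <- stats::runif(q, -0.5, 0.5)
  vW1 <- matrix(0, p, h); vb1 <- numeric(h)
  vW2 <- matrix(0, h, q); vb2 <- numeric(q)
  lr <- lr_min
  prev_loss <- Inf
  ntr <- nrow(Xtr)
  for (it in seq_len(iterations)) {
    H <- sigmoid(sweep(Xtr %*% W1, 2, b1, "+"))
    O <- sigmoid(sweep(H %*% W2, 2, b2, "+"))
    err <- O - Ytr
    loss <- mean(err^2)
    lr <- if (loss < prev_loss) min(lr * 1.05, lr_max) else max(lr * 0.5, lr_min)
    prev_loss <- loss
    dO <- (2 / (ntr * q)) * err * O * (1 - O)
    gW2 <- crossprod(H, dO); gb2 <- colSums(dO)
    dH <- (dO %*% t(W2)) * H * (1 - H)
    gW1 <- crossprod(Xtr, dH); gb1 <- colSums(dH)
    vW2 <- momentum * vW2 - lr * gW2; W2 <- W2 + vW2
    vb2 <- momentum * vb2 - lr * gb2; b2 <- b2 + vb2
    vW1 <- momentum * vW1 - lr * gW1; W1 <- W1 + vW1
    vb1 <- momentum * vb1 - lr * gb1; b1 <- b1 + vb1
  }
  model <- list(structure = c(input = p, hidden = h, output = q),
                W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                scalers = table$scalers,
                meta = list(iterations = iterations, momentum = momentum,
                            lr_min = lr_min, lr_max = lr_max, seed = seed))
  class(model) <- "ems_surrogate"
  model$rmse_train <- surrogate_rmse(model, table, train = TRUE)
  model$rmse_test <- surrogate_rmse(model, table, train = FALSE)
  model
}

surrogate_forward <- function(model, X_scaled) {
  H <- sigmoid(sweep(X_scaled %*% model$W1, 2, model$b1, "+"))
  O <- sigmoid(sweep(H %*% model$W2, 2, model$b2, "+"))
  colnames(O) <- c("d1", "d2")
  O
}

surrogate_rmse <- function(model, table, train) {
  keep <- if (train) table$is_train else !table$is_train
  if (!any(keep)) return(NA_real_)
  pred <- surrogate_forward(model, table$X[keep, , drop = FALSE])
  sqrt(mean((pred - table$Y[keep, , drop = FALSE])^2))
}

#' Predict desirabilities from the surrogate
#'
#' Inputs are scaled by the training-time affine maps; values outside the
#' training ranges are clamped with a warning. Factor A may be fractional.
#'
#' @param object an `ems_surrogate`.
#' @param newdata data.frame with columns `M`, `Z`, `A`, `B`, `C`, `D`.
#' @param ... unused.
#' @return matrix with columns `d1`, `d2`, values in \[0, 1\].
#' @export
predict.ems_surrogate <- function(object, newdata, ...) {
  raw <- as.matrix(newdata[, c("M", "Z", "A", "B", "C", "D")])
  X <- sweep(sweep(raw, 2, object$scalers$lo), 2, object$scalers$range, "/")
  if (any(X < -1e-9 | X > 1 + 1e-9)) {
    warning("inputs outside the training ranges were clamped")
    X <- pmin(1, pmax(0, X))
  }
  surrogate_forward(object, X)
}

#' @export
print.ems_surrogate <- function(x, ...) {
  s <- x$structure
  cat(sprintf("NN surrogate %d-%d-%d | RMSE train %.4f / test %.4f\n",
              s[1], s[2], s[3], x$rmse_train, x$rmse_test))
  invisible(x)
}

#' Search over hidden-layer widths for the best surrogate
#'
#' Trains one model per hidden-node count and selects the structure with
#' the minimal test RMSE (ties toward the smaller network).
#'
#' @param table a [build_training_table()].
#' @param hidden_range candidate hidden widths (default 2:8).
#' @param ... passed to [train_surrogate()] (iterations, seed, ...).
#' @return list with `best` (the selected `ems_surrogate`) and
#'   `comparison` (data.frame: hidden, rmse_train, rmse_test).
#' @export
architecture_search <- function(table, hidden_range = 2:8, ...) {
  stopifnot(length(hidden_range) >= 1)
  models <- lapply(hidden_range, function(h)
    train_surrogate(table, hidden_nodes = h, ...))
  comparison <- data.frame(
    hidden = hidden_range,
    structure = sprintf("%d-%d-%d", ncol(table$X), hidden_range,
                        ncol(table$Y)),
    rmse_train = vapply(models, `[[`, numeric(1), "rmse_train"),
    rmse_test = vapply(models, `[[`, numeric(1), "rmse_test"))
  best <- which.min(comparison$rmse_test)
  list(best = models[[best]], comparison = comparison)
}

#' Serialize a surrogate model to portable JSON
#' @param model an `ems_surrogate`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_surrogate <- function(model, path) {
  obj <- list(structure = unname(model$structure),
              W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              scaler_lo = unname(model$scalers$lo),
              scaler_range = unname(model$scalers$range),
              meta = model$meta,
              rmse_train = model$rmse_train, rmse_test = model$rmse_test)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a surrogate model written by [write_surrogate()]
#' @param path JSON file.
#' @return an `ems_surrogate`.
#' @export
read_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  inputs <- c("M", "Z", "A", "B", "C", "D")
  model <- list(
    structure = c(input = obj$structure[1], hidden = obj$structure[2],
                  output = obj$structure[3]),
    W1 = matrix(obj$W1, nrow = obj$structure[1], byrow = FALSE),
    b1 = as.numeric(obj$b1),
    W2 = matrix(obj$W2, nrow = obj$structure[2], byrow = FALSE),
    b2 = as.numeric(obj$b2),
    scalers = list(lo = stats::setNames(obj$scaler_lo, inputs),
                   range = stats::setNames(obj$scaler_range, inputs)),
    meta = obj$meta,
    rmse_train = obj$rmse_train, rmse_test = obj$rmse_test)
  class(model) <- "ems_surrogate"
  model
}
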