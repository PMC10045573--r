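elm_activations <- list(
  sigmoid = function(x) 1 / (1 + exp(-x)),
  tanh = tanh,
  relu = function(x) pmax(x, 0)
)

as_target_matrix <- function(y) {
  if (is.matrix(y)) return(y)
  matrix(as.numeric(y), ncol = 1L)
}

#' Hidden-layer output matrix of an ELM
#'
#' `H[j, i] = g(W_i . X_j + b_i)` for every sample `j` and hidden unit `i`.
#'
#' @param model An `elm_model` (or any list with `W`, `b`, `activation`).
#' @param X Feature matrix, one sample per row.
#' @return The `N x L` hidden output matrix.
#' @export
hidden_output <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$W)) {
    stop("feature count ", ncol(X), " does not match model input size ",
         ncol(model$W), call. = FALSE)
  }
  g <- elm_activations[[model$activation]]
  pre <- X %*% t(model$W)
  pre <- sweep(pre, 2L, model$b, `+`)
  g(pre)
}

elm_solve_beta <- function(H, T, ridge) {
  if (ridge == 0) {
    MASS::ginv(H) %*% T
  } else {
    L <- ncol(H)
    solve(crossprod(H) + diag(ridge, L), crossprod(H, T))
  }
}

new_elm_model <- function(W, b, beta, activation, ridge) {
  structure(list(W = W, b = b, beta = beta, activation = activation,
                 L = nrow(W), ridge = ridge),
            class = "elm_model")
}

#' Train an extreme learning machine
#'
#' Input weights `W` and biases `b` are drawn uniformly from `[-1, 1]`;
#' the output weights are the minimum-norm least-squares solution
#' `beta = pinv(H) T` via the Moore-Penrose pseudoinverse (`ridge = 0`),
#' or the Tikhonov-stabilized solve otherwise.  With `L = N` distinct
#' samples and `ridge = 0` the network interpolates the targets (training
#' residual at numerical zero).
#'
#' @param X Feature matrix, one sample per row.
#' @param y Targets: a vector of 0/1 labels, a factor/integer vector of
#'   classes (one-hot encoded internally), or a numeric target matrix.
#' @param L Number of hidden neurons.
#' @param activation `"sigmoid"`, `"tanh"` or `"relu"`.
#' @param seed RNG seed for the random input layer.
#' @param ridge Tikhonov regularization; 0 gives the exact pseudoinverse.
#' @return An `elm_model`.
#' @export
elm_train <- function(X, y, L = 100, activation = "sigmoid", seed = 1,
                      ridge = 1e-8) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite features", call. = FALSE)
  stopifnot(L >= 1)
  activation <- match.arg(activation, names(elm_activations))
  T <- as_target_matrix(y)
  stopifnot(nrow(T) == nrow(X))
  set.seed(seed)
  W <- matrix(stats::runif(L * ncol(X), -1, 1), nrow = L)
  b <- stats::runif(L, -1, 1)
  model <- new_elm_model(W, b, beta = NULL, activation, ridge)
  H <- hidden_output(model, X)
  model$beta <- elm_solve_beta(H, T, ridge)
  model
}

#' @export
print.elm_model <- function(x, ...) {
  cat("<elm_model> ", x$L, " hidden units (", x$activation, "), ",
      ncol(x$W), " inputs -> ", ncol(x$beta), " outputs",
      if (!is.null(attr(x, "coa"))) "  [COA-selected input weights]",
      "\n", sep = "")
  invisible(x)
}

#' Predict class labels with a trained ELM
#'
#' Multi-column outputs take the argmax; a single-column output is
#' thresholded at 0.5, with the tie at exactly 0.5 labeled 1.
#'
#' @param model A trained `elm_model`.
#' @param X Feature matrix.
#' @return Integer labels (0/1 for binary, 1-based class index otherwise).
#' @export
elm_predict <- function(model, X) {
  if (is.null(model$beta)) stop("model has no output weights", call. = FALSE)
  O <- hidden_output(model, X) %*% model$beta
  if (ncol(O) == 1L) {
    as.integer(O >= 0.5)
  } else {
    max.col(O, ties.method = "first")
  }
}

elm_raw_output <- function(model, X) hidden_output(model, X) %*% model$beta

stratified_split <- function(y, val_fraction, seed) {
  set.seed(seed)
  cls <- if (is.matrix(y) && ncol(y) > 1L) max.col(y) else as.vector(y)
  val <- integer(0)
  for (c in unique(cls)) {
    idx <- which(cls == c)
    n_val <- max(1L, round(val_fraction * length(idx)))
    if (n_val >= length(idx)) n_val <- length(idx) - 1L
    if (n_val >= 1L) val <- c(val, sample(idx, n_val))
  }
  if (length(val) == 0L || length(val) >= length(cls)) {
    n_val <- max(1L, round(val_fraction * length(cls)))
    val <- sample(seq_along(cls), min(n_val, length(cls) - 1L))
  }
  sort(val)
}

#' Train an ELM with COA-selected input weights
#'
#' The input weights and biases (a `L * (n + 1)` vector in `[-1, 1]`) are
#' chosen by [coa_minimize()]; the fitness of a candidate is its
#' misclassification rate on a stratified held-out fraction, with the
#' output weights recomputed in closed form on the training fraction at
#' every evaluation.  The returned model is rebuilt from the best candidate
#' with `beta` refit on all the data.
#'
#' @inheritParams elm_train
#' @param coa [coa_params()] controlling the search (bounds are forced to
#'   `[-1, 1]`).
#' @param val_fraction Held-out fraction used by the fitness.
#' @return An `elm_model` with attribute `"coa"` holding the `coa_fit`.
#' @export
coa_elm_train <- function(X, y, L = 100, activation = "sigmoid",
                          coa = coa_params(), val_fraction = 0.2,
                          seed = 1, ridge = 1e-8) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite features", call. = FALSE)
  activation <- match.arg(activation, names(elm_activations))
  T <- as_target_matrix(y)
  n <- ncol(X)
  val <- stratified_split(T, val_fraction, seed)
  tr <- setdiff(seq_len(nrow(X)), val)
  Xtr <- X[tr, , drop = FALSE]; Ttr <- T[tr, , drop = FALSE]
  Xv <- X[val, , drop = FALSE]; Tv <- T[val, , drop = FALSE]
  true_val <- if (ncol(T) == 1L) as.integer(Tv >= 0.5) else max.col(Tv)

  unpack <- function(v) {
    W <- matrix(v[seq_len(L * n)], nrow = L)
    b <- v[L * n + seq_len(L)]
    list(W = W, b = b)
  }
  fitness <- function(v) {
    p <- unpack(v)
    m <- new_elm_model(p$W, p$b, beta = NULL, activation, ridge)
    H <- hidden_output(m, Xtr)
    m$beta <- elm_solve_beta(H, Ttr, ridge)
    pred <- elm_predict(m, Xv)
    mean(pred != true_val)
  }

  coa$lower <- -1
  coa$upper <- 1
  fit <- coa_minimize(fitness, coa, dim = L * (n + 1L))
  p <- unpack(fit$gBest)
  model <- new_elm_model(p$W, p$b, beta = NULL, activation, ridge)
  model$beta <- elm_solve_beta(hidden_output(model, X), T, ridge)
  attr(model, "coa") <- fit
  model
}

#' Tidy an ELM model
#'
#' @param x An `elm_model`.
#' @param ... Unused.
#' @return Tibble with one row per hidden unit: bias and output weights.
#' @export
tidy.elm_model <- function(x, ...) {
  out <- tibble::tibble(unit = seq_len(x$L), bias = x$b)
  beta <- x$beta
  colnames(beta) <- paste0("beta", seq_len(ncol(beta)))
  cbind(out, tibble::as_tibble(beta))
}

#' One-row summary of an ELM model
#'
#' @inheritParams tidy.elm_model
#' @return Tibble with layer sizes and whether COA selected the weights.
#' @export
glance.elm_model <- function(x, ...) {
  tibble::tibble(hidden_units = x$L, inputs = ncol(x$W),
                 outputs = ncol(x$beta), activation = x$activation,
                 ridge = x$ridge, coa_selected = !is.null(attr(x, "coa")))
}

#' Serialize an ELM model to a JSON file
#'
#' @param model An `elm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
elm_save <- function(model, path) {
  obj <- list(W = model$W, b = model$b, beta = model$beta,
              activation = model$activation, L = model$L,
              ridge = model$ridge)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load an ELM model saved by [elm_save()]
#'
#' @param path JSON file path.
#' @return An `elm_model`.
#' @export
elm_load <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new_elm_model(as.matrix(obj$W), as.numeric(obj$b), as.matrix(obj$beta),
                obj$activation, obj$ridge)
}
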