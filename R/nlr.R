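#' Numerically stable logistic sigmoid
#'
#' `1 / (1 + exp(-z))`, computed branch-wise so it neither overflows nor
#' returns exactly 0 or 1 for |z| up to ~700.
#'
#' @param z Numeric vector.
#' @return Values in (0, 1).
#' @export
sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  # keep the open interval even where exp() underflows
  pmin(pmax(out, 1e-300), 1 - 1e-16)
}

#' Polynomial feature expansion
#'
#' Expands each row of `X` into all monomials of total degree 1..`degree`,
#' without a constant term (the bias is a separate model parameter).
#' Degree 1 is the identity map; degree 2 on three features yields nine
#' terms: the 3 linear terms, 3 squares and 3 pairwise products.
#'
#' @param X Numeric matrix (n x d) or a single feature vector.
#' @param degree Positive integer expansion order.
#' @return Numeric matrix (n x expanded dimension) with named columns.
#' @export
expand_features <- function(X, degree = 2) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(degree >= 1)
  d <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(d))
  cols <- list()
  # all multisets of column indices of size 1..degree, lexicographic
  for (deg in seq_len(degree)) {
    idx <- multisets(d, deg)
    for (k in seq_len(nrow(idx))) {
      term <- idx[k, ]
      v <- X[, term[1]]
      for (j in term[-1]) v <- v * X[, j]
      cols[[paste(colnames(X)[term], collapse = "*")]] <- v
    }
  }
  do.call(cbind, cols)
}

# non-decreasing index tuples (multisets) of size `deg` from 1..d
multisets <- function(d, deg) {
  if (deg == 1) return(matrix(seq_len(d), ncol = 1))
  prev <- multisets(d, deg - 1)
  out <- do.call(rbind, lapply(seq_len(nrow(prev)), function(k) {
    last <- prev[k, deg - 1]
    cbind(matrix(prev[k, ], nrow = d - last + 1, ncol = deg - 1,
                 byrow = TRUE), seq(last, d))
  }))
  out
}

#' Binary non-linear logistic regression model
#'
#' One of the One-vs-All binaries: weight vector, bias, decision threshold
#' and feature expansion degree. The membership probability of the
#' positive class is `sigmoid(w . expand(x) + b)`; the binary decision is
#' `probability >= threshold`.
#'
#' @param weights Numeric weight vector over the expanded features.
#' @param bias Scalar bias.
#' @param threshold Decision threshold in (0, 1).
#' @param feature_degree Polynomial expansion order of the inputs.
#' @param positive_class Class code this binary recognizes (0, 1 or 2).
#' @return An object of class `binary_nlr`.
#' @export
binary_nlr <- function(weights, bias = 0, threshold = 0.5,
                       feature_degree = 1, positive_class = 1L) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(
    weights = as.numeric(weights), bias = as.numeric(bias),
    threshold = threshold, feature_degree = as.integer(feature_degree),
    positive_class = as.integer(positive_class),
    j_trajectory = NULL
  ), class = "binary_nlr")
}

#' Positive-class membership probability
#'
#' @param model A `binary_nlr`.
#' @param X Raw (already normalized) feature matrix or single vector; the
#'   model's polynomial expansion is applied internally.
#' @return Probabilities in (0, 1), one per row.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "binary_nlr"))
  Xe <- expand_features(X, model$feature_degree)
  if (ncol(Xe) != length(model$weights)) {
    stop(sprintf(
      "model expects %d expanded features, got %d (input dimension mismatch)",
      length(model$weights), ncol(Xe)), call. = FALSE)
  }
  sigmoid(as.numeric(Xe %*% model$weights) + model$bias)
}

# clamp probabilities away from {0,1} before taking logs
.p_eps <- 1e-12

#' Cross-entropy cost
#'
#' Mean negative log-likelihood of binary labels under the model,
#' `-(1/m) * sum(y*log(p) + (1-y)*log(1-p))`, with probabilities clamped to
#' `[1e-12, 1 - 1e-12]`, plus an optional L2 ridge penalty
#' `l2_penalty/(2m) * |w|^2` (bias excluded).
#'
#' @param model A `binary_nlr`.
#' @param X Feature matrix (raw, pre-expansion).
#' @param y Binary labels in `{0, 1}`.
#' @param l2_penalty Non-negative ridge coefficient.
#' @return Scalar cost `J >= 0`.
#' @export
cross_entropy <- function(model, X, y, l2_penalty = 0) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)", call. = FALSE)
  if (!all(y %in% c(0, 1))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  m <- length(y)
  p <- pmin(pmax(predict_proba(model, X), .p_eps), 1 - .p_eps)
  j <- -mean(y * log(p) + (1 - y) * log(1 - p))
  j + l2_penalty / (2 * m) * sum(model$weights^2)
}

#' Analytic gradient of the cross-entropy cost
#'
#' @inheritParams cross_entropy
#' @return List with `weights` (gradient over expanded features) and `bias`.
#' @export
cross_entropy_gradient <- function(model, X, y, l2_penalty = 0) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  m <- length(y)
  Xe <- expand_features(X, model$feature_degree)
  p <- sigmoid(as.numeric(Xe %*% model$weights) + model$bias)
  err <- p - y
  list(weights = as.numeric(crossprod(Xe, err)) / m +
         l2_penalty / m * model$weights,
       bias = mean(err))
}

#' Training hyperparameters
#'
#' @param learning_rate Gradient-descent step size (on normalized features).
#' @param max_iterations Iteration cap.
#' @param convergence_tol Relative cost-change stopping tolerance.
#' @param l2_penalty Ridge coefficient (default 0: plain maximum likelihood).
#' @param threshold_grid Candidate decision thresholds searched on the
#'   validation split.
#' @param seed Integer seed (reserved; training itself is deterministic
#'   from zero initialization).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, max_iterations = 5000,
                         convergence_tol = 1e-8, l2_penalty = 0,
                         threshold_grid = seq(0.05, 0.95, by = 0.01),
                         seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (any(threshold_grid <= 0 | threshold_grid >= 1) ||
      is.unsorted(threshold_grid)) {
    stop("threshold_grid must be sorted and inside (0, 1)", call. = FALSE)
  }
  structure(list(
    learning_rate = learning_rate, max_iterations = as.integer(max_iterations),
    convergence_tol = convergence_tol, l2_penalty = l2_penalty,
    threshold_grid = threshold_grid, seed = as.integer(seed)
  ), class = "train_config")
}

#' Fit one binary classifier by batch gradient descent
#'
#' Full-batch gradient descent on the cross-entropy cost from a
#' zero-initialized model, stopping at `max_iterations` or when the
#' relative cost change drops below `convergence_tol`. The cost trajectory
#' is recorded in the fitted model (`$j_trajectory`).
#'
#' @param X Feature matrix (rows = samples); expanded internally to
#'   `feature_degree`.
#' @param y_binary Binary labels in `{0, 1}`; both classes must be present.
#' @param config A [train_config()].
#' @param feature_degree Polynomial expansion order.
#' @param positive_class Class code recorded in the model.
#' @return A fitted `binary_nlr` (threshold left at 0.5 until
#'   [optimize_threshold()]).
#' @export
fit_binary <- function(X, y_binary, config = train_config(),
                       feature_degree = 1, positive_class = 1L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (!all(y_binary %in% c(0, 1))) {
    stop("labels must be binary (0/1)", call. = FALSE)
  }
  if (length(unique(y_binary)) < 2) {
    stop("both classes must be present in y_binary", call. = FALSE)
  }
  Xe <- expand_features(X, feature_degree)
  m <- nrow(Xe)
  w <- numeric(ncol(Xe))
  b <- 0
  lr <- config$learning_rate
  lam <- config$l2_penalty

  j_of <- function(w, b) {
    p <- pmin(pmax(sigmoid(as.numeric(Xe %*% w) + b), .p_eps), 1 - .p_eps)
    -mean(y_binary * log(p) + (1 - y_binary) * log(1 - p)) +
      lam / (2 * m) * sum(w^2)
  }
  traj <- numeric(config$max_iterations + 1L)
  traj[1] <- j0 <- j_of(w, b)
  j_prev <- j0
  n_iter <- 0L
  for (it in seq_len(config$max_iterations)) {
    p <- sigmoid(as.numeric(Xe %*% w) + b)
    err <- p - y_binary
    w <- w - lr * (as.numeric(crossprod(Xe, err)) / m + lam / m * w)
    b <- b - lr * mean(err)
    j <- j_of(w, b)
    n_iter <- it
    traj[it + 1L] <- j
    if (!is.finite(j) || j > 10 * j0) {
      stop("training diverged (cost grew 10x above start); ",
           "reduce learning_rate", call. = FALSE)
    }
    if (abs(j_prev - j) <= config$convergence_tol * max(j_prev, .p_eps)) break
    j_prev <- j
  }
  model <- binary_nlr(w, b, threshold = 0.5, feature_degree = feature_degree,
                      positive_class = positive_class)
  model$j_trajectory <- traj[seq_len(n_iter + 1L)]
  model
}

#' Tune the decision threshold on a validation set
#'
#' Evaluates the binary F1 of the positive class at every grid value and
#' returns the maximizer; exact ties are broken toward the grid value
#' closest to 0.5 (and toward the lower value if still tied).
#'
#' @param model A fitted `binary_nlr`.
#' @param X_val Validation feature matrix (raw, pre-expansion).
#' @param y_val Binary validation labels in `{0, 1}`.
#' @param grid Candidate thresholds in (0, 1); defaults to the
#'   [train_config()] grid.
#' @return The selected threshold.
#' @export
optimize_threshold <- function(model, X_val, y_val,
                               grid = seq(0.05, 0.95, by = 0.01)) {
  if (length(grid) == 0) stop("threshold grid is empty", call. = FALSE)
  if (length(unique(y_val)) < 2) {
    stop("validation set must contain both classes", call. = FALSE)
  }
  p <- predict_proba(model, X_val)
  f1s <- vapply(grid, function(th) binary_f1(y_val, as.integer(p >= th)), 0)
  best <- f1s >= max(f1s) - 1e-12
  cand <- grid[best]
  cand[order(abs(cand - 0.5), cand)][1]
}

# binary F1 of the positive class; 0 when no true or predicted positives
binary_f1 <- function(y, yhat) {
  tp <- sum(y == 1 & yhat == 1)
  fp <- sum(y == 0 & yhat == 1)
  fn <- sum(y == 1 & yhat == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}
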