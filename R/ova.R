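#' Fit the One-vs-All stiffness classifier
#'
#' Trains three binary non-linear logistic regressions — one per class
#' (void, rigid, soft) against the rest — on the z-scored train split, then
#' tunes each binary's decision threshold on the validation split by F1
#' maximization. The dataset's normalization state is stored in the model
#' so raw sensor triplets can be classified at prediction time.
#'
#' @param ds A split `labeled_dataset` (see [split_dataset()]) containing
#'   all three classes in the train split.
#' @param config A [train_config()].
#' @param feature_degree Polynomial expansion order (default 2; 1 gives
#'   plain logistic regression).
#' @param shared_threshold If `TRUE`, all three binaries share the single
#'   threshold maximizing validation macro-F1 over the grid; default is a
#'   per-class threshold.
#' @return An object of class `ova_classifier`.
#' @export
fit_ova <- function(ds, config = train_config(), feature_degree = 2,
                    shared_threshold = FALSE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (!all(c("train", "validation") %in% ds$rows$split)) {
    stop("dataset must carry train and validation splits", call. = FALSE)
  }
  if (is.null(ds$normalization)) {
    stop("dataset has no normalization state; run split_dataset() first",
         call. = FALSE)
  }
  tr <- dataset_split(ds, "train")
  va <- dataset_split(ds, "validation")
  classes <- unname(class_codes())
  if (!all(classes %in% tr$y)) {
    stop("train split must contain all three classes", call. = FALSE)
  }
  if (!all(classes %in% va$y)) {
    stop("validation split must contain all three classes", call. = FALSE)
  }
  Xtr <- normalize_features(tr$X, ds$normalization)
  Xva <- normalize_features(va$X, ds$normalization)

  binaries <- lapply(classes, function(k) {
    m <- fit_binary(Xtr, as.integer(tr$y == k), config,
                    feature_degree = feature_degree, positive_class = k)
    m$threshold <- optimize_threshold(m, Xva, as.integer(va$y == k),
                                      grid = config$threshold_grid)
    m
  })
  names(binaries) <- names(class_codes())

  model <- structure(list(
    binaries = binaries, normalization = ds$normalization,
    classes = classes, feature_degree = as.integer(feature_degree),
    config = unclass(config)
  ), class = "ova_classifier")

  if (shared_threshold) {
    f1_at <- function(th) {
      for (k in seq_along(model$binaries)) model$binaries[[k]]$threshold <- th
      cm <- confusion(va$y, predict_sample(model, va$X))
      f1_score(cm, "macro")
    }
    f1s <- vapply(config$threshold_grid, f1_at, 0)
    best <- config$threshold_grid[f1s >= max(f1s) - 1e-12]
    th <- best[order(abs(best - 0.5), best)][1]
    for (k in seq_along(model$binaries)) model$binaries[[k]]$threshold <- th
  }
  model
}

#' @export
print.ova_classifier <- function(x, ...) {
  ths <- vapply(x$binaries, `[[`, 0, "threshold")
  cat(sprintf(
    "<ova_classifier> degree-%d expansion | thresholds: %s\n",
    x$feature_degree,
    paste(sprintf("%s=%.2f", names(ths), ths), collapse = " ")))
  invisible(x)
}

# apply stored z-scoring to a raw (current, theta_ref, theta_out) matrix
normalize_features <- function(X, normalization) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  sweep(sweep(X, 2, normalization$mean), 2, normalization$sd, "/")
}

#' Per-class membership probabilities
#'
#' @param model A fitted `ova_classifier`.
#' @param X Raw feature matrix or single (current, theta_ref, theta_out)
#'   triplet; normalization and expansion are applied internally.
#' @return Matrix (n x 3) of probabilities, columns named void/rigid/soft.
#' @export
predict_proba_ova <- function(model, X) {
  stopifnot(inherits(model, "ova_classifier"))
  Xn <- normalize_features(X, model$normalization)
  sapply(model$binaries, function(b) predict_proba(b, Xn))
}

#' Classify sensor samples
#'
#' One-vs-All decision rule: compute the three class probabilities `p_k`;
#' among the classes whose probability reaches their threshold
#' (`p_k >= TH_k`) return the one with the largest margin `p_k - TH_k`;
#' if no class fires, fall back to the largest probability. Exact ties go
#' to the lower class code (0 < 1 < 2).
#'
#' @param model A fitted `ova_classifier`.
#' @param X Raw feature matrix or single triplet.
#' @return Integer class codes in `{0, 1, 2}`, one per row.
#' @export
predict_sample <- function(model, X) {
  P <- predict_proba_ova(model, X)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  TH <- vapply(model$binaries, `[[`, 0, "threshold")
  M <- sweep(P, 2, TH)  # margins p_k - TH_k
  apply_decision <- function(i) {
    fires <- which(M[i, ] >= 0)
    k <- if (length(fires)) fires[which.max(M[i, fires])]
         else which.max(P[i, ])
    model$classes[k]
  }
  vapply(seq_len(nrow(P)), apply_decision, 0L)
}

#' Classify a whole closure
#'
#' Majority vote of [predict_sample()] over the terminal `window` seconds
#' of the trace — the steady-grasp regime the training protocol emphasizes.
#' Vote ties are broken toward the class with the higher characteristic
#' current (rigid > soft > void).
#'
#' @param model A fitted `ova_classifier`.
#' @param trace A `grasp_trace`.
#' @param window Terminal voting window (s), default 0.5.
#' @return Integer class code in `{0, 1, 2}`.
#' @export
predict_closure <- function(model, trace, window = 0.5) {
  stopifnot(inherits(trace, "grasp_trace"))
  n_win <- round(window * trace$sample_rate)
  n <- length(trace$t)
  if (n < n_win) {
    stop(sprintf("trace (%d samples) shorter than the %g s decision window",
                 n, window), call. = FALSE)
  }
  idx <- seq(n - n_win + 1L, n)
  X <- cbind(current = trace$current[idx],
             theta_ref = trace$theta_ref[idx],
             theta_out = trace$theta_out[idx])
  votes <- table(factor(predict_sample(model, X), levels = c(0, 1, 2)))
  top <- names(votes)[votes == max(votes)]
  # current-consistent preference: rigid (1) > soft (2) > void (0)
  pref <- c("1", "2", "0")
  as.integer(pref[pref %in% top][1])
}

#' Save / load a fitted classifier as JSON
#'
#' Serializes per-class weights, biases, thresholds, the feature degree and
#' the normalization state; `load_model` restores a classifier producing
#' identical predictions.
#'
#' @param model A fitted `ova_classifier`.
#' @param path JSON file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns an
#'   `ova_classifier`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ova_classifier"))
  obj <- list(
    feature_degree = model$feature_degree,
    classes = model$classes,
    normalization = lapply(model$normalization, as.numeric),
    binaries = lapply(model$binaries, function(b) {
      list(weights = b$weights, bias = b$bias, threshold = b$threshold,
           positive_class = b$positive_class)
    }),
    config = model$config[c("learning_rate", "max_iterations",
                            "convergence_tol", "l2_penalty", "seed")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  binaries <- lapply(seq_len(3), function(k) {
    b <- list(weights = obj$binaries[[k]]$weights,
              bias = obj$binaries[[k]]$bias,
              threshold = obj$binaries[[k]]$threshold,
              feature_degree = as.integer(obj$feature_degree),
              positive_class = as.integer(obj$binaries[[k]]$positive_class),
              j_trajectory = NULL)
    class(b) <- "binary_nlr"
    b
  })
  names(binaries) <- names(obj$binaries)
  norm <- list(mean = obj$normalization$mean, sd = obj$normalization$sd)
  names(norm$mean) <- names(norm$sd) <- c("current", "theta_ref", "theta_out")
  structure(list(
    binaries = binaries, normalization = norm,
    classes = as.integer(obj$classes),
    feature_degree = as.integer(obj$feature_degree),
    config = obj$config
  ), class = "ova_classifier")
}
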