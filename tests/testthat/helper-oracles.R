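# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: naive loops and literal enumerations only.

# macro-F1 (percent) by explicit per-class loops over the pair list
oracle_macro_f1 <- function(truth, pred) {
  f1s <- c()
  for (k in 0:2) {
    tp <- fp <- fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == k && pred[i] == k) tp <- tp + 1
      if (truth[i] != k && pred[i] == k) fp <- fp + 1
      if (truth[i] == k && pred[i] != k) fn <- fn + 1
    }
    if (tp + fp + fn > 0) f1s <- c(f1s, 200 * tp / (2 * tp + fp + fn))
  }
  mean(f1s)
}

# literal One-vs-All decision rule: threshold gate, margin argmax,
# probability fallback, low-class tie-break
oracle_ova_decision <- function(p, th) {
  fires <- c()
  for (k in 1:3) if (p[k] >= th[k]) fires <- c(fires, k)
  if (length(fires) > 0) {
    best <- fires[1]
    for (k in fires) if (p[k] - th[k] > p[best] - th[best]) best <- k
  } else {
    best <- 1
    for (k in 1:3) if (p[k] > p[best]) best <- k
  }
  as.integer(best - 1)
}

# algebraic torque balance of the steady grasp: the PD loop supplies
# current k_eff*(theta_ref - theta); the spring absorbs torque
# spring_rate*(theta - contact_angle); the PI loop guarantees
# i_out = i_ref. Solve the linear balance for theta, then the current.
oracle_steady_state <- function(motor, gains, object, theta_ref_final) {
  k_eff <- gains$pos_to_current_gain * gains$kp_pos          # mA/deg
  k_el <- 1000 * object$spring_rate / motor$torque_constant  # mA/deg
  theta <- (k_eff * theta_ref_final + k_el * object$contact_angle) /
    (k_eff + k_el)
  min(k_eff * (theta_ref_final - theta), motor$current_limit)
}

# central finite differences of the cross-entropy cost in (weights, bias)
oracle_numeric_gradient <- function(model, X, y, l2 = 0, h = 1e-6) {
  gw <- numeric(length(model$weights))
  for (j in seq_along(gw)) {
    mp <- model; mp$weights[j] <- mp$weights[j] + h
    mm <- model; mm$weights[j] <- mm$weights[j] - h
    gw[j] <- (cross_entropy(mp, X, y, l2) - cross_entropy(mm, X, y, l2)) /
      (2 * h)
  }
  mp <- model; mp$bias <- mp$bias + h
  mm <- model; mm$bias <- mm$bias - h
  list(weights = gw,
       bias = (cross_entropy(mp, X, y, l2) - cross_entropy(mm, X, y, l2)) /
         (2 * h))
}

# build an ova_classifier whose class probabilities are directly
# controllable: identity normalization, degree 1, unit weight on one
# feature each, so p_k = sigmoid(x[, k])
stub_ova <- function(thresholds = c(0.5, 0.5, 0.5)) {
  binaries <- lapply(1:3, function(k) {
    w <- numeric(3); w[k] <- 1
    b <- binary_nlr(w, bias = 0, threshold = thresholds[k],
                    feature_degree = 1, positive_class = k - 1L)
    b
  })
  names(binaries) <- names(class_codes())
  structure(list(
    binaries = binaries,
    normalization = list(mean = c(current = 0, theta_ref = 0, theta_out = 0),
                         sd = c(current = 1, theta_ref = 1, theta_out = 1)),
    classes = 0:2, feature_degree = 1L, config = list()
  ), class = "ova_classifier")
}

logit <- function(p) log(p / (1 - p))
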