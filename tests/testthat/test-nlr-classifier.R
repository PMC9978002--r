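test_that("the sigmoid is exact at known points and stable at extremes", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  z <- seq(-5, 5, 0.5)
  expect_equal(sigmoid(z) + sigmoid(-z), rep(1, length(z)))
  expect_true(all(sigmoid(c(-700, 700)) > 0 & sigmoid(c(-700, 700)) < 1))
})

test_that("polynomial expansion produces the documented monomials", {
  x <- c(a = 2, b = 3, c = 5)
  expect_equal(as.numeric(expand_features(x, 1)), c(2, 3, 5))
  e2 <- expand_features(x, 2)
  expect_equal(ncol(e2), 9)  # 3 linear + 3 squares + 3 cross terms
  expect_equal(as.numeric(e2),
               c(2, 3, 5, 4, 6, 10, 9, 15, 25))  # a b c a2 ab ac b2 bc c2
  sparse <- expand_features(c(1.5, 0, 0), 2)
  expect_equal(sum(sparse != 0), 2)  # a and a^2 only
  X <- matrix(rnorm(12), ncol = 3)
  expect_equal(ncol(expand_features(X, 3)), 3 + 6 + 10)
})

test_that("membership probabilities follow the sigmoid of the linear score", {
  zero <- binary_nlr(weights = c(0, 0, 0), bias = 0, feature_degree = 1)
  X <- matrix(rnorm(30), ncol = 3)
  expect_equal(predict_proba(zero, X), rep(0.5, 10))
  saturated <- binary_nlr(weights = c(0, 0, 0), bias = 500, feature_degree = 1)
  expect_equal(predict_proba(saturated, X), rep(1, 10), tolerance = 1e-12)
  m <- binary_nlr(weights = c(1, 0, 0), bias = 0, feature_degree = 1)
  expect_equal(predict_proba(m, c(log(3), 4, -2)), 0.75)
  expect_error(predict_proba(m, matrix(rnorm(8), ncol = 4)), "mismatch")
  expect_true(all(predict_proba(m, matrix(rnorm(300) * 50, ncol = 3)) > 0))
})

test_that("cross-entropy matches its closed forms and a per-sample loop", {
  X <- matrix(rnorm(30), ncol = 3)
  zero <- binary_nlr(weights = c(0, 0, 0), bias = 0, feature_degree = 1)
  y <- rep(c(0, 1), 5)
  expect_equal(cross_entropy(zero, X, y), log(2))
  # perfect-fit limit
  strong <- binary_nlr(weights = c(1000, 0, 0), bias = 0, feature_degree = 1)
  Xsep <- cbind(c(-1, -1, 1, 1), 0, 0)
  expect_lt(cross_entropy(strong, Xsep, c(0, 0, 1, 1)), 1e-6)
  # vectorized == naive loop
  set.seed(4)
  m <- binary_nlr(weights = rnorm(9), bias = 0.3, feature_degree = 2)
  X <- matrix(rnorm(60), ncol = 3)
  y <- rbinom(20, 1, 0.5)
  loop_j <- 0
  for (i in 1:20) {
    p <- predict_proba(m, X[i, , drop = FALSE])
    loop_j <- loop_j - (y[i] * log(p) + (1 - y[i]) * log(1 - p)) / 20
  }
  expect_equal(cross_entropy(m, X, y), loop_j, tolerance = 1e-12)
  expect_error(cross_entropy(m, X, y + 2), "binary")
  # ridge term
  expect_equal(cross_entropy(m, X, y, l2_penalty = 2),
               loop_j + 2 / (2 * 20) * sum(m$weights^2))
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(10)
  X <- matrix(rnorm(45), ncol = 3)
  y <- rbinom(15, 1, 0.5)
  for (rep in 1:10) {
    m <- binary_nlr(weights = rnorm(9, sd = 0.5), bias = rnorm(1),
                    feature_degree = 2)
    g <- cross_entropy_gradient(m, X, y, l2_penalty = 0.1)
    num <- oracle_numeric_gradient(m, X, y, l2 = 0.1)
    expect_lt(max(abs(g$weights - num$weights)), 1e-6)
    expect_lt(abs(g$bias - num$bias), 1e-6)
  }
})

test_that("gradient descent separates a separable toy set monotonically", {
  X <- cbind(c(-2, -1, 1, 2))
  y <- c(0, 0, 1, 1)
  fit <- fit_binary(X, y, train_config(learning_rate = 1,
                                       max_iterations = 2000))
  expect_equal(as.integer(predict_proba(fit, X) >= 0.5), y)
  expect_true(all(diff(fit$j_trajectory) <= 1e-12))
  expect_error(fit_binary(X, rep(1, 4), train_config()), "both classes")
  # a non-separable set with an absurd step overshoots into saturation
  expect_error(
    fit_binary(cbind(c(1, 2, 3)), c(1, 0, 1),
               train_config(learning_rate = 1e6, max_iterations = 50)),
    "diverged")
})

test_that("the fitted decision boundary agrees with glm on a Gaussian toy", {
  set.seed(21)
  n <- 400
  X <- rbind(matrix(rnorm(n, -1, 1), ncol = 2),
             matrix(rnorm(n, 1, 1), ncol = 2))
  y <- rep(c(0, 1), each = n / 2)
  fit <- fit_binary(X, y, train_config(learning_rate = 0.5,
                                       max_iterations = 20000,
                                       convergence_tol = 1e-12))
  ref <- glm(y ~ X, family = binomial())
  p_ref <- as.numeric(predict(ref, type = "response"))
  expect_lt(max(abs(predict_proba(fit, X) - p_ref)), 0.01)
})

test_that("threshold tuning maximizes validation F1 with the 0.5 tie-break", {
  # perfectly separated scores: any threshold between clusters gives F1 = 1
  m <- binary_nlr(weights = 1, bias = 0, feature_degree = 1)
  X <- cbind(c(rep(-3, 10), rep(3, 10)))
  y <- rep(c(0, 1), each = 10)
  grid <- seq(0.05, 0.95, by = 0.01)
  expect_equal(optimize_threshold(m, X, y, grid), 0.5)
  # flat objective (degenerate zero model) falls back to the 0.5 grid point
  zero <- binary_nlr(weights = 0, bias = 0, feature_degree = 1)
  expect_equal(optimize_threshold(zero, X, y, grid), 0.5)
  expect_error(optimize_threshold(m, X, y, numeric(0)), "empty")
  expect_error(optimize_threshold(m, X, rep(1, 20), grid), "both classes")
})

test_that("tuned thresholds equal exhaustive search and never lose to 0.5", {
  grid <- seq(0.05, 0.95, by = 0.01)
  for (s in 1:25) {
    set.seed(s)
    m <- binary_nlr(weights = rnorm(3), bias = rnorm(1), feature_degree = 1)
    X <- matrix(rnorm(60), ncol = 3)
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    th <- optimize_threshold(m, X, y, grid)
    p <- predict_proba(m, X)
    f1_at <- vapply(grid, function(g)
      graspsense:::binary_f1(y, as.integer(p >= g)), 0)
    expect_equal(f1_at[match(th, grid)], max(f1_at))
    expect_gte(f1_at[match(th, grid)],
               f1_at[match(0.5, grid)])
  }
})

test_that("a known degree-1 model is recovered from its own data", {
  set.seed(33)
  w_true <- c(1.5, -2, 1)
  b_true <- 0.5
  n <- 4000
  X <- matrix(rnorm(3 * n), ncol = 3)
  y <- rbinom(n, 1, sigmoid(X %*% w_true + b_true))
  fit <- fit_binary(X, y, train_config(learning_rate = 0.5,
                                       max_iterations = 20000,
                                       convergence_tol = 1e-12))
  expect_lt(max(abs(fit$weights - w_true) / abs(w_true)), 0.15)
})

test_that("the One-vs-All fit resolves three separable clusters exactly", {
  ds <- cluster_dataset()
  model <- fit_ova(ds, train_config(learning_rate = 1, max_iterations = 2000),
                   feature_degree = 1)
  va <- dataset_split(ds, "validation")
  cm <- confusion(va$y, predict_sample(model, va$X))
  expect_equal(f1_score(cm, "macro"), 100)
  # per-class thresholds live strictly inside (0, 1)
  ths <- vapply(model$binaries, `[[`, 0, "threshold")
  expect_true(all(ths > 0 & ths < 1))
})

test_that("fit_ova insists on complete splits", {
  ds <- cluster_dataset()
  ds$rows$label[ds$rows$label == 2 & ds$rows$split == "train"] <- 1
  expect_error(fit_ova(ds, train_config(max_iterations = 10)),
               "all three classes")
})

test_that("sample decisions match the enumerated One-vs-All rule", {
  # spec'd examples
  model <- stub_ova(thresholds = c(0.5, 0.5, 0.5))
  expect_equal(predict_sample(model, logit(c(0.9, 0.1, 0.1))), 0L)
  expect_equal(predict_sample(model, logit(c(0.4, 0.3, 0.2))), 0L)
  expect_equal(predict_sample(model, logit(c(0.1, 0.2, 0.9))), 2L)
  # randomized agreement with the brute-force rule, varying thresholds
  set.seed(52)
  for (b in 1:20) {
    th <- runif(3, 0.1, 0.9)
    model <- stub_ova(th)
    P <- matrix(runif(50 * 3, 0.01, 0.99), ncol = 3)
    got <- predict_sample(model, logit(P))
    want <- vapply(seq_len(nrow(P)), function(i)
      oracle_ova_decision(P[i, ], th), 0L)
    expect_equal(got, want)
  }
})

test_that("closure decisions are terminal-window majority votes", {
  model <- stub_ova()
  mk_trace <- function(P) {
    n <- nrow(P)
    structure(list(t = (seq_len(n) - 1) / 100,
                   theta_ref = logit(P[, 2]), theta_out = logit(P[, 3]),
                   current = logit(P[, 1]), sample_rate = 100,
                   object_meta = object_model("void", 0, 45)),
              class = "grasp_trace")
  }
  p_void <- c(0.9, 0.1, 0.1); p_rigid <- c(0.1, 0.9, 0.1)
  p_soft <- c(0.1, 0.1, 0.9)
  # unanimity
  tr <- mk_trace(matrix(p_soft, 100, 3, byrow = TRUE))
  expect_equal(predict_closure(model, tr, window = 0.5), 2L)
  # majority 30 rigid vs 20 soft in the window
  P <- rbind(matrix(p_void, 50, 3, byrow = TRUE),
             matrix(p_rigid, 30, 3, byrow = TRUE),
             matrix(p_soft, 20, 3, byrow = TRUE))
  expect_equal(predict_closure(model, mk_trace(P), window = 0.5), 1L)
  # tie between rigid and soft resolves to the higher-current class (rigid)
  P <- rbind(matrix(p_rigid, 25, 3, byrow = TRUE),
             matrix(p_soft, 25, 3, byrow = TRUE))
  expect_equal(predict_closure(model, mk_trace(P), window = 0.5), 1L)
  expect_error(predict_closure(model, mk_trace(P[1:10, ]), window = 0.5),
               "shorter")
})

test_that("serialized models reload with identical predictions", {
  model <- table2_model()
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  set.seed(5)
  X <- cbind(current = runif(50, 0, 1200), theta_ref = runif(50, 0, 100),
             theta_out = runif(50, 0, 100))
  expect_identical(predict_sample(back, X), predict_sample(model, X))
  expect_equal(predict_proba_ova(back, X), predict_proba_ova(model, X))
})
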