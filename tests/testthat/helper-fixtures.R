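# Shared fixtures, built once per test run. The shipped-protocol dataset
# and its fitted classifier are expensive (80 simulated closures, three
# gradient-descent fits), so they are cached in a helper environment.

.fixtures <- new.env(parent = emptyenv())

table2_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    .fixtures$ds <- build_table2_dataset(seed = 42L)
  }
  .fixtures$ds
}

table2_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- fit_ova(table2_dataset(), train_config(),
                               feature_degree = 2)
  }
  .fixtures$model
}

# faster simulator configuration for split/protocol mechanics tests:
# shorter closures, coarse acquisition
quick_sim_config <- function() {
  cfg <- default_sim_config()
  cfg$sim$duration <- 1
  cfg$sim$acquisition_rate <- 50
  cfg
}

# hand-built grasp trace for labeling tests
synthetic_trace <- function(current, object, sample_rate = 100) {
  n <- length(current)
  structure(list(
    t = (seq_len(n) - 1) / sample_rate,
    theta_ref = seq(0, 60, length.out = n),
    theta_out = pmin(seq(0, 60, length.out = n), 50),
    current = current, sample_rate = sample_rate, object_meta = object
  ), class = "grasp_trace")
}

# hand-built labeled dataset around three well-separated Gaussian clusters
cluster_dataset <- function(n_per_class = 60, sep = 8, seed = 11L) {
  set.seed(seed)
  centers <- rbind(c(0, 0, 0), c(sep, 0, sep), c(0, sep, -sep))
  rows <- do.call(rbind, lapply(0:2, function(k) {
    X <- matrix(rnorm(3 * n_per_class), ncol = 3) + rep(centers[k + 1, ],
                                                        each = n_per_class)
    data.frame(current = X[, 1], theta_ref = X[, 2], theta_out = X[, 3],
               label = k, closure_id = k * n_per_class + seq_len(n_per_class),
               split = rep(c("train", "validation"),
                           c(round(0.8 * n_per_class),
                             n_per_class - round(0.8 * n_per_class))))
  }))
  ds <- structure(list(
    rows = rows,
    closures = data.frame(closure_id = rows$closure_id,
                          stiffness_label = names(class_codes())[rows$label + 1]),
    normalization = NULL, protocol = NULL, seed = seed,
    label_rule = "per_sample"
  ), class = "labeled_dataset")
  ds$normalization <- graspsense:::fit_normalization(
    rows[rows$split == "train", ])
  ds
}
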