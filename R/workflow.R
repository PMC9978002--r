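#' Build the shipped-protocol training dataset
#'
#' Runs the full acquisition protocol ([table2_protocol()], 80 closures)
#' through the simulator, labels the samples and assigns the stratified
#' 80/20 closure-level train/validation split.
#'
#' @param seed Master seed for simulation and splitting.
#' @param sim_config Simulator configuration.
#' @param train_frac Train fraction of closures.
#' @return A split `labeled_dataset`.
#' @export
build_table2_dataset <- function(seed = 42L,
                                 sim_config = default_sim_config(),
                                 train_frac = 0.8) {
  ds <- build_protocol_dataset(table2_protocol(), sim_config, seed = seed)
  split_dataset(ds, train_frac = train_frac, seed = seed)
}

#' Train the stiffness classifier end to end
#'
#' Convenience wrapper: builds the shipped-protocol dataset for `seed` and
#' fits the One-vs-All classifier on it.
#'
#' @inheritParams build_table2_dataset
#' @param config A [train_config()].
#' @param feature_degree Polynomial expansion order.
#' @return List with `model` (an `ova_classifier`) and `dataset`.
#' @export
train_stiffness_classifier <- function(seed = 42L,
                                       sim_config = default_sim_config(),
                                       config = train_config(),
                                       feature_degree = 2) {
  ds <- build_table2_dataset(seed, sim_config)
  list(model = fit_ova(ds, config, feature_degree = feature_degree),
       dataset = ds)
}

#' Per-sample test evaluation of a fitted classifier
#'
#' Generates a fresh held-out dataset by re-running the acquisition
#' protocol with an independent seed, classifies every sample and returns
#' the confusion matrix and F1 scores.
#'
#' @param model A fitted `ova_classifier`.
#' @param test_seed Seed of the held-out protocol run (use one different
#'   from the training seed).
#' @param sim_config Simulator configuration.
#' @return List with `confusion`, `macro_f1`, `micro_f1`, `per_class_f1`
#'   and `n` (samples scored).
#' @export
evaluate_on_test <- function(model, test_seed = 4242L,
                             sim_config = default_sim_config()) {
  test_ds <- build_protocol_dataset(table2_protocol(), sim_config,
                                    seed = test_seed)
  te <- dataset_split(test_ds, "all")
  pred <- predict_sample(model, te$X)
  cm <- confusion(te$y, pred)
  list(confusion = cm,
       macro_f1 = f1_score(cm, "macro"),
       micro_f1 = f1_score(cm, "micro"),
       per_class_f1 = f1_score(cm, "per_class"),
       n = length(te$y))
}
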