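#' Class codes
#'
#' Integer label codes used throughout: 0 = void, 1 = rigid, 2 = soft.
#' @return Named integer vector.
#' @export
class_codes <- function() c(void = 0L, rigid = 1L, soft = 2L)

#' Void-labeling current threshold (mA)
#'
#' Samples whose motor-side current is below this value are labeled void
#' (class 0) regardless of the grasped object: below it, the drivetrain is
#' not pressing on anything the current can sense.
#' @return Scalar threshold in mA.
#' @export
void_current_threshold <- function() 300

#' Acquisition protocol for classifier training
#'
#' The shipped 13-row closure protocol: 80 closures over the void
#' pseudo-object, a hand dynamometer (rigid) and five spring combinations
#' spanning the rigid and soft regimes, driven by sinusoidal and EMG-like
#' references.
#'
#' @return A `data.frame` with columns `n_closures`, `object_name`,
#'   `stiffness_label`, `control_signal`.
#' @export
table2_protocol <- function() {
  data.frame(
    n_closures = c(10, 10, 10, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5),
    object_name = c("Void", "Hand dynam", "Hand dynam",
                    "4xS1", "4xS1", "2xS1", "2xS1",
                    "4xS2", "4xS2", "4xS3", "4xS3",
                    "2xS1-2xS4", "2xS1-2xS4"),
    stiffness_label = c("void", "rigid", "rigid",
                        "soft", "soft", "soft", "soft",
                        "rigid", "rigid", "rigid", "rigid",
                        "soft", "soft"),
    control_signal = c("sinusoidal", "sinusoidal", "emg",
                       "sinusoidal", "emg", "sinusoidal", "emg",
                       "sinusoidal", "emg", "sinusoidal", "emg",
                       "sinusoidal", "emg"),
    stringsAsFactors = FALSE
  )
}

#' Label trace samples by the current-gated stiffness rule
#'
#' Per-sample labeling: samples with current below [void_current_threshold()]
#' are void (0) regardless of the object — the pre-contact regime of an
#' object closure is physically indistinguishable from a void closure —
#' while samples at or above it take the object's class (1 rigid, 2 soft).
#' With `rule = "per_closure"` the threshold instead annotates whole
#' closures: a closure whose peak current stays below the threshold is
#' all-void, any other closure is labeled by its object throughout.
#'
#' @param trace A `grasp_trace` carrying `object_meta`.
#' @param rule `"per_sample"` (default) or `"per_closure"`.
#' @return Integer vector of labels in `{0, 1, 2}`, one per sample.
#' @export
label_samples <- function(trace, rule = c("per_sample", "per_closure")) {
  rule <- match.arg(rule)
  stopifnot(inherits(trace, "grasp_trace"))
  if (is.null(trace$object_meta)) {
    stop("trace carries no object_meta; cannot label", call. = FALSE)
  }
  obj_class <- class_codes()[[trace$object_meta$stiffness_class]]
  thr <- void_current_threshold()
  if (rule == "per_sample") {
    ifelse(trace$current >= thr, obj_class, 0L)
  } else {
    if (obj_class == 0L || max(trace$current) < thr) {
      rep(0L, length(trace$current))
    } else {
      rep(obj_class, length(trace$current))
    }
  }
}

#' Build a labeled dataset from an acquisition protocol
#'
#' Simulates `n_closures` closures for every protocol row (with per-closure
#' seeds derived deterministically from `seed`, and small seeded jitter on
#' the reference amplitude and drive so closures are not carbon copies),
#' decimates each trace to the acquisition rate, labels every sample with
#' [label_samples()] and concatenates the rows. Splits are left
#' `"unassigned"`; use [split_dataset()].
#'
#' @param protocol A protocol `data.frame` as from [table2_protocol()].
#' @param sim_config Simulator configuration, see [default_sim_config()].
#' @param seed Master integer seed.
#' @param label_rule Passed to [label_samples()].
#' @return A `labeled_dataset`: list with `rows` (data.frame `current`,
#'   `theta_ref`, `theta_out`, `label`, `closure_id`, `split`), `closures`
#'   (closure-level table), `normalization` (NULL until split) and
#'   provenance fields.
#' @export
build_protocol_dataset <- function(protocol, sim_config = default_sim_config(),
                                   seed = 1L,
                                   label_rule = c("per_sample", "per_closure")) {
  label_rule <- match.arg(label_rule)
  if (!is.data.frame(protocol) || nrow(protocol) == 0) {
    stop("protocol must be a non-empty data.frame", call. = FALSE)
  }
  missing_obj <- setdiff(protocol$object_name, names(sim_config$objects))
  if (length(missing_obj)) {
    stop("no object configured for: ", paste(missing_obj, collapse = ", "),
         call. = FALSE)
  }
  n_total <- sum(protocol$n_closures)
  closure_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_total))

  acq_rate <- sim_config$sim$acquisition_rate %||% 100
  keep_every <- max(1L, round(sim_config$gains$sample_rate / acq_rate))

  rows <- vector("list", n_total)
  closures <- vector("list", n_total)
  cid <- 0L
  for (i in seq_len(nrow(protocol))) {
    object <- sim_config$objects[[protocol$object_name[i]]]
    for (j in seq_len(protocol$n_closures[i])) {
      cid <- cid + 1L
      cs <- closure_seeds[cid]
      prof <- closure_profile(sim_config, protocol$control_signal[i], cs)
      tr <- simulate_closure(sim_config$motor, sim_config$gains, object,
                             prof, duration = sim_config$sim$duration)
      lab <- label_samples(tr, rule = label_rule)
      idx <- seq(1L, length(tr$t), by = keep_every)
      rows[[cid]] <- data.frame(
        current = tr$current[idx], theta_ref = tr$theta_ref[idx],
        theta_out = tr$theta_out[idx], label = lab[idx],
        closure_id = cid, split = "unassigned",
        stringsAsFactors = FALSE
      )
      closures[[cid]] <- data.frame(
        closure_id = cid, object_name = protocol$object_name[i],
        stiffness_label = protocol$stiffness_label[i],
        control_signal = protocol$control_signal[i],
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(
    rows = do.call(rbind, rows),
    closures = do.call(rbind, closures),
    normalization = NULL,
    protocol = protocol, seed = as.integer(seed), label_rule = label_rule
  ), class = "labeled_dataset")
}

# per-closure reference profile with seeded amplitude/drive jitter
closure_profile <- function(sim_config, control_signal, closure_seed) {
  base <- if (control_signal %in% c("emg", "emg_like")) {
    sim_config$reference$emg_like
  } else if (control_signal == "sinusoidal") {
    sim_config$reference$sinusoidal
  } else {
    stop("unknown control signal: ", control_signal, call. = FALSE)
  }
  jit <- with_seed(closure_seed, runif(2, -1, 1))
  base$amplitude <- max(0, base$amplitude + 5 * jit[1])
  if (base$kind == "emg_like") {
    base$drive_level <- base$drive_level * (1 + 0.2 * jit[2])
  }
  base$seed <- closure_seed
  base
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- table(x$rows$label)
  cat(sprintf(
    "<labeled_dataset> %d samples / %d closures | labels: %s | splits: %s\n",
    nrow(x$rows), nrow(x$closures),
    paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
    paste(unique(x$rows$split), collapse = "/")))
  invisible(x)
}

#' Assign stratified closure-level train/validation splits
#'
#' Randomly assigns whole closures (never individual samples, to avoid
#' temporal leakage) to train and validation splits, stratified by
#' stiffness class so every class appears in both splits. Per-feature
#' z-scoring parameters are then fitted on the train rows only and stored
#' in the dataset.
#'
#' @param ds A `labeled_dataset`.
#' @param train_frac Fraction of closures assigned to train (default 0.8).
#' @param seed Integer seed for the assignment.
#' @return The dataset with `rows$split` filled in and `normalization` set.
#' @export
split_dataset <- function(ds, train_frac = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  cl <- ds$closures
  if (nrow(cl) < 5) {
    stop("need at least 5 closures to split", call. = FALSE)
  }
  strata <- split(cl$closure_id, cl$stiffness_label)
  if (any(vapply(strata, length, 0L) < 2)) {
    stop("each stiffness class needs at least 2 closures to stratify",
         call. = FALSE)
  }
  assign_val <- with_seed(seed, {
    unlist(lapply(strata, function(ids) {
      n_val <- min(length(ids) - 1L, max(1L, round((1 - train_frac) * length(ids))))
      sample(ids, n_val)
    }), use.names = FALSE)
  })
  ds$rows$split <- ifelse(ds$rows$closure_id %in% assign_val,
                          "validation", "train")
  ds$normalization <- fit_normalization(ds$rows[ds$rows$split == "train", ])
  ds$split_seed <- as.integer(seed)
  ds
}

# z-scoring parameters for the three raw features, train rows only
fit_normalization <- function(rows) {
  feats <- as.matrix(rows[, c("current", "theta_ref", "theta_out")])
  mu <- colMeans(feats)
  sdv <- apply(feats, 2, sd)
  sdv[sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

#' Extract the feature matrix and labels of one split
#'
#' @param ds A `labeled_dataset`.
#' @param split One of `"train"`, `"validation"`, `"all"`.
#' @return List with `X` (n x 3 matrix: current, theta_ref, theta_out) and
#'   `y` (integer labels).
#' @export
dataset_split <- function(ds, split = c("train", "validation", "all")) {
  split <- match.arg(split)
  rows <- if (split == "all") ds$rows else ds$rows[ds$rows$split == split, ]
  list(X = as.matrix(rows[, c("current", "theta_ref", "theta_out")]),
       y = rows$label)
}

#' Write / read a labeled dataset as CSV
#'
#' Header `current_mA,theta_ref_deg,theta_out_deg,label,closure_id,split`.
#' Numeric columns are written with 17 significant digits so a written
#' dataset re-reads bit-identically.
#'
#' @param ds A `labeled_dataset`.
#' @param path CSV path.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns a `labeled_dataset` (without simulation provenance).
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  df <- data.frame(
    current_mA = sprintf("%.17g", ds$rows$current),
    theta_ref_deg = sprintf("%.17g", ds$rows$theta_ref),
    theta_out_deg = sprintf("%.17g", ds$rows$theta_out),
    label = ds$rows$label, closure_id = ds$rows$closure_id,
    split = ds$rows$split, stringsAsFactors = FALSE
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  rows <- data.frame(
    current = df$current_mA, theta_ref = df$theta_ref_deg,
    theta_out = df$theta_out_deg, label = as.integer(df$label),
    closure_id = as.integer(df$closure_id), split = df$split,
    stringsAsFactors = FALSE
  )
  has_train <- any(rows$split == "train")
  structure(list(
    rows = rows,
    closures = unique(rows[, c("closure_id", "split")]),
    normalization = if (has_train) {
      fit_normalization(rows[rows$split == "train", ])
    },
    protocol = NULL, seed = NA_integer_, label_rule = NA_character_
  ), class = "labeled_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
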