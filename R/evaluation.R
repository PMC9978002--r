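#' Session protocol
#'
#' Composition of one evaluation session: six objects (three rigid, three
#' soft) each presented `presentations_per_object` times, plus `n_void`
#' void closures inserted along the test — 21 trials by default, in seeded
#' random order.
#'
#' @param n_objects Number of distinct objects (must split evenly between
#'   rigid and soft).
#' @param presentations_per_object Presentations of each object.
#' @param n_void Void closures inserted in the session.
#' @return An object of class `session_protocol`.
#' @export
session_protocol <- function(n_objects = 6, presentations_per_object = 3,
                             n_void = 3) {
  structure(list(n_objects = n_objects,
                 presentations_per_object = presentations_per_object,
                 n_void = n_void,
                 n_trials = n_objects * presentations_per_object + n_void),
            class = "session_protocol")
}

#' Draw one randomized session schedule
#'
#' @param protocol A [session_protocol()].
#' @param objects Named list of [object_model()]s; the non-void entries are
#'   the session objects (defaults to the shipped catalog).
#' @param seed Integer seed for the presentation order.
#' @return A `data.frame` with `trial_index`, `object_name`, `true_class`.
#' @export
make_session <- function(protocol = session_protocol(),
                         objects = object_catalog(), seed = 1L) {
  stopifnot(inherits(protocol, "session_protocol"))
  non_void <- objects[vapply(objects, function(o)
    o$stiffness_class != "void", TRUE)]
  if (length(non_void) < protocol$n_objects) {
    stop("catalog has fewer objects than the protocol requires",
         call. = FALSE)
  }
  cls <- vapply(non_void, `[[`, "", "stiffness_class")
  picked <- c(names(non_void)[cls == "rigid"][seq_len(protocol$n_objects / 2)],
              names(non_void)[cls == "soft"][seq_len(protocol$n_objects / 2)])
  schedule <- c(rep(picked, each = protocol$presentations_per_object),
                rep("Void", protocol$n_void))
  order <- with_seed(seed, sample(length(schedule)))
  schedule <- schedule[order]
  truth <- vapply(schedule, function(nm)
    class_codes()[[objects[[nm]]$stiffness_class]], 0L)
  data.frame(trial_index = seq_along(schedule), object_name = schedule,
             true_class = unname(truth), stringsAsFactors = FALSE)
}

#' Confusion matrix over the three stiffness classes
#'
#' @param truth,predicted Integer class codes in `{0, 1, 2}`.
#' @return 3 x 3 integer matrix (rows = truth, columns = predicted) with
#'   void/rigid/soft dimnames, of class `confusion_matrix`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) == 0 || length(truth) != length(predicted)) {
    stop("truth and predicted must be non-empty and equal length",
         call. = FALSE)
  }
  if (!all(c(truth, predicted) %in% c(0, 1, 2))) {
    stop("class codes must be in {0, 1, 2}", call. = FALSE)
  }
  lv <- c(0, 1, 2)
  cm <- table(factor(truth, levels = lv), factor(predicted, levels = lv))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(truth = names(class_codes()),
                               predicted = names(class_codes())))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' F1 score of a confusion matrix
#'
#' Per-class F1 is `2 TP / (2 TP + FP + FN)`. Macro averaging takes the
#' unweighted mean over classes with a defined F1 (a class absent from both
#' truth and predictions is excluded); micro averaging pools the counts —
#' which for single-label multi-class classification equals accuracy.
#' Scores are returned in percent.
#'
#' @param cm A [confusion()] matrix.
#' @param averaging `"macro"`, `"micro"` or `"per_class"`.
#' @return Scalar percent for macro/micro; named vector for per_class
#'   (NaN for undefined classes).
#' @export
f1_score <- function(cm, averaging = c("macro", "micro", "per_class")) {
  averaging <- match.arg(averaging)
  if (sum(cm) == 0) stop("confusion matrix is empty", call. = FALSE)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  denom <- 2 * tp + fp + fn
  per_class <- ifelse(denom > 0, 200 * tp / denom, NaN)
  names(per_class) <- rownames(cm)
  switch(averaging,
    per_class = per_class,
    macro = mean(per_class[!is.nan(per_class)]),
    micro = 200 * sum(tp) / sum(2 * tp + fp + fn)
  )
}

#' Chance-level accuracy
#'
#' @param n_classes Number of classes (>= 2).
#' @return Uniform-guessing accuracy in percent (33.33 for three classes).
#' @export
chance_level <- function(n_classes = 3) {
  if (n_classes < 2) stop("need at least 2 classes", call. = FALSE)
  100 / n_classes
}

#' Simulated session responder
#'
#' Synthetic stand-in for a human participant answering the stiffness
#' question under each feedback condition:
#'
#' * `NoFB` — no cue at all: uniform random answer;
#' * `AFB` — incidental motor audio: detects grasp-vs-void with probability
#'   `afb_motion_accuracy`, then guesses rigid/soft at chance;
#' * `1FB` — vibration presence decoded perfectly (void exact); rigid vs
#'   soft guessed from the vibration-onset latency (soft contacts build
#'   current later) with probability `onefb_onset_accuracy`;
#' * `2FB` — duty level decoded, confusing strong/light with probability
#'   `twofb_duty_confusion`.
#'
#' Response times are drawn from per-condition lognormal distributions.
#' All parameters are synthetic defaults chosen to exercise the expected
#' ordering of the conditions, not to reproduce human magnitudes.
#'
#' @param afb_motion_accuracy Probability the motor audio reveals
#'   grasp-vs-void under AFB.
#' @param onefb_onset_accuracy Probability the onset-latency cue reveals
#'   rigid-vs-soft under 1FB.
#' @param twofb_duty_confusion Probability of confusing the two duty levels
#'   under 2FB.
#' @param rt_mean Named mean response times per condition (s).
#' @param rt_sdlog Lognormal sdlog of response times.
#' @return An object of class `responder_model`.
#' @export
responder_model <- function(afb_motion_accuracy = 0.9,
                            onefb_onset_accuracy = 0.6,
                            twofb_duty_confusion = 0.05,
                            rt_mean = c(NoFB = 4.5, AFB = 4.0,
                                        `1FB` = 3.5, `2FB` = 2.8),
                            rt_sdlog = 0.3) {
  probs <- c(afb_motion_accuracy, onefb_onset_accuracy, twofb_duty_confusion)
  if (any(probs < 0 | probs > 1)) {
    stop("responder probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(afb_motion_accuracy = afb_motion_accuracy,
                 onefb_onset_accuracy = onefb_onset_accuracy,
                 twofb_duty_confusion = twofb_duty_confusion,
                 rt_mean = rt_mean, rt_sdlog = rt_sdlog),
            class = "responder_model")
}

# one responder answer; consumes RNG draws from the current stream
respond_trial <- function(responder, condition, command, true_class) {
  other_object <- function(k) if (k == 1L) 2L else 1L
  switch(condition,
    NoFB = sample(c(0L, 1L, 2L), 1),
    AFB = {
      detected <- runif(1) < responder$afb_motion_accuracy
      is_grasp <- true_class != 0L
      believed_grasp <- if (detected) is_grasp else !is_grasp
      if (!believed_grasp) 0L else sample(c(1L, 2L), 1)
    },
    `1FB` = {
      if (!command$active) 0L
      else if (true_class == 0L) sample(c(1L, 2L), 1)  # spurious vibration
      else if (runif(1) < responder$onefb_onset_accuracy) true_class
      else other_object(true_class)
    },
    `2FB` = {
      if (!command$active) 0L
      else if (runif(1) < responder$twofb_duty_confusion) {
        other_object(command$class_encoded)
      } else command$class_encoded
    },
    stop("unknown condition: ", condition, call. = FALSE)
  )
}

#' Run one simulated closed-loop session
#'
#' For each scheduled trial: simulate the closure on the scheduled object
#' (EMG-like reference with a per-trial seed), classify the closure with
#' the One-vs-All model, encode the prediction for the feedback condition,
#' and query the simulated responder for an answer and a response time.
#' Fully deterministic given `seed`.
#'
#' @param model A fitted `ova_classifier`.
#' @param sim_config Simulator configuration.
#' @param condition Feedback condition (`"NoFB"`, `"AFB"`, `"1FB"`,
#'   `"2FB"`).
#' @param responder A [responder_model()].
#' @param protocol A [session_protocol()].
#' @param seed Integer seed.
#' @param calibration A [vibration_calibration()].
#' @param duration Per-closure duration (s).
#' @return A `data.frame` of trial records: `trial`, `condition`,
#'   `true_class`, `classifier_class`, `user_answer`, `response_time_s`.
#' @export
run_closed_loop_session <- function(model, sim_config = default_sim_config(),
                                    condition = "2FB",
                                    responder = responder_model(),
                                    protocol = session_protocol(),
                                    seed = 1L,
                                    calibration = vibration_calibration(),
                                    duration = 4) {
  stopifnot(inherits(model, "ova_classifier"),
            inherits(responder, "responder_model"))
  condition <- match.arg(condition, c("NoFB", "AFB", "1FB", "2FB"))
  session <- make_session(protocol, sim_config$objects, seed = seed)
  with_seed(seed + 1L, {
    trial_seeds <- sample.int(.Machine$integer.max, nrow(session))
    records <- lapply(seq_len(nrow(session)), function(i) {
      object <- sim_config$objects[[session$object_name[i]]]
      prof <- closure_profile(sim_config, "emg", trial_seeds[i])
      tr <- simulate_closure(sim_config$motor, sim_config$gains, object,
                             prof, duration = duration)
      pred <- predict_closure(model, tr)
      cmd <- encode_feedback(pred, condition, calibration)
      ans <- respond_trial(responder, condition, cmd, session$true_class[i])
      mu <- responder$rt_mean[[condition]]
      rt <- rlnorm(1, log(mu) - responder$rt_sdlog^2 / 2, responder$rt_sdlog)
      data.frame(trial = i, condition = condition,
                 true_class = session$true_class[i],
                 classifier_class = pred, user_answer = ans,
                 response_time_s = rt, stringsAsFactors = FALSE)
    })
    do.call(rbind, records)
  })
}

#' Run a multi-session study over feedback conditions
#'
#' Repeats [run_closed_loop_session()] `n_sessions` times per condition
#' with derived seeds and stacks the trial records, adding a `session`
#' column.
#'
#' @inheritParams run_closed_loop_session
#' @param conditions Character vector of conditions to test.
#' @param n_sessions Sessions per condition.
#' @return A `data.frame` of trial records across sessions and conditions.
#' @export
run_condition_study <- function(model, sim_config = default_sim_config(),
                                conditions = c("NoFB", "AFB", "1FB", "2FB"),
                                n_sessions = 200,
                                responder = responder_model(),
                                protocol = session_protocol(),
                                seed = 1L,
                                calibration = vibration_calibration(),
                                duration = 4) {
  out <- list()
  for (cond in conditions) {
    cond_offset <- 100000L * match(cond, c("NoFB", "AFB", "1FB", "2FB"))
    for (s in seq_len(n_sessions)) {
      rec <- run_closed_loop_session(
        model, sim_config, cond, responder, protocol,
        seed = seed + cond_offset + s, calibration = calibration,
        duration = duration)
      rec$session <- s
      out[[length(out) + 1L]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Summarize trial records per condition
#'
#' Per-session macro-F1 of the user's answers against the truth, then
#' mean and SD across sessions within each condition, alongside accuracy
#' and response-time summaries.
#'
#' @param records Trial records from [run_condition_study()] (needs a
#'   `session` column) or a single session's records.
#' @return A `data.frame` with one row per condition: `condition`,
#'   `n_sessions`, `f1_mean`, `f1_sd`, `accuracy_mean`, `rt_mean`, `rt_sd`.
#' @export
summarize_study <- function(records) {
  if (nrow(records) == 0) stop("no records to summarize", call. = FALSE)
  if (is.null(records$session)) records$session <- 1L
  out <- lapply(split(records, records$condition), function(rc) {
    per_session <- vapply(split(rc, rc$session), function(s) {
      f1_score(confusion(s$true_class, s$user_answer), "macro")
    }, 0)
    data.frame(
      condition = rc$condition[1],
      n_sessions = length(per_session),
      f1_mean = mean(per_session),
      f1_sd = if (length(per_session) > 1) sd(per_session) else 0,
      accuracy_mean = 100 * mean(rc$true_class == rc$user_answer),
      rt_mean = mean(rc$response_time_s),
      rt_sd = if (nrow(rc) > 1) sd(rc$response_time_s) else 0,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$condition, c("NoFB", "AFB", "1FB", "2FB"))), ]
}

#' Write / read a trial log as CSV
#'
#' Header `trial,condition,true_class,classifier_class,user_answer,
#' response_time_s` (plus `session` when present); numeric columns use 17
#' significant digits so the log round-trips exactly.
#'
#' @param records Trial records.
#' @param path CSV path.
#' @return `write_trial_log` returns `path` invisibly; `read_trial_log`
#'   returns the records `data.frame`.
#' @export
write_trial_log <- function(records, path) {
  df <- records
  df$response_time_s <- sprintf("%.17g", df$response_time_s)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("trial", "true_class", "classifier_class", "user_answer",
                "session")) {
    if (!is.null(df[[col]])) df[[col]] <- as.integer(df[[col]])
  }
  df
}
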