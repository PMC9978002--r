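#' Vibromotor amplitude calibration
#'
#' Per-user PWM band found with the method of limits: `pwm_min` is the
#' perception threshold, `pwm_max` the strong-but-comfortable level, `step`
#' the staircase increment used to find them.
#'
#' @param pwm_min Perception-threshold duty (\% of PWM).
#' @param pwm_max Strong-sensation duty (\% of PWM).
#' @param step Staircase increment (\% of PWM), 4-5 by convention.
#' @param saturated Flag set when the staircase hit 100\% before a strong
#'   report.
#' @return An object of class `vibration_calibration`.
#' @export
vibration_calibration <- function(pwm_min = 20, pwm_max = 80, step = 4,
                                  saturated = FALSE) {
  if (pwm_min < 0 || pwm_max > 100 || pwm_min >= pwm_max) {
    stop("need 0 <= pwm_min < pwm_max <= 100", call. = FALSE)
  }
  structure(list(pwm_min = pwm_min, pwm_max = pwm_max, step = step,
                 saturated = saturated),
            class = "vibration_calibration")
}

# carrier frequency of the ERM vibromotor when active (Hz)
vibration_frequency <- function() 200

#' Encode a stiffness prediction as a vibromotor command
#'
#' Maps a predicted class and a feedback condition to a vibration command:
#'
#' * `NoFB`, `AFB` — motor always off (AFB's incidental audio is a
#'   property of the listener, not of the encoder);
#' * `1FB` — rigid and soft both vibrate at the 30\% intensity fraction,
#'   void closures give no vibration;
#' * `2FB` — rigid at the 100\% fraction (strong), soft at 30\% (light),
#'   void silent.
#'
#' Intensity fractions map onto the calibrated band as
#' `duty = pwm_min + f * (pwm_max - pwm_min)` (default), or onto raw duty
#' `f * 100` with `mode = "absolute"`. The carrier is 200 Hz whenever
#' active.
#'
#' @param prediction Predicted class code (0 void, 1 rigid, 2 soft).
#' @param condition One of `"NoFB"`, `"AFB"`, `"1FB"`, `"2FB"`.
#' @param calibration A [vibration_calibration()].
#' @param mode `"range"` (interpolate the calibrated band) or
#'   `"absolute"` (fractions of raw duty).
#' @return A `feedback_command`: list with `active`, `duty` (\%),
#'   `frequency` (Hz), `condition`, `class_encoded`.
#' @export
encode_feedback <- function(prediction,
                            condition = c("NoFB", "AFB", "1FB", "2FB"),
                            calibration = vibration_calibration(),
                            mode = c("range", "absolute")) {
  condition <- match.arg(condition)
  mode <- match.arg(mode)
  stopifnot(inherits(calibration, "vibration_calibration"))
  if (!prediction %in% c(0L, 1L, 2L)) {
    stop("prediction must be a class code in {0, 1, 2}", call. = FALSE)
  }
  fraction <- if (condition %in% c("NoFB", "AFB") || prediction == 0L) {
    NA_real_  # inactive
  } else if (condition == "1FB") {
    0.3
  } else {  # 2FB
    if (prediction == 1L) 1.0 else 0.3
  }
  active <- !is.na(fraction)
  duty <- if (!active) 0 else if (mode == "range") {
    calibration$pwm_min + fraction * (calibration$pwm_max - calibration$pwm_min)
  } else {
    100 * fraction
  }
  structure(list(
    active = active, duty = duty,
    frequency = if (active) vibration_frequency() else 0,
    condition = condition, class_encoded = as.integer(prediction)
  ), class = "feedback_command")
}

#' Method-of-limits amplitude calibration
#'
#' Ascending staircase: starting at 0\% duty and increasing in `step`
#' increments, the responder is probed at each level; the first level
#' reported as perceived becomes `pwm_min` and the first level reported as
#' strong becomes `pwm_max`. Deterministic for a deterministic responder.
#'
#' @param responder Either a function `f(duty)` returning a list with
#'   logical `perceived` and `strong`, or a [psychometric_responder()].
#' @param step Staircase increment in \% duty, within `[4, 5]`.
#' @return A [vibration_calibration()]; if the staircase reaches 100\%
#'   without a strong report, `pwm_max` is set to 100 with
#'   `saturated = TRUE` and a warning.
#' @examples
#' resp <- function(duty) list(perceived = duty >= 18, strong = duty >= 62)
#' method_of_limits(resp, step = 4)  # pwm_min 20, pwm_max 64
#' @export
method_of_limits <- function(responder, step = 4) {
  if (step < 4 || step > 5) {
    stop("staircase step must lie in [4, 5] % duty", call. = FALSE)
  }
  probe <- if (is.function(responder)) responder
           else function(duty) perceive(responder, duty)
  duties <- seq(0, 100, by = step)
  if (duties[length(duties)] < 100) duties <- c(duties, 100)
  pwm_min <- NA_real_
  pwm_max <- NA_real_
  for (d in duties) {
    ans <- probe(d)
    if (is.na(pwm_min) && isTRUE(ans$perceived)) pwm_min <- d
    if (!is.na(pwm_min) && isTRUE(ans$strong)) { pwm_max <- d; break }
  }
  if (is.na(pwm_min)) {
    stop("responder never perceived the vibration up to 100% duty",
         call. = FALSE)
  }
  saturated <- is.na(pwm_max)
  if (saturated) {
    warning("no strong-sensation report before 100% duty; ",
            "calibration saturated", call. = FALSE)
    pwm_max <- 100
  }
  if (pwm_min >= pwm_max) {
    stop("degenerate calibration: perception and strong thresholds collapse ",
         sprintf("(pwm_min = %g, pwm_max = %g)", pwm_min, pwm_max),
         call. = FALSE)
  }
  vibration_calibration(pwm_min, pwm_max, step, saturated)
}

#' Simulated psychophysical responder
#'
#' Logistic psychometric observer for the method-of-limits staircase:
#' at duty `d` it reports "perceived" with probability
#' `plogis((d - threshold_perceive)/slope)` and "strong" with probability
#' `plogis((d - threshold_strong)/slope)`. `slope = 0` gives the
#' deterministic step observer. Draws are seeded and reproducible.
#'
#' @param threshold_perceive,threshold_strong True thresholds (\% duty).
#' @param slope Psychometric slope (\% duty); 0 for deterministic.
#' @param seed Integer seed.
#' @return An object of class `psychometric_responder`.
#' @export
psychometric_responder <- function(threshold_perceive = 18,
                                   threshold_strong = 62,
                                   slope = 0, seed = 1L) {
  env <- new.env(parent = emptyenv())
  env$rng <- with_seed(seed, .Random.seed)
  structure(list(threshold_perceive = threshold_perceive,
                 threshold_strong = threshold_strong,
                 slope = slope, seed = as.integer(seed), env = env),
            class = "psychometric_responder")
}

# one probe of the psychometric observer at a given duty
perceive <- function(responder, duty) {
  if (responder$slope <= 0) {
    return(list(perceived = duty >= responder$threshold_perceive,
                strong = duty >= responder$threshold_strong))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  assign(".Random.seed", responder$env$rng, envir = globalenv())
  u <- runif(2)
  responder$env$rng <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(
    perceived = u[1] < stats::plogis((duty - responder$threshold_perceive) /
                                       responder$slope),
    strong = u[2] < stats::plogis((duty - responder$threshold_strong) /
                                    responder$slope)
  )
}
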