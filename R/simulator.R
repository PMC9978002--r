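#' Unilateral contact torque of a grasped object
#'
#' Spring-damper contact acting only past the contact angle and never
#' pulling: zero for `theta_out <= contact_angle`, otherwise
#' `spring_rate * (theta_out - contact_angle) + contact_damping *
#' max(theta_dot, 0)`, floored at zero.
#'
#' @param theta_out Output-shaft angle (deg); vectorized.
#' @param theta_dot Shaft velocity (deg/s); vectorized.
#' @param object An [object_model()].
#' @return Contact torque (N.m), same length as `theta_out`.
#' @export
contact_torque <- function(theta_out, theta_dot, object) {
  stopifnot(inherits(object, "object_model"))
  if (object$spring_rate == 0) return(numeric(length(theta_out)))
  pen <- theta_out - object$contact_angle
  tau <- ifelse(pen > 0,
                object$spring_rate * pen +
                  object$contact_damping * pmax(theta_dot, 0),
                0)
  pmax(tau, 0)
}

#' Simulate one grasp closure
#'
#' Integrates the single-DOF drivetrain under cascade PD position / PI
#' current control while tracking a reference closure trajectory, against a
#' (possibly void) spring object. Fixed-step semi-implicit Euler at
#' `sample_rate`; anti-windup by conditional integration of the current
#' loop while the voltage command is saturated. Deterministic given the
#' profile seed.
#'
#' @param motor A [motor_params()].
#' @param gains A [controller_gains()]; `gains$sample_rate` sets the
#'   integration step.
#' @param object An [object_model()].
#' @param profile A [reference_profile()]; its `seed` is overridden by
#'   `seed` when supplied.
#' @param duration Closure duration (s), >= 1.
#' @param seed Optional integer overriding `profile$seed`.
#' @return A `grasp_trace`: list with `t` (s), `theta_ref`, `theta_out`
#'   (deg), `current` (mA), `sample_rate` and `object_meta`.
#' @examples
#' cfg <- default_sim_config()
#' tr <- simulate_closure(cfg$motor, cfg$gains, cfg$objects[["Void"]],
#'                        cfg$reference$sinusoidal, duration = 2)
#' max(abs(tr$current))
#' @export
simulate_closure <- function(motor, gains, object, profile,
                             duration = 5, seed = NULL) {
  stopifnot(inherits(motor, "motor_params"),
            inherits(gains, "controller_gains"),
            inherits(object, "object_model"),
            inherits(profile, "reference_profile"))
  if (duration < 1) stop("duration must be at least 1 s", call. = FALSE)
  if (gains$sample_rate < 100) {
    stop("sample_rate must be at least 100 Hz", call. = FALSE)
  }
  if (!is.null(seed)) profile$seed <- as.integer(seed)
  sr <- gains$sample_rate
  theta_ref <- make_reference(profile, duration, sr)
  st <- .simulate_core(
    theta_ref, 1 / sr,
    motor$torque_constant, motor$armature_resistance,
    motor$electrical_time_constant, motor$reflected_inertia,
    motor$viscous_friction, motor$current_limit, motor$voltage_limit,
    gains$kp_pos, gains$kd_pos, gains$pos_to_current_gain,
    gains$kp_cur, gains$ki_cur,
    object$spring_rate, object$contact_angle, object$contact_damping,
    full_closure_angle()
  )
  structure(list(
    t = (seq_along(theta_ref) - 1L) / sr,
    theta_ref = theta_ref,
    theta_out = st[, 1],
    current = st[, 2],
    sample_rate = sr,
    object_meta = object
  ), class = "grasp_trace")
}

#' @export
print.grasp_trace <- function(x, ...) {
  cat(sprintf(
    "<grasp_trace> %s, %.2f s @ %g Hz | peak current %.0f mA, final theta %.1f deg\n",
    x$object_meta$name, max(x$t), x$sample_rate,
    max(abs(x$current)), x$theta_out[length(x$theta_out)]))
  invisible(x)
}

#' Write / read a grasp trace as CSV
#'
#' Plain CSV with header `t_s,theta_ref_deg,theta_out_deg,current_mA`, one
#' row per sample. `read_trace_csv` restores a `grasp_trace`; the object
#' metadata is optional on re-read.
#'
#' @param trace A `grasp_trace`.
#' @param path Output CSV path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `grasp_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "grasp_trace"))
  df <- data.frame(t_s = trace$t, theta_ref_deg = trace$theta_ref,
                   theta_out_deg = trace$theta_out,
                   current_mA = trace$current)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param object Optional [object_model()] to attach as metadata.
#' @export
read_trace_csv <- function(path, object = NULL) {
  df <- read.csv(path)
  need <- c("t_s", "theta_ref_deg", "theta_out_deg", "current_mA")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sr <- 1 / stats::median(diff(df$t_s))
  structure(list(
    t = df$t_s, theta_ref = df$theta_ref_deg, theta_out = df$theta_out_deg,
    current = df$current_mA, sample_rate = sr, object_meta = object
  ), class = "grasp_trace")
}
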