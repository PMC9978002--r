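#' Motor and drivetrain parameters
#'
#' Lumped parameters of the hand powertrain reduced to a single
#' output-shaft coordinate: one DC motor plus planetary gearhead, reflected
#' to the slow shaft. Angles are in degrees at the output shaft (0 = fully
#' open, increasing = closing); currents in mA.
#'
#' @param torque_constant Output-shaft torque per armature ampere (N.m/A).
#' @param armature_resistance Armature resistance (Ohm).
#' @param electrical_time_constant First-order lag of the armature current
#'   response (s).
#' @param reflected_inertia Motor + gearhead inertia reflected at the output
#'   shaft (kg.m^2).
#' @param viscous_friction Viscous friction at the output shaft (N.m.s/rad).
#' @param current_limit Driver current limit (mA); must exceed 300 mA so
#'   contact events can cross the void-labeling threshold.
#' @param voltage_limit Supply voltage limit (V).
#' @return An object of class `motor_params`.
#' @export
motor_params <- function(torque_constant = 0.4,
                         armature_resistance = 1.0,
                         electrical_time_constant = 0.005,
                         reflected_inertia = 5e-3,
                         viscous_friction = 0.01,
                         current_limit = 2000,
                         voltage_limit = 12) {
  p <- list(
    torque_constant = torque_constant,
    armature_resistance = armature_resistance,
    electrical_time_constant = electrical_time_constant,
    reflected_inertia = reflected_inertia,
    viscous_friction = viscous_friction,
    current_limit = current_limit,
    voltage_limit = voltage_limit
  )
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all motor parameters must be finite and strictly positive",
         call. = FALSE)
  }
  if (current_limit <= 300) {
    stop("current_limit must exceed 300 mA (the void-labeling threshold)",
         call. = FALSE)
  }
  structure(p, class = "motor_params")
}

#' Cascade controller gains
#'
#' Gains of the cascade controller: an outer position loop (PD only) whose
#' output, scaled by a proportional gain, becomes the current reference of
#' an inner PI current loop.
#'
#' @param kp_pos,kd_pos Outer-loop proportional (mA/deg) and derivative
#'   (mA.s/deg) gains.
#' @param pos_to_current_gain Dimensionless gain scaling the PD output into
#'   the current reference.
#' @param kp_cur,ki_cur Inner-loop proportional (V/mA) and integral
#'   (V/(mA.s)) gains.
#' @param sample_rate Control/integration rate (Hz).
#' @return An object of class `controller_gains`.
#' @export
controller_gains <- function(kp_pos = 8,
                             kd_pos = 0.15,
                             pos_to_current_gain = 5,
                             kp_cur = 0.002,
                             ki_cur = 0.4,
                             sample_rate = 1000) {
  g <- list(
    kp_pos = kp_pos, kd_pos = kd_pos,
    pos_to_current_gain = pos_to_current_gain,
    kp_cur = kp_cur, ki_cur = ki_cur,
    sample_rate = sample_rate
  )
  vals <- unlist(g)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("controller gains must be finite and non-negative", call. = FALSE)
  }
  if (sample_rate <= 0) stop("sample_rate must be positive", call. = FALSE)
  structure(g, class = "controller_gains")
}

#' Grasped-object model
#'
#' Unilateral spring contact at the output shaft: no torque while the shaft
#' is before `contact_angle`, a linear spring (plus damping while
#' compressing) past it. `void` objects have zero spring rate.
#'
#' @param stiffness_class One of `"void"`, `"soft"`, `"rigid"`.
#' @param spring_rate Contact spring rate at the output shaft (N.m/deg);
#'   must be 0 for void objects, positive otherwise.
#' @param contact_angle Shaft angle at which the fingers meet the object
#'   (deg).
#' @param contact_damping Contact damping while compressing (N.m.s/deg).
#' @param name Optional object name (e.g. `"Hand dynam"`).
#' @return An object of class `object_model`.
#' @export
object_model <- function(stiffness_class = c("void", "soft", "rigid"),
                         spring_rate = 0,
                         contact_angle = 45,
                         contact_damping = 5e-4,
                         name = NULL) {
  stiffness_class <- match.arg(stiffness_class)
  if (stiffness_class == "void") {
    if (spring_rate != 0) {
      stop("void objects must have spring_rate = 0", call. = FALSE)
    }
  } else if (!is.finite(spring_rate) || spring_rate <= 0) {
    stop("soft/rigid objects need a positive spring_rate", call. = FALSE)
  }
  if (contact_angle <= 0 || contact_angle >= full_closure_angle()) {
    stop("contact_angle must lie strictly inside the mechanical range",
         call. = FALSE)
  }
  structure(list(
    stiffness_class = stiffness_class,
    spring_rate = spring_rate,
    contact_angle = contact_angle,
    contact_damping = contact_damping,
    name = if (is.null(name)) stiffness_class else name
  ), class = "object_model")
}

#' Mechanical range of the output shaft
#'
#' Full-closure angle of the single-DOF drivetrain abstraction (deg).
#' @return Scalar angle in degrees.
#' @export
full_closure_angle <- function() 100

#' Reference (commanded closure) profile
#'
#' Two reference families: a smooth `sinusoidal` closure ramp
#' `amplitude * (1 - cos(2*pi*f*t)) / 2`, and an `emg_like` profile that
#' ramps up under a rectified, low-pass-filtered noisy drive and then keeps
#' creeping at `residual_creep_rate` — emulating the residual muscle
#' activity that makes the commanded position grow after the fingers have
#' stopped on an object.
#'
#' @param kind `"sinusoidal"` or `"emg_like"`.
#' @param amplitude Target closure amplitude (deg).
#' @param frequency Sinusoid frequency (Hz); ignored for `emg_like`.
#' @param drive_level Dimensionless drive intensity; scales the nominal
#'   closing speed (60 deg/s at `drive_level = 1`).
#' @param residual_creep_rate Post-plateau creep rate (deg/s); must be
#'   positive for `emg_like`.
#' @param noise_sd Relative standard deviation of the drive noise (a.u.).
#' @param seed Integer seed making the profile reproducible.
#' @return An object of class `reference_profile`.
#' @export
reference_profile <- function(kind = c("sinusoidal", "emg_like"),
                              amplitude = 90,
                              frequency = 0.25,
                              drive_level = 1,
                              residual_creep_rate = 2,
                              noise_sd = 0.3,
                              seed = 1L) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("amplitude must be non-negative", call. = FALSE)
  if (kind == "emg_like" && residual_creep_rate <= 0) {
    stop("emg_like profiles need residual_creep_rate > 0", call. = FALSE)
  }
  structure(list(
    kind = kind, amplitude = amplitude, frequency = frequency,
    drive_level = drive_level, residual_creep_rate = residual_creep_rate,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "reference_profile")
}

# nominal closing speed (deg/s) at drive_level = 1 for emg_like references
.emg_nominal_speed <- 60

#' Shipped object catalog
#'
#' Named catalog of the synthetic spring objects used by the acquisition
#' protocol and the evaluation sessions: a hand dynamometer and spring
#' combinations spanning the rigid and soft regimes, plus the void
#' pseudo-object. The spring rates are synthetic design values chosen so
#' that the void / soft / rigid steady-current regimes are separated while
#' their transients overlap; they are not measured from hardware.
#'
#' @return Named list of [object_model()] objects.
#' @export
object_catalog <- function() {
  list(
    "Void"       = object_model("void",  0,     45),
    "Hand dynam" = object_model("rigid", 0.12,  45, name = "Hand dynam"),
    "4xS3"       = object_model("rigid", 0.08,  46, name = "4xS3"),
    "4xS2"       = object_model("rigid", 0.06,  44, name = "4xS2"),
    "2xS1-2xS4"  = object_model("soft",  0.022, 46, name = "2xS1-2xS4"),
    "4xS1"       = object_model("soft",  0.018, 45, name = "4xS1"),
    "2xS1"       = object_model("soft",  0.012, 44, name = "2xS1")
  )
}

#' Default simulator configuration
#'
#' The shipped parameter set (motor constants, controller gains, object
#' catalog, reference defaults and integration settings). All values are
#' synthetic: chosen so a void closure stays below 300 mA while soft and
#' rigid contacts settle into separated current regimes. See also the
#' packaged YAML equivalent `system.file("extdata", "hannes_like.yaml",
#' package = "graspsense")`.
#'
#' @return A list with components `motor`, `gains`, `objects`, `reference`
#'   and `sim` (duration s, sample_rate Hz, seed).
#' @export
default_sim_config <- function() {
  list(
    motor = motor_params(),
    gains = controller_gains(),
    objects = object_catalog(),
    reference = list(
      sinusoidal = reference_profile("sinusoidal", amplitude = 90,
                                     frequency = 0.25),
      emg_like = reference_profile("emg_like", amplitude = 90,
                                   drive_level = 1,
                                   residual_creep_rate = 2, noise_sd = 0.3)
    ),
    sim = list(duration = 5, sample_rate = 1000, seed = 1L)
  )
}

#' Load a simulator configuration from YAML
#'
#' Reads a YAML file with sections `motor`, `gains`, `objects`, `reference`
#' and `sim`; missing fields fall back to the shipped defaults.
#'
#' @param path Path to the YAML file.
#' @return A configuration list as from [default_sim_config()].
#' @export
load_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_sim_config()
  if (!is.null(raw$motor)) cfg$motor <- do.call(motor_params, raw$motor)
  if (!is.null(raw$gains)) cfg$gains <- do.call(controller_gains, raw$gains)
  if (!is.null(raw$objects)) {
    cfg$objects <- lapply(raw$objects, function(o) do.call(object_model, o))
    names(cfg$objects) <- vapply(cfg$objects, `[[`, "", "name")
  }
  if (!is.null(raw$reference)) {
    for (nm in names(raw$reference)) {
      cfg$reference[[nm]] <- do.call(reference_profile, raw$reference[[nm]])
    }
  }
  if (!is.null(raw$sim)) cfg$sim <- modifyList(cfg$sim, raw$sim)
  cfg
}
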