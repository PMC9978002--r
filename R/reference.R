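#' Sample a reference (commanded closure) trajectory
#'
#' Generates the commanded output-shaft trajectory that the cascade
#' controller will track. Sinusoidal references follow
#' `amplitude * (1 - cos(2*pi*f*t)) / 2`. EMG-like references integrate a
#' rectified, low-pass-filtered noisy drive until the closure amplitude is
#' reached, then keep creeping at `residual_creep_rate` with noisy but
#' mean-preserving increments — so the commanded position keeps growing
#' after contact, which is the signal feature separating object grasps from
#' void closures.
#'
#' @param profile A [reference_profile()].
#' @param duration Trajectory duration (s), > 0.
#' @param sample_rate Sampling rate (Hz).
#' @return Numeric vector of reference angles (deg), sampled at
#'   `t = 0, 1/sample_rate, ..., duration`.
#' @examples
#' prof <- reference_profile("sinusoidal", amplitude = 90, frequency = 0.25)
#' ref <- make_reference(prof, duration = 2, sample_rate = 100)
#' ref[length(ref)]  # 90: half period completes the closure
#' @export
make_reference <- function(profile, duration, sample_rate = 1000) {
  stopifnot(inherits(profile, "reference_profile"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  n <- round(duration * sample_rate) + 1L
  dt <- 1 / sample_rate
  t <- (seq_len(n) - 1L) * dt
  if (profile$amplitude == 0) return(numeric(n))

  switch(profile$kind,
    sinusoidal = profile$amplitude *
      (1 - cos(2 * pi * profile$frequency * t)) / 2,
    emg_like = with_seed(profile$seed, {
      # drive envelope: 1 + noise, low-pass filtered (tau = 0.1 s),
      # rectified; integrates to a monotone-in-expectation ramp
      a <- exp(-dt / 0.1)
      env <- stats::filter(rnorm(n, 0, profile$noise_sd), a,
                           method = "recursive") * (1 - a)
      speed <- .emg_nominal_speed * profile$drive_level *
        pmax(0, 1 + as.numeric(env))
      ramp <- cumsum(speed * dt)
      k_reach <- match(TRUE, ramp >= profile$amplitude)
      if (is.na(k_reach)) return(pmin(ramp, profile$amplitude))
      # post-plateau creep: mean-preserving noisy increments
      creep_env <- pmax(0, 1 + as.numeric(
        stats::filter(rnorm(n, 0, profile$noise_sd), a,
                      method = "recursive") * (1 - a)))
      creep <- cumsum(ifelse(seq_len(n) > k_reach,
                             profile$residual_creep_rate * creep_env * dt, 0))
      ifelse(seq_len(n) < k_reach, ramp, profile$amplitude + creep)
    }),
    stop("unknown reference kind: ", profile$kind, call. = FALSE)
  )
}

# evaluate `expr` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
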