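cfg <- default_sim_config()

test_that("sinusoidal references follow the closed-form closure ramp", {
  prof <- reference_profile("sinusoidal", amplitude = 90, frequency = 0.25)
  ref <- make_reference(prof, duration = 2, sample_rate = 200)
  t <- (seq_along(ref) - 1) / 200
  expect_equal(ref, 90 * (1 - cos(2 * pi * 0.25 * t)) / 2)
  # half period completes the closure
  expect_equal(ref[length(ref)], 90)
  expect_equal(ref[1], 0)
})

test_that("zero-amplitude references are identically zero", {
  for (kind in c("sinusoidal", "emg_like")) {
    prof <- reference_profile(kind, amplitude = 0)
    expect_equal(make_reference(prof, 1, 100), numeric(101))
  }
})

test_that("EMG-like references creep at the configured rate after plateau", {
  # drive_level 0.5 -> 30 deg/s nominal, amplitude 90 -> plateau near t = 3 s
  slopes <- vapply(1:100, function(s) {
    prof <- reference_profile("emg_like", amplitude = 90, drive_level = 0.5,
                              residual_creep_rate = 2, noise_sd = 0.3,
                              seed = s)
    ref <- make_reference(prof, duration = 6, sample_rate = 200)
    (ref[6 * 200 + 1] - ref[4 * 200 + 1]) / 2
  }, 0)
  expect_gt(mean(slopes), 2 * 0.8)
  expect_lt(mean(slopes), 2 * 1.2)
})

test_that("EMG-like references are non-decreasing and seed-reproducible", {
  prof <- reference_profile("emg_like", amplitude = 80, seed = 7)
  ref1 <- make_reference(prof, 5, 500)
  ref2 <- make_reference(prof, 5, 500)
  expect_identical(ref1, ref2)
  for (s in 1:20) {
    prof$seed <- s
    expect_true(all(diff(make_reference(prof, 5, 500)) >= 0))
  }
})

test_that("malformed reference kinds are rejected", {
  expect_error(reference_profile("triangle"))
  prof <- reference_profile("sinusoidal")
  prof$kind <- "triangle"
  expect_error(make_reference(prof, 1, 100), "unknown reference kind")
  expect_error(make_reference(reference_profile("sinusoidal"), -1, 100),
               "duration")
})

test_that("contact torque is unilateral and linear past the contact angle", {
  void <- cfg$objects[["Void"]]
  expect_equal(contact_torque(c(0, 30, 80), c(0, 10, -5), void), c(0, 0, 0))
  obj <- object_model("rigid", spring_rate = 0.02, contact_angle = 40,
                     contact_damping = 0)
  expect_equal(contact_torque(40, 0, obj), 0)      # boundary
  expect_equal(contact_torque(50, 0, obj), 0.2)    # 0.02 * 10
  expect_equal(contact_torque(30, 100, obj), 0)    # before contact
  # damping only while compressing, and never pulls
  objd <- object_model("rigid", spring_rate = 0.02, contact_angle = 40,
                      contact_damping = 0.01)
  expect_equal(contact_torque(50, 10, objd), 0.2 + 0.1)
  expect_equal(contact_torque(50, -10, objd), 0.2)
  expect_gte(min(contact_torque(seq(0, 100, 5), -50, objd)), 0)
})

test_that("an all-zero reference leaves the plant at rest", {
  prof <- reference_profile("sinusoidal", amplitude = 0)
  tr <- simulate_closure(cfg$motor, cfg$gains, cfg$objects[["Void"]], prof,
                         duration = 1)
  expect_equal(max(abs(tr$theta_out)), 0)
  expect_equal(max(abs(tr$current)), 0)
})

test_that("steady grasp current matches the algebraic torque balance", {
  prof <- reference_profile("emg_like", amplitude = 70, drive_level = 1,
                            residual_creep_rate = 0.01, noise_sd = 0.2,
                            seed = 3)
  for (nm in c("Hand dynam", "4xS2", "2xS1", "4xS1")) {
    obj <- cfg$objects[[nm]]
    tr <- simulate_closure(cfg$motor, cfg$gains, obj, prof, duration = 6)
    n <- length(tr$t)
    i_alg <- oracle_steady_state(cfg$motor, cfg$gains, obj, tr$theta_ref[n])
    expect_lt(abs(tr$current[n] - i_alg) / i_alg, 0.02, label = nm)
  }
})

test_that("steady-state current is non-decreasing in spring stiffness", {
  prof <- reference_profile("emg_like", amplitude = 70,
                            residual_creep_rate = 0.01, noise_sd = 0.2,
                            seed = 3)
  rates <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2)
  ss <- vapply(rates, function(k) {
    obj <- object_model("rigid", k, 45)
    tr <- simulate_closure(cfg$motor, cfg$gains, obj, prof, duration = 6)
    tr$current[length(tr$current)]
  }, 0)
  expect_true(all(diff(ss) >= 0))
})

test_that("a stiff object plateaus the encoder while the reference creeps on", {
  obj <- object_model("rigid", spring_rate = 2, contact_angle = 45)
  prof <- reference_profile("emg_like", amplitude = 80,
                            residual_creep_rate = 2, seed = 5)
  tr <- simulate_closure(cfg$motor, cfg$gains, obj, prof, duration = 5)
  n <- length(tr$t)
  expect_lte(tr$theta_out[n], obj$contact_angle + 2)
  expect_gt(tr$theta_ref[n], obj$contact_angle)
})

test_that("void closures under the shipped defaults stay below 300 mA", {
  for (s in 1:5) {
    for (ref in cfg$reference) {
      tr <- simulate_closure(cfg$motor, cfg$gains, cfg$objects[["Void"]],
                             ref, duration = 5, seed = s)
      expect_lt(max(abs(tr$current)), 300)
    }
  }
})

test_that("no sample violates the driver current limit", {
  motor <- motor_params(current_limit = 500)
  obj <- object_model("rigid", spring_rate = 0.5, contact_angle = 30)
  prof <- reference_profile("emg_like", amplitude = 90, drive_level = 2,
                            residual_creep_rate = 3, seed = 2)
  tr <- simulate_closure(motor, cfg$gains, obj, prof, duration = 4)
  expect_lte(max(abs(tr$current)), 500 + 1e-9)
})

test_that("identical configuration and seed give bit-identical traces", {
  prof <- cfg$reference$emg_like
  tr1 <- simulate_closure(cfg$motor, cfg$gains, cfg$objects[["4xS1"]], prof,
                          duration = 3, seed = 9)
  tr2 <- simulate_closure(cfg$motor, cfg$gains, cfg$objects[["4xS1"]], prof,
                          duration = 3, seed = 9)
  expect_identical(tr1$theta_out, tr2$theta_out)
  expect_identical(tr1$current, tr2$current)
})

test_that("an unstable parameter set raises a divergence error", {
  # contact stiffness far beyond what the fixed step can integrate
  bad_motor <- motor_params(reflected_inertia = 1e-9)
  obj <- object_model("rigid", spring_rate = 10, contact_angle = 10)
  expect_error(
    simulate_closure(bad_motor, cfg$gains, obj, cfg$reference$sinusoidal,
                     duration = 1),
    "diverged")
})

test_that("trace CSV round-trips through the documented format", {
  tr <- simulate_closure(cfg$motor, cfg$gains, cfg$objects[["2xS1"]],
                         cfg$reference$sinusoidal, duration = 1)
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "t_s,theta_ref_deg,theta_out_deg,current_mA")
  back <- read_trace_csv(path, object = tr$object_meta)
  expect_equal(back$current, tr$current, tolerance = 1e-6)
  expect_equal(back$theta_out, tr$theta_out, tolerance = 1e-6)
  expect_equal(back$sample_rate, tr$sample_rate, tolerance = 1e-6)
})

test_that("the YAML config loader reproduces the shipped defaults", {
  path <- system.file("extdata", "hannes_like.yaml", package = "graspsense")
  loaded <- load_sim_config(path)
  expect_equal(unclass(loaded$motor), unclass(cfg$motor))
  expect_equal(unclass(loaded$gains), unclass(cfg$gains))
  expect_setequal(names(loaded$objects), names(cfg$objects))
  expect_equal(loaded$objects[["4xS1"]]$spring_rate,
               cfg$objects[["4xS1"]]$spring_rate)
})
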