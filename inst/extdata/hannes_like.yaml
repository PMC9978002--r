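# Synthetic drivetrain + controller configuration ("hannes_like").
# All values are design choices tuned so that void / soft / rigid closures
# produce separated steady-current regimes with overlapping transients;
# none are measured from real hardware.
motor:
  torque_constant: 0.4        # N.m/A at the output shaft
  armature_resistance: 1.0    # Ohm
  electrical_time_constant: 0.005  # s
  reflected_inertia: 0.005    # kg.m^2
  viscous_friction: 0.01      # N.m.s/rad
  current_limit: 2000         # mA
  voltage_limit: 12           # V
gains:
  kp_pos: 8                   # mA/deg
  kd_pos: 0.15                # mA.s/deg
  pos_to_current_gain: 5
  kp_cur: 0.002               # V/mA
  ki_cur: 0.4                 # V/(mA.s)
  sample_rate: 1000           # Hz
objects:
  Void:       {stiffness_class: void,  spring_rate: 0,     contact_angle: 45, name: "Void"}
  Hand dynam: {stiffness_class: rigid, spring_rate: 0.12,  contact_angle: 45, name: "Hand dynam"}
  4xS3:       {stiffness_class: rigid, spring_rate: 0.08,  contact_angle: 46, name: "4xS3"}
  4xS2:       {stiffness_class: rigid, spring_rate: 0.06,  contact_angle: 44, name: "4xS2"}
  2xS1-2xS4:  {stiffness_class: soft,  spring_rate: 0.022, contact_angle: 46, name: "2xS1-2xS4"}
  4xS1:       {stiffness_class: soft,  spring_rate: 0.018, contact_angle: 45, name: "4xS1"}
  2xS1:       {stiffness_class: soft,  spring_rate: 0.012, contact_angle: 44, name: "2xS1"}
reference:
  sinusoidal: {kind: sinusoidal, amplitude: 90, frequency: 0.25}
  emg_like:   {kind: emg_like, amplitude: 90, drive_level: 1,
               residual_creep_rate: 2, noise_sd: 0.3}
sim:
  duration: 5            # s per closure
  sample_rate: 1000      # Hz (integration)
  acquisition_rate: 100  # Hz (dataset rows)
  seed: 1
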