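#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step semi-implicit Euler integration of the single-DOF drivetrain
// under cascade PD (position) / PI (current) control.
//
// Angles in degrees at the output shaft, currents in mA, voltages in V.
// Inertia and friction are in SI (kg.m^2, N.m.s/rad); spring/damping act
// per degree so contact torque is N.m directly.
//
// Per step: eps_pos -> PD -> x gain -> i_ref (clipped); eps_i -> PI -> V
// (clipped, conditional-integration anti-windup); first-order armature
// current lag toward 1000*V/R; then the mechanical update.
// [[Rcpp::export(name = ".simulate_core")]]
NumericMatrix simulate_core(NumericVector theta_ref, double dt,
                            double torque_constant,
                            double armature_resistance,
                            double electrical_time_constant,
                            double reflected_inertia,
                            double viscous_friction,
                            double current_limit, double voltage_limit,
                            double kp_pos, double kd_pos,
                            double pos_to_current_gain,
                            double kp_cur, double ki_cur,
                            double spring_rate, double contact_angle,
                            double contact_damping,
                            double theta_max) {
  const int n = theta_ref.size();
  NumericMatrix out(n, 2);  // theta_out, current
  const double deg2rad = M_PI / 180.0;
  const double rad2deg = 180.0 / M_PI;

  double theta = 0.0, omega = 0.0, current = 0.0, integ = 0.0;
  double eps_prev = theta_ref[0] - theta;

  for (int k = 0; k < n; ++k) {
    out(k, 0) = theta;
    out(k, 1) = current;
    if (k == n - 1) break;

    // outer PD position loop -> current reference
    double eps = theta_ref[k] - theta;
    double deps = (eps - eps_prev) / dt;
    eps_prev = eps;
    double i_ref = pos_to_current_gain * (kp_pos * eps + kd_pos * deps);
    if (i_ref > current_limit) i_ref = current_limit;
    if (i_ref < -current_limit) i_ref = -current_limit;

    // inner PI current loop -> voltage command, conditional integration
    double eps_i = i_ref - current;
    double v = kp_cur * eps_i + ki_cur * integ;
    bool sat = false;
    if (v > voltage_limit) { v = voltage_limit; sat = true; }
    if (v < -voltage_limit) { v = -voltage_limit; sat = true; }
    if (!sat) integ += eps_i * dt;

    // armature current: first-order lag toward V/R, driver-limited
    double i_target = 1000.0 * v / armature_resistance;
    current += (dt / electrical_time_constant) * (i_target - current);
    if (current > current_limit) current = current_limit;
    if (current < -current_limit) current = -current_limit;

    // unilateral spring contact (never pulls)
    double tau_c = 0.0;
    if (spring_rate > 0.0 && theta > contact_angle) {
      tau_c = spring_rate * (theta - contact_angle);
      if (omega > 0.0) tau_c += contact_damping * omega;
      if (tau_c < 0.0) tau_c = 0.0;
    }

    double torque = torque_constant * current / 1000.0
      - viscous_friction * omega * deg2rad - tau_c;
    double alpha = torque / reflected_inertia * rad2deg;  // deg/s^2

    omega += dt * alpha;          // semi-implicit: velocity first
    theta += dt * omega;

    // runaway shaft velocity marks step instability (stiff dynamics vs dt);
    // checked before the mechanical stops can mask it
    if (!std::isfinite(theta) || !std::isfinite(current) ||
        std::fabs(omega) > 1e7) {
      stop("simulation diverged (unstable state at t = %f s); "
           "check motor/controller parameter set against the time step",
           k * dt);
    }
    if (theta < 0.0) { theta = 0.0; if (omega < 0.0) omega = 0.0; }
    if (theta > theta_max) { theta = theta_max; if (omega > 0.0) omega = 0.0; }
  }
  return out;
}
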