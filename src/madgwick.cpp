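#include <Rcpp.h>
using namespace Rcpp;

// Madgwick gradient-descent orientation filter, 6-DOF (accel + gyro) form.
//
// Convention: q = (w, x, y, z) rotates sensor-frame vectors into the world
// frame, and the normalized accelerometer reading at rest equals the world
// +Z axis expressed in the sensor frame. Callers whose accelerometer
// reports the gravity vector itself (reading (0,0,-g) when the sensor "up"
// is +z) should negate the accelerometer input; see removeGravity().
//
// Inputs: accel n x 3 (any consistent unit; normalized internally),
// gyro n x 3 in rad/s, dt in s, beta the algorithm gain, q0 length-4
// initial quaternion. Returns n x 3 matrix of the estimated world-up
// direction expressed in the sensor frame (R(q)^T e3) at every sample.
// [[Rcpp::export]]
NumericMatrix madgwick_up_cpp(NumericMatrix accel, NumericMatrix gyro,
                              double dt, double beta, NumericVector q0) {
  const int n = accel.nrow();
  if (gyro.nrow() != n) stop("accel and gyro must have equal length");
  double q1 = q0[0], q2 = q0[1], q3 = q0[2], q4 = q0[3];
  NumericMatrix up(n, 3);
  for (int i = 0; i < n; ++i) {
    double gx = gyro(i, 0), gy = gyro(i, 1), gz = gyro(i, 2);
    double ax = accel(i, 0), ay = accel(i, 1), az = accel(i, 2);

    // quaternion rate from gyroscope
    double qDot1 = 0.5 * (-q2 * gx - q3 * gy - q4 * gz);
    double qDot2 = 0.5 * (q1 * gx + q3 * gz - q4 * gy);
    double qDot3 = 0.5 * (q1 * gy - q2 * gz + q4 * gx);
    double qDot4 = 0.5 * (q1 * gz + q2 * gy - q3 * gx);

    double norm = std::sqrt(ax * ax + ay * ay + az * az);
    if (norm > 0.0) {
      ax /= norm; ay /= norm; az /= norm;
      // gradient of the alignment objective f(q) = R(q)^T e3 - a
      double _2q1 = 2.0 * q1, _2q2 = 2.0 * q2, _2q3 = 2.0 * q3, _2q4 = 2.0 * q4;
      double _4q1 = 4.0 * q1, _4q2 = 4.0 * q2, _4q3 = 4.0 * q3;
      double _8q2 = 8.0 * q2, _8q3 = 8.0 * q3;
      double q1q1 = q1 * q1, q2q2 = q2 * q2, q3q3 = q3 * q3, q4q4 = q4 * q4;

      double s1 = _4q1 * q3q3 + _2q3 * ax + _4q1 * q2q2 - _2q2 * ay;
      double s2 = _4q2 * q4q4 - _2q4 * ax + 4.0 * q1q1 * q2 - _2q1 * ay -
                  _4q2 + _8q2 * q2q2 + _8q2 * q3q3 + _4q2 * az;
      double s3 = 4.0 * q1q1 * q3 + _2q1 * ax + _4q3 * q4q4 - _2q4 * ay -
                  _4q3 + _8q3 * q2q2 + _8q3 * q3q3 + _4q3 * az;
      double s4 = 4.0 * q2q2 * q4 - _2q2 * ax + 4.0 * q3q3 * q4 - _2q3 * ay;
      double snorm = std::sqrt(s1 * s1 + s2 * s2 + s3 * s3 + s4 * s4);
      if (snorm > 0.0) {
        qDot1 -= beta * s1 / snorm;
        qDot2 -= beta * s2 / snorm;
        qDot3 -= beta * s3 / snorm;
        qDot4 -= beta * s4 / snorm;
      }
    }

    q1 += qDot1 * dt; q2 += qDot2 * dt; q3 += qDot3 * dt; q4 += qDot4 * dt;
    double qn = std::sqrt(q1 * q1 + q2 * q2 + q3 * q3 + q4 * q4);
    q1 /= qn; q2 /= qn; q3 /= qn; q4 /= qn;

    // world up (e3) expressed in the sensor frame: R(q)^T e3
    up(i, 0) = 2.0 * (q2 * q4 - q1 * q3);
    up(i, 1) = 2.0 * (q1 * q2 + q3 * q4);
    up(i, 2) = q1 * q1 - q2 * q2 - q3 * q3 + q4 * q4;
  }
  return up;
}
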