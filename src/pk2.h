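#ifndef POLYB_PK2_H
#define POLYB_PK2_H

#include <cmath>

// Shared closed-form two-compartment infusion machinery (see pk2cmt.cpp for
// the exported R interface and the derivation notes).
namespace pk2 {

struct Macro {
  double V, alpha, beta, A, B;
};

inline Macro macro_constants(double V, double V2, double CL, double Q) {
  double k10 = CL / V, k12 = Q / V, k21 = Q / V2;
  double s = k10 + k12 + k21;
  double disc = s * s - 4.0 * k10 * k21;
  if (disc < 0) disc = 0;
  double root = std::sqrt(disc);
  if (root < 1e-9 * s) { // repeated-root guard
    k21 *= (1.0 + 1e-6);
    s = k10 + k12 + k21;
    disc = s * s - 4.0 * k10 * k21;
    root = std::sqrt(disc > 0 ? disc : 0);
  }
  Macro m;
  m.V = V;
  m.alpha = 0.5 * (s + root);
  m.beta  = 0.5 * (s - root);
  m.A = (m.alpha - k21) / (m.alpha - m.beta);
  m.B = (k21 - m.beta) / (m.alpha - m.beta);
  return m;
}

inline double event_conc(const Macro &m, double R, double D, double u) {
  if (u <= 0) return 0.0;
  const double a = m.alpha, b = m.beta;
  if (u <= D) {
    return (R / m.V) * (m.A * (1.0 - std::exp(-a * u)) / a +
                        m.B * (1.0 - std::exp(-b * u)) / b);
  }
  double w = u - D;
  return (R / m.V) * (m.A / a * (1.0 - std::exp(-a * D)) * std::exp(-a * w) +
                      m.B / b * (1.0 - std::exp(-b * D)) * std::exp(-b * w));
}

inline double event_cumauc(const Macro &m, double R, double D, double u) {
  if (u <= 0) return 0.0;
  const double a = m.alpha, b = m.beta;
  const double c = R / m.V;
  if (u <= D) {
    return c * (m.A / a * (u - (1.0 - std::exp(-a * u)) / a) +
                m.B / b * (u - (1.0 - std::exp(-b * u)) / b));
  }
  double FD = c * (m.A / a * (D - (1.0 - std::exp(-a * D)) / a) +
                   m.B / b * (D - (1.0 - std::exp(-b * D)) / b));
  double w = u - D;
  return FD + c * (m.A / (a * a) * (1.0 - std::exp(-a * D)) * (1.0 - std::exp(-a * w)) +
                   m.B / (b * b) * (1.0 - std::exp(-b * D)) * (1.0 - std::exp(-b * w)));
}

} // namespace pk2

#endif
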