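// Glucose-insulin minimal-model integrator.
//
// State vector (9 components):
//   0 G      plasma glucose                         [mg/dl]
//   1 X      remote insulin action                  [1/min]
//   2 Isc1   subcutaneous insulin, compartment 1    [uU/ml]
//   3 Isc2   subcutaneous insulin, compartment 2    [uU/ml]
//   4 Ip     plasma insulin                         [uU/ml]
//   5 Qsto1  stomach, solid phase                   [mg]
//   6 Qsto2  stomach, liquid phase                  [mg]
//   7 Qgut   gut                                    [mg]
//   8 Aabs   cumulative absorbed glucose (int. Ra)  [mg]
//
// Inputs are piecewise-constant over grid bins: insulin delivery in U/min and
// carbohydrate intake in g/min.  Integration is Dormand-Prince RK45 with
// adaptive step control, restarted at every bin boundary so the input
// discontinuities never fall inside a step.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct MMPar {
  double SG, SI, p2, Gb, VG, kd, ka2, ke, VI, kgri, kempt, kabs, fabs, BW;
  double Ipb;  // basal plasma insulin, set from the basal delivery rate
};

inline void deriv(const MMPar& p, const double* y, double ins_Umin,
                  double cho_gmin, double* dy) {
  const double G = y[0], X = y[1], Isc1 = y[2], Isc2 = y[3], Ip = y[4];
  const double Qsto1 = y[5], Qsto2 = y[6], Qgut = y[7];
  const double Ra = p.fabs * p.kabs * Qgut;               // mg/min
  const double uins = ins_Umin * 1000.0 / (p.VI * p.BW);  // uU/ml/min
  dy[0] = -(p.SG + X) * G + p.SG * p.Gb + Ra / (p.VG * p.BW);
  dy[1] = -p.p2 * (X - p.SI * (Ip - p.Ipb));
  dy[2] = -p.kd * Isc1 + uins;
  dy[3] = p.kd * Isc1 - p.ka2 * Isc2;
  dy[4] = p.ka2 * Isc2 - p.ke * Ip;
  dy[5] = -p.kgri * Qsto1 + cho_gmin * 1000.0;
  dy[6] = p.kgri * Qsto1 - p.kempt * Qsto2;
  dy[7] = p.kempt * Qsto2 - p.kabs * Qgut;
  dy[8] = Ra;
}

const int NS = 9;

// Dormand-Prince 5(4) coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
             a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
             e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// integrate one bin [t0, t0+len] with constant inputs; y updated in place
void integrate_bin(const MMPar& p, double* y, double t0, double len,
                   double ins, double cho, double rtol, double atol) {
  double t = 0.0;
  double h = std::min(len, 1.0);
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS];
  double yt[NS], y5[NS];
  deriv(p, y, ins, cho, k1);
  int iter = 0;
  while (t < len) {
    if (++iter > 100000)
      stop("ODE integrator failed to advance near t = %f min", t0 + t);
    if (h > len - t) h = len - t;
    for (int i = 0; i < NS; ++i) yt[i] = y[i] + h * a21 * k1[i];
    deriv(p, yt, ins, cho, k2);
    for (int i = 0; i < NS; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    deriv(p, yt, ins, cho, k3);
    for (int i = 0; i < NS; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    deriv(p, yt, ins, cho, k4);
    for (int i = 0; i < NS; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    deriv(p, yt, ins, cho, k5);
    for (int i = 0; i < NS; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    deriv(p, yt, ins, cho, k6);
    for (int i = 0; i < NS; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
    deriv(p, y5, ins, cho, k7);
    // error estimate: 5th order minus embedded 4th order
    double err = 0.0;
    for (int i = 0; i < NS; ++i) {
      const double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                                    e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      const double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      const double d = (y5[i] - y4) / sc;
      err += d * d;
    }
    err = std::sqrt(err / NS);
    if (!std::isfinite(err))
      stop("non-finite model state at t = %f min (parameter blow-up?)",
           t0 + t);
    if (err <= 1.0) {  // accept
      t += h;
      for (int i = 0; i < NS; ++i) {
        y[i] = y5[i];
        k1[i] = k7[i];  // FSAL
      }
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-10) stop("ODE step size underflow at t = %f min", t0 + t);
  }
}

MMPar unpack(const NumericVector& par) {
  MMPar p;
  p.SG = par["SG"];     p.SI = par["SI"];     p.p2 = par["p2"];
  p.Gb = par["Gb"];     p.VG = par["VG"];     p.kd = par["kd"];
  p.ka2 = par["ka2"];   p.ke = par["ke"];     p.VI = par["VI"];
  p.kgri = par["kgri"]; p.kempt = par["kempt"]; p.kabs = par["kabs"];
  p.fabs = par["fabs"]; p.BW = par["BW"];     p.Ipb = par["Ipb"];
  return p;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".mm_integrate_cpp")]]
NumericMatrix mm_integrate_cpp(NumericVector par, NumericVector y0,
                               NumericVector insulin, NumericVector cho,
                               double step, double rtol, double atol) {
  const MMPar p = unpack(par);
  const int n = insulin.size();
  if (cho.size() != n) stop("insulin and cho channels differ in length");
  if (y0.size() != NS) stop("state vector must have %d components", NS);
  NumericMatrix out(n + 1, NS);
  double y[NS];
  for (int i = 0; i < NS; ++i) {
    y[i] = y0[i];
    out(0, i) = y[i];
  }
  for (int k = 0; k < n; ++k) {
    integrate_bin(p, y, k * step, step, insulin[k], cho[k], rtol, atol);
    for (int i = 0; i < NS; ++i) out(k + 1, i) = y[i];
    if (!std::isfinite(y[0]))
      stop("non-finite glucose at t = %f min", (k + 1) * step);
  }
  return out;
}
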