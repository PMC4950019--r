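#include <Rcpp.h>
using namespace Rcpp;

// Integrate the boundary (gated dipole) and filling-in dynamics over one
// stimulus frame, during which the oriented drive and the opponent sources
// are constant.  Per boundary step dt: (1) thresholded dipole output from
// the current gates, (2) boundary-gated permeabilities, (3) nsub explicit
// Euler sub-steps of the two filling-in channels with dt/nsub, (4) gate
// update with dt.  State matrices are modified in place; the caller passes
// fresh copies.
// [[Rcpp::export]]
List integrate_frame_cpp(NumericMatrix zv, NumericMatrix zh,
                         NumericMatrix onf, NumericMatrix offf,
                         NumericMatrix dv, NumericMatrix dh,
                         NumericMatrix son, NumericMatrix soff,
                         double alpha, double beta, double tonic,
                         double gamma, double A, double D, double E,
                         double C, double dt, int nsteps, int nsub) {
  const int h = zv.nrow(), w = zv.ncol(), n = h * w;
  const double dtf = dt / nsub;
  NumericMatrix bv(h, w), bh(h, w), pr(h, w), pd(h, w);
  NumericMatrix tmp_on(h, w), tmp_off(h, w);
  const double eps = 1e-300;

  for (int step = 0; step < nsteps; ++step) {
    // dipole output from current gates
    for (int k = 0; k < n; ++k) {
      double yv = (dv[k] + tonic) * zv[k];
      double yh = (dh[k] + tonic) * zh[k];
      double ov = yv - yh - gamma;
      double oh = yh - yv - gamma;
      bv[k] = ov > 0 ? ov : 0;
      bh[k] = oh > 0 ? oh : 0;
    }
    // permeabilities: vertical boundaries block horizontal flow
    for (int c = 0; c < w - 1; ++c)
      for (int r = 0; r < h; ++r)
        pr(r, c) = D / (1.0 + E * (bv(r, c) + bv(r, c + 1)));
    for (int c = 0; c < w; ++c)
      for (int r = 0; r < h - 1; ++r)
        pd(r, c) = D / (1.0 + E * (bh(r, c) + bh(r + 1, c)));
    // filling-in sub-steps, ON and OFF channels independently
    for (int sub = 0; sub < nsub; ++sub) {
      for (int ch = 0; ch < 2; ++ch) {
        NumericMatrix &x = (ch == 0) ? onf : offf;
        NumericMatrix &src = (ch == 0) ? son : soff;
        NumericMatrix &nx = (ch == 0) ? tmp_on : tmp_off;
        for (int c = 0; c < w; ++c) {
          for (int r = 0; r < h; ++r) {
            double xv = x(r, c);
            double flux = 0.0;
            if (c + 1 < w) flux += pr(r, c) * (x(r, c + 1) - xv);
            if (c > 0)     flux += pr(r, c - 1) * (x(r, c - 1) - xv);
            if (r + 1 < h) flux += pd(r, c) * (x(r + 1, c) - xv);
            if (r > 0)     flux += pd(r - 1, c) * (x(r - 1, c) - xv);
            nx(r, c) = xv + dtf * (-A * xv + flux + C * src(r, c));
          }
        }
      }
      std::copy(tmp_on.begin(), tmp_on.end(), onf.begin());
      std::copy(tmp_off.begin(), tmp_off.end(), offf.begin());
    }
    // gate update (explicit Euler on the mass-action equation)
    for (int k = 0; k < n; ++k) {
      double z = zv[k] + dt * (alpha * (1.0 - zv[k]) -
                               beta * (dv[k] + tonic) * zv[k]);
      zv[k] = z < eps ? eps : (z > 1.0 ? 1.0 : z);
      z = zh[k] + dt * (alpha * (1.0 - zh[k]) -
                        beta * (dh[k] + tonic) * zh[k]);
      zh[k] = z < eps ? eps : (z > 1.0 ? 1.0 : z);
    }
  }
  return List::create(_["z_vertical"] = zv, _["z_horizontal"] = zh,
                      _["on_fill"] = onf, _["off_fill"] = offf,
                      _["bv"] = bv, _["bh"] = bh);
}
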