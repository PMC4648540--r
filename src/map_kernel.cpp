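#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <complex>

using namespace Rcpp;

// Per-pixel tuning extraction for the statistical wiring model.
//
// The receptive field of a unit at y is RF_y(x) = sum_j s_j w_j(y) G_j(x),
// so its Fourier transform factorizes into the Gaussian envelope
// exp(-k^2 sigma_r^2 / 2) times A_y(k) = sum_j s_j w_j(y) exp(-i k.x_j).
// |R(k)| is evaluated on a polar grid over the half-plane theta in [0, pi)
// (the other half is its mirror image because RF is real), and
//   theta_pref = arg(mu)/2,  mu = int |R| |k| e^{2i arg k} / int |R|
//   k_pref     = argmax_k |R|  (Maximum method)
//   OSI        = |sum_phi TC e^{2i phi}| / sum_phi TC at k_pref.
// Cells are looked up through a uniform bucket grid with the weight cutoff
// radius r_cut = sqrt(2 log(1e10)) sigma_s.

// [[Rcpp::export]]
List map_tuning_kernel(NumericVector xg, NumericVector yg,
                       NumericVector cx, NumericVector cy,
                       NumericVector sgn,
                       double sigma_r, double sigma_s,
                       int nk, int nth, double kmax) {
  const int nx = xg.size(), ny = yg.size();
  const int ncell = cx.size();
  const double rcut = std::sqrt(2.0 * std::log(1e10)) * sigma_s;
  const double dk = kmax / nk;

  // bucket index over the cell bounding box
  double bx0 = R_PosInf, bx1 = R_NegInf, by0 = R_PosInf, by1 = R_NegInf;
  for (int j = 0; j < ncell; ++j) {
    bx0 = std::min(bx0, cx[j]); bx1 = std::max(bx1, cx[j]);
    by0 = std::min(by0, cy[j]); by1 = std::max(by1, cy[j]);
  }
  const double bs = rcut;
  const int nbx = std::max(1, (int)std::floor((bx1 - bx0) / bs) + 1);
  const int nby = std::max(1, (int)std::floor((by1 - by0) / bs) + 1);
  std::vector< std::vector<int> > buckets((size_t)nbx * nby);
  for (int j = 0; j < ncell; ++j) {
    int ix = std::min(nbx - 1, std::max(0, (int)((cx[j] - bx0) / bs)));
    int iy = std::min(nby - 1, std::max(0, (int)((cy[j] - by0) / bs)));
    buckets[(size_t)iy * nbx + ix].push_back(j);
  }

  std::vector<double> cphi(nth), sphi(nth), c2phi(nth), s2phi(nth);
  for (int t = 0; t < nth; ++t) {
    double phi = M_PI * t / nth;
    cphi[t] = std::cos(phi); sphi[t] = std::sin(phi);
    c2phi[t] = std::cos(2 * phi); s2phi[t] = std::sin(2 * phi);
  }
  std::vector<double> env(nk + 1);
  for (int i = 0; i <= nk; ++i) {
    double k = i * dk;
    env[i] = std::exp(-0.5 * k * k * sigma_r * sigma_r);
  }

  NumericMatrix theta(nx, ny), osi(nx, ny), kpref(nx, ny);
  std::vector<double> modgrid((size_t)(nk + 1) * nth);
  std::vector<double> are((size_t)(nk + 1) * nth), aim((size_t)(nk + 1) * nth);
  std::vector<int> near;
  near.reserve(64);

  for (int jy = 0; jy < ny; ++jy) {
    for (int jx = 0; jx < nx; ++jx) {
      const double px = xg[jx], py = yg[jy];
      // gather nearby cells
      near.clear();
      int ix0 = (int)std::floor((px - rcut - bx0) / bs);
      int ix1 = (int)std::floor((px + rcut - bx0) / bs);
      int iy0 = (int)std::floor((py - rcut - by0) / bs);
      int iy1 = (int)std::floor((py + rcut - by0) / bs);
      for (int biy = std::max(0, iy0); biy <= std::min(nby - 1, iy1); ++biy)
        for (int bix = std::max(0, ix0); bix <= std::min(nbx - 1, ix1); ++bix)
          for (int j : buckets[(size_t)biy * nbx + bix]) {
            double ddx = cx[j] - px, ddy = cy[j] - py;
            if (ddx * ddx + ddy * ddy <= rcut * rcut) near.push_back(j);
          }
      if (near.empty()) {
        theta(jx, jy) = NA_REAL; osi(jx, jy) = NA_REAL;
        kpref(jx, jy) = NA_REAL;
        continue;
      }
      std::fill(are.begin(), are.end(), 0.0);
      std::fill(aim.begin(), aim.end(), 0.0);
      for (int j : near) {
        double ddx = cx[j] - px, ddy = cy[j] - py;
        double w = sgn[j] *
          std::exp(-(ddx * ddx + ddy * ddy) / (2.0 * sigma_s * sigma_s));
        for (int t = 0; t < nth; ++t) {
          // projection of the cell position on the ray direction
          double p = cx[j] * cphi[t] + cy[j] * sphi[t];
          double dc = std::cos(dk * p), ds = -std::sin(dk * p); // e^{-i dk p}
          double er = 1.0, ei = 0.0;
          size_t base = (size_t)t * (nk + 1);
          for (int i = 0; i <= nk; ++i) {
            are[base + i] += w * er;
            aim[base + i] += w * ei;
            double nr = er * dc - ei * ds;
            ei = er * ds + ei * dc;
            er = nr;
          }
        }
      }
      // modulus with envelope; quadrature, mu, maximum
      double tot = 0.0, mur = 0.0, mui = 0.0, best = -1.0;
      int besti = 1, bestt = 0;
      for (int t = 0; t < nth; ++t) {
        size_t base = (size_t)t * (nk + 1);
        for (int i = 1; i <= nk; ++i) {
          double m = env[i] *
            std::sqrt(are[base + i] * are[base + i] +
                      aim[base + i] * aim[base + i]);
          modgrid[base + i] = m;
          double k = i * dk, wq = k;   // d^2k = k dk dphi
          tot += m * wq;
          mur += m * wq * k * c2phi[t];
          mui += m * wq * k * s2phi[t];
          if (m > best) { best = m; besti = i; bestt = t; }
        }
      }
      if (tot <= 0.0 || best <= 0.0) {
        theta(jx, jy) = NA_REAL; osi(jx, jy) = NA_REAL;
        kpref(jx, jy) = NA_REAL;
        continue;
      }
      mur /= tot; mui /= tot;
      // edge-orientation convention: the preferred edge is perpendicular
      // to the preferred grating wavevector
      double th = 0.5 * std::atan2(mui, mur) + M_PI_2;
      th -= M_PI * std::floor(th / M_PI);
      // OSI on the ring k = k_pref
      double rr = 0.0, ri = 0.0, rs = 0.0;
      for (int t = 0; t < nth; ++t) {
        double m = modgrid[(size_t)t * (nk + 1) + besti];
        rr += m * c2phi[t]; ri += m * s2phi[t]; rs += m;
      }
      theta(jx, jy) = th;
      osi(jx, jy) = (rs > 0.0) ? std::sqrt(rr * rr + ri * ri) / rs : 0.0;
      kpref(jx, jy) = besti * dk;
      (void)bestt;
    }
  }
  return List::create(_["theta"] = theta, _["osi"] = osi,
                      _["kpref"] = kpref);
}
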