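#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Random sequential adsorption of equal hard disks in a square box.
// Uniform-random insertion attempts; an attempt is accepted iff the new
// disk overlaps no accepted disk. Overlap tests use a uniform grid hash
// with cell size >= one diameter so each attempt checks at most 9 cells.
// Draws come from R's RNG so set.seed() on the R side fixes the run.
//
// box:        side length (same unit as diameter)
// diameter:   disk diameter
// max_attempts: number of insertion attempts
// periodic:   minimum-image distances and centers in [0, box);
//             otherwise centers confined to [r, box - r] (minus-sampling)
// record_every: if > 0, append (attempts, n_accepted) after every
//             record_every attempts
// [[Rcpp::export]]
List rsa_deposit_cpp(double box, double diameter, double max_attempts,
                     bool periodic, double record_every) {
  const double d2 = diameter * diameter;
  const double r = diameter / 2.0;

  int ncell = (int)std::floor(box / diameter);
  bool use_grid = ncell >= 4;
  if (ncell < 1) ncell = 1;
  const double cell = box / ncell;

  std::vector<double> xs, ys;
  std::vector<std::vector<int>> grid(use_grid ? (size_t)ncell * ncell : 1);

  std::vector<double> rec_attempts, rec_n;

  RNGScope scope;
  double lo = periodic ? 0.0 : r;
  double hi = periodic ? box : box - r;
  if (!periodic && hi < lo) {
    // box too small for even one disk
    return List::create(_["x"] = NumericVector(0), _["y"] = NumericVector(0),
                        _["attempts"] = 0.0,
                        _["rec_attempts"] = NumericVector(0),
                        _["rec_n"] = NumericVector(0));
  }

  const long long n_att = (long long)max_attempts;
  const long long rec_step = record_every > 0 ? (long long)record_every : 0;
  for (long long att = 1; att <= n_att; att++) {
    double x = lo + unif_rand() * (hi - lo);
    double y = lo + unif_rand() * (hi - lo);
    bool ok = true;

    if (use_grid) {
      int cx = (int)(x / cell); if (cx >= ncell) cx = ncell - 1;
      int cy = (int)(y / cell); if (cy >= ncell) cy = ncell - 1;
      for (int dx = -1; dx <= 1 && ok; dx++) {
        for (int dy = -1; dy <= 1 && ok; dy++) {
          int gx = cx + dx, gy = cy + dy;
          if (periodic) {
            gx = (gx + ncell) % ncell;
            gy = (gy + ncell) % ncell;
          } else if (gx < 0 || gx >= ncell || gy < 0 || gy >= ncell) {
            continue;
          }
          const std::vector<int>& bucket = grid[(size_t)gx * ncell + gy];
          for (size_t k = 0; k < bucket.size(); k++) {
            double ddx = x - xs[bucket[k]];
            double ddy = y - ys[bucket[k]];
            if (periodic) {
              if (ddx > box / 2) ddx -= box; else if (ddx < -box / 2) ddx += box;
              if (ddy > box / 2) ddy -= box; else if (ddy < -box / 2) ddy += box;
            }
            if (ddx * ddx + ddy * ddy < d2) { ok = false; break; }
          }
        }
      }
    } else {
      for (size_t k = 0; k < xs.size() && ok; k++) {
        double ddx = x - xs[k];
        double ddy = y - ys[k];
        if (periodic) {
          if (ddx > box / 2) ddx -= box; else if (ddx < -box / 2) ddx += box;
          if (ddy > box / 2) ddy -= box; else if (ddy < -box / 2) ddy += box;
        }
        if (ddx * ddx + ddy * ddy < d2) ok = false;
      }
    }

    if (ok) {
      xs.push_back(x);
      ys.push_back(y);
      if (use_grid) {
        int cx = (int)(x / cell); if (cx >= ncell) cx = ncell - 1;
        int cy = (int)(y / cell); if (cy >= ncell) cy = ncell - 1;
        grid[(size_t)cx * ncell + cy].push_back((int)xs.size() - 1);
      }
    }
    if (rec_step > 0 && att % rec_step == 0) {
      rec_attempts.push_back((double)att);
      rec_n.push_back((double)xs.size());
    }
  }

  return List::create(_["x"] = wrap(xs), _["y"] = wrap(ys),
                      _["attempts"] = max_attempts,
                      _["rec_attempts"] = wrap(rec_attempts),
                      _["rec_n"] = wrap(rec_n));
}
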