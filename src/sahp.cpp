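#include <Rcpp.h>
using namespace Rcpp;

// uniform direction on the unit sphere from R's normal RNG
static inline void rand_unit(double *u) {
  double n2 = 0.0;
  do {
    n2 = 0.0;
    for (int a = 0; a < 3; ++a) {
      u[a] = norm_rand();
      n2 += u[a] * u[a];
    }
  } while (n2 <= 1e-24);
  double inv = 1.0 / std::sqrt(n2);
  for (int a = 0; a < 3; ++a) u[a] *= inv;
}

static inline double dist3(const std::vector<double> &x, int i, int j) {
  double s = 0.0;
  for (int a = 0; a < 3; ++a) {
    double d = x[3 * i + a] - x[3 * j + a];
    s += d * d;
  }
  return std::sqrt(s);
}

// Metropolis chain for the freely-jointed hard-sphere heteropolymer.
// bonds: n-1 constrained bond lengths; radii: n monomer radii (mean blob
// Rg); overlap when |r_i - r_j| < a*(R_i + R_j) for |i - j| >= 2.
// Proposal: bead i>0 displaced by a fixed-magnitude random vector,
// rescaled onto the bond sphere around bead i-1, and the tail j >= i
// translated rigidly. All proposals without overlap are accepted.
// [[Rcpp::export(name = ".sahp_mc_cpp")]]
List sahp_mc_cpp(NumericVector bonds, NumericVector radii, double a,
                 double step_mag, double steps_d, int sample_every,
                 double burnin_d, double cutoff, bool keep_positions) {
  const int n = radii.size();
  if (bonds.size() != n - 1) stop("need n-1 bonds for n monomers");
  const long long steps = (long long)steps_d;
  const long long burnin = (long long)burnin_d;

  std::vector<double> x(3 * n, 0.0);
  double acc = 0.0;
  for (int i = 1; i < n; ++i) {
    acc += bonds[i - 1];
    x[3 * i] = acc; // straight chain along x
  }
  // feasibility: the straight chain maximises every pairwise separation
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      if (dist3(x, i, j) < a * (radii[i] + radii[j]) - 1e-12)
        stop("infeasible SAHP geometry: bonds cannot avoid hard-core overlap");
    }
  }

  NumericMatrix counts(n, n);
  long long n_samp_max = (steps > burnin) ? (steps - burnin) / sample_every + 1 : 0;
  NumericVector pos_store(keep_positions ? (R_xlen_t)(n_samp_max * n * 3) : 0);
  long long n_samp = 0, n_accept = 0;

  GetRNGstate();
  double u[3];
  for (long long step = 1; step <= steps; ++step) {
    int i = 1 + (int)(unif_rand() * (n - 1));
    if (i > n - 1) i = n - 1;
    rand_unit(u);
    double cand[3], dir[3];
    double nrm = 0.0;
    for (int a2 = 0; a2 < 3; ++a2) {
      cand[a2] = x[3 * i + a2] + step_mag * u[a2];
      dir[a2] = cand[a2] - x[3 * (i - 1) + a2];
      nrm += dir[a2] * dir[a2];
    }
    nrm = std::sqrt(nrm);
    if (nrm <= 1e-12) continue; // degenerate direction: reject
    double delta[3];
    for (int a2 = 0; a2 < 3; ++a2) {
      double newp = x[3 * (i - 1) + a2] + bonds[i - 1] * dir[a2] / nrm;
      delta[a2] = newp - x[3 * i + a2];
    }
    // tentative rigid translation of the tail
    for (int j = i; j < n; ++j)
      for (int a2 = 0; a2 < 3; ++a2) x[3 * j + a2] += delta[a2];
    // only head-tail pairs change relative geometry
    bool overlap = false;
    for (int uu = 0; uu < i && !overlap; ++uu) {
      for (int vv = i; vv < n; ++vv) {
        if (vv - uu < 2) continue;
        if (dist3(x, uu, vv) < a * (radii[uu] + radii[vv])) {
          overlap = true;
          break;
        }
      }
    }
    if (overlap) {
      for (int j = i; j < n; ++j)
        for (int a2 = 0; a2 < 3; ++a2) x[3 * j + a2] -= delta[a2];
    } else {
      ++n_accept;
    }
    if (step > burnin && ((step - burnin) % sample_every == 0)) {
      for (int p = 0; p < n; ++p) {
        for (int q = p + 1; q < n; ++q) {
          if (dist3(x, p, q) - (radii[p] + radii[q]) < cutoff) {
            counts(p, q) += 1.0;
            counts(q, p) += 1.0;
          }
        }
      }
      if (keep_positions) {
        for (int p = 0; p < n; ++p)
          for (int a2 = 0; a2 < 3; ++a2)
            pos_store[(R_xlen_t)(n_samp * n * 3 + p * 3 + a2)] = x[3 * p + a2];
      }
      ++n_samp;
    }
  }
  PutRNGstate();

  List out = List::create(
    _["counts"] = counts,
    _["n_samples"] = (double)n_samp,
    _["acceptance_rate"] = steps > 0 ? (double)n_accept / (double)steps : NA_REAL);
  if (keep_positions) {
    NumericVector trimmed(pos_store.begin(),
                          pos_store.begin() + (R_xlen_t)(n_samp * n * 3));
    trimmed.attr("dim") =
      IntegerVector::create(3, n, (int)n_samp); // axis-major; reshaped in R
    out["positions"] = trimmed;
  }
  return out;
}

// Freely-jointed C-alpha chains with optional per-residue spherical
// confinement around the first residue of the residue's blob.
// center_idx: 0-based index of the confinement center residue, -1 = free.
// [[Rcpp::export(name = ".gen_chain_frames_cpp")]]
NumericVector gen_chain_frames_cpp(int n_frames, int n_res, double bond,
                                   IntegerVector center_idx,
                                   NumericVector radius, int max_tries) {
  NumericVector out((R_xlen_t)n_frames * n_res * 3);
  GetRNGstate();
  double u[3];
  std::vector<double> x(3 * n_res);
  for (int f = 0; f < n_frames; ++f) {
    x[0] = x[1] = x[2] = 0.0;
    for (int k = 1; k < n_res; ++k) {
      int ci = center_idx[k];
      double cand[3];
      for (int t = 0; t < max_tries; ++t) {
        rand_unit(u);
        for (int a = 0; a < 3; ++a) cand[a] = x[3 * (k - 1) + a] + bond * u[a];
        if (ci < 0) break;
        double d2 = 0.0;
        for (int a = 0; a < 3; ++a) {
          double d = cand[a] - x[3 * ci + a];
          d2 += d * d;
        }
        if (d2 <= radius[k] * radius[k]) break;
      }
      for (int a = 0; a < 3; ++a) x[3 * k + a] = cand[a];
    }
    for (int k = 0; k < n_res; ++k)
      for (int a = 0; a < 3; ++a)
        out[(R_xlen_t)f * n_res * 3 + (R_xlen_t)k * 3 + a] = x[3 * k + a];
  }
  PutRNGstate();
  out.attr("dim") = IntegerVector::create(3, n_res, n_frames);
  return out;
}
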