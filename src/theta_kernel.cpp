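#include <Rcpp.h>
using namespace Rcpp;

// mean-field radial attraction, closed form; conjugate branch avoids
// cancellation when n*chi is tiny
static inline double f_att_mf(double nl, double nr, double chi) {
  if (nl <= 0.0 || nr <= 0.0) return 0.0;
  double u = 1.0 + (nr - nl) * chi;
  double s = std::sqrt(u * u + 4.0 * nl * chi);
  double pl = (u >= 0.0) ? 2.0 / (u + s) : (-u + s) / (2.0 * nl * chi);
  double v = 1.0 + (nl - nr) * chi;
  double t = std::sqrt(v * v + 4.0 * nr * chi);
  double pr = (v >= 0.0) ? 2.0 / (v + t) : (-v + t) / (2.0 * nr * chi);
  return nl * (std::log(pl) + 0.5 * (1.0 - pl)) +
         nr * (std::log(pr) + 0.5 * (1.0 - pr));
}

static inline double logistic(double x) {
  if (x > 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// lazily filled (i, j) -> f_att table shared across the size grid of one
// row (the attraction depends on the integer counts only)
struct FAttCache {
  std::vector<double> tab;
  int nj;
  double chi;
  FAttCache(int ni_cap, int nj_cap, double chi_)
      : tab((size_t)(ni_cap + 1) * (nj_cap + 1),
            std::numeric_limits<double>::quiet_NaN()),
        nj(nj_cap + 1), chi(chi_) {}
  inline double get(int i, int j) {
    size_t idx = (size_t)i * nj + j;
    if (idx >= tab.size()) return f_att_mf(i, j, chi);
    double v = tab[idx];
    if (std::isnan(v)) {
      v = f_att_mf(i, j, chi);
      tab[idx] = v;
    }
    return v;
  }
};

// Poisson-averaged Langmuir adsorption probability at one particle size.
// log_zv = ln(z * v_bind). The receptor support is truncated at the
// quantile retaining trunc_mass; the ligand support is accumulated with
// log-domain recursive Poisson weights until the same mass is reached.
// Shortcuts that leave the result unchanged beyond ~1e-15: (i,j) terms are
// screened with the limiting-form bound |F_att| <= min(i,j) *
// log1p(max(i,j) * chi) before the mean-field solve; pmf-negligible
// ligand rows are skipped; and once no remaining ligand count can reach
// measurable occupancy (the linear repulsion having irrecoverably beaten
// the logarithmic attraction), the loop stops outright.
static double theta_counts(double mu_l, double mu_r, double chi,
                           double rep_receptor, double rep_ligand,
                           double log_zv, double trunc_mass,
                           FAttCache &cache) {
  int nr_hi = (mu_r > 0.0) ? (int)R::qpois(trunc_mass, mu_r, 1, 0) + 1 : 0;
  std::vector<double> wr(nr_hi + 1);
  for (int j = 0; j <= nr_hi; ++j) {
    wr[j] = (mu_r > 0.0) ? R::dpois(j, mu_r, 0) : (j == 0 ? 1.0 : 0.0);
  }
  const double log_mu = (mu_l > 0.0) ? std::log(mu_l) : 0.0;
  double lw = -mu_l;  // ln P(N_L = 0)
  double theta = 0.0;
  for (int i = 0; ; ++i) {
    if (i > 0) {
      if (mu_l <= 0.0) break;
      lw += log_mu - std::log((double)i);
    }
    double wl = std::exp(lw);
    double li = std::log1p((double)i * chi);
    if (wl > 1e-18) {
      double row = 0.0;
      for (int j = 0; j <= nr_hi; ++j) {
        // cheapest attainable f_tot for this (i,j); skip hopeless terms
        double f_bound = ((i < j) ? i * std::log1p(j * chi) : j * li);
        double arg_ub = log_zv + f_bound - rep_ligand * i - rep_receptor * j;
        if (arg_ub < -37.0) continue;
        double f_tot = cache.get(i, j) + rep_receptor * j + rep_ligand * i;
        row += wr[j] * logistic(log_zv - f_tot);
      }
      theta += wl * row;
    }
    if (mu_l <= 0.0) break;
    // best case over all remaining i: attraction at most nr_hi*log1p(i*chi)
    // grows logarithmically, the ligand repulsion linearly; once the
    // latter has won (and the bound is already decreasing), stop
    if (rep_ligand > 0.0 && i * rep_ligand > nr_hi &&
        log_zv + nr_hi * li - rep_ligand * i < -37.0) {
      break;
    }
    // past the mode the pmf decays geometrically with ratio mu/(i+1), so
    // the remaining mass is below wl / (1 - mu/(i+1)); stop once that
    // bound drops under the truncation allowance
    if (i >= mu_l &&
        wl * (i + 1.0) / (i + 1.0 - mu_l) < 1.0 - trunc_mass) {
      break;
    }
    if (i > 10 * mu_l + 1000) break;  // hard stop, pmf long gone
  }
  return theta;
}

// [[Rcpp::export]]
double theta_forward_row_cpp(double ligand_density, double receptor_density,
                             double bond_energy, double gyration_radius,
                             double brush_height, double size_mean,
                             double size_sd, int size_points,
                             double rep_receptor, double rep_ligand,
                             double activity, double truncation_mass,
                             double min_radius) {
  if (activity <= 0.0) return 0.0;
  double chi = std::exp(-bond_energy);
  double rg = gyration_radius;
  double log_z = std::log(activity);

  // truncated-normal size grid, mirrored from the R averaging layer
  std::vector<double> radius, wt;
  if (size_sd <= 0.0) {
    radius.push_back(size_mean);
    wt.push_back(1.0);
  } else {
    double lo = std::max(size_mean - 3.0 * size_sd,
                         std::max(0.25 * size_sd, 1e-3));
    lo = std::max(lo, min_radius);
    double hi = size_mean + 3.0 * size_sd;
    if (hi <= lo) { radius.push_back(size_mean); wt.push_back(1.0); }
    else {
      double wsum = 0.0;
      for (int k = 0; k < size_points; ++k) {
        double r = lo + (hi - lo) * k / (size_points - 1);
        double w = R::dnorm(r, size_mean, size_sd, 0);
        radius.push_back(r); wt.push_back(w); wsum += w;
      }
      for (int k = 0; k < size_points; ++k) wt[k] /= wsum;
    }
  }

  double r_max = 0.0;
  for (size_t s = 0; s < radius.size(); ++s) {
    if (radius[s] > r_max) r_max = radius[s];
  }
  double mu_l_max = ligand_density * 2.0 * M_PI * r_max * rg;
  double mu_r_max = receptor_density * M_PI *
                    (r_max * r_max - (r_max - rg) * (r_max - rg));
  int nr_cap = (mu_r_max > 0.0)
    ? (int)R::qpois(truncation_mass, mu_r_max, 1, 0) + 1 : 0;
  int ni_cap = (int)(mu_l_max + 12.0 * std::sqrt(mu_l_max + 1.0) + 40.0);
  if (rep_ligand > 0.0) {
    // the tail cutoff limits the support to roughly the point where the
    // linear repulsion has irrecoverably beaten the attraction
    double log_zv_max = log_z +
      std::log(M_PI * (r_max + brush_height) * (r_max + brush_height) * rg);
    double i_stop = 1000.0;
    for (int it = 0; it < 50; ++it) {  // fixed point of the cutoff relation
      double nxt = (log_zv_max + 40.0 +
                    nr_cap * std::log1p(i_stop * chi)) / rep_ligand;
      if (std::abs(nxt - i_stop) < 1.0) { i_stop = nxt; break; }
      i_stop = std::max(nxt, 1.0);
    }
    ni_cap = std::min(ni_cap, (int)(i_stop + 10.0));
  }
  FAttCache cache(std::max(ni_cap, 1), std::max(nr_cap, 1), chi);

  double theta = 0.0;
  for (size_t s = 0; s < radius.size(); ++s) {
    double rnp = radius[s];
    double area_np = 2.0 * M_PI * rnp * rg;
    double area_surf = M_PI * (rnp * rnp - (rnp - rg) * (rnp - rg));
    double r_eff = rnp + brush_height;
    double v_bind = M_PI * r_eff * r_eff * rg;
    double mu_l = ligand_density * area_np;
    double mu_r = receptor_density * area_surf;
    theta += wt[s] * theta_counts(mu_l, mu_r, chi, rep_receptor, rep_ligand,
                                  log_z + std::log(v_bind), truncation_mass,
                                  cache);
  }
  return theta;
}
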