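#include <Rcpp.h>
using namespace Rcpp;

// Growth-detection guard against float noise: an organism "grew" only if its
// final biomass exceeds the founding biomass of 1 by more than this.
static const double GREW_TOL = 1e-12;

struct PairResult {
  double X, Y;                       // final biomasses (fitness)
  double c_net, p_net;               // net signed transfer totals
  double c_given, c_taken;           // split magnitudes (plant -> fungus C)
  double p_given, p_taken;           // split magnitudes (fungus -> plant P)
  bool plant_grew, fungus_grew;
};

// One full lifecycle of a single plant-fungus pair. Each step: gather
// (specialised uptake = biomass, nonspecialised = efficiency * biomass),
// exchange one transfer per resource (a taker's claim is clamped to what the
// partner gathered this step), grow by the smaller post-exchange pool.
// Pools are not stored between steps.
static inline PairResult run_pair(double alpha, double beta,
                                  double gamma, double eps, int steps) {
  PairResult r;
  r.X = 1.0; r.Y = 1.0;
  r.c_net = r.p_net = 0.0;
  r.c_given = r.c_taken = r.p_given = r.p_taken = 0.0;
  for (int n = 0; n < steps; ++n) {
    double plant_c = r.X;            // plant gathers C at 100% of biomass
    double plant_p = alpha * r.X;
    double fungus_p = r.Y;           // fungus gathers P at 100% of biomass
    double fungus_c = beta * r.Y;
    double ct = (gamma >= 0.0) ? gamma * plant_c
                               : -std::min(-gamma * r.X, fungus_c);
    double pt = (eps >= 0.0) ? eps * fungus_p
                             : -std::min(-eps * r.Y, plant_p);
    double pool_pc = plant_c - ct;
    double pool_fc = fungus_c + ct;
    double pool_pp = plant_p + pt;
    double pool_fp = fungus_p - pt;
    r.X += std::min(pool_pc, pool_pp);
    r.Y += std::min(pool_fc, pool_fp);
    r.c_net += ct;
    r.p_net += pt;
    if (ct >= 0.0) r.c_given += ct; else r.c_taken -= ct;
    if (pt >= 0.0) r.p_given += pt; else r.p_taken -= pt;
  }
  r.plant_grew = r.X > 1.0 + GREW_TOL;
  r.fungus_grew = r.Y > 1.0 + GREW_TOL;
  return r;
}

// [[Rcpp::export(name = ".lifecycle_batch_cpp")]]
List lifecycle_batch_cpp(double alpha, double beta,
                         NumericVector gamma, NumericVector epsilon,
                         int steps) {
  int n = gamma.size();
  if (epsilon.size() != n)
    stop("gamma and epsilon must have equal length");
  NumericVector pf(n), ff(n), cnet(n), pnet(n),
      cgiven(n), ctaken(n), pgiven(n), ptaken(n);
  LogicalVector pg(n), fg(n);
  for (int i = 0; i < n; ++i) {
    PairResult r = run_pair(alpha, beta, gamma[i], epsilon[i], steps);
    pf[i] = r.X; ff[i] = r.Y;
    cnet[i] = r.c_net; pnet[i] = r.p_net;
    cgiven[i] = r.c_given; ctaken[i] = r.c_taken;
    pgiven[i] = r.p_given; ptaken[i] = r.p_taken;
    pg[i] = r.plant_grew; fg[i] = r.fungus_grew;
  }
  return List::create(
      _["plant_fitness"] = pf, _["fungus_fitness"] = ff,
      _["total_c_to_fungus"] = cnet, _["total_p_to_plant"] = pnet,
      _["c_given"] = cgiven, _["c_taken"] = ctaken,
      _["p_given"] = pgiven, _["p_taken"] = ptaken,
      _["plant_grew"] = pg, _["fungus_grew"] = fg);
}

// Full outer grid of strategies for one uptake combination; used by
// compute_landscape. Matrices are gamma (rows) x epsilon (cols).
// [[Rcpp::export(name = ".landscape_batch_cpp")]]
List landscape_batch_cpp(double alpha, double beta,
                         NumericVector gamma, NumericVector epsilon,
                         int steps) {
  int ng = gamma.size(), ne = epsilon.size();
  NumericMatrix pf(ng, ne), ff(ng, ne), cnet(ng, ne), pnet(ng, ne);
  LogicalMatrix pg(ng, ne), fg(ng, ne);
  for (int j = 0; j < ne; ++j) {
    for (int i = 0; i < ng; ++i) {
      PairResult r = run_pair(alpha, beta, gamma[i], epsilon[j], steps);
      pf(i, j) = r.X; ff(i, j) = r.Y;
      cnet(i, j) = r.c_net; pnet(i, j) = r.p_net;
      pg(i, j) = r.plant_grew; fg(i, j) = r.fungus_grew;
    }
  }
  return List::create(
      _["plant_fitness"] = pf, _["fungus_fitness"] = ff,
      _["total_c_to_fungus"] = cnet, _["total_p_to_plant"] = pnet,
      _["plant_grew"] = pg, _["fungus_grew"] = fg);
}

// Fisher-Yates shuffle of 0..n-1 using R's RNG (keeps trajectories fully
// reproducible from set.seed()).
static void shuffle_idx(std::vector<int> &idx) {
  int n = (int)idx.size();
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// Weighted sample with replacement: one index from cumulative weights.
static inline int sample_cum(const std::vector<double> &cum, double total) {
  double u = unif_rand() * total;
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] > u) hi = mid; else lo = mid + 1;
  }
  return lo;
}

struct GenRecord {
  double mean_gamma, mean_epsilon, frac_plants_grew, frac_fungi_grew;
  bool plant_extinct, fungus_extinct;
};

// One generation of the individual-based model. Plants carry the gamma trait,
// fungi the epsilon trait. Stages: (i) uniform random one-to-one pairing;
// (ii) each pair runs a full lifecycle; (iii) reproductive weight = final
// biomass (or biomass gain) if the individual grew, else 0; (iv) offspring
// sampled with replacement proportional to weight, each mutated by a
// Gaussian step and clipped to [-1, 1]. A species whose weights are all zero
// is flagged extinct and leaves no offspring. `plant`/`fungus` are updated
// in place when both species survive.
static GenRecord do_generation(std::vector<double> &plant,
                               std::vector<double> &fungus,
                               double alpha, double beta, int steps,
                               double mutation_sd, bool weight_gain,
                               std::vector<int> &perm,
                               std::vector<double> &wp, std::vector<double> &wf,
                               std::vector<double> &np, std::vector<double> &nf) {
  int n = (int)plant.size();
  shuffle_idx(perm);
  int n_pg = 0, n_fg = 0;
  double sum_g = 0.0, sum_e = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = perm[i];
    PairResult r = run_pair(alpha, beta, plant[i], fungus[j], steps);
    wp[i] = r.plant_grew ? (weight_gain ? r.X - 1.0 : r.X) : 0.0;
    wf[j] = r.fungus_grew ? (weight_gain ? r.Y - 1.0 : r.Y) : 0.0;
    if (r.plant_grew) ++n_pg;
    if (r.fungus_grew) ++n_fg;
    sum_g += plant[i];
    sum_e += fungus[j];
  }
  double tot_p = 0.0, tot_f = 0.0;
  for (int i = 0; i < n; ++i) { tot_p += wp[i]; wp[i] = tot_p; }
  for (int i = 0; i < n; ++i) { tot_f += wf[i]; wf[i] = tot_f; }

  GenRecord rec;
  rec.mean_gamma = sum_g / n;
  rec.mean_epsilon = sum_e / n;
  rec.frac_plants_grew = (double)n_pg / n;
  rec.frac_fungi_grew = (double)n_fg / n;
  rec.plant_extinct = tot_p <= 0.0;
  rec.fungus_extinct = tot_f <= 0.0;
  if (rec.plant_extinct || rec.fungus_extinct) return rec;

  for (int k = 0; k < n; ++k) {
    int p = sample_cum(wp, tot_p);
    double t = plant[p] + norm_rand() * mutation_sd;
    np[k] = std::min(1.0, std::max(-1.0, t));
  }
  for (int k = 0; k < n; ++k) {
    int p = sample_cum(wf, tot_f);
    double t = fungus[p] + norm_rand() * mutation_sd;
    nf[k] = std::min(1.0, std::max(-1.0, t));
  }
  plant.swap(np);
  fungus.swap(nf);
  return rec;
}

// [[Rcpp::export(name = ".step_generation_cpp")]]
List step_generation_cpp(NumericVector plant_gamma, NumericVector fungus_epsilon,
                         double alpha, double beta, int steps,
                         double mutation_sd, bool weight_gain) {
  int n = plant_gamma.size();
  if (fungus_epsilon.size() != n)
    stop("plant and fungus populations must have equal size");
  std::vector<double> plant(plant_gamma.begin(), plant_gamma.end());
  std::vector<double> fungus(fungus_epsilon.begin(), fungus_epsilon.end());
  std::vector<int> perm(n);
  std::vector<double> wp(n), wf(n), np(n), nf(n);
  GenRecord rec = do_generation(plant, fungus, alpha, beta, steps,
                                mutation_sd, weight_gain, perm, wp, wf, np, nf);
  List out = List::create(
      _["mean_gamma"] = rec.mean_gamma, _["mean_epsilon"] = rec.mean_epsilon,
      _["frac_plants_grew"] = rec.frac_plants_grew,
      _["frac_fungi_grew"] = rec.frac_fungi_grew,
      _["plant_extinct"] = rec.plant_extinct,
      _["fungus_extinct"] = rec.fungus_extinct);
  if (rec.plant_extinct || rec.fungus_extinct) {
    out["next_plant"] = R_NilValue;
    out["next_fungus"] = R_NilValue;
  } else {
    out["next_plant"] = NumericVector(plant.begin(), plant.end());
    out["next_fungus"] = NumericVector(fungus.begin(), fungus.end());
  }
  return out;
}

// Full evolution run. Matches the generation-by-generation R path
// step_generation() draw for draw (including the reproduction draws of the
// final recorded generation), so both routes give identical trajectories
// from the same seed. outcome code: 0 reached cap, 1 plant extinct,
// 2 fungus extinct, 3 both extinct.
// [[Rcpp::export(name = ".run_evolution_cpp")]]
List run_evolution_cpp(NumericVector plant0, NumericVector fungus0,
                       double alpha, double beta, int steps,
                       double mutation_sd, bool weight_gain,
                       int generation_cap) {
  int n = plant0.size();
  if (fungus0.size() != n)
    stop("plant and fungus populations must have equal size");
  std::vector<double> plant(plant0.begin(), plant0.end());
  std::vector<double> fungus(fungus0.begin(), fungus0.end());
  std::vector<int> perm(n);
  std::vector<double> wp(n), wf(n), np(n), nf(n);
  NumericMatrix rec(generation_cap, 4);
  int g = 0, outcome = 0;
  while (g < generation_cap) {
    GenRecord r = do_generation(plant, fungus, alpha, beta, steps,
                                mutation_sd, weight_gain, perm, wp, wf, np, nf);
    rec(g, 0) = r.mean_gamma; rec(g, 1) = r.mean_epsilon;
    rec(g, 2) = r.frac_plants_grew; rec(g, 3) = r.frac_fungi_grew;
    ++g;
    if (r.plant_extinct || r.fungus_extinct) {
      outcome = (r.plant_extinct ? 1 : 0) + (r.fungus_extinct ? 2 : 0);
      break;
    }
  }
  return List::create(_["records"] = rec, _["terminal"] = g,
                      _["outcome"] = outcome);
}
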