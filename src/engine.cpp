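// Simulation engines for the host-microbiome jump process and its
// Euler-Maruyama diffusion approximation.
//
// All randomness comes from R's RNG (unif_rand / norm_rand / R::rbeta), so
// set.seed() on the R side makes every run bit-reproducible.
//
// Event sampling in the discrete engine is a single-uniform inverse-CDF over
// a fixed lexicographic ordering: host death first; then, for each taxon j in
// index order, the block "a microbe of taxon j dies" (sub-ordered: immigrant
// replacement by taxon 1..K, replicative replacement by taxon 1..K,
// non-replacement); then the block "an empty slot is selected" (same
// sub-order, non-fill last). The block value of the uniform is rescaled into
// the block, which is exactly the flat inverse CDF.

#include <RcppArmadillo.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// discrete jump process
// ---------------------------------------------------------------------------

// Pick which slot "dies": taxon j (prob n_j/N) or empty space (prob x0).
// Rescales u into the chosen block (exact inverse-CDF refinement).
static inline int pick_block(double u, const std::vector<int> &n, int N,
                             int K, double &u_sub) {
  double c = 0.0;
  for (int j = 0; j < K; ++j) {
    double pj = static_cast<double>(n[j]) / N;
    if (pj > 0.0 && u < c + pj) {
      u_sub = (u - c) / pj;
      return j;
    }
    c += pj;
  }
  double p0 = 1.0 - c; // empty-space frequency
  u_sub = (p0 > 0.0) ? (u - c) / p0 : 0.0;
  if (u_sub >= 1.0) u_sub = 0.0; // guard against fp residue
  return K;
}

// Replacement / fill outcome: immigrant of taxon k (m * p_k), replicative
// copy of resident k ((1-m) * x_k / D), or nothing ((1-m) * alpha0*x0/D).
// Returns k in [0, K), or K for "nothing". When D == 0 (empty host,
// alpha0 == 0) the replication term is 0 by continuity and all of (1-m)
// falls on "nothing".
static inline int pick_replacement(double u, double m, double alpha0,
                                   const std::vector<int> &n, long L, int N,
                                   const std::vector<double> &p, int K) {
  double x0 = static_cast<double>(N - L) / N;
  double D = alpha0 * x0 + static_cast<double>(L) / N;
  double c = 0.0;
  for (int k = 0; k < K; ++k) {
    double q = m * p[k];
    if (u < c + q) return k;
    c += q;
  }
  if (D > 0.0) {
    for (int k = 0; k < K; ++k) {
      double q = (1.0 - m) * (static_cast<double>(n[k]) / N) / D;
      if (u < c + q) return k;
      c += q;
    }
  }
  return K;
}

// One step of the jump process. Returns 1 on host death (state untouched),
// 0 otherwise. Counts and total load L are modified in place.
static inline int one_step(std::vector<int> &n, long &L, int N, double m,
                           double tau, double alpha0,
                           const std::vector<double> &p, int K) {
  double u = unif_rand();
  if (u < tau) return 1;
  if (tau > 0.0) u = (u - tau) / (1.0 - tau);
  double us = 0.0;
  int blk = pick_block(u, n, N, K, us);
  int k = pick_replacement(us, m, alpha0, n, L, N, p, K);
  if (blk < K) {          // a microbe of taxon blk dies
    if (k < K) {
      if (k != blk) { n[blk]--; n[k]++; }
    } else {
      n[blk]--; L--;      // unreplaced death
    }
  } else {                // empty slot selected
    if (k < K) { n[k]++; L++; }
  }
  return 0;
}

// [[Rcpp::export]]
List cpp_sim_host_discrete(IntegerVector init, int N, double m, double tau,
                           double alpha0, NumericVector p, int max_steps,
                           int record_every) {
  int K = init.size();
  std::vector<int> n(init.begin(), init.end());
  std::vector<double> pp(p.begin(), p.end());
  long L = 0;
  for (int k = 0; k < K; ++k) L += n[k];

  std::vector<int> times;
  std::vector<int> rec; // row-major K columns
  IntegerVector cmax(K);
  for (int k = 0; k < K; ++k) cmax[k] = n[k];

  times.push_back(0);
  for (int k = 0; k < K; ++k) rec.push_back(n[k]);

  int death_step = NA_INTEGER;
  for (int t = 1; t <= max_steps; ++t) {
    int died = one_step(n, L, N, m, tau, alpha0, pp, K);
    if (died) { death_step = t; break; }
    for (int k = 0; k < K; ++k)
      if (n[k] > cmax[k]) cmax[k] = n[k];
    if (t % record_every == 0) {
      times.push_back(t);
      for (int k = 0; k < K; ++k) rec.push_back(n[k]);
    }
  }

  int nr = times.size();
  IntegerMatrix counts(nr, K);
  for (int i = 0; i < nr; ++i)
    for (int k = 0; k < K; ++k) counts(i, k) = rec[i * K + k];
  return List::create(_["times"] = wrap(times), _["counts"] = counts,
                      _["death_step"] = death_step, _["count_max"] = cmax,
                      _["final"] = IntegerVector(n.begin(), n.end()));
}

// Replicate single steps from a fixed state; returns nrep x (K+1) matrix of
// per-taxon count changes plus a host-death flag column. Used as the Monte
// Carlo oracle for the analytic transition probabilities and the SDE moments.
// [[Rcpp::export]]
IntegerMatrix cpp_one_step_batch(IntegerVector init, int N, double m,
                                 double tau, double alpha0, NumericVector p,
                                 int nrep) {
  int K = init.size();
  std::vector<double> pp(p.begin(), p.end());
  IntegerMatrix out(nrep, K + 1);
  long L0 = 0;
  for (int k = 0; k < K; ++k) L0 += init[k];
  for (int r = 0; r < nrep; ++r) {
    std::vector<int> n(init.begin(), init.end());
    long L = L0;
    int died = one_step(n, L, N, m, tau, alpha0, pp, K);
    for (int k = 0; k < K; ++k) out(r, k) = n[k] - init[k];
    out(r, K) = died;
  }
  return out;
}

// ---------------------------------------------------------------------------
// inheritance kernel (shared by both engines)
// ---------------------------------------------------------------------------

// Draw a transferred fraction per taxon: f ~ Beta(a+1, b+1).
static inline double draw_fraction(double a, double b) {
  return R::rbeta(a + 1.0, b + 1.0);
}

// Discrete split: transferred count = round(f * n_parent), ties to even,
// clamped to [0, n_parent]. Conservation is exact by construction.
static inline int split_count(int n_parent, double a, double b) {
  if (n_parent == 0) return 0;
  double f = draw_fraction(a, b);
  double t = std::nearbyint(f * n_parent);
  if (t < 0.0) t = 0.0;
  if (t > n_parent) t = n_parent;
  return static_cast<int>(t);
}

// ---------------------------------------------------------------------------
// discrete population engine
// ---------------------------------------------------------------------------

// inh_mode: 0 = none (newborns empty), 1 = beta kernel.
// lineage_taxon: 1-based taxon index whose slot-level extinction is tracked,
// 0 to disable.
// [[Rcpp::export]]
List cpp_run_population_discrete(IntegerMatrix init, int N, double m,
                                 double tau, double alpha0, NumericVector p,
                                 int t_max, IntegerVector record_steps,
                                 int inh_mode, NumericVector a,
                                 NumericVector b, bool log_births,
                                 int lineage_taxon) {
  int H = init.nrow(), K = init.ncol();
  std::vector<double> pp(p.begin(), p.end());
  std::vector<std::vector<int> > n(H, std::vector<int>(K));
  std::vector<long> L(H, 0);
  for (int h = 0; h < H; ++h)
    for (int k = 0; k < K; ++k) { n[h][k] = init(h, k); L[h] += init(h, k); }

  int lin = lineage_taxon - 1; // -1 disables
  std::vector<double> ext_time(H, NA_REAL);
  std::vector<int> peak(H, 0);
  if (lin >= 0)
    for (int h = 0; h < H; ++h) {
      peak[h] = n[h][lin];
      if (n[h][lin] == 0) ext_time[h] = 0.0;
    }

  std::vector<double> births; // step, dead, parent, before[K], transf[K], after[K]
  int bw = 3 + 3 * K;

  List snaps;
  std::vector<int> snap_times;
  int rp = 0, nrs = record_steps.size();
  auto maybe_record = [&](int t) {
    while (rp < nrs && record_steps[rp] == t) {
      IntegerMatrix s(H, K);
      for (int h = 0; h < H; ++h)
        for (int k = 0; k < K; ++k) s(h, k) = n[h][k];
      snaps.push_back(s);
      snap_times.push_back(t);
      ++rp;
    }
  };
  maybe_record(0);

  for (int t = 1; t <= t_max; ++t) {
    for (int h = 0; h < H; ++h) {
      int died = one_step(n[h], L[h], N, m, tau, alpha0, pp, K);
      if (died) {
        // uniform parent among the other H-1 hosts
        int par = static_cast<int>(unif_rand() * (H - 1));
        if (par >= H - 1) par = H - 2; // unif_rand() == 1 guard
        if (par >= h) ++par;
        std::vector<int> before(n[par]);
        std::vector<int> transf(K, 0);
        if (inh_mode == 1)
          for (int k = 0; k < K; ++k)
            transf[k] = split_count(before[k], a[k], b[k]);
        long Lnew = 0, Lpar = 0;
        for (int k = 0; k < K; ++k) {
          n[par][k] = before[k] - transf[k];
          n[h][k] = transf[k];
          Lnew += transf[k];
          Lpar += n[par][k];
        }
        L[h] = Lnew;
        L[par] = Lpar;
        if (log_births) {
          births.push_back(t);
          births.push_back(h + 1);
          births.push_back(par + 1);
          for (int k = 0; k < K; ++k) births.push_back(before[k]);
          for (int k = 0; k < K; ++k) births.push_back(transf[k]);
          for (int k = 0; k < K; ++k) births.push_back(n[par][k]);
        }
        if (lin >= 0) {
          if (ISNA(ext_time[h]) && n[h][lin] == 0) ext_time[h] = t;
          if (ISNA(ext_time[par]) && n[par][lin] == 0) ext_time[par] = t;
          if (n[h][lin] > peak[h]) peak[h] = n[h][lin];
        }
      } else if (lin >= 0) {
        if (n[h][lin] > peak[h]) peak[h] = n[h][lin];
        if (ISNA(ext_time[h]) && n[h][lin] == 0) ext_time[h] = t;
      }
    }
    maybe_record(t);
  }

  NumericMatrix bm(births.size() / bw, bw);
  for (int i = 0; i < bm.nrow(); ++i)
    for (int j = 0; j < bw; ++j) bm(i, j) = births[i * bw + j];

  return List::create(
      _["times"] = wrap(snap_times), _["snapshots"] = snaps,
      _["births"] = bm,
      _["lineage_ext_time"] = NumericVector(ext_time.begin(), ext_time.end()),
      _["lineage_peak"] = IntegerVector(peak.begin(), peak.end()));
}

// ---------------------------------------------------------------------------
// SDE engine (Euler-Maruyama)
// ---------------------------------------------------------------------------

// Per-step jump moments of the K-taxon process, on the frequency scale.
// A_k = E[delta_k], V = E[delta delta^T] - A A^T, with delta the one-step
// frequency change (entries in {0, +-1/N}).
static void sde_moments(const arma::vec &x, int N, double m, double tau,
                        double alpha0, const arma::vec &p, arma::vec &A,
                        arma::mat &V) {
  int K = x.n_elem;
  double Nd = static_cast<double>(N);
  double Ltot = arma::accu(x);
  double x0 = 1.0 - Ltot;
  if (x0 < 0.0) x0 = 0.0;
  double D = alpha0 * x0 + Ltot;
  double s = 1.0 - tau;
  arma::vec gain(K), loss(K);
  for (int k = 0; k < K; ++k) {
    double rep = (D > 0.0) ? (1.0 - m) * x[k] / D : 0.0;
    gain[k] = s * (m * p[k] + rep) * (1.0 - x[k]);
    loss[k] = s * x[k] *
              (m * (1.0 - p[k]) + ((D > 0.0) ? (1.0 - m) * (D - x[k]) / D : 0.0));
  }
  A = (gain - loss) / Nd;
  arma::mat M(K, K, arma::fill::zeros);
  for (int k = 0; k < K; ++k) M(k, k) = (gain[k] + loss[k]) / (Nd * Nd);
  for (int k = 0; k < K; ++k)
    for (int l = k + 1; l < K; ++l) {
      double rl = (D > 0.0) ? (1.0 - m) * x[l] / D : 0.0;
      double rk = (D > 0.0) ? (1.0 - m) * x[k] / D : 0.0;
      double pkl = s * x[k] * (m * p[l] + rl); // k dies, replaced by l
      double plk = s * x[l] * (m * p[k] + rk);
      M(k, l) = M(l, k) = -(pkl + plk) / (Nd * Nd);
    }
  V = M - A * A.t();
}

// Symmetric PSD square root with an eigenvalue floor at 0. Eigenvalues below
// -1e-8 signal a genuinely non-PSD matrix and raise an error.
static arma::mat psd_sqrt(const arma::mat &V) {
  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, V))
    stop("eigendecomposition of the covariance matrix failed");
  if (eval.min() < -1e-8)
    stop("covariance matrix has a negative eigenvalue beyond tolerance");
  for (arma::uword i = 0; i < eval.n_elem; ++i)
    if (eval[i] < 0.0) eval[i] = 0.0;
  return evec * arma::diagmat(arma::sqrt(eval)) * evec.t();
}

// One EM update plus the boundary policy (clip negatives to 0; rescale by
// 1/sum if the total frequency exceeds 1).
static void em_step(arma::vec &x, int N, double m, double tau, double alpha0,
                    const arma::vec &p, double dt) {
  int K = x.n_elem;
  arma::vec A(K);
  arma::mat V(K, K);
  sde_moments(x, N, m, tau, alpha0, p, A, V);
  arma::mat B = psd_sqrt(V);
  arma::vec dW(K);
  double sq = std::sqrt(dt);
  for (int k = 0; k < K; ++k) dW[k] = sq * norm_rand();
  x = x + A * dt + B * dW;
  for (int k = 0; k < K; ++k)
    if (x[k] < 0.0) x[k] = 0.0;
  double Ltot = arma::accu(x);
  if (Ltot > 1.0) x *= 1.0 / Ltot;
}

// [[Rcpp::export]]
List cpp_drift_cov(NumericVector x, int N, double m, double tau, double alpha0,
                   NumericVector p) {
  arma::vec xv(x.begin(), x.size());
  arma::vec pv(p.begin(), p.size());
  arma::vec A;
  arma::mat V;
  sde_moments(xv, N, m, tau, alpha0, pv, A, V);
  return List::create(_["A"] = wrap(A), _["V"] = wrap(V));
}

// [[Rcpp::export]]
List cpp_sim_host_sde(NumericVector init, int N, double m, double tau,
                      double alpha0, NumericVector p, double dt, double t_end,
                      double record_every) {
  int K = init.size();
  arma::vec x(init.begin(), K);
  arma::vec pv(p.begin(), K);
  std::vector<double> times;
  std::vector<double> rec;
  times.push_back(0.0);
  for (int k = 0; k < K; ++k) rec.push_back(x[k]);
  double t = 0.0, next_rec = record_every;
  while (t < t_end - 1e-9) {
    double step = std::min(dt, t_end - t);
    em_step(x, N, m, tau, alpha0, pv, step);
    t += step;
    if (t >= next_rec - 1e-9 || t >= t_end - 1e-9) {
      times.push_back(t);
      for (int k = 0; k < K; ++k) rec.push_back(x[k]);
      while (next_rec <= t + 1e-9) next_rec += record_every;
    }
  }
  int nr = times.size();
  NumericMatrix freqs(nr, K);
  for (int i = 0; i < nr; ++i)
    for (int k = 0; k < K; ++k) freqs(i, k) = rec[i * K + k];
  return List::create(_["times"] = wrap(times), _["freqs"] = freqs,
                      _["final"] = NumericVector(x.begin(), x.end()));
}

// Population version: exponential host lifespans (mean 1/tau), EM steps of
// size dt between death events, deaths processed in ascending host index
// within a time step. tau <= 0 means immortal hosts.
// [[Rcpp::export]]
List cpp_run_population_sde(NumericMatrix init, int N, double m, double tau,
                            double alpha0, NumericVector p, double dt,
                            double t_max, NumericVector record_times,
                            int inh_mode, NumericVector a, NumericVector b) {
  int H = init.nrow(), K = init.ncol();
  arma::vec pv(p.begin(), K);
  std::vector<arma::vec> x(H, arma::vec(K));
  for (int h = 0; h < H; ++h)
    for (int k = 0; k < K; ++k) x[h][k] = init(h, k);
  std::vector<double> death(H);
  for (int h = 0; h < H; ++h)
    death[h] = (tau > 0.0) ? exp_rand() / tau : R_PosInf;

  List snaps;
  std::vector<double> snap_times;
  int rp = 0, nrs = record_times.size();
  auto maybe_record = [&](double t) {
    while (rp < nrs && record_times[rp] <= t + 1e-9) {
      NumericMatrix s(H, K);
      for (int h = 0; h < H; ++h)
        for (int k = 0; k < K; ++k) s(h, k) = x[h][k];
      snaps.push_back(s);
      snap_times.push_back(record_times[rp]);
      ++rp;
    }
  };
  maybe_record(0.0);

  double t = 0.0;
  while (t < t_max - 1e-9) {
    double step = std::min(dt, t_max - t);
    for (int h = 0; h < H; ++h) {
      if (death[h] <= t + step) {
        int par = static_cast<int>(unif_rand() * (H - 1));
        if (par >= H - 1) par = H - 2;
        if (par >= h) ++par;
        arma::vec transf(K, arma::fill::zeros);
        if (inh_mode == 1)
          for (int k = 0; k < K; ++k)
            transf[k] = draw_fraction(a[k], b[k]) * x[par][k];
        x[par] -= transf;
        x[h] = transf;
        death[h] = t + step + ((tau > 0.0) ? exp_rand() / tau : R_PosInf);
      } else {
        em_step(x[h], N, m, tau, alpha0, pv, step);
      }
    }
    t += step;
    maybe_record(t);
  }
  maybe_record(t_max);

  return List::create(_["times"] = wrap(snap_times), _["snapshots"] = snaps);
}
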