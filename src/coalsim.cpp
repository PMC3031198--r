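// Structured-coalescent simulator for a taxon-pair (divergence with
// post-divergence symmetric migration and exponential size change), plus
// finite-sites mutation (JC / equal-input F81 / HKY) and the per-locus
// summary-statistic kernel used by the batch reference-table driver.
//
// Unit convention (pinned by the E[pi per site] = theta property test):
// time is measured so that a pair of lineages in a deme of scaled size
// theta_ref = theta_B1 + theta_B2 coalesces at rate 1; a deme of size
// theta_d has per-pair coalescence rate theta_ref / theta_d.  Mutation
// events occur per site at rate theta_eff / 2 per unit branch time.
// Backward per-lineage migration rate is 2 * Nm * theta_ref / theta_d(t).
//
// All randomness comes from R's RNG stream (unif_rand etc.) so set.seed()
// in R makes every simulation reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <map>

using namespace Rcpp;

namespace {

struct Tree {
  int ntip;
  std::vector<int> parent;   // 2*ntip-1 entries, -1 at root
  std::vector<double> time;  // node times, tips at 0
};

inline double runif01() { return unif_rand(); }

inline int sample_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// deme size at time t (backward), piecewise exponential then constant
inline double deme_size(double t, double thB, double thA, double tB) {
  if (tB <= 0.0 || t >= tB) return thA;
  double g = std::log(thB / thA) / tB;
  return thB * std::exp(-g * t);
}

inline double deme_growth(double t, double thB, double thA, double tB) {
  if (tB <= 0.0 || t >= tB) return 0.0;
  return std::log(thB / thA) / tB;
}

// waiting time for hazard a * exp(r u); Inf if the event never fires
inline double hazard_wait(double a, double r, double E) {
  if (a <= 0.0) return R_PosInf;
  if (r == 0.0) return E / a;
  double arg = 1.0 + r * E / a;
  if (arg <= 0.0) return R_PosInf;
  return std::log(arg) / r;
}

Tree sim_tree(int n1, int n2, double tau,
              double thetaA, double thA1, double thA2,
              double thB1, double thB2, double tB1, double tB2,
              double Nm) {
  int n = n1 + n2;
  Tree tr;
  tr.ntip = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.time.assign(2 * n - 1, 0.0);

  double thetaRef = thB1 + thB2;

  std::vector<int> deme[2];
  for (int i = 0; i < n1; ++i) deme[0].push_back(i);
  for (int i = 0; i < n2; ++i) deme[1].push_back(n1 + i);
  int next_node = n;
  int nlin = n;
  double t = 0.0;

  double thB[2] = {thB1, thB2};
  double thA_[2] = {thA1, thA2};
  double tB[2] = {tB1, tB2};

  while (nlin > 1 && t < tau) {
    // end of the current epoch: nearest growth-onset boundary, else tau
    double t_end = tau;
    for (int d = 0; d < 2; ++d)
      if (tB[d] > t && tB[d] < t_end) t_end = tB[d];

    double u_min = R_PosInf;
    int d_min = -1;
    double coal_frac_min = 0.0;
    for (int d = 0; d < 2; ++d) {
      int k = (int)deme[d].size();
      double coal_coeff = 0.5 * k * (k - 1);
      double mig_coeff = 2.0 * Nm * k;
      double tot = coal_coeff + mig_coeff;
      if (tot <= 0.0) continue;
      double sz = deme_size(t, thB[d], thA_[d], tB[d]);
      double a = tot * thetaRef / sz;
      double r = deme_growth(t, thB[d], thA_[d], tB[d]);
      double u = hazard_wait(a, r, exp_rand());
      if (u < u_min) { u_min = u; d_min = d; coal_frac_min = coal_coeff / tot; }
    }

    if (d_min >= 0 && t + u_min < t_end) {
      t += u_min;
      std::vector<int>& dm = deme[d_min];
      if (runif01() < coal_frac_min) {
        int i = sample_int((int)dm.size());
        int j = sample_int((int)dm.size() - 1);
        if (j >= i) ++j;
        int a_node = dm[i], b_node = dm[j];
        int p = next_node++;
        tr.parent[a_node] = p; tr.parent[b_node] = p;
        tr.time[p] = t;
        if (i > j) std::swap(i, j);
        dm[i] = p;
        dm.erase(dm.begin() + j);
        --nlin;
      } else {
        int i = sample_int((int)dm.size());
        deme[1 - d_min].push_back(dm[i]);
        dm.erase(dm.begin() + i);
      }
    } else {
      t = t_end;  // conditional restart at the epoch boundary is exact
    }
  }

  // ancestral panmictic phase: constant size thetaA
  if (nlin > 1) {
    if (t < tau) t = tau;
    std::vector<int> all;
    all.reserve(nlin);
    for (int d = 0; d < 2; ++d)
      for (size_t i = 0; i < deme[d].size(); ++i) all.push_back(deme[d][i]);
    int k = nlin;
    while (k > 1) {
      double rate = 0.5 * k * (k - 1) * thetaRef / thetaA;
      t += exp_rand() / rate;
      int i = sample_int(k);
      int j = sample_int(k - 1);
      if (j >= i) ++j;
      int p = next_node++;
      tr.parent[all[i]] = p; tr.parent[all[j]] = p;
      tr.time[p] = t;
      if (i > j) std::swap(i, j);
      all[i] = p;
      all.erase(all.begin() + j);
      --k;
    }
  }
  return tr;
}

// substitution jump to a state != cur
inline int jump_state(int cur, int model, double kappa, const double* fr) {
  if (model == 0) {  // JC: uniform over the other three
    int j = sample_int(3);
    return j >= cur ? j + 1 : j;
  }
  double w[3];
  int states[3];
  int m = 0;
  for (int j = 0; j < 4; ++j) {
    if (j == cur) continue;
    double wt = fr[j];
    if (model == 2) {  // HKY: transitions (A<->G, C<->T) up-weighted by kappa
      bool ts = ((cur == 0 && j == 2) || (cur == 2 && j == 0) ||
                 (cur == 1 && j == 3) || (cur == 3 && j == 1));
      if (ts) wt *= kappa;
    }
    w[m] = wt; states[m] = j; ++m;
  }
  double tot = w[0] + w[1] + w[2];
  double u = runif01() * tot;
  if (u < w[0]) return states[0];
  if (u < w[0] + w[1]) return states[1];
  return states[2];
}

inline int draw_base(const double* fr) {
  double u = runif01();
  double c = 0.0;
  for (int j = 0; j < 3; ++j) {
    c += fr[j];
    if (u < c) return j;
  }
  return 3;
}

struct MutEvent { int site; int node; double tpos; };

// Tip states at mutated columns only (column-major: states[col*ntip + i]);
// unaffected columns are monomorphic and carry no signal for any statistic
// computed here.
struct MutStates {
  int ntip = 0;
  int S = 0;
  std::vector<int> states;
  std::vector<int> sites;
  // scratch reused across calls to keep the hot loop allocation-free
  std::vector<double> blen, cum;
  std::vector<MutEvent> events;
  std::vector<int> child_head, child_next, order, stack, st, nev_node;
};

// Evolve sequences over the tree.  Events are Poisson on total branch
// length, assigned to branches by length and to sites uniformly; each
// affected site is then evolved root-to-tip, applying that site's events
// in age order along each branch (repeat hits allowed).
void mutate_on_tree(const std::vector<int>& parent, const std::vector<double>& time,
                    int ntip, int L, double mu, int model, double kappa,
                    const double* fr, MutStates& out) {
  int nnode = (int)parent.size();
  out.ntip = ntip;
  out.blen.assign(nnode, 0.0);
  double total = 0.0;
  for (int v = 0; v < nnode; ++v) {
    if (parent[v] >= 0) { out.blen[v] = time[parent[v]] - time[v]; total += out.blen[v]; }
  }
  out.cum.resize(nnode);
  double acc = 0.0;
  for (int v = 0; v < nnode; ++v) { acc += out.blen[v]; out.cum[v] = acc; }

  int nev = (total > 0.0 && mu > 0.0) ? (int)R::rpois(mu * total * L) : 0;

  out.events.clear();
  out.events.reserve(nev);
  for (int e = 0; e < nev; ++e) {
    double u = runif01() * total;
    int v = (int)(std::lower_bound(out.cum.begin(), out.cum.end(), u) - out.cum.begin());
    if (v >= nnode) v = nnode - 1;
    int site = sample_int(L);
    double tpos = time[v] + runif01() * out.blen[v];
    out.events.push_back(MutEvent{site, v, tpos});
  }
  // group by site (ascending), preserving draw order within a site
  std::stable_sort(out.events.begin(), out.events.end(),
                   [](const MutEvent& a, const MutEvent& b) { return a.site < b.site; });

  // children lists + deterministic pre-order (children in increasing id)
  out.child_head.assign(nnode, -1);
  out.child_next.assign(nnode, -1);
  int root = -1;
  for (int v = nnode - 1; v >= 0; --v) {
    if (parent[v] >= 0) {
      out.child_next[v] = out.child_head[parent[v]];
      out.child_head[parent[v]] = v;
    } else {
      root = v;
    }
  }
  out.order.clear();
  out.stack.clear();
  out.stack.push_back(root);
  while (!out.stack.empty()) {
    int v = out.stack.back(); out.stack.pop_back();
    out.order.push_back(v);
    // push in reverse so smaller-id children are visited first
    int ids[64]; int nid = 0;
    for (int c = out.child_head[v]; c >= 0; c = out.child_next[c]) ids[nid++] = c;
    for (int c = nid - 1; c >= 0; --c) out.stack.push_back(ids[c]);
  }

  out.sites.clear();
  out.states.clear();
  out.st.resize(nnode);
  out.nev_node.assign(nnode, 0);

  size_t e0 = 0;
  while (e0 < out.events.size()) {
    size_t e1 = e0;
    int site = out.events[e0].site;
    while (e1 < out.events.size() && out.events[e1].site == site) ++e1;
    // per-branch event counts for this site; order within branch follows
    // tpos (oldest first), but the jump chain outcome only depends on the
    // number of applications given exchangeable event draws
    for (size_t e = e0; e < e1; ++e) out.nev_node[out.events[e].node]++;
    out.sites.push_back(site);
    out.st[root] = draw_base(fr);
    size_t col_base = out.states.size();
    out.states.resize(col_base + ntip);
    for (size_t oi = 0; oi < out.order.size(); ++oi) {
      int v = out.order[oi];
      if (v != root) {
        int s = out.st[parent[v]];
        for (int k = 0; k < out.nev_node[v]; ++k) s = jump_state(s, model, kappa, fr);
        out.st[v] = s;
      }
      if (v < ntip) out.states[col_base + v] = out.st[v];
    }
    for (size_t e = e0; e < e1; ++e) out.nev_node[out.events[e].node] = 0;
    e0 = e1;
  }
  out.S = (int)out.sites.size();
}

// ---- summary statistics ---------------------------------------------------

inline double harmonic(int n) {  // a_n = sum_{i=1}^{n-1} 1/i
  double a = 0.0;
  for (int i = 1; i < n; ++i) a += 1.0 / i;
  return a;
}

// Tajima (1989) variance of (pi - theta_W): e1*S + e2*S*(S-1)
inline double sd_pi_theta_ns(int n, int S) {
  if (S == 0) return 0.0;
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i < n; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * (double)n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double v = e1 * S + e2 * (double)S * (S - 1.0);
  return v > 0.0 ? std::sqrt(v) : 0.0;
}

// class indices in the statistic vector (see R manifest `ss_classes()`)
enum {
  PI_POOL = 0, PI_1, PI_2, PI_B, PI_NET,
  THW_POOL, THW_1, THW_2,
  SDPT_POOL, SDPT_1, SDPT_2,
  SH_POOL, SH_1, SH_2,
  S_POOL, S_1, S_2,
  S_XY, PSI_W, N_CLASSES
};

// within-group mean pi, Wakeley within-sample correlation s, Shannon sH,
// segregating sites etc., all on the per-locus (count) scale.
// `states` is column-major over the S mutated columns.
void stats_from_d(const std::vector<int>& d, const std::vector<int>& states,
                  int S, int n1, int n2, double* out) {
  int n = n1 + n2;
  for (int i = 0; i < N_CLASSES; ++i) out[i] = NA_REAL;

  auto D = [&](int i, int j) { return (double)d[i * n + j]; };

  // pooled / within pi, Wakeley s via shared-member moment sums
  auto group_stats = [&](int lo, int hi, double& pi, double& s_w, int& nseg,
                         double& sh) {
    int m = hi - lo;
    pi = NA_REAL; s_w = NA_REAL; nseg = 0; sh = NA_REAL;
    if (m >= 1) {
      // Shannon on haplotype frequencies (rows identical iff d == 0)
      std::vector<int> rep;
      std::vector<int> cnt;
      for (int i = lo; i < hi; ++i) {
        bool found = false;
        for (size_t r = 0; r < rep.size(); ++r) {
          if (D(i, rep[r]) == 0.0) { cnt[r]++; found = true; break; }
        }
        if (!found) { rep.push_back(i); cnt.push_back(1); }
      }
      double h = 0.0;
      for (size_t r = 0; r < cnt.size(); ++r) {
        double p = (double)cnt[r] / m;
        h -= p * std::log(p);
      }
      sh = h;
    }
    if (m >= 2) {
      double sum = 0.0;
      for (int i = lo; i < hi; ++i)
        for (int j = i + 1; j < hi; ++j) sum += D(i, j);
      pi = sum / (0.5 * m * (m - 1));
      for (int s = 0; s < S; ++s) {
        int first = states[s * n + lo];
        for (int i = lo + 1; i < hi; ++i)
          if (states[s * n + i] != first) { ++nseg; break; }
      }
    }
    if (m >= 3) {
      double m1 = 0.0, m2 = 0.0, m11 = 0.0;
      for (int i = lo; i < hi; ++i) {
        double rs = 0.0, rs2 = 0.0;
        for (int j = lo; j < hi; ++j) {
          if (j == i) continue;
          double v = D(i, j);
          rs += v; rs2 += v * v;
        }
        m11 += rs * rs - rs2;
        m1 += rs; m2 += rs2;
      }
      double npairs = (double)m * (m - 1) * (m - 2);
      m11 /= npairs;
      m1 /= (double)m * (m - 1);
      m2 /= (double)m * (m - 1);
      double var = m2 - m1 * m1;
      s_w = var > 0.0 ? (m11 - m1 * m1) / var : 0.0;
    }
  };

  double pi, s_w, sh;
  int nseg;
  group_stats(0, n, pi, s_w, nseg, sh);
  out[PI_POOL] = pi;
  out[SH_POOL] = sh;
  if (n >= 2) {
    out[THW_POOL] = nseg / harmonic(n);
    out[SDPT_POOL] = sd_pi_theta_ns(n, nseg);
  }
  out[S_POOL] = s_w;

  group_stats(0, n1, pi, s_w, nseg, sh);
  out[PI_1] = pi;
  out[SH_1] = sh;
  if (n1 >= 2) {
    out[THW_1] = nseg / harmonic(n1);
    out[SDPT_1] = sd_pi_theta_ns(n1, nseg);
  }
  out[S_1] = s_w;

  group_stats(n1, n, pi, s_w, nseg, sh);
  out[PI_2] = pi;
  out[SH_2] = sh;
  if (n2 >= 2) {
    out[THW_2] = nseg / harmonic(n2);
    out[SDPT_2] = sd_pi_theta_ns(n2, nseg);
  }
  out[S_2] = s_w;

  if (n1 >= 1 && n2 >= 1) {
    double sum = 0.0;
    for (int i = 0; i < n1; ++i)
      for (int j = n1; j < n; ++j) sum += D(i, j);
    double pib = sum / ((double)n1 * n2);
    out[PI_B] = pib;
    if (n1 >= 2 && n2 >= 2)
      out[PI_NET] = pib - 0.5 * (out[PI_1] + out[PI_2]);

    if (n1 + n2 >= 3) {
      // interpopulation correlation of pairwise differences among cross
      // pairs sharing one sequence.  Two normalisations are reported:
      // s_XY scales the shared-member covariance by the variance of the
      // cross differences (a correlation); Psi_W scales it by their mean.
      // The source derivations print neither formula explicitly, so the
      // normalisation pair is this implementation's documented choice.
      double m1 = 0.0, m2 = 0.0, m11 = 0.0;
      for (int i = 0; i < n1; ++i) {
        double rs = 0.0, rs2 = 0.0;
        for (int j = n1; j < n; ++j) {
          double v = D(i, j);
          rs += v; rs2 += v * v;
          m1 += v; m2 += v * v;
        }
        m11 += rs * rs - rs2;
      }
      for (int j = n1; j < n; ++j) {
        double cs = 0.0, cs2 = 0.0;
        for (int i = 0; i < n1; ++i) {
          double v = D(i, j);
          cs += v; cs2 += v * v;
        }
        m11 += cs * cs - cs2;
      }
      double ncross = (double)n1 * n2;
      double nshare = ncross * (n1 + n2 - 2.0);
      if (nshare > 0) {
        m11 /= nshare;
        m1 /= ncross;
        m2 /= ncross;
        double var = m2 - m1 * m1;
        double cov = m11 - m1 * m1;
        out[S_XY] = var > 0.0 ? cov / var : 0.0;
        out[PSI_W] = m1 > 0.0 ? cov / m1 : 0.0;
      }
    }
  }
}

void compute_stats(const std::vector<int>& states, int S, int n1, int n2,
                   double* out, std::vector<int>& d) {
  int n = n1 + n2;
  d.assign(n * n, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int c = 0;
      for (int s = 0; s < S; ++s)
        if (states[s * n + i] != states[s * n + j]) ++c;
      d[i * n + j] = c; d[j * n + i] = c;
    }
  }
  stats_from_d(d, states, S, n1, n2, out);
}

}  // namespace

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(int n1, int n2, double tau, double thetaA,
                       double thA1, double thA2, double thB1, double thB2,
                       double tB1, double tB2, double Nm) {
  if (n1 + n2 < 2) stop("need at least two sampled sequences");
  if (thetaA <= 0 || thB1 + thB2 <= 0) stop("population sizes must be positive");
  Tree tr = sim_tree(n1, n2, tau, thetaA, thA1, thA2, thB1, thB2, tB1, tB2, Nm);
  return List::create(_["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
                      _["time"] = NumericVector(tr.time.begin(), tr.time.end()),
                      _["ntip"] = tr.ntip);
}

// [[Rcpp::export(name = ".mutate_tree_cpp")]]
List mutate_tree_cpp(IntegerVector parent, NumericVector time, int ntip,
                     int L, double mu, int model, double kappa,
                     NumericVector freqs, bool full) {
  std::vector<int> par(parent.begin(), parent.end());
  std::vector<double> tim(time.begin(), time.end());
  double fr[4] = {freqs[0], freqs[1], freqs[2], freqs[3]};
  MutStates ms;
  mutate_on_tree(par, tim, ntip, L, mu, model, kappa, fr, ms);
  IntegerMatrix states(ntip, ms.S);
  for (int s = 0; s < ms.S; ++s)
    for (int i = 0; i < ntip; ++i) states(i, s) = ms.states[s * ntip + i];
  List out = List::create(_["states"] = states,
                          _["sites"] = IntegerVector(ms.sites.begin(), ms.sites.end()));
  if (full) {
    // root states for unaffected columns are drawn after the mutated
    // columns so the RNG prefix matches the stats-only path exactly
    IntegerMatrix aln(ntip, L);
    std::vector<bool> hit(L, false);
    for (size_t i = 0; i < ms.sites.size(); ++i) hit[ms.sites[i]] = true;
    for (int s = 0; s < L; ++s) {
      if (!hit[s]) {
        int b = draw_base(fr);
        for (int i = 0; i < ntip; ++i) aln(i, s) = b;
      }
    }
    for (int c = 0; c < ms.S; ++c)
      for (int i = 0; i < ntip; ++i) aln(i, ms.sites[c]) = ms.states[c * ntip + i];
    out["alignment"] = aln;
  }
  return out;
}

// [[Rcpp::export(name = ".locus_stats_cpp")]]
NumericVector locus_stats_cpp(IntegerMatrix states, int n1, int n2) {
  int n = states.nrow(), S = states.ncol();
  std::vector<int> buf(n * S);
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < n; ++i) buf[s * n + i] = states(i, s);
  double out[N_CLASSES];
  std::vector<int> d;
  compute_stats(buf, S, n1, n2, out, d);
  return NumericVector(out, out + N_CLASSES);
}

// Batch driver: simulate `nsim` multi-taxon-pair multi-locus data sets and
// return per-pair raw moments (across loci) of the selected statistic
// classes, optionally re-ordered by descending mean pi_b.  Parameter
// matrices are nsim x Y (nsim x total_loci for rate scalars) and are drawn
// in R so the whole stream is governed by set.seed().
//
// Column layout of the result: for class c (order of `classes`), pair slot
// y (1..Y, post-sort), moment k (1..nmom): column ((c*Y)+y)*nmom + k.
// [[Rcpp::export(name = ".sim_batch_cpp")]]
NumericMatrix sim_batch_cpp(int nsim,
                            IntegerVector n1, IntegerVector n2, IntegerVector nloci,
                            IntegerVector L, NumericVector inh, IntegerVector model,
                            NumericVector kappa, NumericMatrix freqs,
                            NumericMatrix tau, NumericMatrix thetaA,
                            NumericMatrix thA1, NumericMatrix thA2,
                            NumericMatrix thB1, NumericMatrix thB2,
                            NumericMatrix tB1, NumericMatrix tB2,
                            NumericMatrix Nm, NumericMatrix rate,
                            IntegerVector classes, int nmom, bool sort_pairs) {
  int Y = n1.size();
  int ncls = classes.size();
  int ncol_out = Y * ncls * nmom;
  NumericMatrix out(nsim, ncol_out);

  std::vector<int> loc_off(Y + 1, 0);
  for (int y = 0; y < Y; ++y) loc_off[y + 1] = loc_off[y] + nloci[y];

  double stats[N_CLASSES];
  // per pair: sums of value^k per selected class + counts, plus pi_b mean
  std::vector<double> msum(Y * ncls * nmom);
  std::vector<int> mcnt(Y * ncls);
  std::vector<double> pib_mean(Y);
  std::vector<int> pib_cnt(Y);
  std::vector<int> ord(Y);
  MutStates ms;
  std::vector<int> dbuf;

  for (int i = 0; i < nsim; ++i) {
    std::fill(msum.begin(), msum.end(), 0.0);
    std::fill(mcnt.begin(), mcnt.end(), 0);
    std::fill(pib_mean.begin(), pib_mean.end(), 0.0);
    std::fill(pib_cnt.begin(), pib_cnt.end(), 0);

    for (int y = 0; y < Y; ++y) {
      for (int l = loc_off[y]; l < loc_off[y + 1]; ++l) {
        Tree tr = sim_tree(n1[y], n2[y], tau(i, y), thetaA(i, y),
                           thA1(i, y), thA2(i, y), thB1(i, y), thB2(i, y),
                           tB1(i, y), tB2(i, y), Nm(i, y));
        double theta_site = (thB1(i, y) + thB2(i, y)) * rate(i, l) * inh[l];
        double fr[4] = {freqs(l, 0), freqs(l, 1), freqs(l, 2), freqs(l, 3)};
        mutate_on_tree(tr.parent, tr.time, tr.ntip, L[l], theta_site / 2.0,
                       model[l], kappa[l], fr, ms);
        compute_stats(ms.states, ms.S, n1[y], n2[y], stats, dbuf);
        if (!ISNA(stats[PI_B])) { pib_mean[y] += stats[PI_B]; pib_cnt[y]++; }
        for (int c = 0; c < ncls; ++c) {
          double v = stats[classes[c]];
          if (ISNA(v)) continue;
          mcnt[y * ncls + c]++;
          double p = 1.0;
          for (int k = 0; k < nmom; ++k) {
            p *= v;
            msum[(y * ncls + c) * nmom + k] += p;
          }
        }
      }
      if (pib_cnt[y] > 0) pib_mean[y] /= pib_cnt[y];
      else pib_mean[y] = NA_REAL;
    }

    for (int y = 0; y < Y; ++y) ord[y] = y;
    if (sort_pairs) {
      std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
        return pib_mean[a] > pib_mean[b];
      });
    }

    for (int c = 0; c < ncls; ++c) {
      for (int slot = 0; slot < Y; ++slot) {
        int y = ord[slot];
        int cnt = mcnt[y * ncls + c];
        for (int k = 0; k < nmom; ++k) {
          double v = cnt > 0 ? msum[(y * ncls + c) * nmom + k] / cnt : NA_REAL;
          out(i, (c * Y + slot) * nmom + k) = v;
        }
      }
    }
  }
  return out;
}
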