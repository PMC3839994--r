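// Compiled kernels: Griffiths-Tavare importance sampling on an
// infinite-sites gene tree, neutral coalescent null simulations, and
// Chinese-restaurant sampling from the Ewens sampling formula.
// All randomness comes from R's RNG (seed with set.seed() on the R side).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Griffiths-Tavare importance sampling
//
// The data is a rooted mutation tree: node 0 is the ancestral type, every
// other node v hangs below its parent by an edge carrying one mutation;
// tipmult[v] chromosomes carry exactly the mutations on v's root path.
// Backward in time the only feasible events are (a) coalescence of two
// lineages of the same type and (b) removal of the terminal mutation of a
// lineage that is the unique carrier of that mutation.  The proposal
// draws event times from the total event intensity (all pairs, all
// lineages) and at each event chooses among the feasible transitions in
// proportion to their rates, multiplying the weight by the feasible
// fraction of the total intensity: the classical Griffiths-Tavare
// jump-chain estimator, extended with event times so that varying
// population size and posterior event ages come for free.  The product of
// the per-event fractions is an unbiased estimate of the
// sample-configuration probability (up to a constant combinatorial factor
// that does not depend on theta or beta).
//
// Time is in coalescent units (1.5 N0 generations for X-linked samples);
// the population size at time t back is N0 * exp(-beta t), so the pair
// coalescence rate is exp(beta t); each lineage mutates at rate theta/2.
// ---------------------------------------------------------------------------

struct GTState {
  int V;
  std::vector<int> parent, cnt, act_below;
  void chain_update(int v, int d) {
    while (v >= 0) { act_below[v] += d; v = parent[v]; }
  }
};

// sample waiting time to next coalescence-type event with rate
// P * exp(beta (t0+u)) ; returns u
static double rcoal_time(double P, double beta, double t0) {
  if (P <= 0) return R_PosInf;
  double E = ::Rf_rexp(1.0);
  if (beta == 0.0) return E / P;
  double x = std::exp(beta * t0) + beta * E / P;
  return std::log(x) / beta - t0;
}

// Per history the log sampling density under any (theta, beta) differs
// from the driving values only through closed-form sufficient statistics:
//   log P(theta, beta) = beta * Tc + M log(theta/2) - (theta/2) * A - C(beta)
// with Tc the sum of coalescence-event times, M the (fixed) number of
// mutations, A the lineage-time integral (sum over intervals of
// n_k * dt), and C(beta) the integral of the pairwise coalescence
// intensity sum_k Np_k (exp(beta t_{k+1}) - exp(beta t_k)) / beta.
// These are returned so that the whole likelihood surface can be
// evaluated from one driving run ("surface from a single run").

// proposal = 0: Griffiths-Tavare backward urn (choice proportional to the
// true transition rates); proposal = 1: Stephens-Donnelly refinement
// (choose an actionable lineage uniformly: coalescence weight n_v,
// mutation-removal weight 1), which concentrates the weights much better
// on large samples.

// [[Rcpp::export]]
List cpp_gt_run(IntegerVector parent_, IntegerVector tipmult_, double theta,
                double beta, int budget, bool collect_ages,
                NumericVector beta_grid = NumericVector::create(),
                int proposal = 0) {
  int V = parent_.size();
  std::vector<int> parent(parent_.begin(), parent_.end()); // -1 for root
  std::vector<int> tipmult(tipmult_.begin(), tipmult_.end());
  int n0 = 0;
  for (int v = 0; v < V; ++v) n0 += tipmult[v];

  int G = beta_grid.size();
  NumericVector logw(budget), Tc(budget), A(budget);
  NumericMatrix Cb(G > 0 ? budget : 0, G);
  NumericMatrix ages;
  NumericVector tmrcas;
  if (collect_ages) { ages = NumericMatrix(budget, V); tmrcas = NumericVector(budget); }

  GTState st;
  st.V = V; st.parent = parent;
  std::vector<int> removable; removable.reserve(V);

  for (int b = 0; b < budget; ++b) {
    st.cnt = tipmult;
    st.act_below.assign(V, 0);
    for (int v = 0; v < V; ++v)
      if (st.cnt[v] > 0) st.chain_update(v, st.cnt[v]);
    int n = n0;
    double t = 0.0, lw = 0.0, tmrca = NA_REAL;
    double tc_sum = 0.0, a_sum = 0.0;
    std::vector<double> cb(G, 0.0);
    std::vector<double> age(collect_ages ? V : 0, NA_REAL);

    while (n > 1 || st.cnt[0] != n) {
      // feasible rates
      long feas_pairs2 = 0; // sum cnt*(cnt-1)
      removable.clear();
      for (int v = 0; v < V; ++v) {
        if (st.cnt[v] >= 2) feas_pairs2 += (long)st.cnt[v] * (st.cnt[v] - 1);
        if (v > 0 && st.cnt[v] == 1 && st.act_below[v] == 1)
          removable.push_back(v);
      }
      double Pf = feas_pairs2 / 2.0;
      int r = (int)removable.size();
      // times from the *total* intensity: all n(n-1)/2 pairs, all n lineages
      double Np = (double)n * (n - 1) / 2.0;
      double tm = (theta > 0) ? ::Rf_rexp(1.0) / (n * theta / 2.0)
                              : R_PosInf;
      double tc = (n > 1) ? rcoal_time(Np, beta, t) : R_PosInf;
      double dt = std::min(tm, tc);
      a_sum += n * dt;
      for (int g = 0; g < G; ++g) {
        double bg = beta_grid[g];
        if (bg == 0.0) cb[g] += Np * dt;
        else cb[g] += Np * (std::exp(bg * (t + dt)) - std::exp(bg * t)) / bg;
      }
      t += dt;
      // feasible fraction of the total intensity at the event time
      double growth = (beta == 0.0) ? 1.0 : std::exp(beta * t);
      double rate_coal_feas = Pf * growth;
      double rate_mut_feas = r * theta / 2.0;
      double rate_total = Np * growth + n * theta / 2.0;
      double feas = rate_coal_feas + rate_mut_feas;
      if (feas <= 0) { lw = R_NegInf; break; }
      // choose the event among feasible transitions
      bool do_coal; int v = -1;
      if (proposal == 0) {
        // choice proportional to the true rates: per-event weight
        // r_i/Lambda over proposal r_i/feas = feas/Lambda
        lw += std::log(feas) - std::log(rate_total);
        do_coal = ::Rf_runif(0.0, 1.0) * feas < rate_coal_feas;
        if (do_coal) {
          double u = ::Rf_runif(0.0, 1.0) * feas_pairs2;
          long acc = 0;
          for (int w = 0; w < V; ++w) {
            if (st.cnt[w] >= 2) {
              acc += (long)st.cnt[w] * (st.cnt[w] - 1);
              if (u <= acc) { v = w; break; }
            }
          }
          if (v < 0) v = V - 1;
        } else {
          int k = (int)(::Rf_runif(0.0, 1.0) * r); if (k >= r) k = r - 1;
          v = removable[k];
        }
      } else {
        // Stephens-Donnelly: actionable-lineage weights a_coal = n_v,
        // a_mut = 1; per-event weight (r_i/Lambda)/(a_i/sum_a)
        long sum_a = r;
        for (int w = 0; w < V; ++w)
          if (st.cnt[w] >= 2) sum_a += st.cnt[w];
        double u = ::Rf_runif(0.0, 1.0) * sum_a;
        long acc = 0;
        do_coal = false;
        for (int w = 0; w < V; ++w) {
          if (st.cnt[w] >= 2) {
            acc += st.cnt[w];
            if (u <= acc) { v = w; do_coal = true; break; }
          }
        }
        if (!do_coal) {
          int k = (int)(u - acc); if (k >= r) k = r - 1; if (k < 0) k = 0;
          v = removable[k];
        }
        double a_i = do_coal ? (double)st.cnt[v] : 1.0;
        double r_i = do_coal
          ? (double)st.cnt[v] * (st.cnt[v] - 1) / 2.0 * growth
          : theta / 2.0;
        lw += std::log(r_i) - std::log(rate_total) +
          std::log((double)sum_a) - std::log(a_i);
      }
      if (do_coal) {
        st.cnt[v] -= 1; n -= 1;
        st.chain_update(v, -1);
        tc_sum += t;
        if (n == 1) tmrca = t;
      } else {
        if (collect_ages) age[v] = t;
        st.cnt[v] = 0; st.chain_update(v, -1);
        st.cnt[parent[v]] += 1; st.chain_update(parent[v], +1);
      }
    }
    if (n0 == 1) tmrca = 0.0;
    logw[b] = lw;
    Tc[b] = tc_sum; A[b] = a_sum;
    for (int g = 0; g < G; ++g) Cb(b, g) = cb[g];
    if (collect_ages) {
      tmrcas[b] = tmrca;
      for (int v = 0; v < V; ++v) ages(b, v) = age[v];
    }
    if ((b & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["logw"] = logw, _["Tc"] = Tc, _["A"] = A,
                          _["Cb"] = Cb);
  if (collect_ages) { out["tmrca"] = tmrcas; out["ages"] = ages; }
  return out;
}

// ---------------------------------------------------------------------------
// Neutral constant-size coalescent null simulations.
// Per replicate: Kingman genealogy for n tips; mutations either exactly S
// (multinomial on branch lengths) or Poisson(theta/2 * branch length).
// Returns per replicate: S, pi, thetaL, thetaH, k (distinct haplotypes).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_coal_null(int n, int reps, int S_fixed, double theta) {
  NumericMatrix out(reps, 5);
  colnames(out) = CharacterVector::create("S", "pi", "thetaL", "thetaH", "k");
  int NN = 2 * n - 1;
  std::vector<int> parent(NN), ntips(NN), muts(NN);
  std::vector<double> blen(NN);
  std::vector<int> active(n);
  double denom_pi = (double)n * (n - 1);

  for (int rep = 0; rep < reps; ++rep) {
    for (int v = 0; v < NN; ++v) { parent[v] = -1; blen[v] = 0; muts[v] = 0; }
    std::vector<double> tnode(NN, 0.0);
    for (int i = 0; i < n; ++i) { active[i] = i; ntips[i] = 1; }
    int m = n, nxt = n;
    double t = 0.0;
    while (m > 1) {
      t += ::Rf_rexp(1.0) / ((double)m * (m - 1) / 2.0);
      int i = (int)(::Rf_runif(0.0, 1.0) * m); if (i >= m) i = m - 1;
      int j = (int)(::Rf_runif(0.0, 1.0) * (m - 1)); if (j >= m - 1) j = m - 2;
      if (j >= i) ++j;
      int a = active[i], b2 = active[j];
      parent[a] = nxt; parent[b2] = nxt;
      blen[a] = t - tnode[a]; blen[b2] = t - tnode[b2];
      tnode[nxt] = t; ntips[nxt] = ntips[a] + ntips[b2];
      active[std::min(i, j)] = nxt;
      active[std::max(i, j)] = active[m - 1];
      ++nxt; --m;
    }
    int root = NN - 1;
    double L = 0.0;
    for (int v = 0; v < NN - 1; ++v) L += blen[v];
    // mutations
    int S = 0;
    double pi = 0, thL = 0, thH = 0;
    if (S_fixed >= 0) {
      S = S_fixed;
      for (int s = 0; s < S; ++s) {
        double u = ::Rf_runif(0.0, 1.0) * L, acc = 0;
        int v = 0;
        for (; v < NN - 1; ++v) { acc += blen[v]; if (u <= acc) break; }
        if (v >= NN - 1) v = NN - 2;
        muts[v] += 1;
      }
    } else {
      for (int v = 0; v < NN - 1; ++v) {
        muts[v] = (int)::Rf_rpois(theta / 2.0 * blen[v]);
        S += muts[v];
      }
    }
    if (S_fixed >= 0) { S = 0; for (int v = 0; v < NN - 1; ++v) S += muts[v]; }
    for (int v = 0; v < NN - 1; ++v) {
      if (muts[v] == 0) continue;
      double c = ntips[v];
      pi += muts[v] * 2.0 * c * (n - c) / denom_pi;
      thH += muts[v] * 2.0 * c * c / denom_pi;
      thL += muts[v] * c / (double)(n - 1);
    }
    // distinct haplotypes: walk each tip up through mutation-free edges
    int k = 0;
    {
      std::vector<char> seen(NN, 0);
      for (int tip = 0; tip < n; ++tip) {
        int v = tip;
        while (v != root && muts[v] == 0) v = parent[v];
        if (!seen[v]) { seen[v] = 1; ++k; }
      }
    }
    out(rep, 0) = S; out(rep, 1) = pi; out(rep, 2) = thL;
    out(rep, 3) = thH; out(rep, 4) = k;
    if ((rep & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Chinese-restaurant sampling from the Ewens sampling formula.
// Returns per replicate: K, sum of squared type counts, and the
// log configuration weight log(n! * prod_j 1/(j^{a_j} a_j!)) used by
// Slatkin's exact test (theta-dependent factors cancel given K).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_crp(int n, double theta, int reps) {
  NumericMatrix out(reps, 3);
  colnames(out) = CharacterVector::create("K", "sum_sq", "log_config");
  std::vector<int> table_of(n);
  std::vector<int> size;
  for (int rep = 0; rep < reps; ++rep) {
    size.clear();
    size.push_back(1); table_of[0] = 0;
    for (int i = 1; i < n; ++i) {
      double u = ::Rf_runif(0.0, 1.0) * (theta + i);
      if (u < theta) { table_of[i] = (int)size.size(); size.push_back(1); }
      else {
        int j = (int)(::Rf_runif(0.0, 1.0) * i); if (j >= i) j = i - 1;
        int tb = table_of[j]; table_of[i] = tb; size[tb] += 1;
      }
    }
    int K = (int)size.size();
    double ss = 0;
    std::map<int, int> mult;
    for (int j = 0; j < K; ++j) { ss += (double)size[j] * size[j]; mult[size[j]] += 1; }
    double lc = ::Rf_lgammafn(n + 1.0);
    for (auto& kv : mult)
      lc -= kv.second * std::log((double)kv.first) + ::Rf_lgammafn(kv.second + 1.0);
    out(rep, 0) = K; out(rep, 1) = ss; out(rep, 2) = lc;
    if ((rep & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
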