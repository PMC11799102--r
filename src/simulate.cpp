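#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sample an unordered daughter pair for a parent of type i from the
// CSR-flattened kernel (per-type cumulative probabilities).
static inline void sample_pair(int i, const IntegerVector &offsets,
                               const IntegerVector &pj,
                               const IntegerVector &pk,
                               const NumericVector &cum, int &j, int &k) {
  int lo = offsets[i], hi = offsets[i + 1];
  double u = unif_rand();
  int idx = hi - 1;
  for (int e = lo; e < hi; ++e) {
    if (u <= cum[e]) { idx = e; break; }
  }
  j = pj[idx];
  k = pk[idx];
}

// Branching-process lineages in discrete generations: each cell divides
// with probability rho[type] (two daughters from the kernel) or dies.
// Type-0 daughters are dropped: they carry no mutant plasmid, cannot
// regain one, and their line is subcritical. A lineage establishes when
// living mutant-carrying cells reach `threshold`.
// Outcomes: 0 extinct, 1 established, 2 event cap reached (flagged).
// [[Rcpp::export]]
IntegerVector cpp_mc_lineages(int n, NumericVector rho,
                              IntegerVector offsets, IntegerVector pj,
                              IntegerVector pk, NumericVector cum,
                              IntegerMatrix starts, int threshold,
                              double event_cap) {
  int reps = starts.nrow();
  IntegerVector out(reps);
  std::vector<long long> counts(n + 1), nxt(n + 1);
  for (int r = 0; r < reps; ++r) {
    std::fill(counts.begin(), counts.end(), 0LL);
    for (int c = 0; c < 2; ++c) {
      int t = starts(r, c);
      if (t >= 1) counts[t]++;
    }
    long long total = 0;
    for (int i = 1; i <= n; ++i) total += counts[i];
    double events = 0.0;
    int res = 0;
    while (true) {
      if (total == 0) { res = 0; break; }
      if (total >= threshold) { res = 1; break; }
      if (events > event_cap) { res = 2; break; }
      std::fill(nxt.begin(), nxt.end(), 0LL);
      for (int i = 1; i <= n; ++i) {
        long long c = counts[i];
        if (c == 0) continue;
        events += (double)c;
        long long div = (long long)R::rbinom((double)c, rho[i]);
        for (long long d = 0; d < div; ++d) {
          int j, k;
          sample_pair(i, offsets, pj, pk, cum, j, k);
          if (j >= 1) nxt[j]++;
          if (k >= 1) nxt[k]++;
        }
      }
      counts.swap(nxt);
      total = 0;
      for (int i = 1; i <= n; ++i) total += counts[i];
    }
    out[r] = res;
  }
  return out;
}

// Exact (direct-method) Gillespie simulation of the rescue process.
//
// Wild-type homozygote cells form a pool of size N dividing at rate
// lambda[0] and dying at rate 1. Each wild-type division carries a
// mutation with probability mut_prob (= u * n); the mutant daughter(s)
// found a new labelled lineage. Lineage cells of type i (1..n mutant
// plasmids) divide at rate lambda[i] and die at rate 1; daughters are
// drawn from the division kernel, and type-0 daughters return to the
// wild-type pool. Mutations arise only in (fully wild-type) pool cells.
//
// mode: 0 = regular (mutation division yields daughters {1, 0}),
//       1 = random (daughter pair drawn from the head-start distribution).
// [[Rcpp::export]]
List cpp_gillespie(int n, NumericVector lambda, double mut_prob, int mode,
                   IntegerVector offsets, IntegerVector pj, IntegerVector pk,
                   NumericVector cum, IntegerVector hs_j, IntegerVector hs_k,
                   NumericVector hs_cum, double N0, double t_max,
                   NumericVector grid, double event_cap) {
  long long N = (long long)N0;
  std::vector<std::vector<long long> > lin;     // per-lineage counts, 1..n
  std::vector<double> lin_birth;
  std::vector<double> mut_times;
  int ngrid = grid.size();
  NumericMatrix traj(n + 1, ngrid);
  int gidx = 0;
  double t = 0.0, events = 0.0;
  int outcome = 1;                              // surviving at t_max
  double t_ext = NA_REAL, first_success = NA_REAL;

  // per-type lineage totals for rate bookkeeping
  std::vector<long long> type_tot(n + 1, 0LL);

  while (true) {
    double totB = (double)N * lambda[0];
    double totD = (double)N;
    for (int i = 1; i <= n; ++i) {
      totB += (double)type_tot[i] * lambda[i];
      totD += (double)type_tot[i];
    }
    double tot = totB + totD;
    if (tot <= 0.0) {                           // everything dead
      while (gidx < ngrid) {                    // flat zero tail
        for (int i = 0; i <= n; ++i) traj(i, gidx) = 0.0;
        gidx++;
      }
      outcome = 0;
      t_ext = t;
      break;
    }
    double tnext = t + exp_rand() / tot;
    // record grid points passed while the current state holds
    while (gidx < ngrid && grid[gidx] < tnext && grid[gidx] <= t_max) {
      traj(0, gidx) = (double)N;
      for (int i = 1; i <= n; ++i) traj(i, gidx) = (double)type_tot[i];
      gidx++;
    }
    if (tnext > t_max) break;
    t = tnext;
    events += 1.0;
    if (events > event_cap) { outcome = 2; break; }

    double r = unif_rand() * tot;
    if (r < (double)N * lambda[0]) {            // wild-type division
      if (unif_rand() < mut_prob) {             // mutation occurs
        N--;
        std::vector<long long> cnt(n + 1, 0LL);
        int j, k;
        if (mode == 0) { j = 1; k = 0; }
        else {
          double u = unif_rand();
          int idx = hs_cum.size() - 1;
          for (int e = 0; e < hs_cum.size(); ++e) {
            if (u <= hs_cum[e]) { idx = e; break; }
          }
          j = hs_j[idx];
          k = hs_k[idx];
        }
        if (j == 0) N++; else { cnt[j]++; type_tot[j]++; }
        if (k == 0) N++; else { cnt[k]++; type_tot[k]++; }
        lin.push_back(cnt);
        lin_birth.push_back(t);
        mut_times.push_back(t);
      } else {
        N++;
      }
      continue;
    }
    r -= (double)N * lambda[0];
    if (r < (double)N) { N--; continue; }       // wild-type death
    r -= (double)N;
    bool done = false;
    for (size_t l = 0; l < lin.size() && !done; ++l) {
      for (int i = 1; i <= n && !done; ++i) {
        long long c = lin[l][i];
        if (c == 0) continue;
        double b = (double)c * lambda[i];
        if (r < b) {                            // lineage division
          int j, k;
          sample_pair(i, offsets, pj, pk, cum, j, k);
          lin[l][i]--; type_tot[i]--;
          if (j == 0) N++; else { lin[l][j]++; type_tot[j]++; }
          if (k == 0) N++; else { lin[l][k]++; type_tot[k]++; }
          done = true;
          break;
        }
        r -= b;
        if (r < (double)c) {                    // lineage death
          lin[l][i]--; type_tot[i]--;
          done = true;
          break;
        }
        r -= (double)c;
      }
    }
    // (floating-point slack: if nothing selected, drop the event)
  }

  // first mutation whose descendants are alive at the end
  for (size_t l = 0; l < lin.size(); ++l) {
    long long alive = 0;
    for (int i = 1; i <= n; ++i) alive += lin[l][i];
    if (alive > 0) {
      if (!R_finite(first_success) || lin_birth[l] < first_success)
        first_success = lin_birth[l];
    }
  }

  return List::create(
    _["trajectory"] = traj, _["outcome"] = outcome, _["t_extinct"] = t_ext,
    _["first_success_time"] = first_success,
    _["mutation_times"] = NumericVector(mut_times.begin(), mut_times.end()),
    _["events"] = events);
}
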