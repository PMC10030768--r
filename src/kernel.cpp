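// Metropolis kernel over precomputed energy tables.
//
// State (0-based): pos[m] = residue of spin system m or -1 (cache);
// ts[m] = active type-set index within m; res2ss[n] = spin system at
// residue n or -1. Tables: ecs (A x N) chemical-shift energy of instance
// a = offset[m] + ts[m] at residue n, +Inf where placement is impossible;
// adj (A x A) adjacency energy of instance a at n against instance b at
// n+1. Total energy = sum over occupied n of ecs[a,n] + adj[a, a_next].
//
// The kernel draws from a fast local generator seeded from R's RNG at the
// start of every call, so set.seed() in R makes trajectories
// bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// fast local generator (xoshiro256+), seeded from R's RNG at the start of
// every kernel call so trajectories stay reproducible under set.seed()
struct RNG64 {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed_from_R() {
    uint64_t x = (uint64_t)(unif_rand() * 9007199254740992.0) + 1ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double ud() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int ri(int n) {
    int r = (int)(ud() * n);
    return r >= n ? n - 1 : r;
  }
};

struct Kern {
  int M, N, A;
  RNG64 rng;
  std::vector<int> pos, ts, res2ss;
  const double *ecs, *adj;
  const int *offset, *I;
  // incremental bookkeeping lists
  std::vector<int> empties, empIdx;  // unoccupied placeable positions
  std::vector<int> placed, plcIdx;   // placed spin systems

  int inst(int m) const { return offset[m] + ts[m]; }
  double ecsAt(int a, int n) const { return ecs[a + (size_t)A * n]; }
  double adjAt(int a, int b) const { return adj[a + (size_t)A * b]; }

  double term(int n) const {
    if (n < 0 || n >= N) return 0.0;
    int m = res2ss[n];
    if (m < 0) return 0.0;
    int a = inst(m);
    double e = ecsAt(a, n);
    if (n + 1 < N) {
      int l = res2ss[n + 1];
      if (l >= 0) e += adjAt(a, inst(l));
    }
    return e;
  }

  static void listRemove(std::vector<int>& lst, std::vector<int>& idx, int v) {
    int i = idx[v], last = lst.back();
    lst[i] = last; idx[last] = i; lst.pop_back(); idx[v] = -1;
  }
  static void listAdd(std::vector<int>& lst, std::vector<int>& idx, int v) {
    idx[v] = (int)lst.size(); lst.push_back(v);
  }

  void place(int m, int n, int i) {
    ts[m] = i; pos[m] = n; res2ss[n] = m;
    listRemove(empties, empIdx, n);
    listAdd(placed, plcIdx, m);
  }
  void unplace(int m) {
    int n = pos[m];
    res2ss[n] = -1; pos[m] = -1;
    listAdd(empties, empIdx, n);
    listRemove(placed, plcIdx, m);
  }

  // uniform legal type-set index for m at n, or -1
  int randInstance(int m, int n) {
    int cnt = 0, chosen = -1;
    for (int i = 0; i < I[m]; ++i)
      if (std::isfinite(ecsAt(offset[m] + i, n))) ++cnt;
    if (!cnt) return -1;
    int k = rng.ri(cnt);
    for (int i = 0; i < I[m]; ++i)
      if (std::isfinite(ecsAt(offset[m] + i, n)) && k-- == 0) { chosen = i; break; }
    return chosen;
  }

  // sum of energy terms at a deduplicated set of positions
  double sumAffected(const int* ns, int cnt) const {
    int uniq[8]; int u = 0;
    for (int i = 0; i < cnt; ++i) {
      int n = ns[i];
      if (n < 0 || n >= N) continue;
      bool seen = false;
      for (int j = 0; j < u; ++j) if (uniq[j] == n) { seen = true; break; }
      if (!seen) uniq[u++] = n;
    }
    double s = 0;
    for (int j = 0; j < u; ++j) s += term(uniq[j]);
    return s;
  }
};

Kern makeKern(IntegerVector pos0, IntegerVector ts0, IntegerVector res2ss0,
              NumericMatrix ecs, NumericMatrix adj,
              IntegerVector offset, IntegerVector I,
              LogicalVector placeable) {
  Kern k;
  k.M = pos0.size(); k.N = res2ss0.size(); k.A = ecs.nrow();
  k.pos.assign(pos0.begin(), pos0.end());
  k.ts.assign(ts0.begin(), ts0.end());
  k.res2ss.assign(res2ss0.begin(), res2ss0.end());
  k.ecs = ecs.begin(); k.adj = adj.begin();
  k.offset = offset.begin(); k.I = I.begin();
  k.empIdx.assign(k.N, -1);
  k.plcIdx.assign(k.M, -1);
  for (int n = 0; n < k.N; ++n)
    if (placeable[n] && k.res2ss[n] < 0) Kern::listAdd(k.empties, k.empIdx, n);
  for (int m = 0; m < k.M; ++m)
    if (k.pos[m] >= 0) Kern::listAdd(k.placed, k.plcIdx, m);
  k.rng.seed_from_R();
  return k;
}

List packState(const Kern& k, double E) {
  return List::create(_["pos"] = IntegerVector(k.pos.begin(), k.pos.end()),
                      _["ts"] = IntegerVector(k.ts.begin(), k.ts.end()),
                      _["res2ss"] = IntegerVector(k.res2ss.begin(), k.res2ss.end()),
                      _["energy"] = E);
}

} // namespace

// Run Metropolis attempts at temperature T until `target_succ` accepted
// swaps have been recorded or `max_attempts` proposals made. With
// probability `peak_prob` an attempt is a crosspeak move: a peak is drawn
// uniformly; ineligible peaks are counted as failed proposals in place,
// while an eligible draw suspends the kernel (`peak_request` = 1-based
// peak id) so the move can be evaluated at the R level. Returns the
// updated state, the post-swap energy sample, and proposal counts.
// [[Rcpp::export]]
List mc_chunk(IntegerVector pos0, IntegerVector ts0, IntegerVector res2ss0,
              double energy,
              NumericMatrix ecs, NumericMatrix adj,
              IntegerVector offset, IntegerVector I,
              LogicalVector placeable,
              double temperature, int target_succ, double max_attempts,
              double peak_prob, LogicalVector peak_elig) {
  Kern k = makeKern(pos0, ts0, res2ss0, ecs, adj, offset, I, placeable);
  double E = energy;
  NumericVector energies(target_succ);
  int succ = 0;
  double attempts = 0, fails = 0;
  int peak_request = 0;
  const int n_peaks = peak_elig.size();

  while (succ < target_succ && attempts < max_attempts) {
    if (peak_prob > 0 && k.rng.ud() < peak_prob) {
      int g = k.rng.ri(n_peaks);
      if (!peak_elig[g]) {        // no productive move for this element
        attempts += 1;
        fails += 1;
        continue;
      }
      peak_request = g + 1;       // hand the eligible draw back to R
      break;
    }
    int m = -1, kind = -1;
    for (int tr = 0; tr < 64 && kind < 0; ++tr) {
      m = k.rng.ri(k.M);
      int kinds[4], nk = 0;
      if (k.pos[m] >= 0) {
        if (!k.empties.empty()) kinds[nk++] = 0;      // relocate
        if ((int)k.placed.size() >= 2) kinds[nk++] = 1; // swap
        kinds[nk++] = 2;                               // to cache
        if (k.I[m] > 1) kinds[nk++] = 3;               // type-set change
      } else if (!k.empties.empty()) kinds[nk++] = 0;  // place from cache
      if (nk) kind = kinds[k.rng.ri(nk)];
    }
    if (kind < 0) break;  // no element has a legal move
    attempts += 1;
    double dE = 0;
    bool legal = true, accepted = false;

    if (kind == 0) {                       // relocate / place from cache
      int n = k.empties[k.rng.ri((int)k.empties.size())];
      int i = k.randInstance(m, n);
      if (i < 0) legal = false;
      else {
        int oldn = k.pos[m], oldi = k.ts[m];
        int aff[4] = {oldn - 1, oldn, n - 1, n};
        double before = k.sumAffected(aff, 4);
        if (oldn >= 0) k.unplace(m);
        k.place(m, n, i);
        dE = k.sumAffected(aff, 4) - before;
        accepted = dE <= 0 || (dE < 40 * temperature &&
                   k.rng.ud() < std::exp(-dE / temperature));
        if (!accepted) {
          k.unplace(m);
          if (oldn >= 0) k.place(m, oldn, oldi);
        }
      }
    } else if (kind == 1) {                // swap two placed systems
      int l = m;
      for (int tr = 0; tr < 100 && l == m; ++tr)
        l = k.placed[k.rng.ri((int)k.placed.size())];
      if (l == m || k.pos[m] < 0) legal = false;
      else {
        int n1 = k.pos[m], n2 = k.pos[l];
        int im = k.randInstance(m, n2), il = k.randInstance(l, n1);
        if (im < 0 || il < 0) legal = false;
        else {
          int oim = k.ts[m], oil = k.ts[l];
          int aff[4] = {n1 - 1, n1, n2 - 1, n2};
          double before = k.sumAffected(aff, 4);
          k.res2ss[n1] = l; k.res2ss[n2] = m;
          k.pos[m] = n2; k.pos[l] = n1;
          k.ts[m] = im; k.ts[l] = il;
          dE = k.sumAffected(aff, 4) - before;
          accepted = dE <= 0 || (dE < 40 * temperature &&
                     k.rng.ud() < std::exp(-dE / temperature));
          if (!accepted) {
            k.res2ss[n1] = m; k.res2ss[n2] = l;
            k.pos[m] = n1; k.pos[l] = n2;
            k.ts[m] = oim; k.ts[l] = oil;
          }
        }
      }
    } else if (kind == 2) {                // placed -> cache
      int n = k.pos[m], oi = k.ts[m];
      int aff[2] = {n - 1, n};
      double before = k.sumAffected(aff, 2);
      k.unplace(m);
      dE = k.sumAffected(aff, 2) - before;
      accepted = dE <= 0 || (dE < 40 * temperature &&
                 k.rng.ud() < std::exp(-dE / temperature));
      if (!accepted) k.place(m, n, oi);
    } else {                               // type-set change in place
      int n = k.pos[m];
      int cnt = 0;
      for (int i = 0; i < k.I[m]; ++i)
        if (i != k.ts[m] && std::isfinite(k.ecsAt(k.offset[m] + i, n))) ++cnt;
      if (!cnt) legal = false;
      else {
        int pick = k.rng.ri(cnt), ni = -1;
        for (int i = 0; i < k.I[m]; ++i)
          if (i != k.ts[m] && std::isfinite(k.ecsAt(k.offset[m] + i, n)) &&
              pick-- == 0) { ni = i; break; }
        int oi = k.ts[m];
        int aff[2] = {n - 1, n};
        double before = k.sumAffected(aff, 2);
        k.ts[m] = ni;
        dE = k.sumAffected(aff, 2) - before;
        accepted = dE <= 0 || (dE < 40 * temperature &&
                   k.rng.ud() < std::exp(-dE / temperature));
        if (!accepted) k.ts[m] = oi;
      }
    }

    if (accepted) {
      E += dE;
      energies[succ++] = E;
    } else {
      fails += 1;
      (void)legal;
    }
  }

  NumericVector esamp(succ);
  for (int i = 0; i < succ; ++i) esamp[i] = energies[i];
  return List::create(
    _["pos"] = IntegerVector(k.pos.begin(), k.pos.end()),
    _["ts"] = IntegerVector(k.ts.begin(), k.ts.end()),
    _["res2ss"] = IntegerVector(k.res2ss.begin(), k.res2ss.end()),
    _["energy"] = E,
    _["energies"] = esamp,
    _["succ"] = succ,
    _["fail"] = fails,
    _["attempts"] = attempts,
    _["peak_request"] = peak_request);
}

// Greedy local minimization: repeatedly try to cache, re-place, swap or
// re-type every spin system at every position, accepting only energy
// decreases. `reps` full sweeps (early exit when a sweep changes nothing).
// [[Rcpp::export]]
List min_sweeps(IntegerVector pos0, IntegerVector ts0, IntegerVector res2ss0,
                double energy,
                NumericMatrix ecs, NumericMatrix adj,
                IntegerVector offset, IntegerVector I,
                LogicalVector placeable, int reps) {
  Kern k = makeKern(pos0, ts0, res2ss0, ecs, adj, offset, I, placeable);
  double E = energy;
  const double eps = 1e-9;

  for (int rep = 0; rep < reps; ++rep) {
    bool changed = false;
    for (int m = 0; m < k.M; ++m) {
      // try caching a placed system
      if (k.pos[m] >= 0) {
        int n = k.pos[m], oi = k.ts[m];
        int aff[2] = {n - 1, n};
        double before = k.sumAffected(aff, 2);
        k.unplace(m);
        double dE = k.sumAffected(aff, 2) - before;
        if (dE < -eps) { E += dE; changed = true; }
        else k.place(m, n, oi);
      }
      // try every position and every legal type set
      for (int n = 0; n < k.N; ++n) {
        if (!std::isfinite(k.ecsAt(k.offset[m], n)) && k.I[m] == 1) continue;
        int occ = k.res2ss[n];
        if (occ == m) {               // type-set change in place
          for (int i = 0; i < k.I[m]; ++i) {
            if (i == k.ts[m] || !std::isfinite(k.ecsAt(k.offset[m] + i, n)))
              continue;
            int oi = k.ts[m];
            int aff[2] = {n - 1, n};
            double before = k.sumAffected(aff, 2);
            k.ts[m] = i;
            double dE = k.sumAffected(aff, 2) - before;
            if (dE < -eps) { E += dE; changed = true; }
            else k.ts[m] = oi;
          }
        } else if (occ < 0) {         // move to empty position
          if (k.empIdx[n] < 0) continue;  // not placeable
          for (int i = 0; i < k.I[m]; ++i) {
            if (!std::isfinite(k.ecsAt(k.offset[m] + i, n))) continue;
            int oldn = k.pos[m], oldi = k.ts[m];
            int aff[4] = {oldn - 1, oldn, n - 1, n};
            double before = k.sumAffected(aff, 4);
            if (oldn >= 0) k.unplace(m);
            k.place(m, n, i);
            double dE = k.sumAffected(aff, 4) - before;
            if (dE < -eps) { E += dE; changed = true; break; }
            k.unplace(m);
            if (oldn >= 0) k.place(m, oldn, oldi);
          }
        } else {                      // swap with occupant (occ -> m's slot)
          int l = occ;
          int n1 = k.pos[m];          // may be -1 (m cached -> l cached)
          for (int i = 0; i < k.I[m]; ++i) {
            if (!std::isfinite(k.ecsAt(k.offset[m] + i, n))) continue;
            int il = -1;
            if (n1 >= 0) {
              if (std::isfinite(k.ecsAt(k.offset[l] + k.ts[l], n1)))
                il = k.ts[l];
              else
                for (int j = 0; j < k.I[l]; ++j)
                  if (std::isfinite(k.ecsAt(k.offset[l] + j, n1))) { il = j; break; }
              if (il < 0) continue;
            }
            int oim = k.ts[m], oil = k.ts[l];
            int aff[4] = {n1 - 1, n1, n - 1, n};
            double before = k.sumAffected(aff, 4);
            if (n1 >= 0) {            // true swap
              k.res2ss[n1] = l; k.res2ss[n] = m;
              k.pos[m] = n; k.pos[l] = n1;
              k.ts[m] = i; k.ts[l] = il;
            } else {                  // m from cache, l to cache
              k.unplace(l);
              k.place(m, n, i);
            }
            double dE = k.sumAffected(aff, 4) - before;
            if (dE < -eps) { E += dE; changed = true; break; }
            if (n1 >= 0) {
              k.res2ss[n1] = m; k.res2ss[n] = l;
              k.pos[m] = n1; k.pos[l] = n;
              k.ts[m] = oim; k.ts[l] = oil;
            } else {
              k.unplace(m);
              k.place(l, n, oil);
            }
          }
        }
      }
    }
    // joint re-optimization of adjacent type-set pairs: the CO/COm-style
    // labeling of neighbouring spin systems couples through the shared
    // adjacency term, which single-element moves cannot cross
    for (int n = 0; n + 1 < k.N; ++n) {
      int m1 = k.res2ss[n], m2 = k.res2ss[n + 1];
      if (m1 < 0 || m2 < 0) continue;
      if (k.I[m1] == 1 && k.I[m2] == 1) continue;
      int aff[3] = {n - 1, n, n + 1};
      int oi = k.ts[m1], oj = k.ts[m2];
      double before = k.sumAffected(aff, 3);
      double bestd = -eps;
      int besti = -1, bestj = -1;
      for (int i = 0; i < k.I[m1]; ++i) {
        if (!std::isfinite(k.ecsAt(k.offset[m1] + i, n))) continue;
        for (int j = 0; j < k.I[m2]; ++j) {
          if (!std::isfinite(k.ecsAt(k.offset[m2] + j, n + 1))) continue;
          if (i == oi && j == oj) continue;
          k.ts[m1] = i; k.ts[m2] = j;
          double d = k.sumAffected(aff, 3) - before;
          if (d < bestd) { bestd = d; besti = i; bestj = j; }
        }
      }
      if (besti >= 0) {
        k.ts[m1] = besti; k.ts[m2] = bestj;
        E += bestd;
        changed = true;
      } else {
        k.ts[m1] = oi; k.ts[m2] = oj;
      }
    }
    if (!changed) break;
  }
  return packState(k, E);
}
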