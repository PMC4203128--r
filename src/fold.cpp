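// RNA secondary-structure dynamic programs.
//
// Two folders over nested (pseudoknot-free) structures with canonical pairs
// {AU, UA, GC, CG, GU, UG} and a minimum hairpin loop of `min_loop` unpaired
// bases:
//
//  * nussinov_fold: maximum base-pair cardinality, deterministic traceback
//    (at each subproblem the 5' base pairs the smallest admissible partner).
//  * zuker_fold: free-energy minimization under a reduced nearest-neighbor
//    model: sequence-dependent stack energies, hairpin/bulge/internal loop
//    penalties by length, and a linear multiloop cost a + b * branches.
//    The open chain is the zero reference state; loop penalties are
//    positive, stacks negative, units kcal/mol.
//
// Sequences arrive as integer codes: A=0, C=1, G=2, U=3.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
#include <stack>

using namespace Rcpp;

static const double INF = 1e9;

static inline bool can_pair(int a, int b) {
  // AU, UA, GC, CG, GU, UG
  return (a + b == 3) || (a == 2 && b == 3) || (a == 3 && b == 2);
}

// ---------------------------------------------------------------- Nussinov

// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
IntegerVector nussinov_fold_cpp(IntegerVector seq, int min_loop) {
  int n = seq.size();
  IntegerVector partner(n, -1);
  if (n < min_loop + 2) {
    partner.attr("score") = 0;
    return partner;
  }
  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int inner = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
        int right = (k < j) ? M[k + 1][j] : 0;
        int cand = inner + right + 1;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }
  // traceback: prefer leaving i unpaired only when pairing i cannot reach
  // the optimum; among qualifying partners take the smallest k.
  std::stack<std::pair<int, int>> st;
  st.push({0, n - 1});
  while (!st.empty()) {
    auto [i, j] = st.top();
    st.pop();
    if (i >= j || j - i <= min_loop) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int inner = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
      int right = (k < j) ? M[k + 1][j] : 0;
      if (inner + right + 1 == M[i][j]) {
        partner[i] = k;
        partner[k] = i;
        if (k - i - 1 > min_loop) st.push({i + 1, k - 1});
        if (k < j) st.push({k + 1, j});
        paired = true;
        break;
      }
    }
    if (!paired) st.push({i + 1, j});
  }
  partner.attr("score") = M[0][n - 1];
  return partner;
}

// ------------------------------------------------------------- Zuker-style

struct EnergyModel {
  // stack[p1][p2]: closing pair p1 = (i,j), inner pair p2 = (i+1, j-1),
  // pair codes 0..5 for AU,UA,GC,CG,GU,UG; INF when either is not a pair.
  double stack[6][6];
  std::vector<double> hairpin;   // by unpaired length, index 0 unused
  std::vector<double> bulge;     // by unpaired length
  std::vector<double> internal_; // by total unpaired length
  double ml_close;               // multiloop closing penalty (a)
  double ml_branch;              // per-branch penalty (b)
  int max_interior;              // cap on bulge/internal unpaired bases
};

static inline int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 3 && b == 0) return 1;  // UA
  if (a == 2 && b == 1) return 2;  // GC
  if (a == 1 && b == 2) return 3;  // CG
  if (a == 2 && b == 3) return 4;  // GU
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

static double loop_cost(const std::vector<double>& tab, int len) {
  if (len <= 0) return INF;
  int m = (int)tab.size() - 1;
  if (len <= m) return tab[len];
  // Jacobson-Stockmayer extrapolation beyond the tabulated lengths
  return tab[m] + 1.75 * 0.616 * std::log((double)len / (double)m);
}

// [[Rcpp::export(name = ".zuker_fold_cpp")]]
List zuker_fold_cpp(IntegerVector seq, int min_loop,
                    NumericMatrix stack_tab,
                    NumericVector hairpin_tab,
                    NumericVector bulge_tab,
                    NumericVector internal_tab,
                    double ml_close, double ml_branch,
                    int max_interior) {
  int n = seq.size();
  EnergyModel em;
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) em.stack[a][b] = stack_tab(a, b);
  em.hairpin.assign(hairpin_tab.begin(), hairpin_tab.end());
  em.hairpin.insert(em.hairpin.begin(), INF);  // index 0
  em.bulge.assign(bulge_tab.begin(), bulge_tab.end());
  em.bulge.insert(em.bulge.begin(), INF);
  em.internal_.assign(internal_tab.begin(), internal_tab.end());
  em.internal_.insert(em.internal_.begin(), INF);
  em.ml_close = ml_close;
  em.ml_branch = ml_branch;
  em.max_interior = max_interior;

  IntegerVector partner(n, -1);
  if (n < min_loop + 2) {
    return List::create(_["partner"] = partner, _["energy"] = 0.0);
  }

  // V(i,j): min energy of structure closed by pair (i,j); INF if unpairable.
  // WM(i,j): min energy of a multiloop interior segment with >=1 branch
  //          (each branch costs ml_branch; unpaired bases free).
  // W(j): external loop minimum over prefix [0..j].
  std::vector<std::vector<double>> V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double>> WM(n, std::vector<double>(n, INF));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pc = pair_code(seq[i], seq[j]);
      if (pc >= 0) {
        double best = loop_cost(em.hairpin, j - i - 1);  // hairpin closure
        // stack / bulge / internal
        for (int ip = i + 1; ip < j - min_loop - 1; ++ip) {
          int lu = ip - i - 1;
          if (lu > em.max_interior) break;
          for (int jp = j - 1; jp > ip + min_loop; --jp) {
            int ru = j - jp - 1;
            if (lu + ru > em.max_interior) break;
            int pc2 = pair_code(seq[ip], seq[jp]);
            if (pc2 < 0) continue;
            if (V[ip][jp] >= INF) continue;
            double cost;
            if (lu == 0 && ru == 0) cost = em.stack[pc][pc2];
            else if (lu == 0 || ru == 0) cost = loop_cost(em.bulge, lu + ru);
            else cost = loop_cost(em.internal_, lu + ru);
            double cand = V[ip][jp] + cost;
            if (cand < best) best = cand;
          }
        }
        // multiloop closed by (i,j): interior split into two WM segments
        for (int k = i + 1; k < j - 1; ++k) {
          if (WM[i + 1][k] >= INF || WM[k + 1][j - 1] >= INF) continue;
          double cand = WM[i + 1][k] + WM[k + 1][j - 1] + em.ml_close;
          if (cand < best) best = cand;
        }
        V[i][j] = best;
      }
      // WM
      double wm = INF;
      if (V[i][j] < INF) wm = V[i][j] + em.ml_branch;
      if (i + 1 <= j && WM[i + 1][j] < wm) wm = WM[i + 1][j];
      if (j - 1 >= i && WM[i][j - 1] < wm) wm = WM[i][j - 1];
      for (int k = i + 1; k < j; ++k) {
        if (WM[i][k] >= INF || WM[k + 1][j] >= INF) continue;
        double cand = WM[i][k] + WM[k + 1][j];
        if (cand < wm) wm = cand;
      }
      WM[i][j] = wm;
    }
  }

  // external loop
  std::vector<double> W(n + 1, 0.0);
  std::vector<int> Wtrace(n + 1, -1);  // -1: j unpaired; else i pairing j
  for (int j = 0; j < n; ++j) {
    double best = W[j];  // base j unpaired (W indices shifted by one)
    int tb = -1;
    for (int i = 0; i <= j - min_loop - 1; ++i) {
      if (V[i][j] >= INF) continue;
      double cand = W[i] + V[i][j];
      if (cand < best - 1e-12) {
        best = cand;
        tb = i;
      }
    }
    W[j + 1] = best;
    Wtrace[j + 1] = tb;
  }

  // -------- traceback
  // external
  std::stack<std::tuple<int, int, int>> st;  // (i, j, mode) mode 0=V, 1=WM
  {
    int j = n;
    while (j > 0) {
      int i = Wtrace[j];
      if (i < 0) {
        --j;
      } else {
        partner[i] = j - 1;
        partner[j - 1] = i;
        st.push({i, j - 1, 0});
        j = i;
      }
    }
  }
  while (!st.empty()) {
    auto [i, j, mode] = st.top();
    st.pop();
    if (mode == 0) {
      // structure closed by (i,j) with energy V[i][j]
      int pc = pair_code(seq[i], seq[j]);
      double target = V[i][j];
      if (std::fabs(loop_cost(em.hairpin, j - i - 1) - target) < 1e-9) continue;
      bool done = false;
      for (int ip = i + 1; ip < j - min_loop - 1 && !done; ++ip) {
        int lu = ip - i - 1;
        if (lu > em.max_interior) break;
        for (int jp = j - 1; jp > ip + min_loop; --jp) {
          int ru = j - jp - 1;
          if (lu + ru > em.max_interior) break;
          int pc2 = pair_code(seq[ip], seq[jp]);
          if (pc2 < 0 || V[ip][jp] >= INF) continue;
          double cost;
          if (lu == 0 && ru == 0) cost = em.stack[pc][pc2];
          else if (lu == 0 || ru == 0) cost = loop_cost(em.bulge, lu + ru);
          else cost = loop_cost(em.internal_, lu + ru);
          if (std::fabs(V[ip][jp] + cost - target) < 1e-9) {
            partner[ip] = jp;
            partner[jp] = ip;
            st.push({ip, jp, 0});
            done = true;
            break;
          }
        }
      }
      if (done) continue;
      for (int k = i + 1; k < j - 1; ++k) {
        if (WM[i + 1][k] >= INF || WM[k + 1][j - 1] >= INF) continue;
        if (std::fabs(WM[i + 1][k] + WM[k + 1][j - 1] + em.ml_close - target) < 1e-9) {
          st.push({i + 1, k, 1});
          st.push({k + 1, j - 1, 1});
          done = true;
          break;
        }
      }
      continue;
    }
    // mode == 1: WM segment
    double target = WM[i][j];
    if (target >= INF) continue;
    if (V[i][j] < INF && std::fabs(V[i][j] + em.ml_branch - target) < 1e-9) {
      partner[i] = j;
      partner[j] = i;
      st.push({i, j, 0});
      continue;
    }
    if (i + 1 <= j && std::fabs(WM[i + 1][j] - target) < 1e-9) {
      st.push({i + 1, j, 1});
      continue;
    }
    if (j - 1 >= i && std::fabs(WM[i][j - 1] - target) < 1e-9) {
      st.push({i, j - 1, 1});
      continue;
    }
    for (int k = i + 1; k < j; ++k) {
      if (WM[i][k] >= INF || WM[k + 1][j] >= INF) continue;
      if (std::fabs(WM[i][k] + WM[k + 1][j] - target) < 1e-9) {
        st.push({i, k, 1});
        st.push({k + 1, j, 1});
        break;
      }
    }
  }

  return List::create(_["partner"] = partner, _["energy"] = W[n]);
}

// ---------------------------------------------------- sliding Hamming scan

// Minimum mismatch count of `tag` against `ref` over every ungapped offset,
// the shorter sequence slid along the longer (including offsets where the
// shorter hangs off either end); bases of the shorter overhanging the longer
// count as mismatches. Codes may be any integers; inequality = mismatch.

// [[Rcpp::export(name = ".slide_mismatch_cpp")]]
List slide_mismatch_cpp(IntegerVector a, IntegerVector b) {
  // slide the shorter over the longer
  const IntegerVector& s = (a.size() <= b.size()) ? a : b;
  const IntegerVector& l = (a.size() <= b.size()) ? b : a;
  int ns = s.size(), nl = l.size();
  int best = ns + 1, best_off = 0;
  for (int off = -(ns - 1); off <= nl - 1; ++off) {
    int mm = 0;
    for (int k = 0; k < ns && mm < best; ++k) {
      int p = off + k;
      if (p < 0 || p >= nl || s[k] != l[p]) ++mm;
    }
    if (mm < best) {
      best = mm;
      best_off = off;
    }
  }
  return List::create(_["mismatches"] = best, _["offset"] = best_off);
}
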