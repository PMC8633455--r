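#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Secondary-structure MFE folding and intermolecular duplex hybridisation
// under a simplified nearest-neighbour stacking model. All energies are
// integers in decikcal/mol so that DP minima are exact (no float ties).
//
// Base codes: A=0, C=1, G=2, U=3.
// Pair types: AU=1, UA=2, GC=3, CG=4, GU=5, UG=6, unpairable=0.

static const int INFE = 100000000;

static inline int pairtype(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 1 && b == 2) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

struct Par {
  const IntegerMatrix& stack;
  const IntegerVector& hairpin;
  const IntegerVector& bulge;
  const IntegerVector& internal_;
  int ml_a, ml_b, ml_c, max_interior, min_hairpin;
  Par(const IntegerMatrix& s, const IntegerVector& h, const IntegerVector& b,
      const IntegerVector& in, int a, int bb, int c, int mi, int mh)
    : stack(s), hairpin(h), bulge(b), internal_(in),
      ml_a(a), ml_b(bb), ml_c(c), max_interior(mi), min_hairpin(mh) {}
  // energy of the loop closed by outer pair (type ptO) with inner pair
  // (type ptI); l1/l2 unpaired bases on the two sides
  int loopE(int l1, int l2, int ptO, int ptI) const {
    if (l1 == 0 && l2 == 0) return stack(ptO - 1, ptI - 1);
    int L = l1 + l2;
    if (l1 == 0 || l2 == 0)
      return (L <= bulge.size()) ? bulge[L - 1] : INFE;
    return (L <= internal_.size()) ? internal_[L - 1] : INFE;
  }
  int hairpinE(int L) const {
    if (L < min_hairpin) return INFE;
    return (L <= hairpin.size()) ? hairpin[L - 1] : INFE;
  }
};

// [[Rcpp::export]]
List fold_dp(IntegerVector codes, IntegerMatrix stack, IntegerVector hairpin,
             IntegerVector bulge, IntegerVector internal_, int ml_a, int ml_b,
             int ml_c, int max_interior, int min_hairpin) {
  Par P(stack, hairpin, bulge, internal_, ml_a, ml_b, ml_c, max_interior,
        min_hairpin);
  const int n = codes.size();
  std::vector<int> c(codes.begin(), codes.end());
  std::vector<int> V((size_t)n * n, INFE), WM((size_t)n * n, INFE);
  auto iv = [&](int i, int j) -> int& { return V[(size_t)i * n + j]; };
  auto iw = [&](int i, int j) -> int& { return WM[(size_t)i * n + j]; };

  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // ---- V(i,j): energy given (i,j) paired ----
      int vt = pairtype(c[i], c[j]);
      int v = INFE;
      if (vt > 0 && j - i - 1 >= min_hairpin) {
        v = P.hairpinE(j - i - 1);
        // stack / bulge / interior loop
        for (int k = i + 1; k < j - 1 && k - i - 1 <= max_interior; ++k) {
          int l1 = k - i - 1;
          for (int l = j - 1; l > k; --l) {
            int l2 = j - l - 1;
            if (l1 + l2 > max_interior) break;
            int pt2 = pairtype(c[k], c[l]);
            if (!pt2) continue;
            int vin = iv(k, l);
            if (vin >= INFE) continue;
            int e = P.loopE(l1, l2, vt, pt2) + vin;
            if (e < v) v = e;
          }
        }
        // multibranch loop: >= 2 interior branches
        for (int k = i + 2; k < j - 2; ++k) {
          int e1 = iw(i + 1, k), e2 = iw(k + 1, j - 1);
          if (e1 < INFE && e2 < INFE) {
            int e = ml_a + ml_b + e1 + e2;
            if (e < v) v = e;
          }
        }
      }
      iv(i, j) = v;
      // ---- WM(i,j): multiloop component with >= 1 branch ----
      int w = INFE;
      if (v < INFE) w = v + ml_b;
      if (len > 1) {
        if (iw(i + 1, j) < INFE) w = std::min(w, iw(i + 1, j) + ml_c);
        if (iw(i, j - 1) < INFE) w = std::min(w, iw(i, j - 1) + ml_c);
        for (int k = i; k < j; ++k) {
          int e1 = iw(i, k), e2 = iw(k + 1, j);
          if (e1 < INFE && e2 < INFE) w = std::min(w, e1 + e2);
        }
      }
      iw(i, j) = w;
    }
  }

  // ---- external: B[i] = best energy of suffix i..n-1 ----
  std::vector<int> B(n + 1, 0);
  for (int i = n - 1; i >= 0; --i) {
    B[i] = B[i + 1];
    for (int j = i + min_hairpin + 1; j < n; ++j) {
      int vv = iv(i, j);
      if (vv < INFE && vv + B[j + 1] < B[i]) B[i] = vv + B[j + 1];
    }
  }

  // ---- traceback (deterministic fixed exploration order) ----
  std::string db(n, '.');
  std::vector<std::array<int, 3>> st;  // {mode 0=V 1=WM, i, j}
  {
    int i = 0;
    while (i < n) {
      bool paired = false;
      for (int j = i + min_hairpin + 1; j < n; ++j) {
        int vv = iv(i, j);
        if (vv < INFE && vv + B[j + 1] == B[i]) {
          st.push_back({0, i, j});
          i = j + 1;
          paired = true;
          break;
        }
      }
      if (!paired) i += 1;
    }
  }
  while (!st.empty()) {
    auto it = st.back();
    st.pop_back();
    int i = it[1], j = it[2];
    if (it[0] == 0) {  // V(i,j)
      db[i] = '(';
      db[j] = ')';
      int v = iv(i, j), vt = pairtype(c[i], c[j]);
      bool done = false;
      for (int k = i + 1; !done && k < j - 1 && k - i - 1 <= max_interior; ++k) {
        int l1 = k - i - 1;
        for (int l = j - 1; l > k; --l) {
          int l2 = j - l - 1;
          if (l1 + l2 > max_interior) break;
          int pt2 = pairtype(c[k], c[l]);
          if (!pt2 || iv(k, l) >= INFE) continue;
          if (P.loopE(l1, l2, vt, pt2) + iv(k, l) == v) {
            st.push_back({0, k, l});
            done = true;
            break;
          }
        }
      }
      if (!done) {
        for (int k = i + 2; k < j - 2; ++k) {
          int e1 = iw(i + 1, k), e2 = iw(k + 1, j - 1);
          if (e1 < INFE && e2 < INFE && ml_a + ml_b + e1 + e2 == v) {
            st.push_back({1, i + 1, k});
            st.push_back({1, k + 1, j - 1});
            done = true;
            break;
          }
        }
      }
      // otherwise hairpin: nothing further
    } else {  // WM(i,j)
      int w = iw(i, j);
      if (iv(i, j) < INFE && iv(i, j) + ml_b == w) {
        st.push_back({0, i, j});
        continue;
      }
      if (i < j && iw(i + 1, j) < INFE && iw(i + 1, j) + ml_c == w) {
        st.push_back({1, i + 1, j});
        continue;
      }
      if (i < j && iw(i, j - 1) < INFE && iw(i, j - 1) + ml_c == w) {
        st.push_back({1, i, j - 1});
        continue;
      }
      bool done = false;
      for (int k = i; k < j && !done; ++k) {
        int e1 = iw(i, k), e2 = iw(k + 1, j);
        if (e1 < INFE && e2 < INFE && e1 + e2 == w) {
          st.push_back({1, i, k});
          st.push_back({1, k + 1, j});
          done = true;
        }
      }
    }
  }

  return List::create(_["energy"] = B[0], _["structure"] = db);
}

// Intermolecular duplex: strand a 5'->3' vs strand b 5'->3', antiparallel,
// no intramolecular pairs. Consecutive pairs may be separated by bulges or
// interior loops (total unpaired <= max_interior); no initiation term.
// [[Rcpp::export]]
List duplex_dp(IntegerVector ca_, IntegerVector cb_, IntegerMatrix stack,
               IntegerVector bulge, IntegerVector internal_, int max_interior) {
  const int n = ca_.size(), m = cb_.size();
  std::vector<int> a(ca_.begin(), ca_.end()), b(cb_.begin(), cb_.end());
  IntegerVector dummyH(1, INFE);
  Par P(stack, dummyH, bulge, internal_, 0, 0, 0, max_interior, 0);
  // D(i,j): best energy of a duplex whose first pair (5'-most in a) is (i,j)
  std::vector<int> D((size_t)n * m, INFE);
  auto idx = [&](int i, int j) -> int& { return D[(size_t)i * m + j]; };
  for (int i = n - 1; i >= 0; --i) {
    for (int j = 0; j < m; ++j) {
      int pt = pairtype(a[i], b[j]);
      if (!pt) continue;
      int best = 0;  // duplex ends here
      for (int k = i + 1; k < n && k - i - 1 <= max_interior; ++k) {
        int l1 = k - i - 1;
        for (int l = j - 1; l >= 0; --l) {
          int l2 = j - l - 1;
          if (l1 + l2 > max_interior) break;
          int pt2 = pairtype(a[k], b[l]);
          if (!pt2 || idx(k, l) >= INFE) continue;
          int e = P.loopE(l1, l2, pt, pt2) + idx(k, l);
          if (e < best) best = e;
        }
      }
      idx(i, j) = best;
    }
  }
  int mfe = 0, bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = m - 1; j >= 0; --j)
      if (idx(i, j) < INFE && idx(i, j) < mfe) { mfe = idx(i, j); bi = i; bj = j; }
  std::vector<int> pi, pj;
  if (bi >= 0) {
    int i = bi, j = bj;
    for (;;) {
      pi.push_back(i + 1);
      pj.push_back(j + 1);
      int cur = idx(i, j), pt = pairtype(a[i], b[j]);
      if (cur == 0) break;
      bool found = false;
      for (int k = i + 1; k < n && k - i - 1 <= max_interior && !found; ++k) {
        int l1 = k - i - 1;
        for (int l = j - 1; l >= 0; --l) {
          int l2 = j - l - 1;
          if (l1 + l2 > max_interior) break;
          int pt2 = pairtype(a[k], b[l]);
          if (!pt2 || idx(k, l) >= INFE) continue;
          if (P.loopE(l1, l2, pt, pt2) + idx(k, l) == cur) {
            i = k; j = l; found = true; break;
          }
        }
      }
      if (!found) break;
    }
  }
  return List::create(_["energy"] = mfe, _["i"] = wrap(pi), _["j"] = wrap(pj));
}
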