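#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <algorithm>
#include <vector>
#include <cmath>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// All randomness goes through R's RNG (unif_rand / R::rpois / R::rbinom) so
// that set.seed() on the R side fully determines every simulation.

// Copy one chromosome of a gamete from the two parental haplotypes.
// Crossover count ~ Poisson(chr_len); breakpoints uniform on [0, chr_len);
// transmission starts from a fair-coin haplotype and switches at each
// breakpoint. Loci with map position < breakpoint belong to the segment
// before it.
static void meiose_chr(const int* hapA, const int* hapB, int* out,
                       const double* pos, int n, double chr_len) {
  int k = (int) R::rpois(chr_len);
  const int* cur = (unif_rand() < 0.5) ? hapA : hapB;
  const int* oth = (cur == hapA) ? hapB : hapA;
  if (k == 0) {
    std::copy(cur, cur + n, out);
    return;
  }
  std::vector<double> xo((size_t) k);
  for (int i = 0; i < k; ++i) xo[i] = unif_rand() * chr_len;
  std::sort(xo.begin(), xo.end());
  int start = 0;
  for (int i = 0; i < k; ++i) {
    int b = (int)(std::lower_bound(pos, pos + n, xo[i]) - pos);
    if (b > start) {
      std::copy(cur + start, cur + b, out + start);
      start = b;
    }
    std::swap(cur, oth);
  }
  if (start < n) std::copy(cur + start, cur + n, out + start);
}

// Recurrent 0<->1 mutation: the number of mutated sites on a transmitted
// gamete is Binomial(L, mu), positions uniform (sampled with replacement;
// at mu ~ 2.5e-5 collisions are negligible).
static void mutate_gamete(int* g, int L, double mu) {
  if (mu <= 0.0) return;
  int nmut = (int) R::rbinom((double) L, mu);
  for (int i = 0; i < nmut; ++i) {
    int j = (int)(unif_rand() * L);
    if (j == L) j = L - 1;
    g[j] = 1 - g[j];
  }
}

// Wright-Fisher burn-in: monoecious population of ne diploids, discrete
// generations, each offspring draws two parents uniformly with replacement
// (selfing allowed). Haplotype matrix is loci x 2*ne, columns 2i-1, 2i are
// individual i. Equally spaced loci at (j + 0.5) * chr_len / lpc.
// [[Rcpp::export]]
IntegerMatrix cpp_wf_burnin(int ne, int ngen, int nchr, int lpc,
                            double chr_len, double mu,
                            Nullable<IntegerMatrix> init) {
  if (ne < 2) stop("effective size must be at least 2");
  if (ngen < 0) stop("number of generations must be non-negative");
  const int L = nchr * lpc;
  IntegerMatrix A(L, 2 * ne), B(L, 2 * ne);
  if (init.isNotNull()) {
    IntegerMatrix I(init);
    if (I.nrow() != L || I.ncol() != 2 * ne)
      stop("init haplotypes must be %d x %d", L, 2 * ne);
    std::copy(I.begin(), I.end(), A.begin());
  } // else: all loci fixed for allele 0
  std::vector<double> pos((size_t) lpc);
  for (int j = 0; j < lpc; ++j) pos[j] = (j + 0.5) * chr_len / lpc;

  for (int g = 0; g < ngen; ++g) {
    int* pa = INTEGER(A);
    int* pb = INTEGER(B);
    for (int i = 0; i < ne; ++i) {
      for (int h = 0; h < 2; ++h) { // maternal then paternal gamete
        int par = (int)(unif_rand() * ne);
        if (par == ne) par = ne - 1;
        int* out = pb + (ptrdiff_t)(2 * i + h) * L;
        const int* h0 = pa + (ptrdiff_t)(2 * par) * L;
        const int* h1 = h0 + L;
        for (int c = 0; c < nchr; ++c)
          meiose_chr(h0 + c * lpc, h1 + c * lpc, out + c * lpc,
                     pos.data(), lpc, chr_len);
        mutate_gamete(out, L, mu);
      }
    }
    std::swap(A, B);
    if ((g & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return A;
}

// Drop gametes through an arbitrary locus map (used in the breeding phase,
// where marker, QTL and IBD-tracking loci are co-inherited on shared
// crossovers). hapA/hapB give, per gamete, the 1-based column indices of the
// parent's two haplotypes in H. chr_off is the 0-based row offset of each
// chromosome, chr_n the locus count per chromosome.
// [[Rcpp::export]]
IntegerMatrix cpp_drop_gametes(IntegerMatrix H, IntegerVector hapA,
                               IntegerVector hapB, IntegerVector chr_off,
                               IntegerVector chr_n, NumericVector pos,
                               double chr_len, double mu) {
  const int L = H.nrow();
  const int ng = hapA.size();
  const int nchr = chr_off.size();
  if (hapB.size() != ng) stop("hapA and hapB lengths differ");
  IntegerMatrix G(L, ng);
  const int* ph = INTEGER(H);
  int* pg = INTEGER(G);
  for (int g = 0; g < ng; ++g) {
    int ca = hapA[g] - 1, cb = hapB[g] - 1;
    if (ca < 0 || cb < 0 || ca >= H.ncol() || cb >= H.ncol())
      stop("haplotype column index out of range");
    const int* h0 = ph + (ptrdiff_t) ca * L;
    const int* h1 = ph + (ptrdiff_t) cb * L;
    int* out = pg + (ptrdiff_t) g * L;
    for (int c = 0; c < nchr; ++c) {
      int off = chr_off[c], n = chr_n[c];
      meiose_chr(h0 + off, h1 + off, out + off, REAL(pos) + off, n, chr_len);
    }
    mutate_gamete(out, L, mu);
  }
  return G;
}

// Exact solution of the square linear assignment problem (shortest
// augmenting path with potentials, O(n^3)); returns for each row the
// 1-based assigned column. Deterministic for a given cost matrix.
// [[Rcpp::export]]
IntegerVector cpp_assignment(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  for (int i = 0; i < n * n; ++i)
    if (!R_finite(cost[i])) stop("cost matrix has non-finite entries");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u((size_t) n + 1, 0.0), v((size_t) n + 1, 0.0);
  std::vector<int> p((size_t) n + 1, 0), way((size_t) n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv((size_t) n + 1, INF);
    std::vector<char> used((size_t) n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j) ans[p[j] - 1] = j;
  return ans;
}

// ---- MCAC local search --------------------------------------------------
//
// Matings m = 1..n carry a fixed sire slot; dams are permuted over slots.
// Contribution of ancestor a to mating m: C[a,m] = S[a,m] + V[a, sigma(m)],
// where S holds the half-rows of the sires' contribution matrix and V the
// half-rows of the dams'. Objective: sum over unordered ancestor pairs of
// |cov across matings| (population covariance). Row means of C are invariant
// under dam permutation, so the centered cross-product matrix
// R[a,b] = sum_m C[a,m]C[b,m] - n mu_a mu_b can be updated by a rank-2
// correction per dam swap, and a candidate swap is scored in O(n_anc^2).

static double mcac_obj_from_R(const std::vector<double>& Rm, int na, int n) {
  double s = 0.0;
  for (int b = 1; b < na; ++b) {
    const double* col = Rm.data() + (ptrdiff_t) b * na;
    for (int a = 0; a < b; ++a) s += std::fabs(col[a]);
  }
  return s / n;
}

static void mcac_build_R(const std::vector<double>& C,
                         const std::vector<double>& mu,
                         std::vector<double>& Rm, int na, int n) {
  std::fill(Rm.begin(), Rm.end(), 0.0);
  for (int m = 0; m < n; ++m) {
    const double* cm = C.data() + (ptrdiff_t) m * na;
    for (int b = 0; b < na; ++b) {
      double cb = cm[b];
      if (cb == 0.0) continue;
      double* col = Rm.data() + (ptrdiff_t) b * na;
      for (int a = 0; a <= b; ++a) col[a] += cm[a] * cb;
    }
  }
  for (int b = 0; b < na; ++b) {
    double* col = Rm.data() + (ptrdiff_t) b * na;
    for (int a = 0; a <= b; ++a) col[a] -= n * mu[a] * mu[b];
  }
}

// The local search over dam swaps uses two evaluation levels. The exact
// delta of a candidate swap (rank-2 update of the centred cross-product
// matrix R) costs O(n_anc^2). The screening surrogate splits R's entries:
// for "stable" pairs (|R_ab| above a data-driven threshold, where the
// update cannot plausibly flip the covariance sign) the delta contribution
// is linear, w' Sg q with Sg = sign(R) zeroed on the small set, which is
// O(1) per candidate after precomputing U = Sg V, B = U'C and W = U'V
// (BLAS); the small-|R| pairs are corrected exactly. Each pass screens all
// candidate swaps, re-scores the most promising ones exactly, and applies
// every strictly-improving one. On small problems (or under
// best_improvement) the local optimum is certified by exact sweeps over
// all candidates; on large problems the search stops when the screen runs
// dry, a documented heuristic cutoff.

// [[Rcpp::export]]
List cpp_mcac_search(NumericMatrix S, NumericMatrix V, IntegerVector sigma0,
                     IntegerVector slot_sire, int max_sweeps,
                     bool best_improvement) {
  const int na = S.nrow();
  const int n = S.ncol();
  if (V.nrow() != na) stop("S and V must have the same number of ancestors");
  if (V.ncol() != n) stop("number of dams must equal number of matings");
  if (sigma0.size() != n) stop("initial assignment has wrong length");

  std::vector<int> sigma(n);
  for (int m = 0; m < n; ++m) sigma[m] = sigma0[m] - 1;

  // C (na x n), column-major by mating
  std::vector<double> C((size_t) na * n), mu((size_t) na, 0.0);
  for (int m = 0; m < n; ++m)
    for (int a = 0; a < na; ++a)
      C[(size_t) m * na + a] = S(a, m) + V(a, sigma[m]);
  for (int m = 0; m < n; ++m)
    for (int a = 0; a < na; ++a) mu[a] += C[(size_t) m * na + a];
  for (int a = 0; a < na; ++a) mu[a] /= n;

  std::vector<double> Rm((size_t) na * na);
  mcac_build_R(C, mu, Rm, na, n);

  std::vector<double> Sg((size_t) na * na);
  std::vector<double> U((size_t) na * n);  // Sg V
  std::vector<double> B((size_t) n * n);   // U' C  (dam x mating)
  std::vector<double> W((size_t) n * n);   // U' V  (dam x dam)
  std::vector<int> smallA, smallB;         // pairs with |R| below threshold
  const double one = 1.0, zero = 0.0;
  const size_t small_cap = 10000;
  const bool certify = best_improvement || na <= 600;
  const int max_exact_sweeps = 10;

  auto refresh_screen = [&]() {
    // data-driven threshold so that at most small_cap pairs are "small"
    size_t npair = (size_t) na * (na - 1) / 2;
    double tau = 0.0;
    if (npair > small_cap) {
      std::vector<double> mag;
      mag.reserve(npair);
      for (int b = 1; b < na; ++b) {
        const double* col = Rm.data() + (ptrdiff_t) b * na;
        for (int a = 0; a < b; ++a) mag.push_back(std::fabs(col[a]));
      }
      std::nth_element(mag.begin(), mag.begin() + small_cap, mag.end());
      tau = mag[small_cap];
    } else {
      tau = R_PosInf; // treat every pair exactly
    }
    smallA.clear(); smallB.clear();
    for (int b = 0; b < na; ++b) {
      const double* col = Rm.data() + (ptrdiff_t) b * na;
      double* sc = Sg.data() + (ptrdiff_t) b * na;
      for (int a = 0; a < b; ++a) {
        double s;
        if (std::fabs(col[a]) < tau) {
          s = 0.0;
          smallA.push_back(a); smallB.push_back(b);
        } else {
          s = (col[a] > 0.0) - (col[a] < 0.0);
        }
        sc[a] = s;
        Sg[(size_t) a * na + b] = s;
      }
      sc[b] = 0.0;
    }
    F77_CALL(dgemm)("N", "N", &na, &n, &na, &one, Sg.data(), &na,
                    REAL(V), &na, &zero, U.data(), &na FCONE FCONE);
    F77_CALL(dgemm)("T", "N", &n, &n, &na, &one, U.data(), &na,
                    C.data(), &na, &zero, B.data(), &n FCONE FCONE);
    F77_CALL(dgemm)("T", "N", &n, &n, &na, &one, U.data(), &na,
                    REAL(V), &na, &zero, W.data(), &n FCONE FCONE);
  };

  std::vector<double> w((size_t) na), q((size_t) na);
  const double eps = 1e-12;
  int sweeps = 0, applied = 0, exact_sweeps = 0;

  auto load_wq = [&](int m1, int m2) {
    const double* c1 = C.data() + (ptrdiff_t) m1 * na;
    const double* c2 = C.data() + (ptrdiff_t) m2 * na;
    const double* v1 = &V(0, sigma[m1]);
    const double* v2 = &V(0, sigma[m2]);
    for (int a = 0; a < na; ++a) {
      w[a] = v2[a] - v1[a];
      q[a] = c1[a] - c2[a] + w[a];
    }
  };

  auto proxy = [&](int m1, int m2) -> double {
    int j1 = sigma[m1], j2 = sigma[m2];
    double t1 = 0.5 * ((B[(size_t) m1 * n + j2] - B[(size_t) m2 * n + j2]) -
                       (B[(size_t) m1 * n + j1] - B[(size_t) m2 * n + j1]));
    double t2 = 0.25 * (W[(size_t) j2 * n + j2] -
                        2.0 * W[(size_t) j2 * n + j1] +
                        W[(size_t) j1 * n + j1]);
    double d = t1 + t2;
    // exact correction for the small-|R| pairs
    load_wq(m1, m2);
    for (size_t k = 0; k < smallA.size(); ++k) {
      int a = smallA[k], b = smallB[k];
      double r = Rm[(size_t) b * na + a];
      double upd = w[a] * q[b] + w[b] * q[a];
      if (upd != 0.0) d += std::fabs(r + upd) - std::fabs(r);
    }
    return d / n;
  };

  auto score_swap = [&](int m1, int m2) -> double {
    load_wq(m1, m2);
    double d = 0.0;
    for (int b = 1; b < na; ++b) {
      const double wb = w[b], qb = q[b];
      const double* col = Rm.data() + (ptrdiff_t) b * na;
      for (int a = 0; a < b; ++a) {
        double upd = w[a] * qb + wb * q[a];
        if (upd != 0.0)
          d += std::fabs(col[a] + upd) - std::fabs(col[a]);
      }
    }
    return d / n;
  };

  auto apply_swap = [&](int m1, int m2) {
    load_wq(m1, m2);
    for (int b = 1; b < na; ++b) {
      const double wb = w[b], qb = q[b];
      double* col = Rm.data() + (ptrdiff_t) b * na;
      for (int a = 0; a < b; ++a) col[a] += w[a] * qb + wb * q[a];
    }
    double* c1 = C.data() + (ptrdiff_t) m1 * na;
    double* c2 = C.data() + (ptrdiff_t) m2 * na;
    for (int a = 0; a < na; ++a) { c1[a] += w[a]; c2[a] -= w[a]; }
    std::swap(sigma[m1], sigma[m2]);
    ++applied;
  };

  const int n_screen = 32;
  refresh_screen();

  while (sweeps < max_sweeps) {
    ++sweeps;

    if (best_improvement) {
      // certified steepest descent: exact evaluation of every candidate
      int bm1 = -1, bm2 = -1;
      double best_d = -eps;
      for (int m1 = 0; m1 < n - 1; ++m1)
        for (int m2 = m1 + 1; m2 < n; ++m2) {
          if (slot_sire[m1] == slot_sire[m2]) continue;
          double d = score_swap(m1, m2);
          if (d < best_d) { best_d = d; bm1 = m1; bm2 = m2; }
        }
      if (bm1 < 0) break;
      apply_swap(bm1, bm2);
      if ((sweeps & 15) == 0) Rcpp::checkUserInterrupt();
      continue;
    }

    // surrogate screen, then exact re-scoring of the most promising
    // candidates in proxy order, applying every strictly-improving one
    std::vector<std::pair<double, int> > cand;
    for (int m1 = 0; m1 < n - 1; ++m1)
      for (int m2 = m1 + 1; m2 < n; ++m2) {
        if (slot_sire[m1] == slot_sire[m2]) continue;
        double d = proxy(m1, m2);
        if (d < -eps) cand.push_back(std::make_pair(d, m1 * n + m2));
      }
    int keep = std::min((int) cand.size(), n_screen);
    std::partial_sort(cand.begin(), cand.begin() + keep, cand.end());
    int applied_here = 0;
    for (int k = 0; k < keep; ++k) {
      int m1 = cand[k].second / n, m2 = cand[k].second % n;
      if (score_swap(m1, m2) < -eps) {
        apply_swap(m1, m2);
        ++applied_here;
      }
    }
    if (applied_here == 0) {
      // heuristic stop on large problems or after enough exact passes
      if (!certify || exact_sweeps >= max_exact_sweeps) break;
      ++exact_sweeps;
      int exact_applied = 0;
      for (int m1 = 0; m1 < n - 1; ++m1)
        for (int m2 = m1 + 1; m2 < n; ++m2) {
          if (slot_sire[m1] == slot_sire[m2]) continue;
          if (score_swap(m1, m2) < -eps) {
            apply_swap(m1, m2);
            ++exact_applied;
          }
        }
      if (exact_applied == 0) break; // local optimum (exactly verified)
    }
    refresh_screen();
    Rcpp::checkUserInterrupt();
  }

  // recompute the objective from scratch for numerical hygiene
  mcac_build_R(C, mu, Rm, na, n);
  double obj = mcac_obj_from_R(Rm, na, n);

  IntegerVector out(n);
  for (int m = 0; m < n; ++m) out[m] = sigma[m] + 1;
  return List::create(_["assignment"] = out, _["objective"] = obj,
                      _["sweeps"] = sweeps, _["swaps"] = applied,
                      _["exact_sweeps"] = exact_sweeps);
}
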