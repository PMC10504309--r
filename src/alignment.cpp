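// Affine-gap pairwise and profile alignment kernels (Gotoh three-state DP).
//
// Conventions shared by every entry point:
//   * a gap run of length L costs gap_open + L * gap_extend;
//   * traceback state preference on score ties: diagonal > up (gap in the
//     second sequence) > left (gap in the first sequence);
//   * percent identity = 100 * identical columns / alignment length, with
//     gap columns counted in the denominator.

#include <Rcpp.h>
#include <limits>
#include <vector>
#include <string>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Map sequence characters to row indices of the substitution matrix.
static std::vector<int> encode(const std::string& s,
                               const std::string& alphabet) {
  std::vector<int> idx(s.size());
  int lookup[256];
  for (int i = 0; i < 256; ++i) lookup[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lookup[(unsigned char)alphabet[i]] = (int)i;
  for (size_t i = 0; i < s.size(); ++i) {
    int v = lookup[(unsigned char)s[i]];
    if (v < 0)
      stop("residue '%s' not present in the substitution matrix alphabet",
           std::string(1, s[i]).c_str());
    idx[i] = v;
  }
  return idx;
}

// flatten the substitution matrix for cheap row-major lookups
static std::vector<double> flatten(const NumericMatrix& submat) {
  const int K = submat.nrow();
  std::vector<double> S((size_t)K * K);
  for (int x = 0; x < K; ++x)
    for (int y = 0; y < K; ++y) S[(size_t)x * K + y] = submat(x, y);
  return S;
}

// state codes used in traceback matrices
enum { ST_M = 0, ST_UP = 1, ST_LEFT = 2, ST_STOP = 3 };

static inline int best3(double m, double up, double left, double& out) {
  // tie preference M > UP > LEFT
  if (m >= up && m >= left) { out = m; return ST_M; }
  if (up >= left)           { out = up; return ST_UP; }
  out = left; return ST_LEFT;
}

// [[Rcpp::export(name = ".cpp_align_pair")]]
List cpp_align_pair(std::string a, std::string b,
                    NumericMatrix submat, std::string alphabet,
                    double gap_open, double gap_extend,
                    bool local) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<int> ea = encode(a, alphabet), eb = encode(b, alphabet);
  const std::vector<double> S = flatten(submat);
  const int K = submat.nrow();
  const double go = gap_open + gap_extend;  // cost of opening a length-1 gap

  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG_INF), U((m + 1) * W, NEG_INF),
      L((m + 1) * W, NEG_INF);
  // traceback: where each state's value came from
  std::vector<signed char> tbM((m + 1) * W, ST_STOP), tbU((m + 1) * W, ST_STOP),
      tbL((m + 1) * W, ST_STOP);

  M[0] = 0.0;
  if (!local) {
    for (int i = 1; i <= m; ++i) {
      U[i * W] = -(gap_open + i * gap_extend);
      tbU[i * W] = (i == 1) ? ST_M : ST_UP;
    }
    for (int j = 1; j <= n; ++j) {
      L[j] = -(gap_open + j * gap_extend);
      tbL[j] = (j == 1) ? ST_M : ST_LEFT;
    }
  }

  double best = 0.0;
  int bi = 0, bj = 0;  // best cell for local mode

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j, cd = (i - 1) * W + (j - 1), cu = (i - 1) * W + j,
                cl = i * W + (j - 1);
      const double s = S[(size_t)ea[i - 1] * K + eb[j - 1]];
      // M: consume one residue from each
      double prev;
      int src = best3(M[cd], U[cd], L[cd], prev);
      double mval;
      if (local) {
        // local alignments restart whenever the best prefix is <= 0
        if (prev == NEG_INF || prev <= 0.0) {
          mval = s;
          src = ST_STOP;
        } else {
          mval = prev + s;
        }
      } else {
        mval = (prev == NEG_INF) ? NEG_INF : prev + s;
      }
      M[c] = mval;
      tbM[c] = (signed char)src;
      // U ("up"): gap in b, consume a_i
      double uval;
      int usrc = best3(M[cu] - go, U[cu] - gap_extend, L[cu] - go, uval);
      U[c] = uval;
      tbU[c] = (signed char)usrc;
      // L ("left"): gap in a, consume b_j
      double lval;
      int lsrc = best3(M[cl] - go, U[cl] - go, L[cl] - gap_extend, lval);
      L[c] = lval;
      tbL[c] = (signed char)lsrc;
      if (local && M[c] > best) {  // strict > keeps the smallest (i, j)
        best = M[c];
        bi = i;
        bj = j;
      }
    }
  }

  std::string ra, rb;
  double score;
  if (local) {
    score = best;
    if (best <= 0.0) {  // empty optimal alignment
      return List::create(_["aligned_a"] = "", _["aligned_b"] = "",
                          _["score"] = 0.0);
    }
    int i = bi, j = bj, st = ST_M;
    while (i > 0 && j > 0) {
      if (st == ST_M) {
        int src = tbM[i * W + j];
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        --i; --j;
        if (src == ST_STOP) break;
        st = src;
      } else if (st == ST_UP) {
        int src = tbU[i * W + j];
        ra.push_back(a[i - 1]);
        rb.push_back('-');
        --i;
        st = src;
      } else {
        int src = tbL[i * W + j];
        ra.push_back('-');
        rb.push_back(b[j - 1]);
        --j;
        st = src;
      }
    }
  } else {
    const int c = m * W + n;
    double dummy;
    int st = best3(M[c], U[c], L[c], dummy);
    score = dummy;
    int i = m, j = n;
    while (i > 0 || j > 0) {
      if (st == ST_M) {
        int src = tbM[i * W + j];
        ra.push_back(a[i - 1]);
        rb.push_back(b[j - 1]);
        --i; --j;
        st = src;
      } else if (st == ST_UP) {
        int src = tbU[i * W + j];
        ra.push_back(a[i - 1]);
        rb.push_back('-');
        --i;
        st = src;
      } else if (st == ST_LEFT) {
        int src = tbL[i * W + j];
        ra.push_back('-');
        rb.push_back(b[j - 1]);
        --j;
        st = src;
      } else {
        stop("internal error: traceback reached STOP before the origin");
      }
      if (i == 0 && j > 0) st = ST_LEFT;
      if (j == 0 && i > 0) st = ST_UP;
      if (i == 0 && j == 0) break;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}

// Score-only variant used for reference sweeps (no traceback storage).
// [[Rcpp::export(name = ".cpp_align_scores")]]
NumericVector cpp_align_scores(std::string a, CharacterVector targets,
                               NumericMatrix submat, std::string alphabet,
                               double gap_open, double gap_extend,
                               bool local) {
  const int nt = targets.size();
  NumericVector out(nt);
  std::vector<int> ea = encode(a, alphabet);
  const int m = (int)a.size();
  const std::vector<double> S = flatten(submat);
  const int K = submat.nrow();
  const double ge = gap_extend, go = gap_open + gap_extend;
  for (int t = 0; t < nt; ++t) {
    std::string b = as<std::string>(targets[t]);
    std::vector<int> eb = encode(b, alphabet);
    const int n = (int)b.size();
    std::vector<double> Mp(n + 1, NEG_INF), Up(n + 1, NEG_INF),
        Lp(n + 1, NEG_INF), Mc(n + 1), Uc(n + 1), Lc(n + 1);
    Mp[0] = 0.0;
    if (!local)
      for (int j = 1; j <= n; ++j) Lp[j] = -(gap_open + j * gap_extend);
    double best = 0.0;
    for (int i = 1; i <= m; ++i) {
      Mc[0] = NEG_INF;
      Uc[0] = local ? NEG_INF : -(gap_open + i * gap_extend);
      Lc[0] = NEG_INF;
      const double* Srow = &S[(size_t)ea[i - 1] * K];
      for (int j = 1; j <= n; ++j) {
        const double s = Srow[eb[j - 1]];
        double prev = std::max(Mp[j - 1], std::max(Up[j - 1], Lp[j - 1]));
        double mval;
        if (local) {
          mval = (prev <= 0.0 || prev == NEG_INF) ? s : prev + s;
          if (mval > best) best = mval;
        } else {
          mval = (prev == NEG_INF) ? NEG_INF : prev + s;
        }
        Mc[j] = mval;
        Uc[j] = std::max(Mp[j] - go, std::max(Up[j] - ge, Lp[j] - go));
        Lc[j] =
            std::max(Mc[j - 1] - go, std::max(Uc[j - 1] - go, Lc[j - 1] - ge));
      }
      std::swap(Mp, Mc); std::swap(Up, Uc); std::swap(Lp, Lc);
    }
    out[t] = local ? best
                   : std::max(Mp[n], std::max(Up[n], Lp[n]));
  }
  return out;
}

// Profile-profile global alignment for progressive MSA.  Column score is the
// average substitution score over residue pairs drawn from the two columns;
// gap characters contribute zero.  Gap penalties are applied at full weight.
// [[Rcpp::export(name = ".cpp_align_profiles")]]
List cpp_align_profiles(CharacterVector profA, CharacterVector profB,
                        NumericMatrix submat, std::string alphabet,
                        double gap_open, double gap_extend) {
  const int nA = profA.size(), nB = profB.size();
  std::vector<std::string> A(nA), B(nB);
  for (int r = 0; r < nA; ++r) A[r] = as<std::string>(profA[r]);
  for (int r = 0; r < nB; ++r) B[r] = as<std::string>(profB[r]);
  const int m = (int)A[0].size(), n = (int)B[0].size();
  const int K = (int)alphabet.size();

  // residue-frequency columns (gap excluded, counts kept)
  std::vector<std::vector<double>> fa(m, std::vector<double>(K, 0.0)),
      fb(n, std::vector<double>(K, 0.0));
  int lookup[256];
  for (int i = 0; i < 256; ++i) lookup[i] = -1;
  for (int i = 0; i < K; ++i) lookup[(unsigned char)alphabet[i]] = i;
  for (int r = 0; r < nA; ++r)
    for (int i = 0; i < m; ++i) {
      char ch = A[r][i];
      if (ch == '-') continue;
      int v = lookup[(unsigned char)ch];
      if (v < 0) stop("profile residue not in substitution matrix alphabet");
      fa[i][v] += 1.0;
    }
  for (int r = 0; r < nB; ++r)
    for (int j = 0; j < n; ++j) {
      char ch = B[r][j];
      if (ch == '-') continue;
      int v = lookup[(unsigned char)ch];
      if (v < 0) stop("profile residue not in substitution matrix alphabet");
      fb[j][v] += 1.0;
    }

  const double norm = (double)nA * (double)nB;
  // sparse residue entries per column of A; dense weight vectors per column
  // of B (w[j][x] = sum_y fb[j][y] * S[x][y]) make the cell score a short
  // sparse dot product.
  const std::vector<double> S = flatten(submat);
  std::vector<std::vector<std::pair<int, double>>> sa(m);
  for (int i = 0; i < m; ++i)
    for (int x = 0; x < K; ++x)
      if (fa[i][x] > 0.0) sa[i].push_back(std::make_pair(x, fa[i][x]));
  std::vector<std::vector<double>> wb(n, std::vector<double>(K, 0.0));
  for (int j = 0; j < n; ++j)
    for (int y = 0; y < K; ++y) {
      if (fb[j][y] == 0.0) continue;
      for (int x = 0; x < K; ++x) wb[j][x] += fb[j][y] * S[(size_t)x * K + y];
    }
  const double go = gap_open + gap_extend;
  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG_INF), U((m + 1) * W, NEG_INF),
      L((m + 1) * W, NEG_INF);
  std::vector<signed char> tbM((m + 1) * W, ST_STOP), tbU((m + 1) * W, ST_STOP),
      tbL((m + 1) * W, ST_STOP);
  M[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    U[i * W] = -(gap_open + i * gap_extend);
    tbU[i * W] = (i == 1) ? ST_M : ST_UP;
  }
  for (int j = 1; j <= n; ++j) {
    L[j] = -(gap_open + j * gap_extend);
    tbL[j] = (j == 1) ? ST_M : ST_LEFT;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = 0.0;
      const std::vector<double>& w = wb[j - 1];
      for (size_t q = 0; q < sa[i - 1].size(); ++q)
        s += sa[i - 1][q].second * w[sa[i - 1][q].first];
      s /= norm;
      const int c = i * W + j, cd = (i - 1) * W + (j - 1), cu = (i - 1) * W + j,
                cl = i * W + (j - 1);
      double v;
      int src = best3(M[cd], U[cd], L[cd], v);
      M[c] = v + s;
      tbM[c] = (signed char)src;
      int usrc = best3(M[cu] - go, U[cu] - gap_extend, L[cu] - go, v);
      U[c] = v;
      tbU[c] = (signed char)usrc;
      int lsrc = best3(M[cl] - go, U[cl] - go, L[cl] - gap_extend, v);
      L[c] = v;
      tbL[c] = (signed char)lsrc;
    }
  }
  // traceback into a column map
  std::vector<int> ops;  // ST_M / ST_UP / ST_LEFT per merged column
  int i = m, j = n;
  double scr;
  int st = best3(M[m * W + n], U[m * W + n], L[m * W + n], scr);
  while (i > 0 || j > 0) {
    if (i == 0) st = ST_LEFT;
    if (j == 0) st = ST_UP;
    ops.push_back(st);
    int src;
    if (st == ST_M) {
      src = tbM[i * W + j];
      --i; --j;
    } else if (st == ST_UP) {
      src = tbU[i * W + j];
      --i;
    } else {
      src = tbL[i * W + j];
      --j;
    }
    st = src;
  }
  std::reverse(ops.begin(), ops.end());
  const int LN = (int)ops.size();
  CharacterVector out(nA + nB);
  for (int r = 0; r < nA; ++r) {
    std::string row;
    row.reserve(LN);
    int p = 0;
    for (int c = 0; c < LN; ++c)
      row.push_back(ops[c] == ST_LEFT ? '-' : A[r][p++]);
    out[r] = row;
  }
  for (int r = 0; r < nB; ++r) {
    std::string row;
    row.reserve(LN);
    int p = 0;
    for (int c = 0; c < LN; ++c)
      row.push_back(ops[c] == ST_UP ? '-' : B[r][p++]);
    out[nA + r] = row;
  }
  return List::create(_["rows"] = out, _["score"] = scr);
}
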