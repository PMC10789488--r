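#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Average ranks (ties -> mean rank) of x over the indices in `use`.
static void avg_rank(const std::vector<double>& x, const std::vector<int>& use,
                     std::vector<double>& out) {
  const int n = use.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return x[use[a]] < x[use[b]];
  });
  out.resize(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[use[ord[j + 1]]] == x[use[ord[i]]]) ++j;
    double r = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) out[ord[k]] = r;
    i = j + 1;
  }
}

static const double CLIP = 1.0 - 1e-6;

static inline double fisher_clip(double r) {
  if (r > CLIP) r = CLIP;
  if (r < -CLIP) r = -CLIP;
  return atanh(r);
}

// Pearson correlation of two centered vectors given their sums of squares.
static inline double corr_centered(const std::vector<double>& a, double ssa,
                                   const std::vector<double>& b, double ssb) {
  if (ssa <= 0.0 || ssb <= 0.0) return NA_REAL;
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * b[i];
  return s / std::sqrt(ssa * ssb);
}

// Mean over patients of Fisher-z (partial) Spearman coefficients between each
// patient's z-map (vs the controls of this assignment) and every template.
// X: n_subj x n_regions; T: n_regions x n_templates; gm: length n_regions or
// empty (plain Spearman when empty). pat_idx/ctl_idx are 0-based rows of X.
static void assignment_stat(const NumericMatrix& X, const NumericMatrix& T,
                            const NumericVector& gm,
                            const std::vector<int>& pat_idx,
                            const std::vector<int>& ctl_idx,
                            std::vector<double>& stat_out) {
  const int n_reg = X.ncol(), n_tpl = T.ncol();
  const int n_pat = pat_idx.size(), n_ctl = ctl_idx.size();
  const bool partial = gm.size() > 0;

  // control mean/sd per region; usable regions have positive sd
  std::vector<double> mu(n_reg), sd(n_reg);
  std::vector<int> use;
  use.reserve(n_reg);
  for (int j = 0; j < n_reg; ++j) {
    double s = 0.0;
    for (int c = 0; c < n_ctl; ++c) s += X(ctl_idx[c], j);
    mu[j] = s / n_ctl;
    double ss = 0.0;
    for (int c = 0; c < n_ctl; ++c) {
      double d = X(ctl_idx[c], j) - mu[j];
      ss += d * d;
    }
    sd[j] = std::sqrt(ss / (n_ctl - 1));
    if (sd[j] > 0.0 && R_finite(sd[j])) use.push_back(j);
  }
  const int m = use.size();
  stat_out.assign(n_tpl, NA_REAL);
  if (m < 4) return;
  const double rmean = 0.5 * (m + 1);

  // template (and GM) ranks over the usable regions, centered
  std::vector<std::vector<double> > tr(n_tpl);
  std::vector<double> t_ss(n_tpl), work(n_reg), ranks;
  for (int k = 0; k < n_tpl; ++k) {
    for (int j = 0; j < n_reg; ++j) work[j] = T(j, k);
    avg_rank(work, use, tr[k]);
    double ss = 0.0;
    for (int i = 0; i < m; ++i) { tr[k][i] -= rmean; ss += tr[k][i] * tr[k][i]; }
    t_ss[k] = ss;
  }
  std::vector<double> gr;
  double g_ss = 0.0;
  std::vector<double> r_tg(n_tpl, 0.0);
  if (partial) {
    for (int j = 0; j < n_reg; ++j) work[j] = gm[j];
    avg_rank(work, use, gr);
    for (int i = 0; i < m; ++i) { gr[i] -= rmean; g_ss += gr[i] * gr[i]; }
    for (int k = 0; k < n_tpl; ++k)
      r_tg[k] = corr_centered(tr[k], t_ss[k], gr, g_ss);
  }

  std::vector<double> acc(n_tpl, 0.0);
  std::vector<int> n_acc(n_tpl, 0);
  std::vector<double> z(n_reg), zr;
  for (int p = 0; p < n_pat; ++p) {
    const int row = pat_idx[p];
    for (int i = 0; i < m; ++i) {
      const int j = use[i];
      z[j] = (X(row, j) - mu[j]) / sd[j];
    }
    avg_rank(z, use, zr);
    double z_ss = 0.0;
    for (int i = 0; i < m; ++i) { zr[i] -= rmean; z_ss += zr[i] * zr[i]; }
    double r_zg = partial ? corr_centered(zr, z_ss, gr, g_ss) : 0.0;
    for (int k = 0; k < n_tpl; ++k) {
      double r = corr_centered(zr, z_ss, tr[k], t_ss[k]);
      if (!R_finite(r)) continue;
      if (partial) {
        double rt = r_tg[k];
        if (!R_finite(r_zg) || !R_finite(rt)) continue;
        double den = (1.0 - r_zg * r_zg) * (1.0 - rt * rt);
        if (den <= 0.0) continue;
        r = (r - r_zg * rt) / std::sqrt(den);
        if (r > 1.0) r = 1.0;
        if (r < -1.0) r = -1.0;
      }
      acc[k] += fisher_clip(r);
      n_acc[k] += 1;
    }
  }
  for (int k = 0; k < n_tpl; ++k)
    stat_out[k] = n_acc[k] > 0 ? acc[k] / n_acc[k] : NA_REAL;
}

// [[Rcpp::export(name = ".coloc_perm_engine")]]
List coloc_perm_engine(NumericMatrix X, LogicalVector is_patient,
                       NumericMatrix T, NumericVector gm, int n_perm) {
  const int n_subj = X.nrow(), n_tpl = T.ncol();
  std::vector<int> pat, ctl;
  for (int i = 0; i < n_subj; ++i)
    (is_patient[i] ? pat : ctl).push_back(i);
  const int n_pat = pat.size();

  std::vector<double> stat;
  assignment_stat(X, T, gm, pat, ctl, stat);
  NumericVector observed(n_tpl);
  for (int k = 0; k < n_tpl; ++k) observed[k] = stat[k];

  NumericMatrix nulls(n_perm, n_tpl);
  std::vector<int> idx(n_subj);
  RNGScope scope;
  for (int b = 0; b < n_perm; ++b) {
    for (int i = 0; i < n_subj; ++i) idx[i] = i;
    // Fisher-Yates with R's RNG: random group-label reassignment
    for (int i = n_subj - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    std::vector<int> p_idx(idx.begin(), idx.begin() + n_pat);
    std::vector<int> c_idx(idx.begin() + n_pat, idx.end());
    assignment_stat(X, T, gm, p_idx, c_idx, stat);
    for (int k = 0; k < n_tpl; ++k) nulls(b, k) = stat[k];
  }
  return List::create(_["observed"] = observed, _["null"] = nulls);
}

// Per-patient Fisher-z (partial) Spearman profiles for a fixed assignment.
// [[Rcpp::export(name = ".coloc_profiles_engine")]]
NumericMatrix coloc_profiles_engine(NumericMatrix Xpat, NumericVector mu,
                                    NumericVector sd, NumericMatrix T,
                                    NumericVector gm) {
  const int n_pat = Xpat.nrow(), n_reg = Xpat.ncol(), n_tpl = T.ncol();
  const bool partial = gm.size() > 0;
  std::vector<int> use;
  for (int j = 0; j < n_reg; ++j)
    if (sd[j] > 0.0 && R_finite(sd[j]) && R_finite(mu[j])) use.push_back(j);
  const int m = use.size();
  NumericMatrix out(n_pat, n_tpl);
  std::fill(out.begin(), out.end(), NA_REAL);
  if (m < 4) return out;
  const double rmean = 0.5 * (m + 1);
  std::vector<std::vector<double> > tr(n_tpl);
  std::vector<double> t_ss(n_tpl), work(n_reg);
  for (int k = 0; k < n_tpl; ++k) {
    for (int j = 0; j < n_reg; ++j) work[j] = T(j, k);
    avg_rank(work, use, tr[k]);
    double ss = 0.0;
    for (int i = 0; i < m; ++i) { tr[k][i] -= rmean; ss += tr[k][i] * tr[k][i]; }
    t_ss[k] = ss;
  }
  std::vector<double> gr;
  double g_ss = 0.0;
  std::vector<double> r_tg(n_tpl, 0.0);
  if (partial) {
    for (int j = 0; j < n_reg; ++j) work[j] = gm[j];
    avg_rank(work, use, gr);
    for (int i = 0; i < m; ++i) { gr[i] -= rmean; g_ss += gr[i] * gr[i]; }
    for (int k = 0; k < n_tpl; ++k)
      r_tg[k] = corr_centered(tr[k], t_ss[k], gr, g_ss);
  }
  std::vector<double> z(n_reg), zr;
  for (int p = 0; p < n_pat; ++p) {
    for (int i = 0; i < m; ++i) {
      const int j = use[i];
      z[j] = (Xpat(p, j) - mu[j]) / sd[j];
    }
    avg_rank(z, use, zr);
    double z_ss = 0.0;
    for (int i = 0; i < m; ++i) { zr[i] -= rmean; z_ss += zr[i] * zr[i]; }
    double r_zg = partial ? corr_centered(zr, z_ss, gr, g_ss) : 0.0;
    for (int k = 0; k < n_tpl; ++k) {
      double r = corr_centered(zr, z_ss, tr[k], t_ss[k]);
      if (!R_finite(r)) continue;
      if (partial) {
        double rt = r_tg[k];
        if (!R_finite(r_zg) || !R_finite(rt)) continue;
        double den = (1.0 - r_zg * r_zg) * (1.0 - rt * rt);
        if (den <= 0.0) continue;
        r = (r - r_zg * rt) / std::sqrt(den);
        if (r > 1.0) r = 1.0;
        if (r < -1.0) r = -1.0;
      }
      out(p, k) = fisher_clip(r);
    }
  }
  return out;
}
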