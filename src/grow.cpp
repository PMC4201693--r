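#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Genotype partition side under a partition code.
//   code 0: {0} | {1,2}   (dominant)
//   code 1: {0,1} | {2}   (recessive)
//   code 2: {1} | {0,2}   (heterozygote vs homozygotes)
// Returns 0 for the low side, 1 for the high side.  Caller handles missing.
static inline int geno_side(int g, int part) {
  switch (part) {
  case 0:  return g == 0 ? 0 : 1;
  case 1:  return g <= 1 ? 0 : 1;
  default: return g == 1 ? 0 : 1;
  }
}

// A score cell: a set of subjects sharing one LR value.
struct Cell {
  double lr, ca, co;
};

// Mann-Whitney U of a grouped LR assignment, from per-cell case/control
// counts.  Ties (equal LR) contribute 1/2 per the kernel.
static double u_from_cells(std::vector<Cell> &cells, double nd, double nk) {
  std::sort(cells.begin(), cells.end(),
            [](const Cell &a, const Cell &b) { return a.lr < b.lr; });
  double below = 0.0, num = 0.0;
  size_t i = 0, m = cells.size();
  while (i < m) {
    size_t j = i;
    double tca = 0.0, tco = 0.0;
    while (j < m && cells[j].lr == cells[i].lr) {
      tca += cells[j].ca;
      tco += cells[j].co;
      ++j;
    }
    num += tca * (below + 0.5 * tco);
    below += tco;
    i = j;
  }
  return num / (nd * nk);
}

static inline double plugin_lr(double ca, double co, double smooth,
                               double dca, double dco) {
  if (smooth == 0.0 && co == 0.0) return R_PosInf;
  return ((ca + smooth) / dca) / ((co + smooth) / dco);
}

// Greedy level-wise forward selection of (SNP, partition) splits.
//
// geno:     n_all x p integer matrix, values 0/1/2/NA.
// rows:     1-based subject row indices (may repeat, e.g. bootstrap).
// is_case:  0/1 per entry of rows.
// cand:     1-based candidate column indices, ascending (tie-break order).
// parts:    partition codes to consider, in tie-break order.
//
// Subjects missing the chosen SNP at a level are frozen: they keep the LR of
// their pre-split group and leave the refined groups' counts.  All subjects
// (frozen included) enter the U that scores each candidate split, with
// N_D/N_Dbar fixed at the full training totals.
// [[Rcpp::export]]
List cpp_grow_tree(IntegerMatrix geno, IntegerVector rows,
                   IntegerVector is_case, IntegerVector cand, int max_depth,
                   int min_group, IntegerVector parts, double smooth,
                   double eps) {
  const int n = rows.size();
  double nd = 0.0;
  for (int i = 0; i < n; ++i) nd += is_case[i];
  const double nk = n - nd;
  const double dca = nd + 2.0 * smooth, dco = nk + 2.0 * smooth;

  std::vector<int> grp(n, 0);
  std::vector<double> lr(n, 1.0);
  std::vector<char> frozen(n, 0);
  std::vector<double> grp_lr(1, 1.0);
  std::vector<Cell> frozen_cells;
  std::vector<char> used(geno.ncol(), 0);

  double cur_u = 0.5;
  std::vector<int> sel_snp, sel_part;
  std::vector<double> u_path;
  std::vector<List> level_info;

  for (int level = 0; level < max_depth; ++level) {
    const int G = 1 << level;
    int best_snp = -1, best_part = -1;
    double best_u = cur_u;
    std::vector<double> ca_cnt(2 * G), co_cnt(2 * G), st_ca(G), st_co(G);
    std::vector<Cell> cells;

    for (int ci = 0; ci < cand.size(); ++ci) {
      const int j = cand[ci] - 1;
      if (used[j]) continue;
      const int *gcol = INTEGER(geno) + (R_xlen_t)j * geno.nrow();
      for (int pi = 0; pi < parts.size(); ++pi) {
        const int p = parts[pi];
        std::fill(ca_cnt.begin(), ca_cnt.end(), 0.0);
        std::fill(co_cnt.begin(), co_cnt.end(), 0.0);
        std::fill(st_ca.begin(), st_ca.end(), 0.0);
        std::fill(st_co.begin(), st_co.end(), 0.0);
        for (int i = 0; i < n; ++i) {
          if (frozen[i]) continue;
          const int g = gcol[rows[i] - 1];
          if (g == NA_INTEGER) {
            if (is_case[i]) st_ca[grp[i]] += 1.0; else st_co[grp[i]] += 1.0;
          } else {
            const int ng = 2 * grp[i] + geno_side(g, p);
            if (is_case[i]) ca_cnt[ng] += 1.0; else co_cnt[ng] += 1.0;
          }
        }
        bool ok = true;
        cells.clear();
        for (int gi = 0; gi < 2 * G; ++gi) {
          const double tot = ca_cnt[gi] + co_cnt[gi];
          if (tot == 0.0) continue;
          if (tot < min_group) { ok = false; break; }
          cells.push_back({plugin_lr(ca_cnt[gi], co_cnt[gi], smooth, dca, dco),
                           ca_cnt[gi], co_cnt[gi]});
        }
        if (!ok) continue;
        for (int gi = 0; gi < G; ++gi)
          if (st_ca[gi] + st_co[gi] > 0.0)
            cells.push_back({grp_lr[gi], st_ca[gi], st_co[gi]});
        for (size_t k = 0; k < frozen_cells.size(); ++k)
          cells.push_back(frozen_cells[k]);
        const double u = u_from_cells(cells, nd, nk);
        if (u > best_u + eps) { best_u = u; best_snp = j; best_part = p; }
      }
    }

    if (best_snp < 0) break;

    // Commit the winning split: recompute its counts, refresh group LRs,
    // freeze subjects missing the chosen SNP.
    std::fill(ca_cnt.begin(), ca_cnt.end(), 0.0);
    std::fill(co_cnt.begin(), co_cnt.end(), 0.0);
    const int *gcol = INTEGER(geno) + (R_xlen_t)best_snp * geno.nrow();
    std::vector<double> fr_ca(G, 0.0), fr_co(G, 0.0);
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      const int g = gcol[rows[i] - 1];
      if (g == NA_INTEGER) {
        frozen[i] = 1;
        if (is_case[i]) fr_ca[grp[i]] += 1.0; else fr_co[grp[i]] += 1.0;
      } else {
        grp[i] = 2 * grp[i] + geno_side(g, best_part);
        if (is_case[i]) ca_cnt[grp[i]] += 1.0; else co_cnt[grp[i]] += 1.0;
      }
    }
    for (int gi = 0; gi < G; ++gi)
      if (fr_ca[gi] + fr_co[gi] > 0.0)
        frozen_cells.push_back({grp_lr[gi], fr_ca[gi], fr_co[gi]});
    std::vector<double> new_lr(2 * G, NA_REAL);
    for (int gi = 0; gi < 2 * G; ++gi)
      if (ca_cnt[gi] + co_cnt[gi] > 0.0)
        new_lr[gi] = plugin_lr(ca_cnt[gi], co_cnt[gi], smooth, dca, dco);
    for (int i = 0; i < n; ++i)
      if (!frozen[i]) lr[i] = new_lr[grp[i]];
    grp_lr = new_lr;
    used[best_snp] = 1;
    sel_snp.push_back(best_snp + 1);
    sel_part.push_back(best_part);
    u_path.push_back(best_u);
    cur_u = best_u;
    level_info.push_back(List::create(
        _["n_case"] = NumericVector(ca_cnt.begin(), ca_cnt.end()),
        _["n_control"] = NumericVector(co_cnt.begin(), co_cnt.end()),
        _["lr"] = NumericVector(new_lr.begin(), new_lr.end())));
  }

  List levels(level_info.size());
  for (size_t k = 0; k < level_info.size(); ++k) levels[k] = level_info[k];
  return List::create(
      _["snp"] = IntegerVector(sel_snp.begin(), sel_snp.end()),
      _["part"] = IntegerVector(sel_part.begin(), sel_part.end()),
      _["u_path"] = NumericVector(u_path.begin(), u_path.end()),
      _["levels"] = levels,
      _["subject_lr"] = NumericVector(lr.begin(), lr.end()),
      _["subject_group"] = IntegerVector(grp.begin(), grp.end()),
      _["subject_frozen"] = LogicalVector(frozen.begin(), frozen.end()));
}
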