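#include <Rcpp.h>
using namespace Rcpp;

// Flattened-forest traversal kernels used by the permutation-importance
// ranker. A forest is passed as parallel arrays: for tree t the nodes live
// at [offsets[t], offsets[t+1]) with 0-based within-tree child indices,
// 0-based split variables (-1 at leaves) and 1-based class predictions at
// leaves. Numeric routing follows the convention value <= split -> left.

static inline int route_row(const IntegerVector& left,
                            const IntegerVector& right,
                            const IntegerVector& svar,
                            const NumericVector& sval,
                            const IntegerVector& pred,
                            int off, const NumericMatrix& X, int row,
                            int sub_col, const double* sub_vals) {
  int node = 0;
  while (pred[off + node] < 0) {
    int v = svar[off + node];
    double x = (v == sub_col && sub_vals != nullptr) ? sub_vals[row]
                                                     : X(row, v);
    node = (x <= sval[off + node]) ? left[off + node] : right[off + node];
  }
  return pred[off + node];
}

// [[Rcpp::export]]
IntegerMatrix cpp_forest_votes(IntegerVector offsets, IntegerVector left,
                               IntegerVector right, IntegerVector svar,
                               NumericVector sval, IntegerVector pred,
                               NumericMatrix X) {
  int n = X.nrow();
  int T = offsets.size() - 1;
  IntegerMatrix votes(n, T);
  for (int t = 0; t < T; ++t) {
    int off = offsets[t];
    for (int i = 0; i < n; ++i)
      votes(i, t) = route_row(left, right, svar, sval, pred, off, X, i, -1,
                              nullptr);
  }
  return votes;
}

// [[Rcpp::export]]
IntegerMatrix cpp_vote_counts(IntegerMatrix votes, int L) {
  int n = votes.nrow(), T = votes.ncol();
  IntegerMatrix counts(n, L);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i)
      counts(i, votes(i, t) - 1)++;
  return counts;
}

// For each (tree, row), the set of split variables met on the row's
// baseline path. A permuted column can only change a row's leaf in trees
// where the baseline path crosses that column, so the permutation sweep
// needs to re-route only those (tree, row) pairs. Returned as a list,
// one element per tree: list(vars = 0-based variable ids sorted,
// offsets, rows) in CSR layout (rows 0-based, grouped by variable).
// [[Rcpp::export]]
List cpp_touch_lists(IntegerVector offsets, IntegerVector left,
                     IntegerVector right, IntegerVector svar,
                     NumericVector sval, IntegerVector pred,
                     NumericMatrix X) {
  int n = X.nrow();
  int T = offsets.size() - 1;
  List out(T);
  std::vector<std::vector<std::pair<int, int>>> pairs; // (var,row) per tree
  for (int t = 0; t < T; ++t) {
    int off = offsets[t];
    std::vector<std::pair<int, int>> vr;
    std::vector<int> seen;
    for (int i = 0; i < n; ++i) {
      seen.clear();
      int node = 0;
      while (pred[off + node] < 0) {
        int v = svar[off + node];
        if (std::find(seen.begin(), seen.end(), v) == seen.end())
          seen.push_back(v);
        node = (X(i, v) <= sval[off + node]) ? left[off + node]
                                             : right[off + node];
      }
      for (int v : seen) vr.emplace_back(v, i);
    }
    std::sort(vr.begin(), vr.end());
    int m = vr.size();
    std::vector<int> vars, offs, rows(m);
    for (int k = 0; k < m; ++k) {
      if (k == 0 || vr[k].first != vr[k - 1].first) {
        vars.push_back(vr[k].first);
        offs.push_back(k);
      }
      rows[k] = vr[k].second;
    }
    offs.push_back(m);
    out[t] = List::create(Named("vars") = wrap(vars),
                          Named("offsets") = wrap(offs),
                          Named("rows") = wrap(rows));
  }
  return out;
}

// Misclassification rates after permuting one column, re-routing only the
// (tree, row) pairs whose baseline path crosses it. perms holds one
// 1-based row permutation per repetition (n x K); base_votes /
// base_counts are the unpermuted per-tree votes and per-row class vote
// counts; y is 1-based true classes. touch_rows/touch_offsets give, per
// affected tree, the rows to re-route (CSR slice for this column).
// [[Rcpp::export]]
NumericVector cpp_pfi_gene(IntegerVector offsets, IntegerVector left,
                           IntegerVector right, IntegerVector svar,
                           NumericVector sval, IntegerVector pred,
                           NumericMatrix X, int col, IntegerMatrix perms,
                           IntegerMatrix base_votes,
                           IntegerMatrix base_counts, IntegerVector y,
                           IntegerVector trees, List touch_rows, int L) {
  int n = X.nrow();
  int K = perms.ncol();
  int nt = trees.size();
  NumericVector errors(K);
  std::vector<double> permuted(n);
  std::vector<int> counts(n * L);

  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i)
      permuted[i] = X(perms(i, k) - 1, col);
    // start from baseline counts, swap in the re-routed rows' new votes
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l)
        counts[i * L + l] = base_counts(i, l);
    for (int ti = 0; ti < nt; ++ti) {
      int t = trees[ti];
      int off = offsets[t];
      IntegerVector rows = touch_rows[ti];
      int nr = rows.size();
      for (int r = 0; r < nr; ++r) {
        int i = rows[r];
        int nv = route_row(left, right, svar, sval, pred, off, X, i, col,
                           permuted.data());
        int ov = base_votes(i, t);
        if (nv != ov) {
          counts[i * L + ov - 1]--;
          counts[i * L + nv - 1]++;
        }
      }
    }
    int wrong = 0;
    for (int i = 0; i < n; ++i) {
      int best = 0, bc = counts[i * L];
      for (int l = 1; l < L; ++l)
        if (counts[i * L + l] > bc) { bc = counts[i * L + l]; best = l; }
      if (best + 1 != y[i]) wrong++;
    }
    errors[k] = (double)wrong / n;
  }
  return errors;
}
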