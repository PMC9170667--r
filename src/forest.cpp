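// Bagged regression trees with curvature-test split-predictor selection,
// surrogate splits for missing values, and a categorical feature channel.
// Feature matrix convention: columns are predictors; categorical columns are
// integer-coded 0..k-1 (k <= 20) and flagged via `cat`. NA allowed anywhere.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <map>
#include <cmath>
using namespace Rcpp;

static const double EPS = 1e-12;

struct SurrRule {
  int feat;
  bool is_cat;
  double thr;        // numeric rule: x <= thr
  unsigned int mask; // categorical rule: bit set for levels routed left
  bool flip;         // numeric only: if true, x <= thr routes right
  double agree;      // fraction agreement with primary split
};

struct Node {
  int feat;          // -1 for leaf
  bool is_cat;
  double thr;
  unsigned int mask;
  int left, right;   // node indices, -1 for none
  double pred;       // mean response of node samples
  int n;
  bool larger_left;  // fallback routing for unresolvable missing values
  std::vector<SurrRule> surr;
};

// type-7 quantile of a sorted vector
static double quantile7(const std::vector<double>& v, double p) {
  const int n = (int)v.size();
  if (n == 1) return v[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return v[n - 1];
  return v[lo] + (h - lo) * (v[lo + 1] - v[lo]);
}

// quartile-bin assignment: 4 cells split at the 25/50/75% quantiles;
// duplicate edges collapse cells (merged later as empty rows/cols)
static void quartile_bins(const std::vector<double>& x, std::vector<int>& bin) {
  std::vector<double> s(x);
  std::sort(s.begin(), s.end());
  double e1 = quantile7(s, 0.25), e2 = quantile7(s, 0.50), e3 = quantile7(s, 0.75);
  bin.resize(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    bin[i] = (v <= e1) ? 0 : (v <= e2) ? 1 : (v <= e3) ? 2 : 3;
  }
}

static void level_bins(const std::vector<double>& x, std::vector<int>& bin) {
  std::map<int, int> lev;
  bin.resize(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    int v = (int)std::lround(x[i]);
    auto it = lev.find(v);
    if (it == lev.end()) { int id = (int)lev.size(); lev[v] = id; bin[i] = id; }
    else bin[i] = it->second;
  }
}

// Pearson chi-square independence p-value on the (binned x) x (binned y)
// contingency table; zero rows/columns dropped; df = (r-1)(c-1)
static double chisq_table_p(const std::vector<int>& xb, const std::vector<int>& yb,
                            int nx, int ny) {
  const int n = (int)xb.size();
  std::vector<double> tab(nx * ny, 0.0), rs(nx, 0.0), cs(ny, 0.0);
  for (int i = 0; i < n; ++i) {
    tab[xb[i] * ny + yb[i]] += 1.0;
    rs[xb[i]] += 1.0; cs[yb[i]] += 1.0;
  }
  int r = 0, c = 0;
  for (int i = 0; i < nx; ++i) if (rs[i] > 0) ++r;
  for (int j = 0; j < ny; ++j) if (cs[j] > 0) ++c;
  if (r < 2 || c < 2) return 1.0;
  double stat = 0.0;
  for (int i = 0; i < nx; ++i) {
    if (rs[i] <= 0) continue;
    for (int j = 0; j < ny; ++j) {
      if (cs[j] <= 0) continue;
      double e = rs[i] * cs[j] / n;
      double d = tab[i * ny + j] - e;
      stat += d * d / e;
    }
  }
  int df = (r - 1) * (c - 1);
  return R::pchisq(stat, (double)df, 0, 0);
}

// curvature-test p-value for one predictor against the response; pairs with
// missing x removed first; constant predictor (or < 2 distinct responses,
// or < 4 usable pairs) -> p = 1 so it is never preferred
static double curvature_p(const std::vector<double>& x, const std::vector<double>& y,
                          bool is_cat) {
  const int n = (int)x.size();
  if (n < 4) return 1.0;
  bool xconst = true, yconst = true;
  for (int i = 1; i < n; ++i) {
    if (x[i] != x[0]) xconst = false;
    if (y[i] != y[0]) yconst = false;
  }
  if (xconst || yconst) return 1.0;
  std::vector<int> xb, yb;
  int nx;
  if (is_cat) {
    level_bins(x, xb);
    nx = 1 + *std::max_element(xb.begin(), xb.end());
  } else {
    quartile_bins(x, xb);
    nx = 4;
  }
  quartile_bins(y, yb);
  return chisq_table_p(xb, yb, nx, 4);
}

// [[Rcpp::export(name = ".cb_curvature_p")]]
double cb_curvature_p(NumericVector x, NumericVector y, bool is_cat) {
  std::vector<double> xs, ys;
  for (int i = 0; i < x.size(); ++i) {
    if (NumericVector::is_na(x[i]) || NumericVector::is_na(y[i])) continue;
    xs.push_back(x[i]); ys.push_back(y[i]);
  }
  return curvature_p(xs, ys, is_cat);
}

struct SplitCand {
  bool valid = false;
  bool is_cat = false;
  double thr = 0.0;
  unsigned int mask = 0;
  double gain = -1.0;
};

class Grower {
public:
  const NumericMatrix& X;
  const NumericVector& y;
  const LogicalVector& cat;
  int min_leaf;
  bool use_surr;
  bool curvature;
  std::vector<Node> nodes;

  Grower(const NumericMatrix& X_, const NumericVector& y_, const LogicalVector& cat_,
         int min_leaf_, bool use_surr_, bool curvature_)
    : X(X_), y(y_), cat(cat_), min_leaf(min_leaf_), use_surr(use_surr_),
      curvature(curvature_) {}

  bool obs(int i, int j) const { return !NumericMatrix::is_na(X(i, j)); }

  // best SSE-reduction cut for feature j restricted to idx (missing x skipped);
  // ties broken by the leftmost candidate cut
  SplitCand best_split(int j, const std::vector<int>& idx) const {
    SplitCand out;
    std::vector<std::pair<double, double>> xy;
    xy.reserve(idx.size());
    for (int i : idx) if (obs(i, j)) xy.push_back({X(i, j), y[i]});
    const int n = (int)xy.size();
    if (n < 2 * min_leaf) return out;
    double S = 0.0;
    for (auto& p : xy) S += p.second;
    if (cat[j]) {
      // exhaustive binary level partitions (level of lowest value pinned left)
      std::map<int, std::pair<int, double>> lev; // level -> (count, sum)
      for (auto& p : xy) {
        int v = (int)std::lround(p.first);
        lev[v].first += 1; lev[v].second += p.second;
      }
      const int k = (int)lev.size();
      if (k < 2) return out;
      if (k > 20) stop("categorical predictor with more than 20 levels");
      std::vector<int> lval; std::vector<double> lsum; std::vector<int> lcnt;
      for (auto& kv : lev) { lval.push_back(kv.first); lcnt.push_back(kv.second.first); lsum.push_back(kv.second.second); }
      double base = S * S / n;
      for (unsigned int m = 1; m < (1u << k); m += 2) { // bit0 set: first level left
        if (m == (1u << k) - 1) continue;
        int nl = 0; double sl = 0.0;
        for (int b = 0; b < k; ++b) if (m & (1u << b)) { nl += lcnt[b]; sl += lsum[b]; }
        int nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double sr = S - sl;
        double gain = sl * sl / nl + sr * sr / nr - base;
        if (gain > out.gain + EPS || !out.valid) {
          if (out.valid && gain <= out.gain + EPS) continue;
          out.valid = true; out.is_cat = true; out.gain = gain;
          unsigned int mask = 0;
          for (int b = 0; b < k; ++b)
            if (m & (1u << b)) {
              if (lval[b] < 0 || lval[b] > 31) stop("categorical levels must be coded 0..31");
              mask |= (1u << lval[b]);
            }
          out.mask = mask;
        }
      }
      return out;
    }
    std::sort(xy.begin(), xy.end(),
              [](const std::pair<double,double>& a, const std::pair<double,double>& b) {
                return a.first < b.first;
              });
    double base = S * S / n;
    double sl = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      sl += xy[i].second;
      int nl = i + 1, nr = n - nl;
      if (nl < min_leaf) continue;
      if (nr < min_leaf) break;
      if (xy[i].first == xy[i + 1].first) continue;
      double sr = S - sl;
      double gain = sl * sl / nl + sr * sr / nr - base;
      if (!out.valid || gain > out.gain + EPS) {
        out.valid = true; out.gain = gain;
        out.thr = (xy[i].first + xy[i + 1].first) / 2.0;
      }
    }
    return out;
  }

  bool goes_left_primary(int i, const Node& nd) const {
    double v = X(i, nd.feat);
    if (nd.is_cat) {
      int l = (int)std::lround(v);
      return (nd.mask >> l) & 1u;
    }
    return v <= nd.thr;
  }

  // route observation i through node nd: 0 left, 1 right; primary first,
  // then surrogates in rank order, then the larger child
  int route(int i, const Node& nd) const {
    if (obs(i, nd.feat)) return goes_left_primary(i, nd) ? 0 : 1;
    for (const SurrRule& s : nd.surr) {
      if (!obs(i, s.feat)) continue;
      double v = X(i, s.feat);
      bool left;
      if (s.is_cat) left = (s.mask >> (int)std::lround(v)) & 1u;
      else left = s.flip ? (v > s.thr) : (v <= s.thr);
      return left ? 0 : 1;
    }
    return nd.larger_left ? 0 : 1;
  }

  void fit_surrogates(Node& nd, const std::vector<int>& idx) {
    // labels from samples where the primary predictor is observed
    std::vector<int> used; std::vector<bool> lab; // true = left
    for (int i : idx) if (obs(i, nd.feat)) {
      used.push_back(i); lab.push_back(goes_left_primary(i, nd));
    }
    int nl = 0;
    for (bool b : lab) if (b) ++nl;
    const int nu = (int)used.size();
    const int majority = std::max(nl, nu - nl);
    const int p = X.ncol();
    for (int j = 0; j < p; ++j) {
      if (j == nd.feat) continue;
      std::vector<std::pair<double, bool>> xl;
      for (size_t t = 0; t < used.size(); ++t)
        if (obs(used[t], j)) xl.push_back({X(used[t], j), lab[t]});
      const int m = (int)xl.size();
      if (m < 2) continue;
      SurrRule best; best.feat = j; best.agree = -1.0;
      int bestagree = -1;
      if (cat[j]) {
        std::map<int, std::pair<int, int>> lev; // level -> (nleft, ntot)
        for (auto& pr : xl) {
          auto& e = lev[(int)std::lround(pr.first)];
          if (pr.second) e.first += 1;
          e.second += 1;
        }
        if (lev.size() < 2) continue;
        unsigned int mask = 0; int agree = 0;
        for (auto& kv : lev) {
          int l1 = kv.second.first, tot = kv.second.second;
          if (2 * l1 >= tot) { // level majority goes left (ties left)
            if (kv.first < 0 || kv.first > 31) stop("categorical levels must be coded 0..31");
            mask |= (1u << kv.first);
            agree += l1;
          } else agree += tot - l1;
        }
        bestagree = agree;
        best.is_cat = true; best.mask = mask; best.thr = 0.0; best.flip = false;
      } else {
        std::sort(xl.begin(), xl.end());
        int tot1 = 0;
        for (auto& pr : xl) if (pr.second) ++tot1;
        int c1 = 0; // left-labels among x <= cut
        for (int i2 = 0; i2 < m - 1; ++i2) {
          if (xl[i2].second) ++c1;
          if (xl[i2].first == xl[i2 + 1].first) continue;
          int nle = i2 + 1;
          int agree_plain = c1 + ((m - nle) - (tot1 - c1)); // x<=c -> left
          int agree_flip = m - agree_plain;                  // x<=c -> right
          int a = std::max(agree_plain, agree_flip);
          if (a > bestagree) {
            bestagree = a;
            best.is_cat = false;
            best.thr = (xl[i2].first + xl[i2 + 1].first) / 2.0;
            best.flip = agree_flip > agree_plain;
          }
        }
        if (bestagree < 0) continue;
      }
      // scale agreement to the primary-observed node samples; discard rules
      // that do not beat the larger-child baseline
      if (bestagree > majority && nu > 0) {
        best.agree = (double)bestagree / (double)nu;
        nd.surr.push_back(best);
      }
    }
    std::stable_sort(nd.surr.begin(), nd.surr.end(),
                     [](const SurrRule& a, const SurrRule& b) { return a.agree > b.agree; });
  }

  int grow(const std::vector<int>& idx) {
    Node nd;
    nd.feat = -1; nd.is_cat = false; nd.thr = 0.0; nd.mask = 0;
    nd.left = nd.right = -1; nd.n = (int)idx.size(); nd.larger_left = true;
    double s = 0.0, ymin = R_PosInf, ymax = R_NegInf;
    for (int i : idx) {
      s += y[i];
      if (y[i] < ymin) ymin = y[i];
      if (y[i] > ymax) ymax = y[i];
    }
    nd.pred = s / nd.n;
    const int me = (int)nodes.size();
    nodes.push_back(nd);
    if (nd.n < 2 * min_leaf || ymax - ymin < EPS) return me;

    const int p = X.ncol();
    // rank predictors: curvature test when applicable, else exhaustive gain
    std::vector<int> order;
    bool by_curv = curvature && nd.n >= 4;
    std::vector<SplitCand> cands(p);
    if (by_curv) {
      std::vector<std::pair<double, int>> pr(p);
      for (int j = 0; j < p; ++j) {
        std::vector<double> xs, ys;
        for (int i : idx) if (obs(i, j)) { xs.push_back(X(i, j)); ys.push_back(y[i]); }
        pr[j] = {curvature_p(xs, ys, cat[j]), j};
      }
      std::stable_sort(pr.begin(), pr.end());
      for (auto& q : pr) order.push_back(q.second);
    } else {
      std::vector<std::pair<double, int>> gr;
      for (int j = 0; j < p; ++j) {
        cands[j] = best_split(j, idx);
        if (cands[j].valid) gr.push_back({-cands[j].gain, j});
      }
      std::stable_sort(gr.begin(), gr.end());
      for (auto& q : gr) order.push_back(q.second);
    }

    int chosen = -1;
    SplitCand sc;
    for (int j : order) {
      SplitCand c = by_curv ? best_split(j, idx) : cands[j];
      if (c.valid) { chosen = j; sc = c; break; }
    }
    if (chosen < 0) return me;

    nodes[me].feat = chosen;
    nodes[me].is_cat = sc.is_cat;
    nodes[me].thr = sc.thr;
    nodes[me].mask = sc.mask;

    if (use_surr) fit_surrogates(nodes[me], idx);

    // split: observed by primary rule, missing by surrogates / larger child
    std::vector<int> li, ri, miss;
    for (int i : idx) {
      if (obs(i, chosen)) {
        if (goes_left_primary(i, nodes[me])) li.push_back(i); else ri.push_back(i);
      } else miss.push_back(i);
    }
    nodes[me].larger_left = (int)li.size() >= (int)ri.size();
    for (int i : miss) {
      if (route(i, nodes[me]) == 0) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) { // degenerate (all-missing edge); make leaf
      nodes[me].feat = -1; nodes[me].surr.clear();
      return me;
    }
    int l = grow(li);
    int r = grow(ri);
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  List as_list() const {
    const int m = (int)nodes.size();
    IntegerVector feat(m), left(m), right(m), n(m);
    NumericVector thr(m), pred(m), mask(m);
    LogicalVector iscat(m), larger_left(m);
    int nsur = 0;
    for (const Node& nd : nodes) nsur += (int)nd.surr.size();
    IntegerMatrix surr(nsur, 3);      // node, feat, flip(or 0)
    NumericMatrix surrv(nsur, 3);     // thr, mask, agree
    LogicalVector surrcat(nsur);
    int t = 0;
    for (int i = 0; i < m; ++i) {
      const Node& nd = nodes[i];
      feat[i] = nd.feat; left[i] = nd.left; right[i] = nd.right;
      thr[i] = nd.thr; mask[i] = (double)nd.mask; pred[i] = nd.pred; n[i] = nd.n;
      iscat[i] = nd.is_cat; larger_left[i] = nd.larger_left;
      for (const SurrRule& s : nd.surr) {
        surr(t, 0) = i; surr(t, 1) = s.feat; surr(t, 2) = s.flip ? 1 : 0;
        surrv(t, 0) = s.thr; surrv(t, 1) = (double)s.mask; surrv(t, 2) = s.agree;
        surrcat[t] = s.is_cat;
        ++t;
      }
    }
    return List::create(_["feat"] = feat, _["is_cat"] = iscat, _["thr"] = thr,
                        _["mask"] = mask, _["left"] = left, _["right"] = right,
                        _["pred"] = pred, _["n"] = n, _["larger_left"] = larger_left,
                        _["surr"] = surr, _["surr_val"] = surrv, _["surr_cat"] = surrcat);
  }
};

static void tree_from_list(const List& tr, std::vector<Node>& nodes) {
  IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"], n = tr["n"];
  NumericVector thr = tr["thr"], mask = tr["mask"], pred = tr["pred"];
  LogicalVector iscat = tr["is_cat"], larger_left = tr["larger_left"];
  IntegerMatrix surr = tr["surr"];
  NumericMatrix surrv = tr["surr_val"];
  LogicalVector surrcat = tr["surr_cat"];
  const int m = feat.size();
  nodes.assign(m, Node());
  for (int i = 0; i < m; ++i) {
    nodes[i].feat = feat[i]; nodes[i].is_cat = iscat[i]; nodes[i].thr = thr[i];
    nodes[i].mask = (unsigned int)mask[i]; nodes[i].left = left[i];
    nodes[i].right = right[i]; nodes[i].pred = pred[i]; nodes[i].n = n[i];
    nodes[i].larger_left = larger_left[i];
  }
  for (int t = 0; t < surr.nrow(); ++t) {
    SurrRule s;
    s.feat = surr(t, 1); s.flip = surr(t, 2) == 1; s.is_cat = surrcat[t];
    s.thr = surrv(t, 0); s.mask = (unsigned int)surrv(t, 1); s.agree = surrv(t, 2);
    nodes[surr(t, 0)].surr.push_back(s);
  }
}

static double predict_row(const std::vector<Node>& nodes, const NumericMatrix& X, int i) {
  int cur = 0;
  while (nodes[cur].feat >= 0) {
    const Node& nd = nodes[cur];
    int side;
    if (!NumericMatrix::is_na(X(i, nd.feat))) {
      double v = X(i, nd.feat);
      bool left = nd.is_cat ? (((nd.mask >> (int)std::lround(v)) & 1u) != 0) : (v <= nd.thr);
      side = left ? 0 : 1;
    } else {
      side = 1; bool done = false;
      for (const SurrRule& s : nd.surr) {
        if (NumericMatrix::is_na(X(i, s.feat))) continue;
        double v = X(i, s.feat);
        bool left;
        if (s.is_cat) left = ((s.mask >> (int)std::lround(v)) & 1u) != 0;
        else left = s.flip ? (v > s.thr) : (v <= s.thr);
        side = left ? 0 : 1; done = true; break;
      }
      if (!done) side = nd.larger_left ? 0 : 1;
    }
    cur = (side == 0) ? nd.left : nd.right;
  }
  return nodes[cur].pred;
}

// [[Rcpp::export(name = ".cb_grow_tree")]]
List cb_grow_tree(NumericMatrix X, NumericVector y, LogicalVector cat,
                  IntegerVector idx, int min_leaf, bool surrogate, bool curvature) {
  if (X.nrow() != y.size()) stop("feature/response length mismatch");
  if (idx.size() < 1) stop("empty training index set");
  Grower g(X, y, cat, min_leaf, surrogate, curvature);
  std::vector<int> id(idx.begin(), idx.end());
  for (int& v : id) {
    v -= 1;
    if (v < 0 || v >= X.nrow()) stop("training index out of range");
  }
  g.grow(id);
  return g.as_list();
}

// [[Rcpp::export(name = ".cb_fit_forest")]]
List cb_fit_forest(NumericMatrix X, NumericVector y, LogicalVector cat,
                   IntegerMatrix boot, int min_leaf, bool surrogate, bool curvature) {
  const int T = boot.ncol();
  List trees(T);
  for (int t = 0; t < T; ++t) {
    Grower g(X, y, cat, min_leaf, surrogate, curvature);
    std::vector<int> id(boot.nrow());
    for (int i = 0; i < boot.nrow(); ++i) {
      id[i] = boot(i, t) - 1;
      if (id[i] < 0 || id[i] >= X.nrow()) stop("bootstrap index out of range");
    }
    g.grow(id);
    trees[t] = g.as_list();
  }
  return trees;
}

// [[Rcpp::export(name = ".cb_predict_trees")]]
NumericMatrix cb_predict_trees(List trees, NumericMatrix X) {
  const int T = trees.size(), n = X.nrow();
  NumericMatrix out(n, T);
  std::vector<Node> nodes;
  for (int t = 0; t < T; ++t) {
    tree_from_list(trees[t], nodes);
    for (int i = 0; i < n; ++i) out(i, t) = predict_row(nodes, X, i);
  }
  return out;
}
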