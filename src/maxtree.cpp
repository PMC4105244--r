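#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
#include <cmath>
using namespace Rcpp;

// Max-tree attribute filtering on quantised grey-level images, plus
// 8-connected component labelling and small path utilities.
//
// The max-tree is built with the union-find method on pixels sorted by
// decreasing grey level (Berger-style). Node attributes (second-order
// moments) are accumulated bottom-up over canonical nodes.
// Filtering uses the direct rule: a node failing the criterion takes the
// value of its nearest surviving ancestor; for increasing criteria this
// coincides with the standard attribute opening.

namespace {

inline int uf_find(std::vector<int>& par, int x) {
  int r = x;
  while (par[r] != r) r = par[r];
  while (par[x] != r) { int n = par[x]; par[x] = r; x = n; }
  return r;
}

} // namespace

// attr codes: 1 = moment-ellipse minor axis ("width"),
//             2 = moment-ellipse major axis ("length"),
//             3 = elongation (major/minor axis ratio of the moment ellipse).
// keep rule:  attr 1,2 -> keep node if attr >= thresh (opening);
//             attr 3   -> keep node if attr <= thresh (thinning).
// [[Rcpp::export(name = ".maxtree_filter")]]
IntegerMatrix maxtree_filter_cpp(IntegerMatrix img, int attr_code, double thresh) {
  const int H = img.nrow(), W = img.ncol(), N = H * W;
  if (attr_code < 1 || attr_code > 3) stop("unknown attribute code");

  int maxlev = 0;
  for (int i = 0; i < N; ++i) {
    if (img[i] < 0) stop("negative grey level");
    if (img[i] > maxlev) maxlev = img[i];
  }

  // counting sort, highest level first; within a level, raster order
  std::vector<int> order(N);
  {
    std::vector<int> start(maxlev + 2, 0), cnt(maxlev + 1, 0);
    for (int i = 0; i < N; ++i) cnt[img[i]]++;
    int acc = 0;
    for (int l = maxlev; l >= 0; --l) { start[l] = acc; acc += cnt[l]; }
    for (int i = 0; i < N; ++i) order[start[img[i]]++] = i;
  }

  std::vector<int> parent(N), zpar(N);
  std::vector<char> seen(N, 0);
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int k = 0; k < N; ++k) {
    const int p = order[k];
    const int r = p % H, c = p / H;
    parent[p] = p; zpar[p] = p; seen[p] = 1;
    for (int j = 0; j < 8; ++j) {
      const int rr = r + dr[j], cc = c + dc[j];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      const int q = rr + cc * H;
      if (!seen[q]) continue;
      const int rootq = uf_find(zpar, q);
      if (rootq != p) { parent[rootq] = p; zpar[rootq] = p; }
    }
  }

  // canonicalise root-first: every pixel's parent then points to the
  // canonical (first-processed) pixel of its own node or of the parent node
  for (int k = N - 1; k >= 0; --k) {
    const int p = order[k];
    const int q = parent[p];
    if (img[parent[q]] == img[q]) parent[p] = parent[q];
  }

  std::vector<char> canonical(N);
  for (int p = 0; p < N; ++p)
    canonical[p] = (parent[p] == p) || (img[parent[p]] != img[p]);

  // per-node accumulators over canonical pixels
  std::vector<double> nn(N, 0), nsr(N, 0), nsc(N, 0), nsrr(N, 0), nscc(N, 0), nsrc(N, 0);
  for (int p = 0; p < N; ++p) {
    const int can = canonical[p] ? p : parent[p];
    const int r = p % H, c = p / H;
    nn[can] += 1; nsr[can] += r; nsc[can] += c;
    nsrr[can] += (double)r * r; nscc[can] += (double)c * c; nsrc[can] += (double)r * c;
  }
  // push child subtree totals into parents; decreasing level = children first
  for (int k = 0; k < N; ++k) {
    const int p = order[k];
    if (!canonical[p]) continue;
    const int q = parent[p];
    if (q == p) continue;
    nn[q] += nn[p]; nsr[q] += nsr[p]; nsc[q] += nsc[p];
    nsrr[q] += nsrr[p]; nscc[q] += nscc[p]; nsrc[q] += nsrc[p];
  }

  // resolve output levels root-first (increasing level order)
  std::vector<int> out(N);
  for (int k = N - 1; k >= 0; --k) {
    const int p = order[k];
    if (!canonical[p]) continue;
    // rotation-invariant size attributes from the node's moment ellipse:
    // width = minor axis, length = major axis, elongation = axis ratio
    const double n = nn[p];
    const double mr = nsr[p] / n, mc = nsc[p] / n;
    const double vrr = nsrr[p] / n - mr * mr + 1.0 / 12.0;
    const double vcc = nscc[p] / n - mc * mc + 1.0 / 12.0;
    const double vrc = nsrc[p] / n - mr * mc;
    const double tr = vrr + vcc, det = vrr * vcc - vrc * vrc;
    double disc = tr * tr / 4.0 - det;
    if (disc < 0) disc = 0;
    const double l1 = tr / 2.0 + std::sqrt(disc);
    const double l2 = std::max(tr / 2.0 - std::sqrt(disc), 0.0);
    double a;
    if (attr_code == 1) a = 4.0 * std::sqrt(l2);
    else if (attr_code == 2) a = 4.0 * std::sqrt(l1);
    else a = (l2 <= 1e-12) ? R_PosInf : std::sqrt(l1 / l2);
    const bool keep = (parent[p] == p) ||
      (attr_code == 3 ? (a <= thresh) : (a >= thresh));
    out[p] = keep ? img[p] : out[parent[p]];
  }

  IntegerMatrix res(H, W);
  for (int p = 0; p < N; ++p) res[p] = canonical[p] ? out[p] : out[parent[p]];
  return res;
}

// 8-connected labelling of a logical mask. Components are numbered in the
// column-major order of their first pixel, so the result is deterministic.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol(), N = H * W;
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int p = 0; p < N; ++p) {
    if (!mask[p] || lab[p]) continue;
    lab[p] = ++next;
    stack.push_back(p);
    while (!stack.empty()) {
      const int q = stack.back(); stack.pop_back();
      const int r = q % H, c = q / H;
      for (int j = 0; j < 8; ++j) {
        const int rr = r + dr[j], cc = c + dc[j];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        const int u = rr + cc * H;
        if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  return lab;
}

// Assign orphan foreground pixels (mask true, label 0) to a neighbouring
// label by iterative 8-neighbour dilation inside the mask; ties resolve to
// the smallest label. Guarantees splitting conserves the mask exactly.
// [[Rcpp::export(name = ".fill_orphans")]]
IntegerMatrix fill_orphans_cpp(IntegerMatrix lab, LogicalMatrix mask) {
  const int H = lab.nrow(), W = lab.ncol(), N = H * W;
  IntegerMatrix cur(clone(lab));
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::vector<int> orphans;
  for (int p = 0; p < N; ++p) if (mask[p] && cur[p] == 0) orphans.push_back(p);
  while (!orphans.empty()) {
    std::vector<int> remaining;
    std::vector<std::pair<int, int> > assign;
    for (size_t i = 0; i < orphans.size(); ++i) {
      const int p = orphans[i];
      const int r = p % H, c = p / H;
      int best = 0;
      for (int j = 0; j < 8; ++j) {
        const int rr = r + dr[j], cc = c + dc[j];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        const int u = rr + cc * H;
        if (cur[u] > 0 && (best == 0 || cur[u] < best)) best = cur[u];
      }
      if (best > 0) assign.push_back(std::make_pair(p, best));
      else remaining.push_back(p);
    }
    if (assign.empty()) break;  // isolated orphans: leave unlabelled
    for (size_t i = 0; i < assign.size(); ++i) cur[assign[i].first] = assign[i].second;
    orphans.swap(remaining);
  }
  return cur;
}

// Minimum-cost left-to-right path with lateral steps in {-1, 0, +1}.
// cost: H x W matrix, NA/Inf = forbidden. Returns the 1-based row index of
// the path in each column, 0 where no admissible pixel exists. Ties break
// toward the smaller row index, deterministically.
// [[Rcpp::export(name = ".min_cost_path")]]
IntegerVector min_cost_path_cpp(NumericMatrix cost) {
  const int H = cost.nrow(), W = cost.ncol();
  const double INF = R_PosInf;
  NumericMatrix acc(H, W);
  IntegerMatrix back(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double x = cost(r, c);
      if (NumericMatrix::is_na(x)) x = INF;
      if (c == 0) { acc(r, c) = x; back(r, c) = -1; continue; }
      double best = INF; int barg = -1;
      for (int d = -1; d <= 1; ++d) {
        const int rr = r + d;
        if (rr < 0 || rr >= H) continue;
        if (acc(rr, c - 1) < best) { best = acc(rr, c - 1); barg = rr; }
      }
      // a fresh path may start wherever the previous column is inadmissible
      if (x == INF) { acc(r, c) = INF; back(r, c) = barg; continue; }
      acc(r, c) = (best == INF) ? x : best + x;
      back(r, c) = (best == INF) ? -1 : barg;
    }
  IntegerVector path(W);
  int cend = W - 1;
  while (cend >= 0) {
    bool any = false;
    for (int r = 0; r < H; ++r) if (acc(r, cend) < INF) { any = true; break; }
    if (any) break;
    --cend;
  }
  if (cend < 0) return path;
  int r = 0; double best = INF;
  for (int rr = 0; rr < H; ++rr) if (acc(rr, cend) < best) { best = acc(rr, cend); r = rr; }
  for (int c = cend; c >= 0; --c) {
    path[c] = r + 1;
    if (back(r, c) >= 0) r = back(r, c);
    else if (c > 0) {
      double b2 = INF; int r2 = r;
      for (int rr = 0; rr < H; ++rr) if (acc(rr, c - 1) < b2) { b2 = acc(rr, c - 1); r2 = rr; }
      r = r2;
    }
  }
  return path;
}
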