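#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

// Disjoint-set forest with path halving.
static int ds_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void ds_union(std::vector<int>& parent, int a, int b) {
  a = ds_find(parent, a);
  b = ds_find(parent, b);
  if (a != b) parent[std::max(a, b)] = std::min(a, b);
}

//' Connected-component labeling of a binary mask.
//'
//' Two-pass union-find labeling. `connectivity` is 4 (edge neighbours) or
//' 8 (edge + diagonal neighbours). Labels are assigned in raster order
//' starting at 1; background is 0.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0);  // background sentinel

  // first pass: provisional labels, merging with up / left (+ diagonals)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int neigh[4][2] = {{r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}};
      const int nneigh = (connectivity == 4) ? 2 : 4;
      for (int k = 0; k < nneigh; ++k) {
        int rr = neigh[k][0], cc = neigh[k][1];
        if (rr < 0 || cc < 0 || rr >= nr) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else ds_union(parent, best, l);
          if (l < best) best = l;
        }
      }
      if (best == 0) {
        best = (int)parent.size();
        parent.push_back(best);
      }
      lab(r, c) = best;
    }
  }

  // second pass: flatten and renumber consecutively
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (size_t i = 1; i < parent.size(); ++i) {
    int root = ds_find(parent, (int)i);
    if (remap[root] == 0) remap[root] = ++next;
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = remap[ds_find(parent, lab(r, c))];

  lab.attr("n_labels") = next;
  return lab;
}

//' Scanline rasterization of polygons (even-odd rule, pixel-centre test).
//'
//' Polygons are closed rings given as n x 2 matrices of (x, y) coordinates
//' in micrometres. Pixel (r, c) (1-based) has its centre at
//' (origin_x + (c - 0.5) * pixel_size, origin_y + (r - 0.5) * pixel_size).
//' Returns an integer label matrix; attribute `n_overlap` counts pixels
//' claimed by more than one polygon (later polygons win).
// [[Rcpp::export(name = ".rasterize_polygons")]]
IntegerMatrix rasterize_polygons(List polys, int nrow, int ncol,
                                 double pixel_size, double origin_x,
                                 double origin_y) {
  IntegerMatrix lab(nrow, ncol);
  long long n_overlap = 0;
  for (int p = 0; p < polys.size(); ++p) {
    NumericMatrix poly = polys[p];
    const int nv = poly.nrow();
    if (nv < 3) continue;
    double ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < nv; ++i) {
      ymin = std::min(ymin, poly(i, 1));
      ymax = std::max(ymax, poly(i, 1));
    }
    int r_lo = std::max(1, (int)std::ceil((ymin - origin_y) / pixel_size + 0.5));
    int r_hi = std::min(nrow, (int)std::floor((ymax - origin_y) / pixel_size + 0.5));
    std::vector<double> xs;
    for (int r = r_lo; r <= r_hi; ++r) {
      double y = origin_y + (r - 0.5) * pixel_size;
      xs.clear();
      for (int i = 0; i < nv; ++i) {
        int j = (i + 1) % nv;
        double y1 = poly(i, 1), y2 = poly(j, 1);
        if ((y1 <= y && y < y2) || (y2 <= y && y < y1)) {
          double x1 = poly(i, 0), x2 = poly(j, 0);
          xs.push_back(x1 + (y - y1) * (x2 - x1) / (y2 - y1));
        }
      }
      std::sort(xs.begin(), xs.end());
      for (size_t k = 0; k + 1 < xs.size(); k += 2) {
        int c_lo = (int)std::ceil((xs[k] - origin_x) / pixel_size + 0.5);
        int c_hi = (int)std::ceil((xs[k + 1] - origin_x) / pixel_size + 0.5) - 1;
        c_lo = std::max(1, c_lo);
        c_hi = std::min(ncol, c_hi);
        for (int c = c_lo; c <= c_hi; ++c) {
          if (lab(r - 1, c - 1) != 0) ++n_overlap;
          lab(r - 1, c - 1) = p + 1;
        }
      }
    }
  }
  lab.attr("n_overlap") = (double)n_overlap;
  return lab;
}

// One directed boundary edge between pixel corners.
struct BEdge {
  int x0, y0, x1, y1;
  bool used;
};

//' Outer boundary polygons of labelled components.
//'
//' For each label 1..n_labels, traces the outer contour along pixel edges.
//' Corner coordinates are 0-based: pixel (r, c) (1-based) spans
//' x in [c-1, c], y in [r-1, r]. Returns a list of k x 2 matrices (x, y),
//' closed implicitly (last vertex connects to first). The outer ring is the
//' traced loop with the largest absolute signed area.
// [[Rcpp::export(name = ".trace_boundaries")]]
List trace_boundaries(IntegerMatrix lab, int n_labels) {
  const int nr = lab.nrow(), nc = lab.ncol();
  // collect pixels per label
  std::vector<std::vector<std::pair<int, int> > > px(n_labels + 1);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l > 0 && l <= n_labels) px[l].push_back(std::make_pair(r, c));
    }

  List out(n_labels);
  for (int l = 1; l <= n_labels; ++l) {
    std::vector<BEdge> edges;
    for (size_t i = 0; i < px[l].size(); ++i) {
      int r = px[l][i].first, c = px[l][i].second;
      bool up = (r > 0) && lab(r - 1, c) == l;
      bool dn = (r + 1 < nr) && lab(r + 1, c) == l;
      bool lf = (c > 0) && lab(r, c - 1) == l;
      bool rt = (c + 1 < nc) && lab(r, c + 1) == l;
      // clockwise (screen coords, y down) traversal of the pixel square
      if (!up) { BEdge e = {c, r, c + 1, r, false}; edges.push_back(e); }
      if (!rt) { BEdge e = {c + 1, r, c + 1, r + 1, false}; edges.push_back(e); }
      if (!dn) { BEdge e = {c + 1, r + 1, c, r + 1, false}; edges.push_back(e); }
      if (!lf) { BEdge e = {c, r + 1, c, r, false}; edges.push_back(e); }
    }
    // index edges by start corner
    std::multimap<long long, int> by_start;
    const long long W1 = nc + 1;
    for (size_t i = 0; i < edges.size(); ++i)
      by_start.insert(std::make_pair((long long)edges[i].y0 * W1 + edges[i].x0, (int)i));

    double best_area = -1.0;
    std::vector<std::pair<int, int> > best_loop;
    for (size_t s = 0; s < edges.size(); ++s) {
      if (edges[s].used) continue;
      std::vector<std::pair<int, int> > loop;
      int cur = (int)s;
      int guard = (int)edges.size() + 4;
      while (!edges[cur].used && guard-- > 0) {
        edges[cur].used = true;
        loop.push_back(std::make_pair(edges[cur].x0, edges[cur].y0));
        long long key = (long long)edges[cur].y1 * W1 + edges[cur].x1;
        int dx = edges[cur].x1 - edges[cur].x0;
        int dy = edges[cur].y1 - edges[cur].y0;
        // candidate continuations; at saddle corners prefer the sharpest
        // right turn (keeps the loop tight around the component)
        int next = -1, best_turn = -3;
        std::pair<std::multimap<long long, int>::iterator,
                  std::multimap<long long, int>::iterator> rng =
            by_start.equal_range(key);
        for (std::multimap<long long, int>::iterator it = rng.first;
             it != rng.second; ++it) {
          int cand = it->second;
          if (edges[cand].used) continue;
          int cdx = edges[cand].x1 - edges[cand].x0;
          int cdy = edges[cand].y1 - edges[cand].y0;
          // cross product in screen coords: >0 = right turn (y down)
          int cross = dx * cdy - dy * cdx;
          int turn = (cross > 0) ? 1 : (cross < 0 ? -1 : 0);
          if (turn > best_turn) { best_turn = turn; next = cand; }
        }
        if (next < 0) break;
        cur = next;
      }
      // signed shoelace area of the loop (corner coords)
      double a = 0.0;
      for (size_t i = 0; i < loop.size(); ++i) {
        size_t j = (i + 1) % loop.size();
        a += (double)loop[i].first * loop[j].second -
             (double)loop[j].first * loop[i].second;
      }
      a = std::fabs(a / 2.0);
      if (a > best_area) { best_area = a; best_loop = loop; }
    }
    NumericMatrix m(best_loop.size(), 2);
    for (size_t i = 0; i < best_loop.size(); ++i) {
      m(i, 0) = best_loop[i].first;
      m(i, 1) = best_loop[i].second;
    }
    out[l - 1] = m;
  }
  return out;
}

//' Per-label pixel counts, centroid sums and bounding boxes.
//'
//' Returns a matrix with one row per label: count, sum_r, sum_c,
//' rmin, rmax, cmin, cmax (1-based pixel indices).
// [[Rcpp::export(name = ".label_stats")]]
NumericMatrix label_stats(IntegerMatrix lab, int n_labels) {
  NumericMatrix out(n_labels, 7);
  for (int l = 0; l < n_labels; ++l) {
    out(l, 3) = R_PosInf; out(l, 4) = R_NegInf;
    out(l, 5) = R_PosInf; out(l, 6) = R_NegInf;
  }
  const int nr = lab.nrow(), nc = lab.ncol();
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l <= 0 || l > n_labels) continue;
      --l;
      out(l, 0) += 1;
      out(l, 1) += r + 1;
      out(l, 2) += c + 1;
      if (r + 1 < out(l, 3)) out(l, 3) = r + 1;
      if (r + 1 > out(l, 4)) out(l, 4) = r + 1;
      if (c + 1 < out(l, 5)) out(l, 5) = c + 1;
      if (c + 1 > out(l, 6)) out(l, 6) = c + 1;
    }
  return out;
}

//' Separable convolution with a symmetric 1-D kernel, replicate borders.
//'
//' Applies the kernel along rows then columns. Used for Gaussian
//' smoothing; direct evaluation beats FFT at these kernel sizes.
// [[Rcpp::export(name = ".sep_conv2")]]
NumericMatrix sep_conv2(NumericMatrix m, NumericVector kernel) {
  const int nr = m.nrow(), nc = m.ncol();
  const int kl = kernel.size();
  const int r = kl / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* src = REAL(m);
  double* t = REAL(tmp);
  double* o = REAL(out);
  // along columns (x direction): accumulate whole columns so memory access
  // stays sequential (column-major storage)
  for (int c = 0; c < nc; ++c) {
    double* tcol = t + (size_t)c * nr;
    for (int k = -r; k <= r; ++k) {
      int cc = c + k;
      if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
      const double w = kernel[k + r];
      const double* mcol = src + (size_t)cc * nr;
      if (k == -r) for (int i = 0; i < nr; ++i) tcol[i] = w * mcol[i];
      else for (int i = 0; i < nr; ++i) tcol[i] += w * mcol[i];
    }
  }
  // along rows (y direction): within-column windows are contiguous
  for (int c = 0; c < nc; ++c) {
    const double* tcol = t + (size_t)c * nr;
    double* ocol = o + (size_t)c * nr;
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      if (i >= r && i + r < nr) {
        const double* w0 = tcol + i - r;
        for (int k = 0; k < kl; ++k) acc += kernel[k] * w0[k];
      } else {
        for (int k = -r; k <= r; ++k) {
          int rr = i + k;
          if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
          acc += kernel[k + r] * tcol[rr];
        }
      }
      ocol[i] = acc;
    }
  }
  return out;
}

//' 2-D convolution with a small kernel, replicate borders.
// [[Rcpp::export(name = ".conv2_small")]]
NumericMatrix conv2_small(NumericMatrix m, NumericMatrix kern) {
  const int nr = m.nrow(), nc = m.ncol();
  const int kr = kern.nrow() / 2, kc = kern.ncol() / 2;
  NumericMatrix out(nr, nc);
  const double* src = REAL(m);
  double* o = REAL(out);
  for (int c = 0; c < nc; ++c) {
    double* ocol = o + (size_t)c * nr;
    const bool c_inner = (c >= kc && c + kc < nc);
    for (int i = 0; i < nr; ++i) {
      double acc = 0;
      if (c_inner && i >= kr && i + kr < nr) {
        for (int b = -kc; b <= kc; ++b) {
          const double* mcol = src + (size_t)(c + b) * nr + i;
          for (int a = -kr; a <= kr; ++a)
            acc += kern(a + kr, b + kc) * mcol[a];
        }
      } else {
        for (int b = -kc; b <= kc; ++b) {
          int cc = c + b;
          if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
          const double* mcol = src + (size_t)cc * nr;
          for (int a = -kr; a <= kr; ++a) {
            int rr = i + a;
            if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
            acc += kern(a + kr, b + kc) * mcol[rr];
          }
        }
      }
      ocol[i] = acc;
    }
  }
  return out;
}

//' Evaluate a compiled probability forest on a feature matrix.
//'
//' `left`, `right`, `varid` (0-based feature column), `splitval` and the
//' per-node probability of the target class are flat per-tree vectors.
//' Traversal: descend left when x[var] <= splitval. Returns the mean
//' target-class probability over trees for each row of X.
// [[Rcpp::export(name = ".forest_prob")]]
NumericVector forest_prob(List left, List right, List varid, List splitval,
                          List nodeprob, NumericMatrix X) {
  const int n = X.nrow();
  const int ntree = left.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    IntegerVector L = left[t], R = right[t], V = varid[t];
    NumericVector S = splitval[t], P = nodeprob[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (L[node] != 0 || R[node] != 0) {
        node = (X(i, V[node]) <= S[node]) ? L[node] : R[node];
      }
      out[i] += P[node];
    }
  }
  return out / (double)ntree;
}
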