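// 3D Delaunay tetrahedralization, incremental Bowyer-Watson.
// Circumsphere predicates evaluated in long double via cached circumcenters;
// callers are expected to pre-jitter exactly degenerate inputs (see R side).
#include <Rcpp.h>
#include <array>
#include <map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

typedef long double ld;

struct Tet {
  std::array<int, 4> v;
  std::array<ld, 3> cc;  // circumcenter
  ld r2;                 // squared circumradius
  bool alive;
};

// Circumcenter of four points; returns false when (near-)degenerate, in
// which case the circumsphere is treated as unbounded.
bool circumsphere(const std::vector<std::array<ld, 3> > &P, const std::array<int, 4> &v,
                  std::array<ld, 3> &cc, ld &r2) {
  const std::array<ld, 3> &a = P[v[0]];
  ld A[3][3], b[3];
  for (int i = 0; i < 3; ++i) {
    const std::array<ld, 3> &p = P[v[i + 1]];
    b[i] = 0;
    for (int j = 0; j < 3; ++j) {
      A[i][j] = 2 * (p[j] - a[j]);
      b[i] += p[j] * p[j] - a[j] * a[j];
    }
  }
  ld det = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
         - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
         + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  ld scale = 0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) scale = std::max(scale, (ld)std::fabs((double)A[i][j]));
  if (std::fabs((double)det) <= 1e-30 * scale * scale * scale) return false;
  // Cramer's rule
  ld x[3];
  for (int k = 0; k < 3; ++k) {
    ld M[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) M[i][j] = (j == k) ? b[i] : A[i][j];
    ld dk = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1])
          - M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0])
          + M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
    x[k] = dk / det;
  }
  r2 = 0;
  for (int j = 0; j < 3; ++j) {
    cc[j] = x[j];
    ld d = x[j] - a[j];
    r2 += d * d;
  }
  return true;
}

inline ld dist2(const std::array<ld, 3> &p, const std::array<ld, 3> &q) {
  ld s = 0;
  for (int j = 0; j < 3; ++j) { ld d = p[j] - q[j]; s += d * d; }
  return s;
}

}  // namespace

// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<std::array<ld, 3> > P(n + 4);
  ld lo[3], hi[3];
  for (int j = 0; j < 3; ++j) { lo[j] = pts(0, j); hi[j] = pts(0, j); }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      P[i][j] = pts(i, j);
      lo[j] = std::min(lo[j], P[i][j]);
      hi[j] = std::max(hi[j], P[i][j]);
    }
  ld ext = 0, c[3];
  for (int j = 0; j < 3; ++j) {
    ext = std::max(ext, hi[j] - lo[j]);
    c[j] = (hi[j] + lo[j]) / 2;
  }
  if (ext <= 0) stop("degenerate point set: zero extent");
  const ld R = 1e5L * ext;
  // regular super-tetrahedron around the centroid
  const ld sv[4][3] = { {0, 0, 3}, {2.828427L, 0, -1}, {-1.414214L, 2.449490L, -1},
                        {-1.414214L, -2.449490L, -1} };
  for (int k = 0; k < 4; ++k)
    for (int j = 0; j < 3; ++j) P[n + k][j] = c[j] + R * sv[k][j];

  std::vector<Tet> tets;
  {
    Tet t0;
    t0.v = { n, n + 1, n + 2, n + 3 };
    t0.alive = circumsphere(P, t0.v, t0.cc, t0.r2);
    if (!t0.alive) stop("internal error: super tetrahedron degenerate");
    t0.alive = true;
    tets.push_back(t0);
  }

  std::vector<int> bad;
  typedef std::array<int, 3> Face;
  for (int i = 0; i < n; ++i) {
    bad.clear();
    for (size_t t = 0; t < tets.size(); ++t) {
      if (!tets[t].alive) continue;
      if (dist2(P[i], tets[t].cc) < tets[t].r2) bad.push_back((int)t);
    }
    if (bad.empty()) {
      // numerical fallback: nearest circumsphere by signed margin
      ld best = 0; int bidx = -1;
      for (size_t t = 0; t < tets.size(); ++t) {
        if (!tets[t].alive) continue;
        ld m = dist2(P[i], tets[t].cc) - tets[t].r2;
        if (bidx < 0 || m < best) { best = m; bidx = (int)t; }
      }
      if (bidx < 0) stop("internal error: no live tetrahedra");
      bad.push_back(bidx);
    }
    std::map<Face, int> faceCount;
    for (size_t bi = 0; bi < bad.size(); ++bi) {
      Tet &t = tets[bad[bi]];
      t.alive = false;
      static const int fidx[4][3] = { {0,1,2}, {0,1,3}, {0,2,3}, {1,2,3} };
      for (int f = 0; f < 4; ++f) {
        Face fa = { t.v[fidx[f][0]], t.v[fidx[f][1]], t.v[fidx[f][2]] };
        if (fa[0] > fa[1]) std::swap(fa[0], fa[1]);
        if (fa[1] > fa[2]) std::swap(fa[1], fa[2]);
        if (fa[0] > fa[1]) std::swap(fa[0], fa[1]);
        faceCount[fa]++;
      }
    }
    for (std::map<Face, int>::const_iterator it = faceCount.begin();
         it != faceCount.end(); ++it) {
      if (it->second != 1) continue;  // interior face of the cavity
      Tet nt;
      nt.v = { it->first[0], it->first[1], it->first[2], i };
      if (!circumsphere(P, nt.v, nt.cc, nt.r2)) {
        // flat cavity face + new point: treat circumsphere as unbounded so
        // the sliver is consumed by the next insertion touching it
        nt.cc = P[i];
        nt.r2 = 4 * R * R * 1e6L;
      }
      nt.alive = true;
      tets.push_back(nt);
    }
    // periodic compaction keeps the scan-all insertion loop affordable
    if (tets.size() > 4096 && i % 64 == 0) {
      std::vector<Tet> keep;
      keep.reserve(tets.size());
      for (size_t t = 0; t < tets.size(); ++t)
        if (tets[t].alive) keep.push_back(tets[t]);
      tets.swap(keep);
    }
  }

  std::vector<std::array<int, 4> > out;
  for (size_t t = 0; t < tets.size(); ++t) {
    if (!tets[t].alive) continue;
    bool real = true;
    for (int k = 0; k < 4; ++k) if (tets[t].v[k] >= n) { real = false; break; }
    if (real) out.push_back(tets[t].v);
  }
  IntegerMatrix res((int)out.size(), 4);
  for (size_t t = 0; t < out.size(); ++t) {
    std::array<int, 4> v = out[t];
    std::sort(v.begin(), v.end());
    for (int k = 0; k < 4; ++k) res((int)t, k) = v[k] + 1;
  }
  return res;
}
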