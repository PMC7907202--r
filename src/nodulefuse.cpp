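#include <Rcpp.h>
#include <map>
#include <vector>
#include <utility>
#include <cmath>
using namespace Rcpp;

// Number of 26-connected foreground components in a 3-D binary grid.
// [[Rcpp::export]]
int cpp_n_components_26(IntegerVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<int> lab(n, 0);
  int ncomp = 0;
  std::vector<int> stack;
  for (int s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++ncomp;
    stack.push_back(s);
    lab[s] = ncomp;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int w = xx + nx * (yy + ny * zz);
            if (mask[w] != 0 && lab[w] == 0) { lab[w] = ncomp; stack.push_back(w); }
          }
    }
  }
  return ncomp;
}

// Marching tetrahedra over a scalar field sampled on a regular grid.
// Each cell is split into 6 tetrahedra sharing the main diagonal; the
// iso-surface crossing of every tetrahedron is one or two triangles whose
// vertices sit on cell edges (welded via the grid-edge key), so the output
// is a closed, edge-manifold triangulation for any level set that stays
// inside the grid. Coordinates are returned in 0-based voxel units.
static const int TET_OFF[8][3] = {
  {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
static const int TETS[6][4] = {
  {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dim, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  typedef long long ll;
  std::map<std::pair<ll,ll>, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  double fv[8];
  ll gid[8];
  double px[8], py[8], pz[8];

  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        for (int c = 0; c < 8; ++c) {
          int cx = x + TET_OFF[c][0], cy = y + TET_OFF[c][1], cz = z + TET_OFF[c][2];
          ll g = cx + (ll)nx * (cy + (ll)ny * cz);
          gid[c] = g;
          fv[c] = field[(R_xlen_t)g];
          px[c] = cx; py[c] = cy; pz[c] = cz;
        }
        for (int t = 0; t < 6; ++t) {
          int id[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          bool in[4];
          int nin = 0;
          for (int k = 0; k < 4; ++k) { in[k] = fv[id[k]] > iso; if (in[k]) ++nin; }
          if (nin == 0 || nin == 4) continue;

          // vertex on the edge between tet corners a,b (indices into id[])
          auto edge_v = [&](int a, int b) -> int {
            int ca = id[a], cb = id[b];
            ll ga = gid[ca], gb = gid[cb];
            std::pair<ll,ll> key = ga < gb ? std::make_pair(ga, gb)
                                           : std::make_pair(gb, ga);
            std::map<std::pair<ll,ll>, int>::iterator it = edge_vertex.find(key);
            if (it != edge_vertex.end()) return it->second;
            double fa = fv[ca], fb = fv[cb];
            double u = (iso - fa) / (fb - fa);
            vx.push_back(px[ca] + u * (px[cb] - px[ca]));
            vy.push_back(py[ca] + u * (py[cb] - py[ca]));
            vz.push_back(pz[ca] + u * (pz[cb] - pz[ca]));
            int idx = (int)vx.size() - 1;
            edge_vertex[key] = idx;
            return idx;
          };

          // orientation reference: from inside centroid toward outside centroid
          double ix = 0, iy = 0, iz = 0, ox = 0, oy = 0, oz = 0;
          for (int k = 0; k < 4; ++k) {
            if (in[k]) { ix += px[id[k]]; iy += py[id[k]]; iz += pz[id[k]]; }
            else       { ox += px[id[k]]; oy += py[id[k]]; oz += pz[id[k]]; }
          }
          ix /= nin; iy /= nin; iz /= nin;
          ox /= (4 - nin); oy /= (4 - nin); oz /= (4 - nin);
          double rx = ox - ix, ry = oy - iy, rz = oz - iz;

          auto emit = [&](int a, int b, int c) {
            double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
            double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
            double nxv = uy * wz - uz * wy;
            double nyv = uz * wx - ux * wz;
            double nzv = ux * wy - uy * wx;
            if (nxv * rx + nyv * ry + nzv * rz < 0) { int tmp = b; b = c; c = tmp; }
            tri.push_back(a); tri.push_back(b); tri.push_back(c);
          };

          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int k = 0; k < 4; ++k) if (in[k] == (nin == 1)) apex = k;
            int other[3], m = 0;
            for (int k = 0; k < 4; ++k) if (k != apex) other[m++] = k;
            int v0 = edge_v(apex, other[0]);
            int v1 = edge_v(apex, other[1]);
            int v2 = edge_v(apex, other[2]);
            emit(v0, v1, v2);
          } else { // nin == 2
            int a0 = -1, a1 = -1, b0 = -1, b1 = -1;
            for (int k = 0; k < 4; ++k) {
              if (in[k]) { if (a0 < 0) a0 = k; else a1 = k; }
              else       { if (b0 < 0) b0 = k; else b1 = k; }
            }
            int v00 = edge_v(a0, b0);
            int v01 = edge_v(a0, b1);
            int v11 = edge_v(a1, b1);
            int v10 = edge_v(a1, b0);
            emit(v00, v01, v11);
            emit(v00, v11, v10);
          }
        }
      }

  int nv = (int)vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) { verts(i,0) = vx[i]; verts(i,1) = vy[i]; verts(i,2) = vz[i]; }
  int nt = (int)tri.size() / 3;
  IntegerMatrix faces(nt, 3);
  for (int i = 0; i < nt; ++i)
    for (int k = 0; k < 3; ++k) faces(i,k) = tri[3*i + k] + 1; // 1-based for R
  return List::create(_["vertices"] = verts, _["triangles"] = faces);
}

// One attraction cycle (Jacobi update from the previous coordinates):
// C'_i = C_i + sum_{j in N(i)} [ ca1 * d_ji * |d_ji|^2 + ca2 * d_ji / |d_ji| ],
// d_ji = C_j - C_i. Coincident pairs (|d| = 0) contribute nothing.
// [[Rcpp::export]]
NumericMatrix cpp_attraction(NumericMatrix nodes, List neighbors,
                             double ca1, double ca2) {
  const int n = nodes.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = neighbors[i];
    double ax = 0, ay = 0, az = 0;
    for (int k = 0; k < nb.size(); ++k) {
      int j = nb[k] - 1;
      double dx = nodes(j,0) - nodes(i,0);
      double dy = nodes(j,1) - nodes(i,1);
      double dz = nodes(j,2) - nodes(i,2);
      double l2 = dx*dx + dy*dy + dz*dz;
      if (l2 == 0) continue;
      double l = std::sqrt(l2);
      ax += ca1 * dx * l2 + ca2 * dx / l;
      ay += ca1 * dy * l2 + ca2 * dy / l;
      az += ca1 * dz * l2 + ca2 * dz / l;
    }
    out(i,0) = nodes(i,0) + ax;
    out(i,1) = nodes(i,1) + ay;
    out(i,2) = nodes(i,2) + az;
  }
  return out;
}

// One repulsion cycle with back-projection onto the unit sphere:
// C°_i = C'_i + (cr / 2I) * sum_{j != i} (C_i - C_j) / |C_i - C_j|^2,
// then C°_i <- C°_i / |C°_i|. Coincident pairs are skipped; nodes whose
// updated vector is exactly zero are returned as-is (caller jitters).
// [[Rcpp::export]]
NumericMatrix cpp_repulsion(NumericMatrix nodes, double cr) {
  const int n = nodes.nrow();
  NumericMatrix out(n, 3);
  const double scale = cr / (2.0 * n);
  std::vector<double> x(n), y(n), z(n), ax(n, 0.0), ay(n, 0.0), az(n, 0.0);
  for (int i = 0; i < n; ++i) { x[i] = nodes(i,0); y[i] = nodes(i,1); z[i] = nodes(i,2); }
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    double sx = 0, sy = 0, sz = 0;
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      double l2 = dx*dx + dy*dy + dz*dz;
      if (l2 == 0) continue;
      double inv = 1.0 / l2;
      dx *= inv; dy *= inv; dz *= inv;
      sx += dx; sy += dy; sz += dz;
      ax[j] -= dx; ay[j] -= dy; az[j] -= dz;
    }
    ax[i] += sx; ay[i] += sy; az[i] += sz;
  }
  for (int i = 0; i < n; ++i) {
    double ox = x[i] + scale * ax[i];
    double oy = y[i] + scale * ay[i];
    double oz = z[i] + scale * az[i];
    double nrm = std::sqrt(ox*ox + oy*oy + oz*oz);
    if (nrm > 0) { ox /= nrm; oy /= nrm; oz /= nrm; }
    out(i,0) = ox; out(i,1) = oy; out(i,2) = oz;
  }
  return out;
}
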