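// Isodensity surface extraction by marching tetrahedra.
// Each grid cell is split into six tetrahedra sharing the main diagonal;
// the iso-level crossing of each tetrahedron is triangulated with vertices
// interpolated along cell edges. "Inside" means value < level (structures
// are dark). Vertices are deduplicated per grid edge, so the mesh is
// watertight wherever the inside region does not touch the grid border.
#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

static inline long flat(int i, int j, int k, int nx, int ny) {
  return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
}

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  std::unordered_map<uint64_t, int> edge_vertex;
};

// [[Rcpp::export]]
List cpp_march_tetra(const NumericVector &vol, const IntegerVector &dims,
                     const double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // corner offsets of a cell
  const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // six tetrahedra sharing the 0-6 diagonal
  const int tets[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  MeshAcc m;

  double cval[8];
  long cid[8];
  double cpos[8][3];

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          cid[c] = flat(ii, jj, kk, nx, ny);
          cval[c] = vol[cid[c]];
          cpos[c][0] = ii + 0.5; cpos[c][1] = jj + 0.5; cpos[c][2] = kk + 0.5;
          (cval[c] < level ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            int v = tets[t][c];
            if (cval[v] < level) in[nin++] = v; else out[nout++] = v;
          }
          if (nin == 0 || nin == 4) continue;
          // vertex on edge (a inside, b outside)
          auto evert = [&](int a, int b) -> int {
            uint64_t ka = (uint64_t)cid[a], kb = (uint64_t)cid[b];
            uint64_t key = (std::min(ka, kb) << 32) | (uint64_t)(std::max(ka, kb) & 0xffffffffULL);
            auto it = m.edge_vertex.find(key);
            if (it != m.edge_vertex.end()) return it->second;
            double f = (level - cval[a]) / (cval[b] - cval[a]);
            if (!std::isfinite(f)) f = 0.5;
            if (f < 0) f = 0; else if (f > 1) f = 1;
            m.vx.push_back(cpos[a][0] + f * (cpos[b][0] - cpos[a][0]));
            m.vy.push_back(cpos[a][1] + f * (cpos[b][1] - cpos[a][1]));
            m.vz.push_back(cpos[a][2] + f * (cpos[b][2] - cpos[a][2]));
            int id = (int)m.vx.size() - 1;
            m.edge_vertex[key] = id;
            return id;
          };
          if (nin == 1) {
            m.tri.push_back(evert(in[0], out[0]));
            m.tri.push_back(evert(in[0], out[1]));
            m.tri.push_back(evert(in[0], out[2]));
          } else if (nin == 3) {
            m.tri.push_back(evert(in[0], out[0]));
            m.tri.push_back(evert(in[1], out[0]));
            m.tri.push_back(evert(in[2], out[0]));
          } else { // nin == 2
            int a = in[0], b = in[1], c = out[0], d = out[1];
            int v0 = evert(a, c), v1 = evert(a, d), v2 = evert(b, d), v3 = evert(b, c);
            m.tri.push_back(v0); m.tri.push_back(v1); m.tri.push_back(v2);
            m.tri.push_back(v0); m.tri.push_back(v2); m.tri.push_back(v3);
          }
        }
      }

  int nv = (int)m.vx.size(), nt = (int)m.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v,0) = m.vx[v]; V(v,1) = m.vy[v]; V(v,2) = m.vz[v]; }
  IntegerMatrix Fc(nt, 3);
  for (int t = 0; t < nt; ++t) {
    Fc(t,0) = m.tri[3*t] + 1; Fc(t,1) = m.tri[3*t+1] + 1; Fc(t,2) = m.tri[3*t+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = Fc);
}
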