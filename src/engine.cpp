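// Dynamically-triangulated-surface Monte Carlo engine.
//
// Holds the full simulation state (mesh connectivity, per-triangle and
// per-vertex geometry caches, inclusions, running energy totals) and performs
// the four trial moves with incremental energy evaluation.  All randomness
// comes from R's RNG stream so a single set.seed() upstream fixes the
// trajectory.  Energies are in kBT, lengths in the DTS unit length.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1]*b[2] - a[2]*b[1];
  out[1] = a[2]*b[0] - a[0]*b[2];
  out[2] = a[0]*b[1] - a[1]*b[0];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }
static inline double clamp1(double x) { return x > 1.0 ? 1.0 : (x < -1.0 ? -1.0 : x); }

struct PairPot {
  double A = 0.0, B = 0.0, C = 0.0, Th0 = 0.0, g0 = 0.0;
  int n = 1;
  bool active = false;
};

struct InclType {
  int cls = 1;                       // 1: isotropic, 2: anisotropic
  double dk = 0, dkg = 0, c0 = 0;    // type-1 params
  double k1 = 0, k2 = 0, cpar0 = 0, cperp0 = 0; // type-2 params
};

class Engine {
public:
  int NV = 0, NT = 0, NE = 0;
  std::vector<double> X;          // 3*NV positions (unwrapped)
  std::vector<int> tri;           // 3*NT vertex ids
  std::vector<int> everts;        // 2*NE
  std::vector<int> etri;          // 2*NE
  std::vector<int> tedge;         // 3*NT edge ids per triangle
  std::vector<std::vector<int>> vnbr, vedge, vtri;

  double L[3] = {1, 1, 1};
  bool per[3] = {false, false, false};

  // caches
  std::vector<double> t_area, t_norm, t_vol;  // NT, 3*NT, NT
  std::vector<double> v_area, v_norm, v_T1, v_T2, v_c1, v_c2, v_2HA, v_e;
  double Atot = 0, Vtot = 0, Mtot = 0, Evert = 0, Epair = 0;

  // membrane params
  double kappa = 20, kappaG = 0, Cbar = 0;
  // couplings
  bool en_tension = false; double tau = 0, box_prob = 1, box_amp = 0.01;
  bool en_area = false;    double KA = 0, A0 = 1;
  bool en_vol = false;     double dP = 0, Kv = 0, vt = 1;
  bool en_osm = false;     double RT = 0, cin = 0, cout_ = 0, Vini = 1;
  bool en_gc = false;      double kr = 0, m0 = 0;
  bool closed = false;     // enclosed-volume bookkeeping valid
  // constraints
  double lmin = 1.0, lmax = std::sqrt(3.0), mindist = 1.0, mincos = 0.0;
  // moves
  double delta = 0.1, rot_amp = M_PI / 4;
  double beta = 1.0;
  bool frozen = false;
  // confinement: 0 none, 1 slab z, 2 ellipsoid, 3 shell, 4 block
  int conf_kind = 0;
  std::vector<double> conf_par;
  // external harmonic force
  bool en_force = false; int force_v = -1; double anchor[3] = {0,0,0}; double kspring = 0;

  // inclusions
  int NI = 0;
  std::vector<int> inc_vert, inc_type, vert_inc;
  std::vector<double> inc_dir;    // 3*NI
  std::vector<InclType> types;
  std::vector<PairPot> pots;      // ntypes*ntypes

  // cell list (spatial hash, cell size >= mindist)
  std::unordered_map<int64_t, std::vector<int>> cells;
  double cellw[3] = {1, 1, 1};
  int ncell[3] = {1, 1, 1};

  // ---- basic helpers -------------------------------------------------
  void mimg(double* d) const {
    for (int k = 0; k < 3; ++k)
      if (per[k]) d[k] -= L[k] * std::nearbyint(d[k] / L[k]);
  }
  double dist2(const double* a, const double* b) const {
    double d[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
    mimg(d);
    return dot3(d, d);
  }

  // ---- cell list -----------------------------------------------------
  int64_t cell_key(const double* p) const {
    int64_t k = 0;
    for (int a = 0; a < 3; ++a) {
      long i = (long)std::floor(p[a] / cellw[a]);
      if (per[a]) { i %= ncell[a]; if (i < 0) i += ncell[a]; }
      k = k * 1000003 + (i + 500000);
    }
    return k;
  }
  void rebuild_cells() {
    for (int a = 0; a < 3; ++a) {
      if (per[a]) {
        ncell[a] = std::max(1, (int)std::floor(L[a] / mindist));
        cellw[a] = L[a] / ncell[a];
      } else { ncell[a] = 1; cellw[a] = std::max(mindist, 1.0); }
    }
    cells.clear();
    for (int v = 0; v < NV; ++v) cells[cell_key(&X[3*v])].push_back(v);
  }
  void cell_remove(int v, const double* p) {
    auto it = cells.find(cell_key(p));
    if (it == cells.end()) return;
    auto& vec = it->second;
    for (size_t i = 0; i < vec.size(); ++i)
      if (vec[i] == v) { vec[i] = vec.back(); vec.pop_back(); break; }
  }
  void cell_insert(int v, const double* p) { cells[cell_key(p)].push_back(v); }

  // true if some vertex other than `self` lies closer than mindist to p
  bool too_close(const double* p, int self) const {
    double md2 = mindist * mindist;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          double q[3] = {p[0] + dx * cellw[0], p[1] + dy * cellw[1], p[2] + dz * cellw[2]};
          auto it = cells.find(cell_key(q));
          if (it == cells.end()) continue;
          for (int u : it->second) {
            if (u == self) continue;
            if (dist2(p, &X[3*u]) < md2) return true;
          }
        }
    return false;
  }

  // ---- construction --------------------------------------------------
  void build_topology() {
    std::unordered_map<int64_t, int> emap;
    everts.clear(); etri.clear();
    tedge.assign(3 * NT, -1);
    vnbr.assign(NV, {}); vedge.assign(NV, {}); vtri.assign(NV, {});
    for (int t = 0; t < NT; ++t) {
      for (int k = 0; k < 3; ++k) {
        int a = tri[3*t + k], b = tri[3*t + (k + 1) % 3];
        vtri[a].push_back(t);
        int lo = std::min(a, b), hi = std::max(a, b);
        int64_t key = (int64_t)lo * 10000019 + hi;
        auto it = emap.find(key);
        int e;
        if (it == emap.end()) {
          e = NE++;
          emap[key] = e;
          everts.push_back(lo); everts.push_back(hi);
          etri.push_back(t); etri.push_back(-1);
          vnbr[a].push_back(b); vnbr[b].push_back(a);
          vedge[a].push_back(e); vedge[b].push_back(e);
        } else {
          e = it->second;
          if (etri[2*e + 1] != -1) stop("edge shared by >2 triangles");
          etri[2*e + 1] = t;
        }
        tedge[3*t + k] = e;
      }
    }
    for (int e = 0; e < NE; ++e)
      if (etri[2*e + 1] == -1) stop("open edge: mesh is not closed");
  }

  void tri_geom(int t) {
    const double *p1 = &X[3*tri[3*t]], *p2 = &X[3*tri[3*t+1]], *p3 = &X[3*tri[3*t+2]];
    double u[3] = {p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2]};
    double w[3] = {p3[0]-p1[0], p3[1]-p1[1], p3[2]-p1[2]};
    mimg(u); mimg(w);
    double n[3]; cross3(u, w, n);
    double a2 = norm3(n);
    t_area[t] = 0.5 * a2;
    if (a2 > 0) for (int k = 0; k < 3; ++k) t_norm[3*t + k] = n[k] / a2;
    if (closed) {
      // signed tetrahedron volume against the origin (absolute coordinates)
      double c[3]; cross3(p2, p3, c);
      t_vol[t] = dot3(p1, c) / 6.0;
    }
  }

  // discrete shape operator at vertex v; updates all per-vertex caches
  void vertex_geom(int v) {
    double A = 0, n[3] = {0, 0, 0};
    for (int t : vtri[v]) {
      A += t_area[t] / 3.0;
      for (int k = 0; k < 3; ++k) n[k] += t_area[t] * t_norm[3*t + k];
    }
    double nn = norm3(n);
    if (nn < 1e-14 || A <= 0) stop("degenerate one-ring at a vertex");
    for (int k = 0; k < 3; ++k) n[k] /= nn;

    double S[6] = {0, 0, 0, 0, 0, 0}; // xx xy xz yy yz zz
    for (int e : vedge[v]) {
      int t1 = etri[2*e], t2 = etri[2*e + 1];
      const double *n1 = &t_norm[3*t1], *n2 = &t_norm[3*t2];
      int a = everts[2*e], b = everts[2*e + 1];
      double ev[3] = {X[3*b]-X[3*a], X[3*b+1]-X[3*a+1], X[3*b+2]-X[3*a+2]};
      mimg(ev);
      double el = norm3(ev);
      if (el < 1e-14) stop("zero-length edge");
      double ed[3] = {ev[0]/el, ev[1]/el, ev[2]/el};
      double cosd = clamp1(dot3(n1, n2));
      double theta = std::acos(cosd);
      // convexity sign: normals tilt away from each other across a ridge;
      // face centroids taken relative to edge endpoint a (minimum image)
      double c1c[3] = {0,0,0}, c2c[3] = {0,0,0};
      for (int j = 0; j < 3; ++j) {
        double d1[3] = {X[3*tri[3*t1+j]] - X[3*a], X[3*tri[3*t1+j]+1] - X[3*a+1], X[3*tri[3*t1+j]+2] - X[3*a+2]};
        double d2[3] = {X[3*tri[3*t2+j]] - X[3*a], X[3*tri[3*t2+j]+1] - X[3*a+1], X[3*tri[3*t2+j]+2] - X[3*a+2]};
        mimg(d1); mimg(d2);
        for (int k = 0; k < 3; ++k) { c1c[k] += d1[k] / 3.0; c2c[k] += d2[k] / 3.0; }
      }
      double dn[3] = {n1[0]-n2[0], n1[1]-n2[1], n1[2]-n2[2]};
      double dc[3] = {c1c[0]-c2c[0], c1c[1]-c2c[1], c1c[2]-c2c[2]};
      double s = dot3(dn, dc) >= 0 ? 1.0 : -1.0;
      double h = 2.0 * el * std::sin(theta / 2.0) * s;
      double ne[3] = {n1[0]+n2[0], n1[1]+n2[1], n1[2]+n2[2]};
      double nne = norm3(ne);
      for (int k = 0; k < 3; ++k) ne[k] /= nne;
      double bb[3]; cross3(ed, ne, bb);
      double nb = norm3(bb);
      if (nb < 1e-14) continue;
      for (int k = 0; k < 3; ++k) bb[k] /= nb;
      S[0] += h * bb[0]*bb[0]; S[1] += h * bb[0]*bb[1]; S[2] += h * bb[0]*bb[2];
      S[3] += h * bb[1]*bb[1]; S[4] += h * bb[1]*bb[2]; S[5] += h * bb[2]*bb[2];
    }
    double inv = 1.0 / (2.0 * A);
    for (int k = 0; k < 6; ++k) S[k] *= inv;

    // tangent basis
    double t1r[3];
    if (std::fabs(n[0]) < 0.9) { t1r[0] = 1; t1r[1] = 0; t1r[2] = 0; }
    else { t1r[0] = 0; t1r[1] = 1; t1r[2] = 0; }
    double pr = dot3(t1r, n);
    for (int k = 0; k < 3; ++k) t1r[k] -= pr * n[k];
    double nt1 = norm3(t1r);
    for (int k = 0; k < 3; ++k) t1r[k] /= nt1;
    double t2r[3]; cross3(n, t1r, t2r);

    // project S to tangent plane: Sab = t_a^T S t_b (n-components drop out)
    double St1[3] = {S[0]*t1r[0]+S[1]*t1r[1]+S[2]*t1r[2],
                     S[1]*t1r[0]+S[3]*t1r[1]+S[4]*t1r[2],
                     S[2]*t1r[0]+S[4]*t1r[1]+S[5]*t1r[2]};
    double St2[3] = {S[0]*t2r[0]+S[1]*t2r[1]+S[2]*t2r[2],
                     S[1]*t2r[0]+S[3]*t2r[1]+S[4]*t2r[2],
                     S[2]*t2r[0]+S[4]*t2r[1]+S[5]*t2r[2]};
    double a11 = dot3(t1r, St1), a12 = dot3(t1r, St2), a22 = dot3(t2r, St2);
    double tr = a11 + a22;
    double disc = std::sqrt(0.25*(a11 - a22)*(a11 - a22) + a12*a12);
    double c1 = 0.5*tr + disc, c2 = 0.5*tr - disc;

    double e1[2];
    if (std::fabs(a12) > 1e-14 || std::fabs(a11 - c1) > std::fabs(a22 - c1)) {
      e1[0] = a12; e1[1] = c1 - a11;
      if (std::fabs(e1[0]) + std::fabs(e1[1]) < 1e-14) { e1[0] = c1 - a22; e1[1] = a12; }
    } else { e1[0] = 1; e1[1] = 0; }
    double ne1 = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1]);
    if (ne1 < 1e-14) { e1[0] = 1; e1[1] = 0; ne1 = 1; }
    e1[0] /= ne1; e1[1] /= ne1;

    double T1[3], T2[3];
    if (c1 - c2 < 1e-9) {
      // umbilic: reference-axis convention (tangent projection of x, else y)
      for (int k = 0; k < 3; ++k) T1[k] = t1r[k];
    } else {
      for (int k = 0; k < 3; ++k) T1[k] = e1[0]*t1r[k] + e1[1]*t2r[k];
    }
    cross3(n, T1, T2);

    v_area[v] = A;
    for (int k = 0; k < 3; ++k) {
      v_norm[3*v+k] = n[k]; v_T1[3*v+k] = T1[k]; v_T2[3*v+k] = T2[k];
    }
    v_c1[v] = c1; v_c2[v] = c2;
    v_2HA[v] = (c1 + c2) * A;
  }

  // ---- energies ------------------------------------------------------
  double site_energy(int v) const {
    int ii = vert_inc[v];
    if (ii < 0) return 0.0;
    const InclType& ty = types[inc_type[ii]];
    double c1 = v_c1[v], c2 = v_c2[v], A = v_area[v];
    if (ty.cls == 1) {
      double H = 0.5 * (c1 + c2), K = c1 * c2;
      return (2.0*ty.dk*H*H - 2.0*(ty.dk + kappa)*ty.c0*H - ty.dkg*K) * A;
    }
    const double* d = &inc_dir[3*ii];
    double ct = dot3(d, &v_T1[3*v]), st = dot3(d, &v_T2[3*v]);
    double n2 = ct*ct + st*st;
    if (n2 < 1e-14) n2 = 1.0;
    double cpar = (c1*ct*ct + c2*st*st) / n2;
    double cperp = (c1*st*st + c2*ct*ct) / n2;
    return (0.5*ty.k1*(cpar - ty.cpar0)*(cpar - ty.cpar0) +
            0.5*ty.k2*(cperp - ty.cperp0)*(cperp - ty.cperp0)) * A;
  }

  double bend_energy(int v) const {
    double c1 = v_c1[v], c2 = v_c2[v], A = v_area[v];
    double twoH = c1 + c2;
    return (0.5*kappa*(twoH - Cbar)*(twoH - Cbar) - kappaG*c1*c2) * A;
  }

  double vert_energy(int v) const { return bend_energy(v) + site_energy(v); }

  // Eq.-10 interaction of the two inclusions on edge e (both occupied)
  double pair_energy_edge(int e) const {
    int u = everts[2*e], w = everts[2*e + 1];
    int iu = vert_inc[u], iw = vert_inc[w];
    const PairPot& pp = pots[inc_type[iu] * (int)types.size() + inc_type[iw]];
    if (!pp.active) return 0.0;
    double r[3] = {X[3*w]-X[3*u], X[3*w+1]-X[3*u+1], X[3*w+2]-X[3*u+2]};
    mimg(r);
    const double *nu = &v_norm[3*u], *nw = &v_norm[3*w];
    double Th = 0.0;
    double pu[3], pw[3];
    double du_ = dot3(r, nu), dw_ = dot3(r, nw);
    for (int k = 0; k < 3; ++k) { pu[k] = r[k] - du_*nu[k]; pw[k] = r[k] - dw_*nw[k]; }
    double npu = norm3(pu), npw = norm3(pw);
    if (npu > 1e-12 && npw > 1e-12) {
      for (int k = 0; k < 3; ++k) { pu[k] /= npu; pw[k] /= npw; }
      const double *Du = &inc_dir[3*iu], *Dw = &inc_dir[3*iw];
      double cu[3]; cross3(pu, Du, cu);
      double Thu = std::atan2(dot3(nu, cu), dot3(pu, Du));
      double cw[3]; cross3(pw, Dw, cw);
      double Thw = std::atan2(dot3(nw, cw), dot3(pw, Dw));
      Th = Thw - Thu;
    }
    double g = std::acos(clamp1(dot3(nu, nw)));
    double tip[3] = {r[0] + nw[0] - nu[0], r[1] + nw[1] - nu[1], r[2] + nw[2] - nu[2]};
    if (dot3(tip, tip) < dot3(r, r)) g = -g;
    return -pp.A - pp.B * std::cos(pp.n * (Th - pp.Th0)) - pp.C * std::cos(g - pp.g0);
  }

  double area_E(double A) const { return en_area ? NT * 0.5 * KA * (A/A0 - 1.0)*(A/A0 - 1.0) : 0.0; }
  double vol_E(double V, double A) const {
    if (!en_vol) return 0.0;
    double V0 = std::pow(A, 1.5) / (6.0 * std::sqrt(M_PI));
    return -dP * V + 0.5 * Kv * (V/V0 - vt)*(V/V0 - vt);
  }
  double osm_E(double V) const {
    if (!en_osm) return 0.0;
    return -RT * (cin * Vini * std::log(V / Vini) - cout_ * (V - Vini));
  }
  double gc_E(double M, double A) const {
    if (!en_gc) return 0.0;
    return 0.5 * kr / A * (M - m0 * A) * (M - m0 * A);
  }
  double tension_E() const { return en_tension ? -tau * L[0] * L[1] : 0.0; }
  double force_E() const {
    if (!en_force) return 0.0;
    double d[3] = {X[3*force_v]-anchor[0], X[3*force_v+1]-anchor[1], X[3*force_v+2]-anchor[2]};
    return 0.5 * kspring * dot3(d, d);
  }
  double global_E(double A, double V, double M) const {
    return area_E(A) + vol_E(V, A) + osm_E(V) + gc_E(M, A) + tension_E() + force_E();
  }
  double total_E() const { return Evert + Epair + global_E(Atot, Vtot, Mtot); }

  bool confined_ok(const double* p) const {
    switch (conf_kind) {
      case 0: return true;
      case 1: return p[2] >= conf_par[0] && p[2] <= conf_par[1];
      case 2: {
        double s = 0;
        for (int k = 0; k < 3; ++k) {
          double d = (p[k] - conf_par[k]) / conf_par[3 + k];
          s += d * d;
        }
        return s <= 1.0;
      }
      case 3: {
        double s = 0;
        for (int k = 0; k < 3; ++k) {
          double d = (p[k] - conf_par[k]) / conf_par[3 + k];
          s += d * d;
        }
        double r = std::sqrt(s);
        return r >= conf_par[6] && r <= 1.0;
      }
      case 4:
        return p[0] >= conf_par[0] && p[0] <= conf_par[1] &&
               p[1] >= conf_par[2] && p[1] <= conf_par[3] &&
               p[2] >= conf_par[4] && p[2] <= conf_par[5];
    }
    return true;
  }

  void full_recompute() {
    for (int t = 0; t < NT; ++t) tri_geom(t);
    Atot = 0; Vtot = 0;
    for (int t = 0; t < NT; ++t) { Atot += t_area[t]; if (closed) Vtot += t_vol[t]; }
    Mtot = 0; Evert = 0;
    for (int v = 0; v < NV; ++v) {
      vertex_geom(v);
      retangent(v);
    }
    for (int v = 0; v < NV; ++v) { Mtot += v_2HA[v]; v_e[v] = vert_energy(v); Evert += v_e[v]; }
    Epair = 0;
    for (int e = 0; e < NE; ++e)
      if (vert_inc[everts[2*e]] >= 0 && vert_inc[everts[2*e+1]] >= 0)
        Epair += pair_energy_edge(e);
  }

  // keep an inclusion direction tangent after its host normal changed
  void retangent(int v) {
    int ii = vert_inc[v];
    if (ii < 0) return;
    double* d = &inc_dir[3*ii];
    const double* n = &v_norm[3*v];
    double pr = dot3(d, n);
    for (int k = 0; k < 3; ++k) d[k] -= pr * n[k];
    double nd = norm3(d);
    if (nd < 1e-12) { for (int k = 0; k < 3; ++k) d[k] = v_T1[3*v+k]; }
    else for (int k = 0; k < 3; ++k) d[k] /= nd;
  }

  // ---- region bookkeeping for trial moves ----------------------------
  struct TriSave { int t; double area, vol, n[3]; };
  struct VertSave {
    int v; double area, c1, c2, twoHA, e, n[3], T1[3], T2[3];
    int inc; double dir[3];
  };
  std::vector<TriSave> tsave;
  std::vector<VertSave> vsave;
  std::vector<int> region, affpairs;

  void save_tri(int t) {
    TriSave s; s.t = t; s.area = t_area[t]; s.vol = closed ? t_vol[t] : 0.0;
    for (int k = 0; k < 3; ++k) s.n[k] = t_norm[3*t+k];
    tsave.push_back(s);
  }
  void save_vert(int v) {
    VertSave s; s.v = v; s.area = v_area[v]; s.c1 = v_c1[v]; s.c2 = v_c2[v];
    s.twoHA = v_2HA[v]; s.e = v_e[v];
    for (int k = 0; k < 3; ++k) {
      s.n[k] = v_norm[3*v+k]; s.T1[k] = v_T1[3*v+k]; s.T2[k] = v_T2[3*v+k];
    }
    s.inc = vert_inc[v];
    if (s.inc >= 0) for (int k = 0; k < 3; ++k) s.dir[k] = inc_dir[3*s.inc+k];
    vsave.push_back(s);
  }
  void restore_saved() {
    for (const auto& s : tsave) {
      t_area[s.t] = s.area; if (closed) t_vol[s.t] = s.vol;
      for (int k = 0; k < 3; ++k) t_norm[3*s.t+k] = s.n[k];
    }
    for (const auto& s : vsave) {
      v_area[s.v] = s.area; v_c1[s.v] = s.c1; v_c2[s.v] = s.c2;
      v_2HA[s.v] = s.twoHA; v_e[s.v] = s.e;
      for (int k = 0; k < 3; ++k) {
        v_norm[3*s.v+k] = s.n[k]; v_T1[3*s.v+k] = s.T1[k]; v_T2[3*s.v+k] = s.T2[k];
      }
      if (s.inc >= 0) for (int k = 0; k < 3; ++k) inc_dir[3*s.inc+k] = s.dir[k];
    }
    tsave.clear(); vsave.clear();
  }

  // occupied-occupied edges with an endpoint in `region` (unique)
  void collect_pairs(std::vector<int>& out) const {
    out.clear();
    for (int v : region) {
      if (vert_inc[v] < 0) continue;
      for (int e : vedge[v]) {
        int o = everts[2*e] == v ? everts[2*e+1] : everts[2*e];
        if (vert_inc[o] < 0) continue;
        bool seen = false;
        for (int q : out) if (q == e) { seen = true; break; }
        if (!seen) out.push_back(e);
      }
    }
  }

  double pairs_sum(const std::vector<int>& es) const {
    double s = 0;
    for (int e : es) s += pair_energy_edge(e);
    return s;
  }

  // ---- trial moves ---------------------------------------------------
  bool try_vertex_move(int v) {
    double np[3];
    for (int k = 0; k < 3; ++k) np[k] = X[3*v+k] + delta * (2.0*unif_rand() - 1.0);
    if (!confined_ok(np)) return false;
    // edge-length window for incident edges
    for (int w : vnbr[v]) {
      double d[3] = {X[3*w]-np[0], X[3*w+1]-np[1], X[3*w+2]-np[2]};
      mimg(d);
      double l2 = dot3(d, d);
      if (l2 < lmin*lmin || l2 > lmax*lmax) return false;
    }
    if (too_close(np, v)) return false;

    // tentative normals of incident triangles -> dihedral bound
    std::vector<int>& ts = vtri[v];
    int nt = ts.size();
    double tmpn[64 * 3];
    double tmpa[64], tmpvol[64];
    if (nt > 64) stop("vertex valence too large");
    double oldp[3] = {X[3*v], X[3*v+1], X[3*v+2]};
    X[3*v] = np[0]; X[3*v+1] = np[1]; X[3*v+2] = np[2];
    bool ok = true;
    for (int i = 0; i < nt && ok; ++i) {
      int t = ts[i];
      const double *p1 = &X[3*tri[3*t]], *p2 = &X[3*tri[3*t+1]], *p3 = &X[3*tri[3*t+2]];
      double u[3] = {p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2]};
      double w[3] = {p3[0]-p1[0], p3[1]-p1[1], p3[2]-p1[2]};
      mimg(u); mimg(w);
      double n[3]; cross3(u, w, n);
      double a2 = norm3(n);
      if (a2 < 1e-12) { ok = false; break; }
      tmpa[i] = 0.5 * a2;
      for (int k = 0; k < 3; ++k) tmpn[3*i+k] = n[k] / a2;
      if (closed) { double c[3]; cross3(p2, p3, c); tmpvol[i] = dot3(p1, c) / 6.0; }
    }
    if (ok) {
      // dihedral bound on all edges of the incident triangles
      for (int i = 0; i < nt && ok; ++i) {
        int t = ts[i];
        for (int k = 0; k < 3 && ok; ++k) {
          int e = tedge[3*t+k];
          int ta = etri[2*e], tb = etri[2*e+1];
          const double *na = nullptr, *nb = nullptr;
          for (int j = 0; j < nt; ++j) { if (ts[j] == ta) na = &tmpn[3*j]; if (ts[j] == tb) nb = &tmpn[3*j]; }
          if (!na) na = &t_norm[3*ta];
          if (!nb) nb = &t_norm[3*tb];
          if (dot3(na, nb) < mincos) ok = false;
        }
      }
    }
    if (!ok) { X[3*v] = oldp[0]; X[3*v+1] = oldp[1]; X[3*v+2] = oldp[2]; return false; }

    // energy difference over the refresh region; all "old" terms must be
    // evaluated at the old position (global_E includes the external force)
    X[3*v] = oldp[0]; X[3*v+1] = oldp[1]; X[3*v+2] = oldp[2];
    double E0g = global_E(Atot, Vtot, Mtot);
    region.clear(); region.push_back(v);
    for (int w : vnbr[v]) region.push_back(w);
    collect_pairs(affpairs);
    double Epair_old = pairs_sum(affpairs);
    double Evert_old = 0;
    for (int u : region) Evert_old += v_e[u];
    X[3*v] = np[0]; X[3*v+1] = np[1]; X[3*v+2] = np[2];

    tsave.clear(); vsave.clear();
    double dA = 0, dV = 0, dM = 0;
    for (int i = 0; i < nt; ++i) {
      int t = ts[i];
      save_tri(t);
      dA += tmpa[i] - t_area[t];
      t_area[t] = tmpa[i];
      for (int k = 0; k < 3; ++k) t_norm[3*t+k] = tmpn[3*i+k];
      if (closed) { dV += tmpvol[i] - t_vol[t]; t_vol[t] = tmpvol[i]; }
    }
    double Evert_new = 0;
    for (int u : region) {
      save_vert(u);
      vertex_geom(u);
      retangent(u);
      dM += v_2HA[u] - vsave.back().twoHA;
      v_e[u] = vert_energy(u);
      Evert_new += v_e[u];
    }
    double Epair_new = pairs_sum(affpairs);
    double E1g = global_E(Atot + dA, Vtot + dV, Mtot + dM);
    double dE = (Evert_new - Evert_old) + (Epair_new - Epair_old) + (E1g - E0g);

    if (dE <= 0 || unif_rand() < std::exp(-beta * dE)) {
      Atot += dA; Vtot += dV; Mtot += dM;
      Evert += Evert_new - Evert_old;
      Epair += Epair_new - Epair_old;
      cell_remove(v, oldp);
      cell_insert(v, np);
      tsave.clear(); vsave.clear();
      return true;
    }
    X[3*v] = oldp[0]; X[3*v+1] = oldp[1]; X[3*v+2] = oldp[2];
    restore_saved();
    return false;
  }

  // rewire edge e; returns false if topologically illegal.  Caller handles
  // caches.  a,b,c,d of the quad are reported through the out parameters.
  bool flip_rewire(int e, int& a, int& b, int& c, int& d) {
    a = everts[2*e]; b = everts[2*e+1];
    int t1 = etri[2*e], t2 = etri[2*e+1];
    // orient so that t1 contains the directed edge a->b
    bool fwd = false;
    for (int k = 0; k < 3; ++k)
      if (tri[3*t1+k] == a && tri[3*t1+(k+1)%3] == b) fwd = true;
    if (!fwd) std::swap(a, b);
    c = -1; d = -1;
    for (int k = 0; k < 3; ++k) {
      if (tri[3*t1+k] != a && tri[3*t1+k] != b) c = tri[3*t1+k];
      if (tri[3*t2+k] != a && tri[3*t2+k] != b) d = tri[3*t2+k];
    }
    if (c < 0 || d < 0 || c == d) return false;
    if ((int)vnbr[a].size() <= 3 || (int)vnbr[b].size() <= 3) return false;
    for (int w : vnbr[c]) if (w == d) return false; // duplicate edge

    // locate boundary edges
    int e_bc = -1, e_ca = -1, e_ad = -1, e_db = -1;
    for (int k = 0; k < 3; ++k) {
      int q = tedge[3*t1+k];
      int u1 = everts[2*q], u2 = everts[2*q+1];
      if ((u1 == b && u2 == c) || (u1 == c && u2 == b)) e_bc = q;
      if ((u1 == c && u2 == a) || (u1 == a && u2 == c)) e_ca = q;
      q = tedge[3*t2+k];
      u1 = everts[2*q]; u2 = everts[2*q+1];
      if ((u1 == a && u2 == d) || (u1 == d && u2 == a)) e_ad = q;
      if ((u1 == d && u2 == b) || (u1 == b && u2 == d)) e_db = q;
    }
    if (e_bc < 0 || e_ca < 0 || e_ad < 0 || e_db < 0) return false;

    // new triangles (consistent winding): t1 <- (b,c,d), t2 <- (a,d,c)
    tri[3*t1] = b; tri[3*t1+1] = c; tri[3*t1+2] = d;
    tri[3*t2] = a; tri[3*t2+1] = d; tri[3*t2+2] = c;
    tedge[3*t1] = e_bc; tedge[3*t1+1] = e;    tedge[3*t1+2] = e_db;
    tedge[3*t2] = e_ad; tedge[3*t2+1] = e;    tedge[3*t2+2] = e_ca;
    everts[2*e] = std::min(c, d); everts[2*e+1] = std::max(c, d);
    // boundary edge face pointers: (c,a) t1 -> t2 ; (d,b) t2 -> t1
    for (int s = 0; s < 2; ++s) {
      if (etri[2*e_ca+s] == t1) etri[2*e_ca+s] = t2;
      if (etri[2*e_db+s] == t2) etri[2*e_db+s] = t1;
    }
    auto drop = [](std::vector<int>& vec, int x) {
      for (size_t i = 0; i < vec.size(); ++i)
        if (vec[i] == x) { vec[i] = vec.back(); vec.pop_back(); return; }
    };
    drop(vnbr[a], b); drop(vnbr[b], a);
    vnbr[c].push_back(d); vnbr[d].push_back(c);
    drop(vedge[a], e); drop(vedge[b], e);
    vedge[c].push_back(e); vedge[d].push_back(e);
    drop(vtri[a], t1); drop(vtri[b], t2);
    vtri[c].push_back(t2); vtri[d].push_back(t1);
    return true;
  }

  bool try_flip(int e) {
    int t1 = etri[2*e], t2 = etri[2*e+1];
    int a, b, c, d;
    // quick duplicate/degree checks happen inside flip_rewire; but first the
    // new-edge length window (cheap, avoids rewiring):
    {
      int aa = everts[2*e], bb = everts[2*e+1];
      int cc = -1, dd = -1;
      for (int k = 0; k < 3; ++k) {
        if (tri[3*t1+k] != aa && tri[3*t1+k] != bb) cc = tri[3*t1+k];
        if (tri[3*t2+k] != aa && tri[3*t2+k] != bb) dd = tri[3*t2+k];
      }
      if (cc < 0 || dd < 0 || cc == dd) return false;
      double dv[3] = {X[3*dd]-X[3*cc], X[3*dd+1]-X[3*cc+1], X[3*dd+2]-X[3*cc+2]};
      mimg(dv);
      double l2 = dot3(dv, dv);
      if (l2 < lmin*lmin || l2 > lmax*lmax) return false;
    }

    // save connectivity of the quad for rollback
    int sv[4];
    std::vector<int> s_nbr[4], s_edge[4], s_tri[4];
    int s_tri1[3] = {tri[3*t1], tri[3*t1+1], tri[3*t1+2]};
    int s_tri2[3] = {tri[3*t2], tri[3*t2+1], tri[3*t2+2]};
    int s_te1[3] = {tedge[3*t1], tedge[3*t1+1], tedge[3*t1+2]};
    int s_te2[3] = {tedge[3*t2], tedge[3*t2+1], tedge[3*t2+2]};
    int s_ev[2] = {everts[2*e], everts[2*e+1]};
    // edges whose face pointers may change: all edges of t1,t2
    int touched[6];
    for (int k = 0; k < 3; ++k) { touched[k] = tedge[3*t1+k]; touched[3+k] = tedge[3*t2+k]; }
    int s_facep[12];
    for (int k = 0; k < 6; ++k) { s_facep[2*k] = etri[2*touched[k]]; s_facep[2*k+1] = etri[2*touched[k]+1]; }

    {
      int qa = s_ev[0], qb = s_ev[1];
      int qc = -1, qd = -1;
      for (int k = 0; k < 3; ++k) {
        if (s_tri1[k] != qa && s_tri1[k] != qb) qc = s_tri1[k];
        if (s_tri2[k] != qa && s_tri2[k] != qb) qd = s_tri2[k];
      }
      sv[0] = qa; sv[1] = qb; sv[2] = qc; sv[3] = qd;
      for (int k = 0; k < 4; ++k) {
        s_nbr[k] = vnbr[sv[k]]; s_edge[k] = vedge[sv[k]]; s_tri[k] = vtri[sv[k]];
      }
    }

    // old local energies
    double E0g = global_E(Atot, Vtot, Mtot);
    region.assign(sv, sv + 4);
    collect_pairs(affpairs);
    double Epair_old = pairs_sum(affpairs);
    double Evert_old = 0;
    for (int u : region) Evert_old += v_e[u];

    if (!flip_rewire(e, a, b, c, d)) return false;

    auto rollback_topo = [&]() {
      for (int k = 0; k < 3; ++k) {
        tri[3*t1+k] = s_tri1[k]; tri[3*t2+k] = s_tri2[k];
        tedge[3*t1+k] = s_te1[k]; tedge[3*t2+k] = s_te2[k];
      }
      everts[2*e] = s_ev[0]; everts[2*e+1] = s_ev[1];
      for (int k = 0; k < 6; ++k) { etri[2*touched[k]] = s_facep[2*k]; etri[2*touched[k]+1] = s_facep[2*k+1]; }
      for (int k = 0; k < 4; ++k) {
        vnbr[sv[k]] = s_nbr[k]; vedge[sv[k]] = s_edge[k]; vtri[sv[k]] = s_tri[k];
      }
    };

    // new triangle geometry + dihedral bound on the 6 local edges
    tsave.clear(); vsave.clear();
    save_tri(t1); save_tri(t2);
    double dA = -t_area[t1] - t_area[t2];
    double dV = closed ? (-t_vol[t1] - t_vol[t2]) : 0.0;
    tri_geom(t1); tri_geom(t2);
    dA += t_area[t1] + t_area[t2];
    if (closed) dV += t_vol[t1] + t_vol[t2];
    bool ok = t_area[t1] > 1e-12 && t_area[t2] > 1e-12;
    for (int k = 0; k < 6 && ok; ++k) {
      int q = touched[k];
      if (dot3(&t_norm[3*etri[2*q]], &t_norm[3*etri[2*q+1]]) < mincos) ok = false;
    }
    if (!ok) {
      restore_saved();
      rollback_topo();
      return false;
    }

    double dM = 0, Evert_new = 0;
    for (int u : region) {
      save_vert(u);
      vertex_geom(u);
      retangent(u);
      dM += v_2HA[u] - vsave.back().twoHA;
      v_e[u] = vert_energy(u);
      Evert_new += v_e[u];
    }
    std::vector<int> newpairs;
    collect_pairs(newpairs);
    double Epair_new = pairs_sum(newpairs);
    double E1g = global_E(Atot + dA, Vtot + dV, Mtot + dM);
    double dE = (Evert_new - Evert_old) + (Epair_new - Epair_old) + (E1g - E0g);

    if (dE <= 0 || unif_rand() < std::exp(-beta * dE)) {
      Atot += dA; Vtot += dV; Mtot += dM;
      Evert += Evert_new - Evert_old;
      Epair += Epair_new - Epair_old;
      tsave.clear(); vsave.clear();
      return true;
    }
    restore_saved();
    rollback_topo();
    return false;
  }

  bool try_incl_move(int i) {
    int u = inc_vert[i];
    if (unif_rand() < 0.5) {
      // in-plane rotation
      double ang = rot_amp * (2.0*unif_rand() - 1.0);
      double old[3] = {inc_dir[3*i], inc_dir[3*i+1], inc_dir[3*i+2]};
      const double* n = &v_norm[3*u];
      double nxd[3]; cross3(n, old, nxd);
      double ca = std::cos(ang), sa = std::sin(ang);
      region.clear(); region.push_back(u);
      collect_pairs(affpairs);
      double e_old = v_e[u] + pairs_sum(affpairs);
      for (int k = 0; k < 3; ++k) inc_dir[3*i+k] = ca*old[k] + sa*nxd[k];
      double ve_new = vert_energy(u);
      double e_new = ve_new + pairs_sum(affpairs);
      double dE = e_new - e_old;
      if (dE <= 0 || unif_rand() < std::exp(-beta * dE)) {
        Evert += ve_new - v_e[u];
        Epair += e_new - ve_new - (e_old - v_e[u]);
        v_e[u] = ve_new;
        return true;
      }
      for (int k = 0; k < 3; ++k) inc_dir[3*i+k] = old[k];
      return false;
    }
    // hop to a uniformly chosen adjacent vertex (sorted copy: canonical
    // draw independent of internal adjacency-list order)
    std::vector<int> nbrs(vnbr[u]);
    std::sort(nbrs.begin(), nbrs.end());
    int nn = nbrs.size();
    int w = nbrs[std::min(nn - 1, (int)(unif_rand() * nn))];
    if (vert_inc[w] >= 0) return false;
    double old[3] = {inc_dir[3*i], inc_dir[3*i+1], inc_dir[3*i+2]};
    region.clear(); region.push_back(u); region.push_back(w);
    collect_pairs(affpairs);
    double e_old = v_e[u] + v_e[w] + pairs_sum(affpairs);
    // parallel transport old dir from u to w
    double nd[3];
    transport(u, w, old, nd);
    vert_inc[u] = -1; vert_inc[w] = i; inc_vert[i] = w;
    for (int k = 0; k < 3; ++k) inc_dir[3*i+k] = nd[k];
    double veu = vert_energy(u), vew = vert_energy(w);
    std::vector<int> newpairs;
    collect_pairs(newpairs);
    double e_new = veu + vew + pairs_sum(newpairs);
    double dE = e_new - e_old;
    if (dE <= 0 || unif_rand() < std::exp(-beta * dE)) {
      Evert += veu + vew - v_e[u] - v_e[w];
      Epair += (e_new - veu - vew) - (e_old - v_e[u] - v_e[w]);
      v_e[u] = veu; v_e[w] = vew;
      return true;
    }
    vert_inc[w] = -1; vert_inc[u] = i; inc_vert[i] = u;
    for (int k = 0; k < 3; ++k) inc_dir[3*i+k] = old[k];
    return false;
  }

  // parallel transport of tangent vector t at u to vertex w (adjacent)
  void transport(int u, int w, const double* tv, double* out) const {
    double r[3] = {X[3*w]-X[3*u], X[3*w+1]-X[3*u+1], X[3*w+2]-X[3*u+2]};
    mimg(r);
    const double *nu = &v_norm[3*u], *nw = &v_norm[3*w];
    double a[3], b[3];
    double pu = dot3(r, nu), pw = dot3(r, nw);
    for (int k = 0; k < 3; ++k) { a[k] = r[k] - pu*nu[k]; b[k] = r[k] - pw*nw[k]; }
    double na = norm3(a), nb = norm3(b);
    if (na < 1e-12 || nb < 1e-12) { for (int k = 0; k < 3; ++k) out[k] = tv[k]; return; }
    for (int k = 0; k < 3; ++k) { a[k] /= na; b[k] /= nb; }
    double aperp[3], bperp[3];
    cross3(nu, a, aperp); cross3(nw, b, bperp);
    double ca = dot3(tv, a), sa = dot3(tv, aperp);
    for (int k = 0; k < 3; ++k) out[k] = ca*b[k] + sa*bperp[k];
  }

  bool try_box() {
    double lam = 1.0 + box_amp * (2.0*unif_rand() - 1.0);
    double E0 = total_E();
    // save full state (once per sweep at most; O(N) is acceptable)
    std::vector<double> sX(X), sta(t_area), stn(t_norm), stv(t_vol);
    std::vector<double> sva(v_area), svn(v_norm), sT1(v_T1), sT2(v_T2),
        sc1(v_c1), sc2(v_c2), s2HA(v_2HA), sve(v_e), sdir(inc_dir);
    double sA = Atot, sV = Vtot, sM = Mtot, sEv = Evert, sEp = Epair;
    double sL0 = L[0], sL1 = L[1];

    for (int v = 0; v < NV; ++v) { X[3*v] *= lam; X[3*v+1] *= lam; }
    L[0] *= lam; L[1] *= lam;

    auto rollback = [&]() {
      X = sX; t_area = sta; t_norm = stn; t_vol = stv;
      v_area = sva; v_norm = svn; v_T1 = sT1; v_T2 = sT2;
      v_c1 = sc1; v_c2 = sc2; v_2HA = s2HA; v_e = sve; inc_dir = sdir;
      Atot = sA; Vtot = sV; Mtot = sM; Evert = sEv; Epair = sEp;
      L[0] = sL0; L[1] = sL1;
      rebuild_cells();
    };

    // constraints: edge window always; min distance only when shrinking
    bool ok = true;
    for (int e = 0; e < NE && ok; ++e) {
      double d[3] = {X[3*everts[2*e+1]]-X[3*everts[2*e]],
                     X[3*everts[2*e+1]+1]-X[3*everts[2*e]+1],
                     X[3*everts[2*e+1]+2]-X[3*everts[2*e]+2]};
      mimg(d);
      double l2 = dot3(d, d);
      if (l2 < lmin*lmin || l2 > lmax*lmax) ok = false;
    }
    if (ok && conf_kind != 0)
      for (int v = 0; v < NV && ok; ++v)
        if (!confined_ok(&X[3*v])) ok = false;
    if (ok && lam < 1.0) {
      rebuild_cells();
      for (int v = 0; v < NV && ok; ++v)
        if (too_close(&X[3*v], v)) ok = false;
    }
    if (!ok) { rollback(); return false; }

    full_recompute();
    // dihedral bound after rescale
    for (int e = 0; e < NE && ok; ++e)
      if (dot3(&t_norm[3*etri[2*e]], &t_norm[3*etri[2*e+1]]) < mincos) ok = false;
    if (!ok) { rollback(); return false; }

    double dE = total_E() - E0;
    double logacc = -beta * dE + NV * 2.0 * std::log(lam);
    if (logacc >= 0 || unif_rand() < std::exp(logacc)) {
      rebuild_cells();
      return true;
    }
    rollback();
    return false;
  }

  // ---- sweep ---------------------------------------------------------
  void sweep(long* acc, long* tries) {
    if (!frozen) {
      for (int k = 0; k < NT; ++k) {
        // canonical edge draw via (triangle slot, corner): slot numbering is
        // stable across flips and state round trips, unlike internal edge
        // ids; every edge owns exactly two slots, so the draw is uniform
        int t = std::min(NT - 1, (int)(unif_rand() * NT));
        int c = std::min(2, (int)(unif_rand() * 3));
        tries[0]++; if (try_flip(tedge[3*t + c])) acc[0]++;
      }
      for (int k = 0; k < NV; ++k) {
        int v = std::min(NV - 1, (int)(unif_rand() * NV));
        tries[1]++; if (try_vertex_move(v)) acc[1]++;
      }
    }
    for (int k = 0; k < NI; ++k) {
      int i = std::min(NI - 1, (int)(unif_rand() * NI));
      tries[2]++; if (try_incl_move(i)) acc[2]++;
    }
    if (!frozen && en_tension && unif_rand() < box_prob) {
      tries[3]++; if (try_box()) acc[3]++;
    }
  }
};

static void init_engine(Engine& E, List cfg) {
  NumericMatrix V = cfg["vertices"];
  IntegerMatrix T = cfg["triangles"];
  NumericVector bl = cfg["boxL"];
  LogicalVector pp = cfg["periodic"];
  E.NV = V.nrow(); E.NT = T.nrow();
  E.X.resize(3 * E.NV);
  for (int i = 0; i < E.NV; ++i) for (int k = 0; k < 3; ++k) E.X[3*i+k] = V(i, k);
  E.tri.resize(3 * E.NT);
  for (int i = 0; i < E.NT; ++i) for (int k = 0; k < 3; ++k) E.tri[3*i+k] = T(i, k) - 1;
  for (int k = 0; k < 3; ++k) { E.L[k] = bl[k]; E.per[k] = pp[k]; }
  E.closed = !(E.per[0] || E.per[1] || E.per[2]);

  E.kappa = as<double>(cfg["kappa"]);
  E.kappaG = as<double>(cfg["kappaG"]);
  E.Cbar = as<double>(cfg["Cbar"]);

  List cons = cfg["constraints"];
  E.lmin = as<double>(cons["lmin"]); E.lmax = as<double>(cons["lmax"]);
  E.mindist = as<double>(cons["mindist"]); E.mincos = as<double>(cons["mincos"]);

  List mv = cfg["moves"];
  E.delta = as<double>(mv["delta"]); E.rot_amp = as<double>(mv["rot_amp"]);
  E.box_amp = as<double>(mv["box_amp"]); E.box_prob = as<double>(mv["box_prob"]);

  List cup = cfg["couplings"];
  List tn = cup["tension"];
  E.en_tension = as<bool>(tn["enabled"]); E.tau = as<double>(tn["tau"]);
  List ar = cup["area"];
  E.en_area = as<bool>(ar["enabled"]);
  if (E.en_area) { E.KA = as<double>(ar["KA"]); E.A0 = as<double>(ar["A0"]); }
  List vo = cup["volume"];
  E.en_vol = as<bool>(vo["enabled"]);
  if (E.en_vol) { E.dP = as<double>(vo["dP"]); E.Kv = as<double>(vo["K"]); E.vt = as<double>(vo["vt"]); }
  List os = cup["osmotic"];
  E.en_osm = as<bool>(os["enabled"]);
  if (E.en_osm) {
    E.RT = as<double>(os["RT"]); E.cin = as<double>(os["cin"]);
    E.cout_ = as<double>(os["cout"]); E.Vini = as<double>(os["Vini"]);
  }
  List gc = cup["global_curvature"];
  E.en_gc = as<bool>(gc["enabled"]);
  if (E.en_gc) { E.kr = as<double>(gc["kr"]); E.m0 = as<double>(gc["m0"]); }

  List cf = cfg["confinement"];
  E.conf_kind = as<int>(cf["kind"]);
  if (E.conf_kind != 0) E.conf_par = as<std::vector<double>>(cf["params"]);

  List fr = cfg["force"];
  E.en_force = as<bool>(fr["enabled"]);
  if (E.en_force) {
    E.force_v = as<int>(fr["vertex"]) - 1;
    NumericVector an = fr["anchor"];
    for (int k = 0; k < 3; ++k) E.anchor[k] = an[k];
    E.kspring = as<double>(fr["k"]);
  }

  E.frozen = as<bool>(cfg["frozen"]);
  E.beta = as<double>(cfg["beta"]);

  // inclusions
  List inc = cfg["inclusions"];
  IntegerVector iv = inc["vertex"], it = inc["type"];
  NumericMatrix idir = inc["dir"];
  E.NI = iv.size();
  E.inc_vert.resize(E.NI); E.inc_type.resize(E.NI); E.inc_dir.resize(3 * E.NI);
  E.vert_inc.assign(E.NV, -1);
  for (int i = 0; i < E.NI; ++i) {
    E.inc_vert[i] = iv[i] - 1;
    E.inc_type[i] = it[i] - 1;
    if (E.vert_inc[E.inc_vert[i]] >= 0) stop("two inclusions on one vertex");
    E.vert_inc[E.inc_vert[i]] = i;
    for (int k = 0; k < 3; ++k) E.inc_dir[3*i+k] = idir(i, k);
  }
  List tys = inc["types"];
  int nty = tys.size();
  E.types.resize(std::max(nty, 1));
  for (int i = 0; i < nty; ++i) {
    List ty = tys[i];
    InclType t;
    t.cls = as<int>(ty["cls"]);
    t.dk = as<double>(ty["dk"]); t.dkg = as<double>(ty["dkg"]); t.c0 = as<double>(ty["c0"]);
    t.k1 = as<double>(ty["k1"]); t.k2 = as<double>(ty["k2"]);
    t.cpar0 = as<double>(ty["cpar0"]); t.cperp0 = as<double>(ty["cperp0"]);
    E.types[i] = t;
  }
  E.pots.assign(std::max(nty, 1) * std::max(nty, 1), PairPot());
  if (inc.containsElementNamed("pair_potentials")) {
    List pl = inc["pair_potentials"];
    for (int i = 0; i < pl.size(); ++i) {
      List p = pl[i];
      int ti = as<int>(p["i"]) - 1, tj = as<int>(p["j"]) - 1;
      PairPot q;
      q.A = as<double>(p["A"]); q.B = as<double>(p["B"]); q.C = as<double>(p["C"]);
      q.n = as<int>(p["n"]); q.Th0 = as<double>(p["Theta0"]); q.g0 = as<double>(p["gamma0"]);
      q.active = true;
      E.pots[ti * nty + tj] = q;
      E.pots[tj * nty + ti] = q;
    }
  }

  E.build_topology();
  E.t_area.resize(E.NT); E.t_norm.resize(3 * E.NT); E.t_vol.resize(E.NT);
  E.v_area.resize(E.NV); E.v_norm.resize(3 * E.NV);
  E.v_T1.resize(3 * E.NV); E.v_T2.resize(3 * E.NV);
  E.v_c1.resize(E.NV); E.v_c2.resize(E.NV);
  E.v_2HA.resize(E.NV); E.v_e.resize(E.NV);
  E.rebuild_cells();
  E.full_recompute();
}

// [[Rcpp::export]]
List cpp_geometry(NumericMatrix vertices, IntegerMatrix triangles,
                  NumericVector boxL, LogicalVector periodic) {
  Engine E;
  List cfg = List::create(
    _["vertices"] = vertices, _["triangles"] = triangles,
    _["boxL"] = boxL, _["periodic"] = periodic,
    _["kappa"] = 0.0, _["kappaG"] = 0.0, _["Cbar"] = 0.0,
    _["constraints"] = List::create(_["lmin"] = 0.0, _["lmax"] = 1e9,
                                    _["mindist"] = 1e-6, _["mincos"] = -2.0),
    _["moves"] = List::create(_["delta"] = 0.1, _["rot_amp"] = 0.1,
                              _["box_amp"] = 0.01, _["box_prob"] = 0.0),
    _["couplings"] = List::create(
      _["tension"] = List::create(_["enabled"] = false, _["tau"] = 0.0),
      _["area"] = List::create(_["enabled"] = false),
      _["volume"] = List::create(_["enabled"] = false),
      _["osmotic"] = List::create(_["enabled"] = false),
      _["global_curvature"] = List::create(_["enabled"] = false)),
    _["confinement"] = List::create(_["kind"] = 0),
    _["force"] = List::create(_["enabled"] = false),
    _["frozen"] = false, _["beta"] = 1.0,
    _["inclusions"] = List::create(
      _["vertex"] = IntegerVector(0), _["type"] = IntegerVector(0),
      _["dir"] = NumericMatrix(0, 3), _["types"] = List::create()));
  init_engine(E, cfg);

  NumericVector area(E.NV), c1(E.NV), c2(E.NV);
  NumericMatrix nrm(E.NV, 3), T1(E.NV, 3), T2(E.NV, 3);
  for (int v = 0; v < E.NV; ++v) {
    area[v] = E.v_area[v]; c1[v] = E.v_c1[v]; c2[v] = E.v_c2[v];
    for (int k = 0; k < 3; ++k) {
      nrm(v, k) = E.v_norm[3*v+k]; T1(v, k) = E.v_T1[3*v+k]; T2(v, k) = E.v_T2[3*v+k];
    }
  }
  double vol = E.closed ? E.Vtot : NA_REAL;
  return List::create(_["area"] = area, _["normal"] = nrm,
                      _["c1"] = c1, _["c2"] = c2, _["T1"] = T1, _["T2"] = T2,
                      _["total_area"] = E.Atot, _["volume"] = vol);
}

// Sample the piecewise-linear surface height on a regular ng x ng grid over
// the periodic frame (barycentric interpolation; multiply covered grid
// points, e.g. under overhangs, are averaged).
// [[Rcpp::export]]
NumericMatrix cpp_sample_heights(NumericMatrix vertices, IntegerMatrix triangles,
                                 NumericVector boxL, int ng) {
  int nt = triangles.nrow();
  double Lx = boxL[0], Ly = boxL[1];
  double hx = Lx / ng, hy = Ly / ng;
  NumericMatrix z(ng, ng);
  NumericMatrix cnt(ng, ng);
  for (int t = 0; t < nt; ++t) {
    int a = triangles(t, 0) - 1, b = triangles(t, 1) - 1, c = triangles(t, 2) - 1;
    double p1[3] = {vertices(a, 0), vertices(a, 1), vertices(a, 2)};
    double d2[3] = {vertices(b, 0) - p1[0], vertices(b, 1) - p1[1], vertices(b, 2) - p1[2]};
    double d3[3] = {vertices(c, 0) - p1[0], vertices(c, 1) - p1[1], vertices(c, 2) - p1[2]};
    d2[0] -= Lx * std::nearbyint(d2[0] / Lx); d2[1] -= Ly * std::nearbyint(d2[1] / Ly);
    d3[0] -= Lx * std::nearbyint(d3[0] / Lx); d3[1] -= Ly * std::nearbyint(d3[1] / Ly);
    double det = d2[0] * d3[1] - d2[1] * d3[0];
    if (std::fabs(det) < 1e-14) continue;
    double xmin = std::min(0.0, std::min(d2[0], d3[0])) + p1[0];
    double xmax = std::max(0.0, std::max(d2[0], d3[0])) + p1[0];
    double ymin = std::min(0.0, std::min(d2[1], d3[1])) + p1[1];
    double ymax = std::max(0.0, std::max(d2[1], d3[1])) + p1[1];
    for (long gx = (long)std::ceil(xmin / hx - 1e-9); gx * hx <= xmax + 1e-9; ++gx) {
      for (long gy = (long)std::ceil(ymin / hy - 1e-9); gy * hy <= ymax + 1e-9; ++gy) {
        double rx = gx * hx - p1[0], ry = gy * hy - p1[1];
        double w2 = (rx * d3[1] - ry * d3[0]) / det;
        double w3 = (-rx * d2[1] + ry * d2[0]) / det;
        double w1 = 1.0 - w2 - w3;
        if (w1 < -1e-9 || w2 < -1e-9 || w3 < -1e-9) continue;
        double zz = w1 * p1[2] + w2 * (p1[2] + d2[2]) + w3 * (p1[2] + d3[2]);
        int ix = (int)(((gx % ng) + ng) % ng);
        int iy = (int)(((gy % ng) + ng) % ng);
        z(ix, iy) += zz;
        cnt(ix, iy) += 1.0;
      }
    }
  }
  for (int i = 0; i < ng; ++i)
    for (int j = 0; j < ng; ++j)
      if (cnt(i, j) > 0) z(i, j) /= cnt(i, j);
  return z;
}

// [[Rcpp::export]]
List cpp_run(List cfg, int n_sweeps, int record_every, int resync_every = 256) {
  Engine E;
  init_engine(E, cfg);

  long acc[4] = {0, 0, 0, 0}, tries[4] = {0, 0, 0, 0};
  int nrec = record_every > 0 ? n_sweeps / record_every : 0;
  List frames(nrec);
  NumericMatrix obs(nrec, 7); // sweep E A V Ap M Epair
  int irec = 0;

  for (int s = 1; s <= n_sweeps; ++s) {
    E.sweep(acc, tries);
    if (resync_every > 0 && s % resync_every == 0) E.full_recompute();
    if (record_every > 0 && s % record_every == 0 && irec < nrec) {
      NumericMatrix Vf(E.NV, 3);
      for (int v = 0; v < E.NV; ++v)
        for (int k = 0; k < 3; ++k) Vf(v, k) = E.X[3*v+k];
      IntegerMatrix Tf(E.NT, 3);
      for (int t = 0; t < E.NT; ++t)
        for (int k = 0; k < 3; ++k) Tf(t, k) = E.tri[3*t+k] + 1;
      frames[irec] = List::create(
        _["sweep"] = s, _["vertices"] = Vf, _["triangles"] = Tf,
        _["boxL"] = NumericVector::create(E.L[0], E.L[1], E.L[2]));
      obs(irec, 0) = s; obs(irec, 1) = E.total_E(); obs(irec, 2) = E.Atot;
      obs(irec, 3) = E.closed ? E.Vtot : NA_REAL; obs(irec, 4) = E.L[0]*E.L[1];
      obs(irec, 5) = E.Mtot; obs(irec, 6) = E.Epair;
      irec++;
    }
    if (s % 512 == 0) Rcpp::checkUserInterrupt();
  }
  E.full_recompute(); // exact caches for the returned state

  NumericMatrix Vout(E.NV, 3);
  for (int v = 0; v < E.NV; ++v)
    for (int k = 0; k < 3; ++k) Vout(v, k) = E.X[3*v+k];
  IntegerMatrix Tout(E.NT, 3);
  for (int t = 0; t < E.NT; ++t)
    for (int k = 0; k < 3; ++k) Tout(t, k) = E.tri[3*t+k] + 1;
  IntegerVector iv(E.NI);
  NumericMatrix idir(E.NI, 3);
  for (int i = 0; i < E.NI; ++i) {
    iv[i] = E.inc_vert[i] + 1;
    for (int k = 0; k < 3; ++k) idir(i, k) = E.inc_dir[3*i+k];
  }

  List en = List::create(
    _["total"] = E.total_E(), _["vertex"] = E.Evert, _["pair"] = E.Epair,
    _["area"] = E.area_E(E.Atot), _["volume"] = E.vol_E(E.Vtot, E.Atot),
    _["osmotic"] = E.osm_E(E.Vtot), _["global_curvature"] = E.gc_E(E.Mtot, E.Atot),
    _["tension"] = E.tension_E(), _["force"] = E.force_E());

  return List::create(
    _["vertices"] = Vout, _["triangles"] = Tout,
    _["boxL"] = NumericVector::create(E.L[0], E.L[1], E.L[2]),
    _["inclusion_vertex"] = iv, _["inclusion_dir"] = idir,
    _["acc"] = NumericVector::create(
      _["flip"] = (double)acc[0], _["vertex"] = (double)acc[1],
      _["inclusion"] = (double)acc[2], _["box"] = (double)acc[3]),
    _["tries"] = NumericVector::create(
      _["flip"] = (double)tries[0], _["vertex"] = (double)tries[1],
      _["inclusion"] = (double)tries[2], _["box"] = (double)tries[3]),
    _["energy"] = en,
    _["totals"] = NumericVector::create(
      _["A"] = E.Atot, _["V"] = E.closed ? E.Vtot : NA_REAL, _["M"] = E.Mtot,
      _["Ap"] = E.L[0] * E.L[1]),
    _["frames"] = frames, _["observables"] = obs);
}
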