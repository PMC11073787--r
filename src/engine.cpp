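// Monte Carlo reaction-diffusion core: volume molecules as Brownian point
// particles, surface molecules on barycentric grid tiles, per-collision
// reaction probabilities, network-free pathway lookup via R callbacks, and
// a fixed per-iteration event order (release -> diffuse/react -> count).
// All randomness comes from one seedable xoshiro256++ stream per world.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded through splitmix64; portable and reproducible.

struct Rng {
  uint64_t s[4];
  bool has_spare = false;
  double spare = 0.0;

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; i++) s[i] = splitmix(x);
    has_spare = false;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {  // Marsaglia polar, deterministic draw order
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f; has_spare = true;
    return u * f;
  }
  double expo(double rate) {
    if (rate <= 0.0) return INF;
    return -std::log(unif()) / rate;
  }
  int pick(int n) { return (int)(unif() * n) % n; }
};

// ---------------------------------------------------------------------------
// Small vector helpers

struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { return {x, y, z}; }
static inline V3 operator+(V3 a, V3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline V3 operator-(V3 a, V3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 operator*(V3 a, double s) { return {a.x * s, a.y * s, a.z * s}; }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm(V3 a) { return std::sqrt(dot(a, a)); }
static inline V3 unit(V3 a) { double n = norm(a); return n > 0 ? a * (1.0 / n) : a; }

// ---------------------------------------------------------------------------
// Geometry: Moller-Trumbore segment/triangle intersection

struct Hit { double t; int tri; int side; double u, v; };  // u,v barycentric on (v2,v3)

static bool seg_tri(const V3 &o, const V3 &d, const V3 &a, const V3 &b,
                    const V3 &c, Hit &h) {
  const double EPS = 1e-12;
  V3 e1 = b - a, e2 = c - a;
  V3 p = cross(d, e2);
  double det = dot(e1, p);
  if (std::fabs(det) < 1e-18) return false;
  double inv = 1.0 / det;
  V3 tv = o - a;
  double u = dot(tv, p) * inv;
  if (u < -EPS || u > 1 + EPS) return false;
  V3 q = cross(tv, e1);
  double v = dot(d, q) * inv;
  if (v < -EPS || u + v > 1 + EPS) return false;
  double t = dot(e2, q) * inv;
  if (t <= EPS || t > 1.0 + EPS) return false;
  h.t = std::min(t, 1.0);
  h.u = u; h.v = v;
  h.side = det > 0 ? 1 : -1;  // det>0: d opposes the outward normal => front-face hit
  return true;
}

struct Mesh {
  std::vector<V3> verts;
  std::vector<std::array<int,3>> tris;      // 0-based
  std::vector<int> tri_obj, tri_region;     // 1-based obj, 0 = no region
  std::vector<std::array<int,3>> tri_nbr;   // -1 = boundary; edge k: vk-v(k+1)
  std::vector<int> tri_n, tri_off;          // grid subdivision, tile offsets
  std::vector<double> tri_area;
  std::vector<V3> tri_v0, tri_e1, tri_e2, tri_normal;  // precomputed
  int n_tiles = 0;

  void precompute() {
    tri_v0.clear(); tri_e1.clear(); tri_e2.clear(); tri_normal.clear();
    for (size_t i = 0; i < tris.size(); i++) {
      const auto &t = tris[i];
      tri_v0.push_back(verts[t[0]]);
      tri_e1.push_back(verts[t[1]] - verts[t[0]]);
      tri_e2.push_back(verts[t[2]] - verts[t[0]]);
      tri_normal.push_back(unit(cross(tri_e1[i], tri_e2[i])));
    }
  }
  V3 normal(int i) const { return tri_normal[i]; }
  // fast segment-triangle test using precomputed edges
  bool seg_hit(int i, const V3 &o, const V3 &d, Hit &h) const {
    const double EPS = 1e-12;
    const V3 &e1 = tri_e1[i], &e2 = tri_e2[i];
    V3 p = cross(d, e2);
    double det = dot(e1, p);
    if (std::fabs(det) < 1e-18) return false;
    double inv = 1.0 / det;
    V3 tv = o - tri_v0[i];
    double u = dot(tv, p) * inv;
    if (u < -EPS || u > 1 + EPS) return false;
    V3 q = cross(tv, e1);
    double v = dot(d, q) * inv;
    if (v < -EPS || u + v > 1 + EPS) return false;
    double t = dot(e2, q) * inv;
    if (t <= EPS || t > 1.0 + EPS) return false;
    h.t = std::min(t, 1.0);
    h.u = u; h.v = v;
    h.side = det > 0 ? 1 : -1;
    h.tri = i;
    return true;
  }
  // barycentric weights (w2, w3) of point p in triangle i
  void bary(int i, const V3 &p, double &w2, double &w3) const {
    const auto &t = tris[i];
    V3 a = verts[t[0]], e1 = verts[t[1]] - a, e2 = verts[t[2]] - a, r = p - a;
    double d11 = dot(e1, e1), d12 = dot(e1, e2), d22 = dot(e2, e2);
    double r1 = dot(r, e1), r2 = dot(r, e2);
    double den = d11 * d22 - d12 * d12;
    w2 = (d22 * r1 - d12 * r2) / den;
    w3 = (d11 * r2 - d12 * r1) / den;
  }
  int tile_of(int tri, double w2, double w3) const {
    int n = tri_n[tri];
    double x = n * w2, y = n * w3;
    int i = std::max(0, std::min((int)std::floor(x), n - 1));
    int j = std::max(0, std::min((int)std::floor(y), n - 1));
    bool down = (x - i) + (y - j) > 1.0;
    if (i + j > n - 1 || (down && i + j > n - 2)) {
      down = false;
      if (i + j > n - 1) {
        int s = i + j - (n - 1);
        i = std::max(0, i - s); j = (n - 1) - i;
      }
    }
    return j * (2 * n - j) + 2 * i + (down ? 1 : 0);
  }
  // center of tile (scaled barycentric corners averaged)
  V3 tile_center(int tri, int tile) const {
    int n = tri_n[tri];
    int j = 0, k = tile;
    while (k >= 2 * (n - j) - 1) { k -= 2 * (n - j) - 1; j++; }
    int i = k / 2;
    bool up = (k % 2) == 0;
    double ci, cj;
    if (up) { ci = (3 * i + 1) / (3.0 * n); cj = (3 * j + 1) / (3.0 * n); }
    else    { ci = (3 * i + 2) / (3.0 * n); cj = (3 * j + 2) / (3.0 * n); }
    const auto &t = tris[tri];
    V3 a = verts[t[0]];
    return a + (verts[t[1]] - a) * ci + (verts[t[2]] - a) * cj;
  }
  double tile_area(int tri) const {
    return tri_area[tri] / ((double)tri_n[tri] * tri_n[tri]);
  }
};

// decompose tile index -> (i, j, up)
static inline void tile_ij(int n, int tile, int &i, int &j, bool &up) {
  j = 0; int k = tile;
  while (k >= 2 * (n - j) - 1) { k -= 2 * (n - j) - 1; j++; }
  i = k / 2; up = (k % 2) == 0;
}
static inline int tile_idx(int n, int i, int j, bool up) {
  return j * (2 * n - j) + 2 * i + (up ? 0 : 1);
}

// tiles of triangle `tri` lying on its edge e (0: v0-v1, 1: v1-v2, 2: v2-v0)
// with their [s0,s1] interval along the edge (s from first to second vertex)
struct EdgeTile { int tile; double s0, s1; };
static void edge_tiles(const Mesh &M, int tri, int e, std::vector<EdgeTile> &out) {
  int n = M.tri_n[tri];
  out.clear();
  for (int q = 0; q < n; q++) {
    if (e == 0) {          // j == 0 upward tiles, s along v0->v1 is w2
      out.push_back({tile_idx(n, q, 0, true), q / (double)n, (q + 1) / (double)n});
    } else if (e == 1) {   // diagonal (w1 = 0): up tiles i + j = n-1, s = w3
      int j = q;
      out.push_back({tile_idx(n, n - 1 - j, j, true), j / (double)n, (j + 1) / (double)n});
    } else {               // e == 2, w2 = 0, s along v2->v0 = 1 - w3
      int j = q;
      out.push_back({tile_idx(n, 0, j, true), 1.0 - (j + 1) / (double)n, 1.0 - j / (double)n});
    }
  }
}

// find which edge of `nb` is shared with edge e of `tri` (by vertex ids)
static int shared_edge_of(const Mesh &M, int tri, int e, int nb) {
  int a = M.tris[tri][e], b = M.tris[tri][(e + 1) % 3];
  for (int k = 0; k < 3; k++) {
    int c = M.tris[nb][k], d = M.tris[nb][(k + 1) % 3];
    if ((c == a && d == b) || (c == b && d == a)) return k;
  }
  return -1;
}

// ---------------------------------------------------------------------------
// Pathways

struct Pathway {
  double rate;            // internal units (um^3/N/s, um^2/N/s, or 1/s)
  int context;            // 0 unimol, 1 vol bimol (incl vol-surf), 2 surf-surf
  int rule;               // 1-based rule index
  std::vector<int> prods; // 1-based species ids
  bool dyn = false;       // hybrid-coupled rate
  double dyncoef = 0.0;
};

struct Engine;

struct PStats { double maxp = 0, sump = 0, excess = 0; double ntests = 0; };

struct Engine {
  // config
  double dt, rint, eps_len = 1e-12;
  int n_iter, iter0, count_stride, cleanup_interval;
  double time0;
  double vs_const, ss_const;
  Rng rng;

  // species
  std::vector<double> spD;     // cm^2/s
  std::vector<int> spdim, spcomp;
  std::vector<std::vector<double>> obsmat;  // per species: n_obs values
  int n_obs = 0;
  std::vector<int> obs_scope, obs_rule;
  std::vector<long long> sp_count;

  // molecules (structure of arrays); alive flag, stable ids
  struct Vol { int id, sp, comp, born; V3 p; double tun; bool alive; };
  struct Surf { int id, sp, tri, tile, born; double tun; bool alive; };
  std::vector<Vol> vol;
  std::vector<Surf> surf;
  std::unordered_map<int,int> surf_slot;  // mol id -> index in surf
  int next_id = 1;

  // geometry
  bool has_geom = false;
  Mesh M;
  std::vector<int> occup;                 // tile -> mol id (0 empty)
  std::vector<int> obj_comp_in, obj_comp_out, obj_surf_comp;
  std::vector<int> region_edge_reflective; // by region id (1-based), 0/1
  // surface classes: key = species*1e6 + obj*1e3 + region  -> behavior
  std::unordered_map<long long,int> surf_class;
  V3 aabb_min, aabb_max;

  // reaction caches
  Function *bimol_provider = nullptr, *unimol_provider = nullptr;
  std::unordered_map<long long, std::vector<Pathway>> bimol;
  std::unordered_map<int, std::vector<Pathway>> unimol;
  std::unordered_map<int, double> unimol_ktot;
  std::unordered_map<int, bool> unimol_dyn;

  // rules / stats
  int n_rules = 0;
  std::vector<double> fired, fired_prev;
  std::vector<PStats> pstats;
  std::vector<std::string> warnings;

  // callbacks
  struct RxnCb { int rule; Function fn; RObject ctx; };
  struct WallCb { int sp, obj; Function fn; RObject ctx; };
  std::vector<RxnCb> rxn_cbs;
  std::vector<WallCb> wall_cbs;

  // hybrid
  bool has_hybrid = false;
  double hyb_value = 0, hyb_decay = 0, hyb_coupled_coef = 0;
  int hyb_coupled_rule = 0;
  bool hyb_warned = false;
  std::vector<int> hyb_prod_sp, hyb_cons_sp, hyb_gain_rules;
  std::vector<double> hyb_prod_coef, hyb_cons_coef;

  // outputs
  std::vector<double> count_rows;
  int count_ncol = 0;

  // scratch buffers reused across molecule steps
  struct Ev { double t; int kind; int idx; };
  std::vector<Hit> sc_hits;
  std::vector<Ev> sc_evs;
  std::vector<int> sc_tested;
  std::vector<int> gr_cnt, gr_cidx, gr_fill, gr_cells, gr_grid;

  double now = 0;
  int cur_iter = 0;

  // ---------- species bookkeeping
  void grow_species(List ns) {
    NumericVector D = ns["D"]; IntegerVector dim = ns["dim"], comp = ns["comp"];
    NumericMatrix om = ns["obs"];
    for (int i = 0; i < D.size(); i++) {
      spD.push_back(D[i]); spdim.push_back(dim[i]); spcomp.push_back(comp[i]);
      std::vector<double> row(n_obs, 0.0);
      for (int o = 0; o < n_obs && o < om.ncol(); o++) row[o] = om(i, o);
      obsmat.push_back(row);
      sp_count.push_back(0);
    }
  }

  std::vector<Pathway> parse_pathways(List pws) {
    std::vector<Pathway> out;
    if (pws.size() == 0) return out;
    NumericVector rate = pws["rate"];
    IntegerVector ctx = pws["context"], rule = pws["rule"];
    List prods = pws["prods"];
    NumericVector dyn = pws.containsElementNamed("dyncoef") ?
      NumericVector(pws["dyncoef"]) : NumericVector(rate.size());
    for (int i = 0; i < rate.size(); i++) {
      Pathway p;
      p.rate = rate[i]; p.context = ctx[i]; p.rule = rule[i];
      IntegerVector pr = prods[i];
      for (int k = 0; k < pr.size(); k++) p.prods.push_back(pr[k]);
      if (dyn[i] != 0) { p.dyn = true; p.dyncoef = dyn[i]; }
      out.push_back(p);
    }
    return out;
  }

  const std::vector<Pathway> &get_bimol(int a, int b) {
    long long key = a <= b ? ((long long)a << 24) | b : ((long long)b << 24) | a;
    auto it = bimol.find(key);
    if (it != bimol.end()) return it->second;
    List res = (*bimol_provider)(a, b);
    if (res.containsElementNamed("new_species"))
      grow_species(res["new_species"]);
    bimol[key] = parse_pathways(res["pw"]);
    return bimol[key];
  }
  const std::vector<Pathway> &get_unimol(int a) {
    auto it = unimol.find(a);
    if (it != unimol.end()) return it->second;
    List res = (*unimol_provider)(a);
    if (res.containsElementNamed("new_species"))
      grow_species(res["new_species"]);
    std::vector<Pathway> pw = parse_pathways(res["pw"]);
    double ktot = 0; bool dyn = false;
    for (auto &p : pw) { ktot += effective_rate(p); if (p.dyn) dyn = true; }
    unimol[a] = pw;
    unimol_ktot[a] = ktot;
    unimol_dyn[a] = dyn;
    return unimol[a];
  }
  double effective_rate(const Pathway &p) {
    return p.dyn ? p.dyncoef * hyb_value : p.rate;
  }
  double unimol_rate(int sp) {
    get_unimol(sp);
    if (!unimol_dyn[sp]) return unimol_ktot[sp];
    double k = 0;
    for (auto &p : unimol[sp]) k += effective_rate(p);
    return k;
  }

  // mean diffusion step length (um) of species
  double lbar(int sp) {
    double Dum = spD[sp - 1] * 1e8;
    return std::sqrt(16.0 * Dum * dt / M_PI);
  }
  // per-collision probability, volume-volume
  double p_vv(const Pathway &pw, int spA, int spB) {
    double den = M_PI * rint * rint * (lbar(spA) + lbar(spB));
    if (den <= 0) return pw.rate > 0 ? 2.0 : 0.0;  // degenerate => force warn
    return pw.rate * dt / den;
  }
  // per-wall-hit probability, volume-surface (k in um^3/N/s)
  double p_vs(const Pathway &pw, int sp_vol, double tile_area) {
    double Dum = spD[sp_vol - 1] * 1e8;
    double den = vs_const * tile_area * std::sqrt(Dum * dt / M_PI);
    if (den <= 0) return pw.rate > 0 ? 2.0 : 0.0;
    return pw.rate * dt / den;
  }
  // per-contact probability, surface-surface (k in um^2/N/s)
  double p_ss(const Pathway &pw, double tile_area) {
    return pw.rate * dt / (ss_const * tile_area);
  }
  void record_p(int rule, double p) {
    PStats &s = pstats[rule - 1];
    if (p > s.maxp) s.maxp = p;
    s.sump += p;
    if (p > 1) s.excess += p - 1;
    s.ntests += 1;
  }

  // ---------- molecule management
  void sched_unimol_vol(Vol &m) {
    double k = unimol_rate(m.sp);
    m.tun = now + rng.expo(k);
  }
  void sched_unimol_surf(Surf &m) {
    double k = unimol_rate(m.sp);
    m.tun = now + rng.expo(k);
  }
  int add_vol(int sp, V3 p, int comp, int born) {
    Vol m; m.id = next_id++; m.sp = sp; m.p = p;
    m.comp = comp ? comp : spcomp[sp - 1];
    m.born = born; m.alive = true; m.tun = 0;
    sched_unimol_vol(m);
    vol.push_back(m);
    sp_count[sp - 1]++;
    return m.id;
  }
  int add_surf(int sp, int tri, int tile, int born) {
    Surf m; m.id = next_id++; m.sp = sp; m.tri = tri; m.tile = tile;
    m.born = born; m.alive = true; m.tun = 0;
    sched_unimol_surf(m);
    occup[M.tri_off[tri] + tile] = m.id;
    surf_slot[m.id] = (int)surf.size();
    surf.push_back(m);
    sp_count[sp - 1]++;
    return m.id;
  }
  void kill_vol(Vol &m) {
    if (!m.alive) return;
    m.alive = false; sp_count[m.sp - 1]--;
  }
  void kill_surf(Surf &m) {
    if (!m.alive) return;
    m.alive = false; sp_count[m.sp - 1]--;
    occup[M.tri_off[m.tri] + m.tile] = 0;
  }

  int surface_class(int sp, int obj, int region) {
    // most specific first: (sp,obj,region), (sp,obj,0), (0,obj,region), (0,obj,0)
    long long keys[4] = {
      (long long)sp * 1000000LL + obj * 1000LL + region,
      (long long)sp * 1000000LL + obj * 1000LL,
      (long long)obj * 1000LL + region,
      (long long)obj * 1000LL };
    for (int i = 0; i < 4; i++) {
      auto it = surf_class.find(keys[i]);
      if (it != surf_class.end()) return it->second;
    }
    return 0;  // reflective
  }

  // ---------- callbacks
  void fire_rxn_callbacks(int rule, V3 at) {
    for (auto &cb : rxn_cbs) {
      if (cb.rule != 0 && cb.rule != rule) continue;
      RObject res = cb.fn(now, rule, NumericVector::create(at.x, at.y, at.z),
                          cb.ctx);
      if (res.isNULL()) continue;
      List lr(res);
      if (lr.containsElementNamed("create")) {
        List cr = lr["create"];
        IntegerVector sp = cr["sp"];
        NumericVector x = cr["x"], y = cr["y"], z = cr["z"];
        for (int i = 0; i < sp.size(); i++)
          add_vol(sp[i], v3(x[i], y[i], z[i]), 0, cur_iter);
      }
    }
  }
  void fire_wall_callbacks(int sp, int tri, V3 at) {
    for (auto &cb : wall_cbs) {
      if (cb.sp != 0 && cb.sp != sp) continue;
      if (cb.obj != 0 && cb.obj != M.tri_obj[tri]) continue;
      cb.fn(now, sp, tri + 1, NumericVector::create(at.x, at.y, at.z), cb.ctx);
    }
  }

  // ---------- reaction execution
  // consume reactants (already killed by caller), place products
  void place_products(const Pathway &pw, V3 at, int vol_comp, int side_tri,
                      int side_sign, int surf_tri, int surf_tile) {
    bool tile_used = false;
    for (int sp : pw.prods) {
      if (spdim[sp - 1] == 3) {
        V3 pos = at;
        if (side_tri >= 0) {
          V3 n = M.normal(side_tri);
          int sgn = side_sign;
          int pc = spcomp[sp - 1];
          if (pc && M.tri_obj[side_tri] >= 1) {
            int obj = M.tri_obj[side_tri];
            if (pc == obj_comp_in[obj - 1]) sgn = -1;
            else if (pc == obj_comp_out[obj - 1]) sgn = 1;
          }
          pos = at + n * (1e-9 * sgn);
        }
        add_vol(sp, pos, vol_comp, cur_iter);
      } else {
        int tri = surf_tri, tile = surf_tile;
        if (tri < 0) { warnings.push_back("surface product with no tile context"); continue; }
        if (tile_used || occup[M.tri_off[tri] + tile] != 0) {
          int atri, atile;
          if (!find_vacant_adjacent(tri, tile, atri, atile)) {
            warnings.push_back("no vacant tile for surface product");
            continue;
          }
          tri = atri; tile = atile;
        }
        add_surf(sp, tri, tile, cur_iter);
        tile_used = true;
      }
    }
  }

  bool find_vacant_adjacent(int tri, int tile, int &otri, int &otile) {
    std::vector<std::pair<int,int>> adj;
    adjacent_tiles(tri, tile, adj);
    for (auto &a : adj) {
      if (occup[M.tri_off[a.first] + a.second] == 0) {
        otri = a.first; otile = a.second; return true;
      }
    }
    return false;
  }

  // edge-sharing tiles, including across triangle boundaries
  void adjacent_tiles(int tri, int tile, std::vector<std::pair<int,int>> &out) {
    out.clear();
    int n = M.tri_n[tri];
    int i, j; bool up;
    tile_ij(n, tile, i, j, up);
    if (up) {
      if (i + j < n - 1) out.push_back({tri, tile_idx(n, i, j, false)});
      if (i > 0) out.push_back({tri, tile_idx(n, i - 1, j, false)});
      if (j > 0) out.push_back({tri, tile_idx(n, i, j - 1, false)});
      // boundary edges
      if (j == 0) cross_edge_tiles(tri, 0, i / (double)n, (i + 1.0) / n, out);
      if (i == 0) cross_edge_tiles(tri, 2, 1.0 - (j + 1.0) / n, 1.0 - j / (double)n, out);
      if (i + j == n - 1) cross_edge_tiles(tri, 1, j / (double)n, (j + 1.0) / n, out);
    } else {
      out.push_back({tri, tile_idx(n, i, j, true)});
      if (i + 1 + j <= n - 1) out.push_back({tri, tile_idx(n, i + 1, j, true)});
      if (j + 1 <= n - 1 && i + j + 1 <= n - 1)
        out.push_back({tri, tile_idx(n, i, j + 1, true)});
    }
  }
  void cross_edge_tiles(int tri, int e, double s0, double s1,
                        std::vector<std::pair<int,int>> &out) {
    int nb = M.tri_nbr[tri][e];
    if (nb < 0) return;
    int e2 = shared_edge_of(M, tri, e, nb);
    if (e2 < 0) return;
    std::vector<EdgeTile> et;
    edge_tiles(M, nb, e2, et);
    // neighbor's edge runs opposite: s' = 1 - s
    double t0 = 1.0 - s1, t1 = 1.0 - s0;
    for (auto &x : et) {
      if (x.s1 > t0 + 1e-12 && x.s0 < t1 - 1e-12)
        out.push_back({nb, x.tile});
    }
  }

  // ---------- unimolecular firing
  void fire_unimol_vol(Vol &m) {
    const std::vector<Pathway> &pw = get_unimol(m.sp);
    if (pw.empty()) { m.tun = INF; return; }
    double ktot = 0; for (auto &p : pw) ktot += effective_rate(p);
    if (ktot <= 0) { m.tun = INF; return; }
    double u = rng.unif() * ktot, acc = 0;
    const Pathway *sel = &pw[0];
    for (auto &p : pw) { acc += effective_rate(p); if (u <= acc) { sel = &p; break; } }
    double at_time = m.tun;
    now = at_time;
    kill_vol(m);
    place_products(*sel, m.p, m.comp, -1, 1, -1, -1);
    fired[sel->rule - 1] += 1;
    fire_rxn_callbacks(sel->rule, m.p);
  }
  void fire_unimol_surf(Surf &m) {
    const std::vector<Pathway> &pw = get_unimol(m.sp);
    if (pw.empty()) { m.tun = INF; return; }
    double ktot = 0; for (auto &p : pw) ktot += effective_rate(p);
    if (ktot <= 0) { m.tun = INF; return; }
    double u = rng.unif() * ktot, acc = 0;
    const Pathway *sel = &pw[0];
    for (auto &p : pw) { acc += effective_rate(p); if (u <= acc) { sel = &p; break; } }
    now = m.tun;
    V3 at = M.tile_center(m.tri, m.tile);
    int tri = m.tri, tile = m.tile;
    kill_surf(m);
    place_products(*sel, at, 0, tri, 1, tri, tile);
    fired[sel->rule - 1] += 1;
    fire_rxn_callbacks(sel->rule, at);
  }

  // ---------- volume diffusion with collisions and walls
  void diffuse_vol(Vol &m, const std::vector<int> &grid,
                   const std::vector<int> &cellstart, int gx, int gy, int gz,
                   double cell, V3 gmin) {
    double Dum = spD[m.sp - 1] * 1e8;
    double sd = std::sqrt(2.0 * Dum * dt);
    if (sd == 0) return;
    V3 d = v3(sd * rng.gauss(), sd * rng.gauss(), sd * rng.gauss());
    V3 p = m.p;
    for (int bounce = 0; bounce < 64; bounce++) {
      double dlen = norm(d);
      if (dlen < 1e-15) break;
      // wall hits
      std::vector<Hit> &hits = sc_hits;
      hits.clear();
      if (has_geom) {
        Hit h;
        for (int ti = 0; ti < (int)M.tris.size(); ti++)
          if (M.seg_hit(ti, p, d, h)) hits.push_back(h);
        std::sort(hits.begin(), hits.end(),
                  [](const Hit &a, const Hit &b) {
                    return a.t < b.t || (a.t == b.t && a.tri < b.tri); });
        // grazing dedup: keep lowest-index triangle for near-equal t
        size_t w = 0;
        for (size_t r = 0; r < hits.size(); r++) {
          if (w > 0 && std::fabs(hits[w - 1].t - hits[r].t) < 1e-12) continue;
          hits[w++] = hits[r];
        }
        hits.resize(w);
      }
      // partner candidates along segment
      std::vector<Ev> &evs = sc_evs;
      evs.clear();
      double inv2 = 1.0 / (dlen * dlen);
      // grid query over AABB of segment +- rint
      V3 lo = v3(std::min(p.x, p.x + d.x) - rint, std::min(p.y, p.y + d.y) - rint,
                 std::min(p.z, p.z + d.z) - rint);
      V3 hi = v3(std::max(p.x, p.x + d.x) + rint, std::max(p.y, p.y + d.y) + rint,
                 std::max(p.z, p.z + d.z) + rint);
      // one extra cell each way: partners are binned by their
      // iteration-start position but may have moved up to a step length
      int x0 = std::max(0, (int)((lo.x - gmin.x) / cell) - 1);
      int y0 = std::max(0, (int)((lo.y - gmin.y) / cell) - 1);
      int z0 = std::max(0, (int)((lo.z - gmin.z) / cell) - 1);
      int x1 = std::min(gx - 1, (int)((hi.x - gmin.x) / cell) + 1);
      int y1 = std::min(gy - 1, (int)((hi.y - gmin.y) / cell) + 1);
      int z1 = std::min(gz - 1, (int)((hi.z - gmin.z) / cell) + 1);
      for (int cx = x0; cx <= x1; cx++)
      for (int cy = y0; cy <= y1; cy++)
      for (int cz = z0; cz <= z1; cz++) {
        int c = (cz * gy + cy) * gx + cx;
        for (int q = cellstart[c]; q < cellstart[c + 1]; q++) {
          int vi = grid[q];
          Vol &o = vol[vi];
          if (!o.alive || o.id == m.id || o.born >= cur_iter) continue;
          V3 r = o.p - p;
          double tp = dot(r, d) * inv2;
          // cylinder sweep only (no end caps): matches the derivation of
          // the per-collision probability p = k dt / (pi r^2 (lA + lB))
          if (tp < 0 || tp > 1) continue;
          V3 close = p + d * tp;
          if (norm(o.p - close) <= rint) evs.push_back({tp, 0, vi});
        }
      }
      for (int hi2 = 0; hi2 < (int)hits.size(); hi2++)
        evs.push_back({hits[hi2].t, 1, hi2});
      std::sort(evs.begin(), evs.end(), [](const Ev &a, const Ev &b) {
        return a.t < b.t || (a.t == b.t && a.kind < b.kind); });

      bool resegment = false;
      for (auto &ev : evs) {
        if (ev.kind == 0) {
          Vol &o = vol[ev.idx];
          if (!o.alive) continue;
          const std::vector<Pathway> &pws = get_bimol(m.sp, o.sp);
          if (pws.empty()) continue;
          double ptot = 0;
          for (auto &pw2 : pws) ptot += p_vv(pw2, m.sp, o.sp);
          if (pws.size()) record_p(pws[0].rule, ptot);
          if (ptot <= 0) continue;
          double u = rng.unif();
          if (u < ptot) {
            double acc = 0; const Pathway *sel = &pws[0];
            for (auto &pw2 : pws) { acc += p_vv(pw2, m.sp, o.sp); if (u <= acc) { sel = &pw2; break; } }
            V3 at = p + d * ev.t;
            int comp = m.comp;
            kill_vol(m); kill_vol(o);
            place_products(*sel, at, comp, -1, 1, -1, -1);
            fired[sel->rule - 1] += 1;
            fire_rxn_callbacks(sel->rule, at);
            return;
          }
        } else {
          Hit &h = hits[ev.idx];
          int tri = h.tri, obj = M.tri_obj[tri], reg = M.tri_region[tri];
          V3 at = p + d * h.t;
          fire_wall_callbacks(m.sp, tri, at);
          int beh = surface_class(m.sp, obj, reg);
          if (beh == 1) {  // transparent: update compartment, keep going
            if (obj >= 1) {
              int into = h.side > 0 ? obj_comp_in[obj - 1] : obj_comp_out[obj - 1];
              if (into) m.comp = into;
            }
            continue;
          }
          if (beh == 2) {  // absorptive
            kill_vol(m);
            return;
          }
          // reflective wall; check for a surface partner on the hit tile
          double w2, w3;
          M.bary(tri, at, w2, w3);
          int tile = M.tile_of(tri, w2, w3);
          int occ_id = occup[M.tri_off[tri] + tile];
          if (occ_id) {
            Surf &o = surf[surf_slot[occ_id]];
            if (o.alive && o.born < cur_iter) {
              const std::vector<Pathway> &pws = get_bimol(m.sp, o.sp);
              double ta = M.tile_area(tri);
              double ptot = 0;
              for (auto &pw2 : pws) ptot += p_vs(pw2, m.sp, ta);
              if (pws.size()) record_p(pws[0].rule, ptot);
              if (ptot > 0) {
                double u = rng.unif();
                if (u < ptot) {
                  double acc = 0; const Pathway *sel = &pws[0];
                  for (auto &pw2 : pws) { acc += p_vs(pw2, m.sp, ta); if (u <= acc) { sel = &pw2; break; } }
                  int comp = m.comp;
                  kill_vol(m); kill_surf(o);
                  place_products(*sel, at, comp, tri, h.side, tri, tile);
                  fired[sel->rule - 1] += 1;
                  fire_rxn_callbacks(sel->rule, at);
                  return;
                }
              }
            }
          }
          // specular reflection; advance an epsilon along the reflected
          // direction so a near-corner bounce cannot tunnel through the
          // adjacent face
          V3 nrm = M.normal(tri);
          V3 drem = d * (1.0 - h.t);
          V3 dref = drem - nrm * (2.0 * dot(drem, nrm));
          double rl = norm(dref);
          double adv = std::min(1e-9, 0.5 * rl);
          p = at + (rl > 0 ? dref * (adv / rl) : nrm * (h.side > 0 ? adv : -adv));
          d = dref * (rl > 0 ? (1.0 - adv / rl) : 0.0);
          resegment = true;
          break;
        }
      }
      if (!resegment) { p = p + d; break; }
    }
    m.p = p;
  }

  // ---------- surface diffusion
  void diffuse_surf(Surf &m) {
    double Dum = spD[m.sp - 1] * 1e8;
    if (Dum <= 0) { surf_partners(m); return; }
    double sd = std::sqrt(2.0 * Dum * dt);
    int tri = m.tri;
    V3 p = M.tile_center(tri, m.tile);
    // local in-plane displacement
    const auto &tv = M.tris[tri];
    V3 e1 = unit(M.verts[tv[1]] - M.verts[tv[0]]);
    V3 nr = M.normal(tri);
    V3 e2 = cross(nr, e1);
    V3 d = e1 * (sd * rng.gauss()) + e2 * (sd * rng.gauss());
    for (int bounce = 0; bounce < 64; bounce++) {
      if (norm(d) < 1e-15) break;
      // exit parameter: barycentric weights linear along the segment
      double w2a, w3a, w2b, w3b;
      M.bary(tri, p, w2a, w3a);
      M.bary(tri, p + d, w2b, w3b);
      double w1a = 1 - w2a - w3a, w1b = 1 - w2b - w3b;
      double tmin = 2; int edge = -1;
      // w1 = 0 -> edge 1 (v1-v2); w2 = 0 -> edge 2 (v2-v0); w3 = 0 -> edge 0
      if (w1b < 0) { double t = w1a / (w1a - w1b); if (t < tmin) { tmin = t; edge = 1; } }
      if (w2b < 0) { double t = w2a / (w2a - w2b); if (t < tmin) { tmin = t; edge = 2; } }
      if (w3b < 0) { double t = w3a / (w3a - w3b); if (t < tmin) { tmin = t; edge = 0; } }
      if (edge < 0) { p = p + d; break; }
      V3 exitp = p + d * tmin;
      V3 drem = d * (1.0 - tmin);
      int nb = M.tri_nbr[tri][edge];
      bool reflect = nb < 0;
      if (!reflect) {
        int reg = M.tri_region[tri], reg2 = M.tri_region[nb];
        if (reg >= 1 && reg != reg2 &&
            reg <= (int)region_edge_reflective.size() - 1 &&
            region_edge_reflective[reg])
          reflect = true;
      }
      if (reflect) {
        V3 ev = unit(M.verts[M.tris[tri][(edge + 1) % 3]] -
                     M.verts[M.tris[tri][edge]]);
        V3 dpar = ev * dot(drem, ev);
        d = dpar * 2.0 - drem;
        // nudge inside
        p = exitp + unit(d) * 1e-12;
        continue;
      }
      // unfold into neighbor plane
      V3 ev = unit(M.verts[M.tris[tri][(edge + 1) % 3]] -
                   M.verts[M.tris[tri][edge]]);
      V3 n1 = M.normal(tri), n2 = M.normal(nb);
      double c = dot(n1, n2);
      if (c > 1) c = 1; if (c < -1) c = -1;
      double s = dot(cross(n1, n2), ev);
      // Rodrigues rotation of drem about axis ev by the dihedral angle
      V3 dnew = drem * c + cross(ev, drem) * s + ev * (dot(ev, drem) * (1 - c));
      p = exitp;
      d = dnew;
      tri = nb;
    }
    // land on tile
    double w2, w3;
    M.bary(tri, p, w2, w3);
    int tile = M.tile_of(tri, w2, w3);
    int dst = M.tri_off[tri] + tile;
    if (occup[dst] == 0) {
      occup[M.tri_off[m.tri] + m.tile] = 0;
      m.tri = tri; m.tile = tile;
      occup[dst] = m.id;
    } else if (occup[dst] != m.id) {
      // destination occupied: stay at origin tile
    }
    surf_partners(m);
  }

  void surf_partners(Surf &m) {
    std::vector<std::pair<int,int>> adj;
    adjacent_tiles(m.tri, m.tile, adj);
    std::sort(adj.begin(), adj.end());
    for (auto &a : adj) {
      int occ_id = occup[M.tri_off[a.first] + a.second];
      if (!occ_id || occ_id == m.id) continue;
      Surf &o = surf[surf_slot[occ_id]];
      if (!o.alive || o.born >= cur_iter) continue;
      const std::vector<Pathway> &pws = get_bimol(m.sp, o.sp);
      if (pws.empty()) continue;
      double ta = M.tile_area(m.tri);
      double ptot = 0;
      for (auto &pw2 : pws) ptot += p_ss(pw2, ta);
      record_p(pws[0].rule, ptot);
      if (ptot <= 0) continue;
      double u = rng.unif();
      if (u < ptot) {
        double acc = 0; const Pathway *sel = &pws[0];
        for (auto &pw2 : pws) { acc += p_ss(pw2, ta); if (u <= acc) { sel = &pw2; break; } }
        V3 at = M.tile_center(m.tri, m.tile);
        int tri = m.tri, tile = m.tile;
        kill_surf(m); kill_surf(o);
        place_products(*sel, at, 0, tri, 1, tri, tile);
        fired[sel->rule - 1] += 1;
        fire_rxn_callbacks(sel->rule, at);
        return;
      }
    }
  }

  // ---------- counting
  void record_counts() {
    count_rows.push_back(now);
    for (int o = 0; o < n_obs; o++) {
      double val = 0;
      if (obs_rule[o] > 0) {
        val = fired[obs_rule[o] - 1];
      } else {
        for (auto &m : vol) {
          if (!m.alive) continue;
          double w = obsmat[m.sp - 1][o];
          if (w == 0) continue;
          if (obs_scope[o] == 0 || obs_scope[o] == m.comp) val += w;
        }
        for (auto &m : surf) {
          if (!m.alive) continue;
          double w = obsmat[m.sp - 1][o];
          if (w == 0) continue;
          if (obs_scope[o] == 0 || obs_scope[o] == spcomp[m.sp - 1])
            val += w;
        }
      }
      count_rows.push_back(val);
    }
    if (has_hybrid) count_rows.push_back(hyb_value);
  }

  // ---------- cleanup: drop cached classes that reference dead species
  int cleanup() {
    std::vector<char> dead(spD.size() + 1, 0);
    bool any = false;
    for (size_t i = 0; i < spD.size(); i++)
      if (sp_count[i] == 0) { dead[i + 1] = 1; any = true; }
    if (!any) return 0;
    int evicted = 0;
    for (auto it = bimol.begin(); it != bimol.end();) {
      int a = (int)(it->first >> 24), b = (int)(it->first & 0xFFFFFF);
      bool drop = dead[a] || dead[b];
      if (!drop) for (auto &p : it->second)
        for (int pr : p.prods) if (dead[pr]) { drop = true; break; }
      if (drop) { it = bimol.erase(it); evicted++; } else ++it;
    }
    for (auto it = unimol.begin(); it != unimol.end();) {
      bool drop = dead[it->first];
      if (!drop) for (auto &p : it->second)
        for (int pr : p.prods) if (dead[pr]) { drop = true; break; }
      if (drop) {
        unimol_ktot.erase(it->first); unimol_dyn.erase(it->first);
        it = unimol.erase(it); evicted++;
      } else ++it;
    }
    return evicted;
  }
};

// ---------------------------------------------------------------------------

static Mesh build_mesh(List g) {
  Mesh M;
  NumericMatrix verts = g["verts"];
  IntegerMatrix tris = g["tris"];
  for (int i = 0; i < verts.nrow(); i++)
    M.verts.push_back(v3(verts(i,0), verts(i,1), verts(i,2)));
  IntegerVector tobj = g["tri_obj"], treg = g["tri_region"],
                tn = g["tri_n"], toff = g["tri_off"];
  IntegerMatrix tnbr = g["tri_nbr"];
  for (int i = 0; i < tris.nrow(); i++) {
    M.tris.push_back({tris(i,0) - 1, tris(i,1) - 1, tris(i,2) - 1});
    M.tri_obj.push_back(tobj[i]);
    M.tri_region.push_back(treg[i]);
    M.tri_nbr.push_back({tnbr(i,0) - 1, tnbr(i,1) - 1, tnbr(i,2) - 1});
    M.tri_n.push_back(tn[i]);
    M.tri_off.push_back(toff[i]);
    V3 a = M.verts[M.tris[i][0]], b = M.verts[M.tris[i][1]], c = M.verts[M.tris[i][2]];
    M.tri_area.push_back(0.5 * norm(cross(b - a, c - a)));
  }
  M.n_tiles = as<int>(g["n_tiles"]);
  M.precompute();
  return M;
}

// [[Rcpp::export]]
List cpp_run_engine(List st, List providers, List callbacks) {
  Engine E;
  List cfg = st["cfg"];
  E.dt = as<double>(cfg["dt"]);
  E.rint = as<double>(cfg["rint"]);
  E.n_iter = as<int>(cfg["n_iter"]);
  E.iter0 = as<int>(cfg["iter0"]);
  E.time0 = as<double>(cfg["time0"]);
  E.count_stride = as<int>(cfg["count_stride"]);
  E.cleanup_interval = as<int>(cfg["cleanup_interval"]);
  E.vs_const = as<double>(cfg["vs_const"]);
  E.ss_const = as<double>(cfg["ss_const"]);
  RawVector rs = cfg["rng_state"];
  bool fresh = true;
  for (int i = 0; i < rs.size(); i++) if (rs[i] != 0) { fresh = false; break; }
  if (fresh) {
    E.rng.seed((uint64_t)as<double>(cfg["seed"]));
  } else {
    for (int i = 0; i < 4; i++) {
      uint64_t w = 0;
      for (int b = 0; b < 8; b++) w |= ((uint64_t)rs[i * 8 + b]) << (8 * b);
      E.rng.s[i] = w;
    }
  }
  E.now = E.time0;

  List sp = st["species"];
  {
    NumericVector D = sp["D"]; IntegerVector dim = sp["dim"], comp = sp["comp"];
    NumericMatrix om = st["obsmat"];
    E.n_obs = om.ncol();
    for (int i = 0; i < D.size(); i++) {
      E.spD.push_back(D[i]); E.spdim.push_back(dim[i]); E.spcomp.push_back(comp[i]);
      std::vector<double> row(E.n_obs);
      for (int o = 0; o < E.n_obs; o++) row[o] = om(i, o);
      E.obsmat.push_back(row);
      E.sp_count.push_back(0);
    }
    IntegerVector oscope = st["obs_scope"], orule = st["obs_rule"];
    for (int i = 0; i < oscope.size(); i++) {
      E.obs_scope.push_back(oscope[i]); E.obs_rule.push_back(orule[i]);
    }
  }
  E.n_rules = as<int>(st["n_rules"]);
  E.fired.assign(E.n_rules, 0.0);
  {
    NumericVector f0 = st["fired"];
    for (int i = 0; i < f0.size() && i < E.n_rules; i++) E.fired[i] = f0[i];
  }
  E.pstats.assign(E.n_rules, PStats());

  Function bprov = providers["bimol"], uprov = providers["unimol"];
  E.bimol_provider = &bprov; E.unimol_provider = &uprov;

  // geometry
  if (st.containsElementNamed("geom") && !Rf_isNull(st["geom"])) {
    List g = st["geom"];
    E.has_geom = true;
    E.M = build_mesh(g);
    IntegerVector occ = g["occup"];
    E.occup.assign(occ.begin(), occ.end());
    IntegerVector ci = g["obj_comp_in"], co = g["obj_comp_out"],
                  cs = g["obj_surf_comp"];
    E.obj_comp_in.assign(ci.begin(), ci.end());
    E.obj_comp_out.assign(co.begin(), co.end());
    E.obj_surf_comp.assign(cs.begin(), cs.end());
    IntegerVector rer = g["region_edge_reflective"];
    E.region_edge_reflective.assign(rer.begin(), rer.end());
    IntegerMatrix sc = g["surf_class"];
    for (int i = 0; i < sc.nrow(); i++) {
      long long key = (long long)sc(i,0) * 1000000LL + sc(i,1) * 1000LL + sc(i,2);
      E.surf_class[key] = sc(i,3);
    }
    // AABB
    E.aabb_min = v3(INF, INF, INF); E.aabb_max = v3(-INF, -INF, -INF);
    for (auto &v : E.M.verts) {
      E.aabb_min.x = std::min(E.aabb_min.x, v.x);
      E.aabb_min.y = std::min(E.aabb_min.y, v.y);
      E.aabb_min.z = std::min(E.aabb_min.z, v.z);
      E.aabb_max.x = std::max(E.aabb_max.x, v.x);
      E.aabb_max.y = std::max(E.aabb_max.y, v.y);
      E.aabb_max.z = std::max(E.aabb_max.z, v.z);
    }
  }

  // molecules
  E.next_id = as<int>(st["next_id"]);
  {
    List vm = st["vol"];
    IntegerVector id = vm["id"], spv = vm["sp"], comp = vm["comp"], born = vm["born"];
    NumericVector x = vm["x"], y = vm["y"], z = vm["z"], tun = vm["tun"];
    for (int i = 0; i < id.size(); i++) {
      Engine::Vol m;
      m.id = id[i]; m.sp = spv[i]; m.comp = comp[i]; m.born = born[i];
      m.p = v3(x[i], y[i], z[i]); m.tun = tun[i]; m.alive = true;
      E.vol.push_back(m);
      E.sp_count[m.sp - 1]++;
    }
    List sm = st["surf"];
    IntegerVector id2 = sm["id"], sps = sm["sp"], tri = sm["tri"], tile = sm["tile"],
                  born2 = sm["born"];
    NumericVector tun2 = sm["tun"];
    if (id2.size() > 0 && !E.has_geom)
      stop("surface molecules require geometry");
    for (int i = 0; i < id2.size(); i++) {
      Engine::Surf m;
      m.id = id2[i]; m.sp = sps[i]; m.tri = tri[i] - 1; m.tile = tile[i];
      m.born = born2[i]; m.tun = tun2[i]; m.alive = true;
      E.surf_slot[m.id] = (int)E.surf.size();
      E.surf.push_back(m);
      E.sp_count[m.sp - 1]++;
      E.occup[E.M.tri_off[m.tri] + m.tile] = m.id;
    }
  }

  // callbacks
  if (callbacks.containsElementNamed("rxn")) {
    List rcbs = callbacks["rxn"];
    for (int i = 0; i < rcbs.size(); i++) {
      List cb = rcbs[i];
      E.rxn_cbs.push_back({as<int>(cb["rule"]), Function(cb["fn"]),
                           RObject(cb["ctx"])});
    }
  }
  if (callbacks.containsElementNamed("wall")) {
    List wcbs = callbacks["wall"];
    for (int i = 0; i < wcbs.size(); i++) {
      List cb = wcbs[i];
      E.wall_cbs.push_back({as<int>(cb["sp"]), as<int>(cb["obj"]),
                            Function(cb["fn"]), RObject(cb["ctx"])});
    }
  }

  // hybrid
  if (st.containsElementNamed("hybrid") && !Rf_isNull(st["hybrid"])) {
    List h = st["hybrid"];
    E.has_hybrid = true;
    E.hyb_value = as<double>(h["value"]);
    E.hyb_decay = as<double>(h["decay"]);
    E.hyb_coupled_rule = as<int>(h["coupled_rule"]);
    E.hyb_coupled_coef = as<double>(h["coupled_coef"]);
    IntegerVector ps = h["prod_sp"], cs = h["cons_sp"], gr = h["gain_rules"];
    NumericVector pc = h["prod_coef"], cc = h["cons_coef"];
    E.hyb_prod_sp.assign(ps.begin(), ps.end());
    E.hyb_cons_sp.assign(cs.begin(), cs.end());
    E.hyb_gain_rules.assign(gr.begin(), gr.end());
    E.hyb_prod_coef.assign(pc.begin(), pc.end());
    E.hyb_cons_coef.assign(cc.begin(), cc.end());
  }

  // releases
  List rels = st["releases"];

  E.count_ncol = 1 + E.n_obs + (E.has_hybrid ? 1 : 0);
  if (E.iter0 == 0) E.record_counts();

  std::vector<double> fired_before(E.n_rules, 0.0);

  // ---------------- main loop
  for (int it = 0; it < E.n_iter; it++) {
    E.cur_iter = E.iter0 + it;
    double t_start = E.time0 + (double)it * E.dt;
    double t_end = t_start + E.dt;
    E.now = t_start;
    for (int r = 0; r < E.n_rules; r++) fired_before[r] = E.fired[r];

    // 1. ReleaseEvents
    for (int ri = 0; ri < rels.size(); ri++) {
      List rl = rels[ri];
      if (as<int>(rl["iter"]) != E.cur_iter) continue;
      int kind = as<int>(rl["kind"]);
      int rsp = as<int>(rl["sp"]);
      if (kind == 2) {  // points
        NumericMatrix pts = rl["pts"];
        for (int i = 0; i < pts.nrow(); i++)
          E.add_vol(rsp, v3(pts(i,0), pts(i,1), pts(i,2)), as<int>(rl["comp"]),
                    E.cur_iter - 1);
      } else if (kind == 0) {  // volume region (object id), rejection sampling
        int obj = as<int>(rl["obj"]);
        int count = as<int>(rl["count"]);
        // object triangle set for containment
        std::vector<int> otris;
        for (int ti = 0; ti < (int)E.M.tris.size(); ti++)
          if (E.M.tri_obj[ti] == obj) otris.push_back(ti);
        V3 lo = E.aabb_min, hi = E.aabb_max;
        int made = 0, attempts = 0;
        while (made < count && attempts < 100000 + 1000 * count) {
          attempts++;
          V3 q = v3(lo.x + E.rng.unif() * (hi.x - lo.x),
                    lo.y + E.rng.unif() * (hi.y - lo.y),
                    lo.z + E.rng.unif() * (hi.z - lo.z));
          // parity along +x
          V3 dir = v3(2.0 * (hi.x - lo.x) + 1.0, 0, 0);
          int crossings = 0;
          Hit h;
          for (int ti : otris) {
            const auto &t = E.M.tris[ti];
            if (seg_tri(q, dir, E.M.verts[t[0]], E.M.verts[t[1]],
                        E.M.verts[t[2]], h))
              crossings++;
          }
          if (crossings % 2 == 1) {
            E.add_vol(rsp, q, as<int>(rl["comp"]), E.cur_iter - 1);
            made++;
          }
        }
        if (made < count)
          E.warnings.push_back("volume release did not place all molecules");
      } else {  // surface region: kind 1 count, kind 3 density
        int obj = as<int>(rl["obj"]);
        int region = as<int>(rl["region"]);
        std::vector<std::pair<int,int>> vacant;
        double area = 0;
        for (int ti = 0; ti < (int)E.M.tris.size(); ti++) {
          if (E.M.tri_obj[ti] != obj) continue;
          if (region != 0 && E.M.tri_region[ti] != region) continue;
          area += E.M.tri_area[ti];
          int nt = E.M.tri_n[ti] * E.M.tri_n[ti];
          for (int k = 0; k < nt; k++)
            if (E.occup[E.M.tri_off[ti] + k] == 0)
              vacant.push_back({ti, k});
        }
        int count = kind == 3 ?
          (int)std::floor(as<double>(rl["density"]) * area + 0.5) :
          as<int>(rl["count"]);
        if (count > (int)vacant.size())
          stop("surface release exceeds vacant tiles on object %d region %d",
               obj, region);
        // partial Fisher-Yates
        for (int k = 0; k < count; k++) {
          int j = k + E.rng.pick((int)vacant.size() - k);
          std::swap(vacant[k], vacant[j]);
          E.add_surf(rsp, vacant[k].first, vacant[k].second, E.cur_iter - 1);
        }
      }
    }

    // 2. DiffuseReactEvent
    // spatial grid over current volume molecules
    int gx = 1, gy = 1, gz = 1;
    double cell = 1.0;
    V3 gmin = v3(0, 0, 0);
    std::vector<int> &grid = E.gr_grid, &cellstart = E.gr_cells;
    {
      V3 lo = v3(INF, INF, INF), hi = v3(-INF, -INF, -INF);
      double maxsd = 0;
      for (auto &m : E.vol) {
        if (!m.alive) continue;
        lo.x = std::min(lo.x, m.p.x); lo.y = std::min(lo.y, m.p.y);
        lo.z = std::min(lo.z, m.p.z);
        hi.x = std::max(hi.x, m.p.x); hi.y = std::max(hi.y, m.p.y);
        hi.z = std::max(hi.z, m.p.z);
        double Dum = E.spD[m.sp - 1] * 1e8;
        maxsd = std::max(maxsd, std::sqrt(2.0 * Dum * E.dt));
      }
      if (E.has_geom) { lo = E.aabb_min; hi = E.aabb_max; }
      if (lo.x > hi.x) { lo = v3(0,0,0); hi = v3(1,1,1); }
      cell = std::max({4.0 * maxsd + E.rint, E.rint * 2, 1e-6});
      gx = std::max(1, std::min(32, (int)((hi.x - lo.x) / cell) + 1));
      gy = std::max(1, std::min(32, (int)((hi.y - lo.y) / cell) + 1));
      gz = std::max(1, std::min(32, (int)((hi.z - lo.z) / cell) + 1));
      cell = std::max({(hi.x - lo.x) / gx, (hi.y - lo.y) / gy,
                       (hi.z - lo.z) / gz, cell});
      gmin = lo;
      std::vector<int> &cnt = E.gr_cnt, &cidx = E.gr_cidx, &fill = E.gr_fill;
      cnt.assign(gx * gy * gz + 1, 0);
      cidx.assign(E.vol.size(), -1);
      for (size_t i = 0; i < E.vol.size(); i++) {
        if (!E.vol[i].alive) continue;
        int cx = std::max(0, std::min(gx - 1, (int)((E.vol[i].p.x - gmin.x) / cell)));
        int cy = std::max(0, std::min(gy - 1, (int)((E.vol[i].p.y - gmin.y) / cell)));
        int cz = std::max(0, std::min(gz - 1, (int)((E.vol[i].p.z - gmin.z) / cell)));
        cidx[i] = (cz * gy + cy) * gx + cx;
        cnt[cidx[i] + 1]++;
      }
      cellstart.assign(cnt.size(), 0);
      for (size_t c = 1; c < cnt.size(); c++) cellstart[c] = cellstart[c - 1] + cnt[c];
      grid.assign(cellstart.back(), -1);
      fill.assign(cellstart.begin(), cellstart.end());
      for (size_t i = 0; i < E.vol.size(); i++) {
        if (cidx[i] < 0) continue;
        grid[fill[cidx[i]]++] = (int)i;
      }
    }

    // unimolecular events due this step, molecules in ascending id order
    // (vol then surf); then diffusion sweep in ascending id order
    size_t nvol_at_start = E.vol.size(), nsurf_at_start = E.surf.size();
    for (size_t i = 0; i < nvol_at_start; i++) {
      Engine::Vol &m = E.vol[i];
      if (!m.alive || m.born >= E.cur_iter) continue;
      if (m.tun <= t_end) { E.fire_unimol_vol(m); continue; }
    }
    for (size_t i = 0; i < nsurf_at_start; i++) {
      Engine::Surf &m = E.surf[i];
      if (!m.alive || m.born >= E.cur_iter) continue;
      if (m.tun <= t_end) { E.fire_unimol_surf(m); continue; }
    }
    E.now = t_start;
    for (size_t i = 0; i < nvol_at_start; i++) {
      Engine::Vol &m = E.vol[i];
      if (!m.alive || m.born >= E.cur_iter) continue;
      E.diffuse_vol(m, grid, cellstart, gx, gy, gz, cell, gmin);
    }
    for (size_t i = 0; i < nsurf_at_start; i++) {
      Engine::Surf &m = E.surf[i];
      if (!m.alive || m.born >= E.cur_iter) continue;
      E.diffuse_surf(m);
    }
    E.now = t_end;

    // 3. hybrid explicit-Euler update and coupled-rate refresh
    if (E.has_hybrid) {
      // linear-in-R production/loss with coefficients frozen over the
      // iteration; sub-stepped explicit Euler keeps the stiff loss term
      // stable when the sequestration rate is large
      double P = 0, lam = E.hyb_decay;
      for (size_t k = 0; k < E.hyb_prod_sp.size(); k++)
        P += E.hyb_prod_coef[k] * E.sp_count[E.hyb_prod_sp[k] - 1];
      for (size_t k = 0; k < E.hyb_cons_sp.size(); k++)
        lam += E.hyb_cons_coef[k] * E.sp_count[E.hyb_cons_sp[k] - 1];
      int nsub = 1 + (int)(10.0 * lam * E.dt);
      if (nsub > 10000) nsub = 10000;
      double h = E.dt / nsub;
      for (int ssub = 0; ssub < nsub; ssub++)
        E.hyb_value += h * (P - lam * E.hyb_value);
      double gain = 0;
      for (int r : E.hyb_gain_rules) gain += E.fired[r - 1] - fired_before[r - 1];
      E.hyb_value += gain;
      if (E.hyb_value < 0) {
        E.hyb_value = 0;
        if (!E.hyb_warned) {
          E.warnings.push_back("hybrid copy number clamped at zero");
          E.hyb_warned = true;
        }
      }
      // reschedule molecules of species with dynamic unimolecular rates
      for (auto &kv : E.unimol_dyn) {
        if (!kv.second) continue;
        int spd = kv.first;
        double k = E.unimol_rate(spd);
        for (auto &m : E.vol)
          if (m.alive && m.sp == spd) m.tun = t_end + E.rng.expo(k);
        for (auto &m : E.surf)
          if (m.alive && m.sp == spd) m.tun = t_end + E.rng.expo(k);
      }
    }

    // 4. MolRxnCountEvent
    if (E.count_stride > 0 &&
        ((it + 1) % E.count_stride == 0 || it == E.n_iter - 1))
      E.record_counts();

    // cache cleanup
    if (E.cleanup_interval > 0 && (E.cur_iter + 1) % E.cleanup_interval == 0)
      E.cleanup();

    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // ---------------- marshal state back
  int nv = 0, ns = 0;
  for (auto &m : E.vol) if (m.alive) nv++;
  for (auto &m : E.surf) if (m.alive) ns++;
  IntegerVector vid(nv), vsp(nv), vcomp(nv), vborn(nv);
  NumericVector vx(nv), vy(nv), vz(nv), vtun(nv);
  int k = 0;
  for (auto &m : E.vol) {
    if (!m.alive) continue;
    vid[k] = m.id; vsp[k] = m.sp; vcomp[k] = m.comp; vborn[k] = m.born;
    vx[k] = m.p.x; vy[k] = m.p.y; vz[k] = m.p.z; vtun[k] = m.tun; k++;
  }
  IntegerVector sid(ns), ssp(ns), stri(ns), stile(ns), sborn(ns);
  NumericVector stun(ns);
  k = 0;
  for (auto &m : E.surf) {
    if (!m.alive) continue;
    sid[k] = m.id; ssp[k] = m.sp; stri[k] = m.tri + 1; stile[k] = m.tile;
    sborn[k] = m.born; stun[k] = m.tun; k++;
  }
  int nrow = E.count_ncol > 0 ? (int)E.count_rows.size() / E.count_ncol : 0;
  NumericMatrix counts(nrow, E.count_ncol);
  for (int r = 0; r < nrow; r++)
    for (int c = 0; c < E.count_ncol; c++)
      counts(r, c) = E.count_rows[r * E.count_ncol + c];
  RawVector rng_out(32);
  for (int i = 0; i < 4; i++)
    for (int b = 0; b < 8; b++)
      rng_out[i * 8 + b] = (E.rng.s[i] >> (8 * b)) & 0xFF;
  NumericMatrix pst(E.n_rules, 4);
  for (int r = 0; r < E.n_rules; r++) {
    pst(r, 0) = E.pstats[r].maxp;
    pst(r, 1) = E.pstats[r].ntests;
    pst(r, 2) = E.pstats[r].sump;
    pst(r, 3) = E.pstats[r].excess;
  }
  // species table may have grown
  int nsp = (int)E.spD.size();
  NumericVector oD(nsp); IntegerVector odim(nsp), ocomp(nsp);
  NumericMatrix oobs(nsp, E.n_obs);
  for (int i = 0; i < nsp; i++) {
    oD[i] = E.spD[i]; odim[i] = E.spdim[i]; ocomp[i] = E.spcomp[i];
    for (int o = 0; o < E.n_obs; o++) oobs(i, o) = E.obsmat[i][o];
  }
  NumericVector spcount(nsp);
  for (int i = 0; i < nsp; i++) spcount[i] = (double)E.sp_count[i];
  return List::create(
    _["vol"] = List::create(_["id"] = vid, _["sp"] = vsp, _["comp"] = vcomp,
                            _["born"] = vborn, _["x"] = vx, _["y"] = vy,
                            _["z"] = vz, _["tun"] = vtun),
    _["surf"] = List::create(_["id"] = sid, _["sp"] = ssp, _["tri"] = stri,
                             _["tile"] = stile, _["born"] = sborn,
                             _["tun"] = stun),
    _["occup"] = IntegerVector(E.occup.begin(), E.occup.end()),
    _["counts"] = counts,
    _["rng_state"] = rng_out,
    _["next_id"] = E.next_id,
    _["fired"] = NumericVector(E.fired.begin(), E.fired.end()),
    _["pstats"] = pst,
    _["sp_count"] = spcount,
    _["species"] = List::create(_["D"] = oD, _["dim"] = odim, _["comp"] = ocomp),
    _["obsmat"] = oobs,
    _["hybrid_value"] = E.has_hybrid ? wrap(E.hyb_value) : R_NilValue,
    _["warnings"] = wrap(E.warnings),
    _["time"] = E.time0 + (double)E.n_iter * E.dt,
    _["iter"] = E.iter0 + E.n_iter);
}

// ---------------------------------------------------------------------------
// Ray-mesh utilities shared with the R layer

// [[Rcpp::export]]
NumericMatrix cpp_ray_mesh_hits(NumericVector origin, NumericVector disp,
                                NumericMatrix verts, IntegerMatrix tris) {
  V3 o = v3(origin[0], origin[1], origin[2]);
  V3 d = v3(disp[0], disp[1], disp[2]);
  std::vector<Hit> hits;
  Hit h;
  for (int i = 0; i < tris.nrow(); i++) {
    V3 a = v3(verts(tris(i,0)-1,0), verts(tris(i,0)-1,1), verts(tris(i,0)-1,2));
    V3 b = v3(verts(tris(i,1)-1,0), verts(tris(i,1)-1,1), verts(tris(i,1)-1,2));
    V3 c = v3(verts(tris(i,2)-1,0), verts(tris(i,2)-1,1), verts(tris(i,2)-1,2));
    if (seg_tri(o, d, a, b, c, h)) { h.tri = i; hits.push_back(h); }
  }
  std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
    return a.t < b.t || (a.t == b.t && a.tri < b.tri); });
  std::vector<Hit> uniq;
  for (auto &hh : hits) {
    if (!uniq.empty() && std::fabs(uniq.back().t - hh.t) < 1e-12) continue;
    uniq.push_back(hh);
  }
  NumericMatrix out((int)uniq.size(), 3);
  for (size_t i = 0; i < uniq.size(); i++) {
    out(i, 0) = uniq[i].t;
    out(i, 1) = uniq[i].tri + 1;
    out(i, 2) = uniq[i].side;
  }
  return out;
}

// [[Rcpp::export]]
bool cpp_point_in_mesh(NumericVector p, NumericMatrix verts, IntegerMatrix tris) {
  // crossing parity along a fixed direction chosen to avoid axis alignment
  double span = 0;
  for (int i = 0; i < verts.nrow(); i++)
    span = std::max(span, std::fabs(verts(i,0)) + std::fabs(verts(i,1)) +
                    std::fabs(verts(i,2)));
  V3 o = v3(p[0], p[1], p[2]);
  V3 d = v3(0.5380032, 0.3759213, 0.7559149);
  d = d * (4.0 * span + 1.0);
  std::vector<Hit> hits;
  Hit h;
  for (int i = 0; i < tris.nrow(); i++) {
    V3 a = v3(verts(tris(i,0)-1,0), verts(tris(i,0)-1,1), verts(tris(i,0)-1,2));
    V3 b = v3(verts(tris(i,1)-1,0), verts(tris(i,1)-1,1), verts(tris(i,1)-1,2));
    V3 c = v3(verts(tris(i,2)-1,0), verts(tris(i,2)-1,1), verts(tris(i,2)-1,2));
    if (seg_tri(o, d, a, b, c, h)) { h.tri = i; hits.push_back(h); }
  }
  std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
    return a.t < b.t; });
  int crossings = 0;
  double last_t = -1;
  for (auto &hh : hits) {
    if (last_t >= 0 && std::fabs(hh.t - last_t) < 1e-12) continue;
    crossings++; last_t = hh.t;
  }
  return crossings % 2 == 1;
}

// ---------------------------------------------------------------------------
// Gillespie direct-method SSA over an expanded concrete network

// [[Rcpp::export]]
NumericMatrix cpp_ssa(int n_species, IntegerVector r1, IntegerVector r2,
                      NumericVector c, List prods, IntegerVector y0,
                      NumericVector t_grid, double seed) {
  Rng rng; rng.seed((uint64_t)seed);
  int nr = r1.size();
  std::vector<std::vector<int>> pr(nr);
  for (int i = 0; i < nr; i++) {
    IntegerVector p = prods[i];
    pr[i].assign(p.begin(), p.end());
  }
  std::vector<double> n(n_species);
  for (int i = 0; i < n_species; i++) n[i] = y0[i];
  int ng = t_grid.size();
  NumericMatrix out(ng, n_species);
  int gi = 0;
  double t = 0;
  auto record_until = [&](double tnow) {
    while (gi < ng && t_grid[gi] <= tnow + 1e-15) {
      for (int i = 0; i < n_species; i++) out(gi, i) = n[i];
      gi++;
    }
  };
  record_until(t);
  std::vector<double> a(nr);
  while (gi < ng) {
    double atot = 0;
    for (int i = 0; i < nr; i++) {
      double ai;
      int s1 = r1[i], s2 = r2[i];
      if (s2 == 0) ai = c[i] * n[s1 - 1];
      else if (s1 == s2) ai = c[i] * n[s1 - 1] * (n[s1 - 1] - 1) / 2.0;
      else ai = c[i] * n[s1 - 1] * n[s2 - 1];
      a[i] = ai > 0 ? ai : 0;
      atot += a[i];
    }
    if (atot <= 0) { t = t_grid[ng - 1] + 1; record_until(t); break; }
    double tau = rng.expo(atot);
    double u = rng.unif() * atot, acc = 0;
    int sel = nr - 1;
    for (int i = 0; i < nr; i++) { acc += a[i]; if (u <= acc) { sel = i; break; } }
    if (t + tau > t_grid[ng - 1]) { t = t_grid[ng - 1]; record_until(t); break; }
    record_until(t + tau - 1e-15);
    t += tau;
    n[r1[sel] - 1] -= 1;
    if (r2[sel] > 0) n[r2[sel] - 1] -= 1;
    for (int p : pr[sel]) n[p - 1] += 1;
    record_until(t);
  }
  // fill any remaining grid points with final state
  for (; gi < ng; gi++)
    for (int i = 0; i < n_species; i++) out(gi, i) = n[i];
  return out;
}
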