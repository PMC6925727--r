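// Galerkin boundary-element assembly for the Laplace layer potentials on a
// closed triangle mesh, with piecewise-linear (hat) trial/test functions.
//
//   V  : single layer      v_ij = (1/4pi) iint phi_i(x) phi_j(y) / |x-y|
//   K  : double layer      k_ij = (1/4pi) iint phi_i(x) phi_j(y) <x-y, n_y> / |x-y|^3
//   D  : hypersingular, assembled in the integration-by-parts (surface-curl)
//        weak form  d_ij = (1/4pi) iint <curl phi_i(x), curl phi_j(y)> / |x-y|
//        (annihilates constants exactly at the discrete level)
//
// Far pairs: tensor Gauss of the requested order.  Coincident / adjacent /
// close pairs: adaptive outer subdivision with EXACT closed-form inner panel
// integrals (edge-based formulas for int 1/R and int (y-rho)/R, the
// van Oosterom-Strackee solid angle for int h/R^3, and int (y-rho)/R^3 =
// -sum_e m_e f_e), so the weak singularity is integrated analytically.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using Rcpp::NumericMatrix;
using Rcpp::IntegerMatrix;
using Rcpp::List;

struct V3 {
  double x, y, z;
};
static inline V3 v3(double x, double y, double z) { V3 r; r.x = x; r.y = y; r.z = z; return r; }
static inline V3 sub(const V3 &a, const V3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 add(const V3 &a, const V3 &b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 scl(const V3 &a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3 &a, const V3 &b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double nrm(const V3 &a) { return std::sqrt(dot(a, a)); }

// ---------- triangle quadrature rules (barycentric coords, weights sum 1) ----

struct TriRule {
  std::vector<double> b1, b2, b3, w;
  int n;
};

static void push_sym(TriRule &r, double a, double b, double c, double w) {
  // push all distinct permutations of (a, b, c)
  double p[6][3] = {{a,b,c},{a,c,b},{b,a,c},{b,c,a},{c,a,b},{c,b,a}};
  for (int i = 0; i < 6; ++i) {
    bool dup = false;
    for (size_t j = 0; j < r.b1.size(); ++j)
      if (std::fabs(r.b1[j]-p[i][0]) < 1e-14 && std::fabs(r.b2[j]-p[i][1]) < 1e-14 &&
          std::fabs(r.b3[j]-p[i][2]) < 1e-14) { dup = true; break; }
    if (!dup) { r.b1.push_back(p[i][0]); r.b2.push_back(p[i][1]); r.b3.push_back(p[i][2]); r.w.push_back(w); }
  }
}

static void gauss_legendre01(int n, std::vector<double> &x, std::vector<double> &w) {
  // Golub-Welsch on [0,1]
  arma::mat J(n, n, arma::fill::zeros);
  for (int i = 1; i < n; ++i) {
    double b = i / std::sqrt(4.0 * i * i - 1.0);
    J(i, i - 1) = b; J(i - 1, i) = b;
  }
  arma::vec eval; arma::mat evec;
  arma::eig_sym(eval, evec, J);
  x.resize(n); w.resize(n);
  for (int i = 0; i < n; ++i) {
    x[i] = 0.5 * (eval(i) + 1.0);
    double v0 = evec(0, i);
    w[i] = v0 * v0;            // weights on [-1,1] are 2*v0^2; halved for [0,1]
  }
}

static TriRule conical_rule(int n) {
  // Duffy map of an n x n Gauss-Legendre grid; exactness ~ degree n-1
  std::vector<double> x, w;
  gauss_legendre01(n, x, w);
  TriRule r;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double s = x[i], t = x[j];
      // P = (1-s) A + s(1-t) B + s t C, area weight 2 s
      r.b1.push_back(1.0 - s);
      r.b2.push_back(s * (1.0 - t));
      r.b3.push_back(s * t);
      r.w.push_back(2.0 * s * w[i] * w[j]);
    }
  r.n = (int)r.w.size();
  return r;
}

static TriRule tri_rule(int order) {
  TriRule r;
  if (order <= 2) {                       // 3-point, degree 2
    push_sym(r, 2.0/3.0, 1.0/6.0, 1.0/6.0, 1.0/3.0);
  } else if (order <= 4) {                // 6-point, degree 4 (Strang)
    push_sym(r, 0.108103018168070, 0.445948490915965, 0.445948490915965,
             0.223381589678011);
    push_sym(r, 0.816847572980459, 0.091576213509771, 0.091576213509771,
             0.109951743655322);
  } else if (order <= 6) {                // 7-point, degree 5
    push_sym(r, 1.0/3.0, 1.0/3.0, 1.0/3.0, 0.225);
    push_sym(r, 0.059715871789770, 0.470142064105115, 0.470142064105115,
             0.132394152788506);
    push_sym(r, 0.797426985353087, 0.101286507323456, 0.101286507323456,
             0.125939180544827);
  } else {
    return conical_rule((order + 2) / 2);
  }
  r.n = (int)r.w.size();
  return r;
}

// ---------- per-face geometry cache -----------------------------------------

struct Face {
  int i0, i1, i2;          // vertex ids (0-based)
  V3 p0, p1, p2;           // coordinates
  V3 n;                    // unit outward normal
  double area;
  V3 ctr;
  double rad;              // bounding radius about ctr
  V3 g0, g1, g2;           // in-plane gradients of the hat functions
  V3 c0, c1, c2;           // surface curls  c_a = n x g_a
};

static Face make_face(const NumericMatrix &Vm, int i0, int i1, int i2) {
  Face f;
  f.i0 = i0; f.i1 = i1; f.i2 = i2;
  f.p0 = v3(Vm(i0, 0), Vm(i0, 1), Vm(i0, 2));
  f.p1 = v3(Vm(i1, 0), Vm(i1, 1), Vm(i1, 2));
  f.p2 = v3(Vm(i2, 0), Vm(i2, 1), Vm(i2, 2));
  V3 cr = cross(sub(f.p1, f.p0), sub(f.p2, f.p0));
  double a2 = nrm(cr);
  f.area = 0.5 * a2;
  f.n = scl(cr, 1.0 / a2);
  f.ctr = scl(add(add(f.p0, f.p1), f.p2), 1.0 / 3.0);
  double r0 = nrm(sub(f.p0, f.ctr)), r1 = nrm(sub(f.p1, f.ctr)), r2 = nrm(sub(f.p2, f.ctr));
  f.rad = std::max(r0, std::max(r1, r2));
  f.g0 = scl(cross(f.n, sub(f.p2, f.p1)), 1.0 / a2);
  f.g1 = scl(cross(f.n, sub(f.p0, f.p2)), 1.0 / a2);
  f.g2 = scl(cross(f.n, sub(f.p1, f.p0)), 1.0 / a2);
  f.c0 = cross(f.n, f.g0);
  f.c1 = cross(f.n, f.g1);
  f.c2 = cross(f.n, f.g2);
  return f;
}

// barycentric coordinates of the in-plane projection of p (affine extension)
static inline void bary_of(const Face &f, const V3 &rho, double b[3]) {
  b[0] = 1.0 + dot(f.g0, sub(rho, f.p0));
  b[1] = dot(f.g1, sub(rho, f.p0));
  b[2] = dot(f.g2, sub(rho, f.p0));
}

// ---------- exact panel moments ----------------------------------------------
// For observation point p and panel f:
//   I0    = int_T 1/R dA
//   Iv    = int_T (y - rho)/R dA
//   Omega = int_T <y - p, n>/R^3 dA   (signed solid angle; = -h * int 1/R^3)
//   Jv    = int_T (y - rho)/R^3 dA
// rho = in-plane projection of p, h = <p - p0, n> (signed height).

struct Moments {
  double I0, Omega;
  V3 Iv, Jv, rho;
  double h;
};

static Moments panel_moments(const Face &f, const V3 &p) {
  Moments M;
  double h = dot(sub(p, f.p0), f.n);
  M.h = h;
  V3 rho = sub(p, scl(f.n, h));
  M.rho = rho;
  double ah = std::fabs(h);

  // signed solid angle Omega = int_T <y - p, n>/R^3 dA via
  // van Oosterom-Strackee; for h = 0 the principal value is 0
  V3 r1 = sub(f.p0, p), r2 = sub(f.p1, p), r3 = sub(f.p2, p);
  double n1 = nrm(r1), n2 = nrm(r2), n3 = nrm(r3);
  double det = dot(r1, cross(r2, r3));
  double den = n1 * n2 * n3 + dot(r1, r2) * n3 + dot(r1, r3) * n2 +
               dot(r2, r3) * n1;
  double omega_vos = 2.0 * std::atan2(det, den);
  // for p off the plane, sign(<y-p, n>) = -sign(h); |Omega| = |omega_vos|
  M.Omega = (ah > 0.0) ? -(h / ah) * std::fabs(omega_vos) : 0.0;

  const V3 *r1s[3] = {&f.p0, &f.p1, &f.p2};
  const V3 *r2s[3] = {&f.p1, &f.p2, &f.p0};
  double dfsum = 0.0;
  V3 Iv = v3(0, 0, 0), Jv = v3(0, 0, 0);
  for (int e = 0; e < 3; ++e) {
    V3 ev = sub(*r2s[e], *r1s[e]);
    double l = nrm(ev);
    V3 s = scl(ev, 1.0 / l);
    V3 m = cross(s, f.n);                 // outward in-plane edge normal
    double lm = dot(sub(*r1s[e], rho), s);
    double lp = dot(sub(*r2s[e], rho), s);
    double d = dot(sub(*r1s[e], rho), m); // <y - rho, m> for y on the edge
    double R0sq = d * d + h * h;
    double R0 = std::sqrt(R0sq);
    double fe;                            // int_e dl / R
    if (R0 > 1e-300 && R0 > 1e-14 * l) {
      fe = std::asinh(lp / R0) - std::asinh(lm / R0);
    } else if (lm > 0.0) {
      fe = std::log(lp / lm);
    } else if (lp < 0.0) {
      fe = std::log(lm / lp);
    } else {
      fe = 0.0;                           // p on the open edge segment: excluded
    }
    double Rm = std::sqrt(lm * lm + R0sq);
    double Rp = std::sqrt(lp * lp + R0sq);
    dfsum += d * fe;
    // int_e R dl = (lp*Rp - lm*Rm + R0sq*fe)/2
    double intR = 0.5 * (lp * Rp - lm * Rm + R0sq * fe);
    Iv = add(Iv, scl(m, intR));
    Jv = sub(Jv, scl(m, fe));
  }
  // divergence identities: int (1/R + h^2/R^3) = sum_e <y-rho, m> f_e
  //                        int 1/R^3 = |Omega| / |h|
  M.I0 = dfsum - ah * std::fabs(omega_vos);
  M.Iv = Iv;
  M.Jv = Jv;
  return M;
}

// inner integrals against the three hat functions of panel f at point p:
//  SV[b] = int_T phi_b / R dA
//  SK[b] = int_T phi_b <p - y, n_f> / R^3 dA  ( = h * int phi_b / R^3 )
static inline void panel_shape_integrals(const Face &f, const V3 &p,
                                         double SV[3], double SK[3],
                                         double coplanar_tol) {
  Moments M = panel_moments(f, p);
  double b[3];
  bary_of(f, M.rho, b);
  const V3 *g[3] = {&f.g0, &f.g1, &f.g2};
  bool coplanar = std::fabs(M.h) < coplanar_tol;
  for (int k = 0; k < 3; ++k) {
    SV[k] = b[k] * M.I0 + dot(*g[k], M.Iv);
    SK[k] = coplanar ? 0.0 : (-b[k] * M.Omega + M.h * dot(*g[k], M.Jv));
  }
}

// ---------- assembly ----------------------------------------------------------

struct SubTri {
  V3 q0, q1, q2;        // global corners
  double b0[3], b1[3], b2[3];   // barycentric coords of corners wrt parent
  int depth;
};

static inline double tri_area(const V3 &a, const V3 &b, const V3 &c) {
  return 0.5 * nrm(cross(sub(b, a), sub(c, a)));
}

// [[Rcpp::export(name = ".assemble_bem")]]
List assemble_bem(NumericMatrix Vtx, IntegerMatrix Fc,
                  int far_order = 5, int near_order = 5,
                  int max_subdiv = 3, double eta = 2.0) {
  const int nV = Vtx.nrow();
  const int nF = Fc.nrow();
  const double inv4pi = 1.0 / (4.0 * M_PI);

  std::vector<Face> faces(nF);
  for (int t = 0; t < nF; ++t)
    faces[t] = make_face(Vtx, Fc(t, 0) - 1, Fc(t, 1) - 1, Fc(t, 2) - 1);

  TriRule far = tri_rule(far_order);
  TriRule nearR = tri_rule(near_order);

  // cache far-rule points per face (global coords)
  const int q = far.n;
  std::vector<double> qp(3 * q * nF);
  for (int t = 0; t < nF; ++t) {
    const Face &f = faces[t];
    for (int k = 0; k < q; ++k) {
      V3 p = add(add(scl(f.p0, far.b1[k]), scl(f.p1, far.b2[k])), scl(f.p2, far.b3[k]));
      qp[3 * (q * t + k) + 0] = p.x;
      qp[3 * (q * t + k) + 1] = p.y;
      qp[3 * (q * t + k) + 2] = p.z;
    }
  }
  // rule shape values (phi_a at point k) times weight
  std::vector<double> wphi(3 * q);
  for (int k = 0; k < q; ++k) {
    wphi[3 * k + 0] = far.w[k] * far.b1[k];
    wphi[3 * k + 1] = far.w[k] * far.b2[k];
    wphi[3 * k + 2] = far.w[k] * far.b3[k];
  }

  arma::mat Vm(nV, nV, arma::fill::zeros);
  arma::mat Km(nV, nV, arma::fill::zeros);
  arma::mat Dm(nV, nV, arma::fill::zeros);

  double mesh_scale = 0.0;
  for (int t = 0; t < nF; ++t) mesh_scale = std::max(mesh_scale, faces[t].rad);
  const double cop_tol = 1e-12 * mesh_scale;

  double Vloc[3][3], Kloc[3][3], K2loc[3][3];

  for (int t1 = 0; t1 < nF; ++t1) {
    const Face &F1 = faces[t1];
    const int id1[3] = {F1.i0, F1.i1, F1.i2};
    for (int t2 = t1; t2 < nF; ++t2) {
      const Face &F2 = faces[t2];
      const int id2[3] = {F2.i0, F2.i1, F2.i2};

      int shared = 0;
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          if (id1[a] == id2[b]) ++shared;

      double cd = nrm(sub(F1.ctr, F2.ctr));
      bool admissible = (shared == 0) && (cd > eta * (F1.rad + F2.rad));

      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          Vloc[a][b] = 0.0; Kloc[a][b] = 0.0; K2loc[a][b] = 0.0;
        }
      double Dsc = 0.0;

      if (t1 != t2 && admissible) {
        // ---- far: tensor Gauss ----
        const double *P1 = &qp[3 * q * t1];
        const double *P2 = &qp[3 * q * t2];
        const double n2x = F2.n.x, n2y = F2.n.y, n2z = F2.n.z;
        const double n1x = F1.n.x, n1y = F1.n.y, n1z = F1.n.z;
        for (int k1 = 0; k1 < q; ++k1) {
          const double x0 = P1[3 * k1], x1 = P1[3 * k1 + 1], x2 = P1[3 * k1 + 2];
          double sV[3] = {0, 0, 0}, sK[3] = {0, 0, 0}, s2[3] = {0, 0, 0}, s0 = 0.0;
          for (int k2 = 0; k2 < q; ++k2) {
            const double rx = x0 - P2[3 * k2];
            const double ry = x1 - P2[3 * k2 + 1];
            const double rz = x2 - P2[3 * k2 + 2];
            const double r2 = rx * rx + ry * ry + rz * rz;
            const double invr = 1.0 / std::sqrt(r2);
            const double invr3 = invr / r2;
            const double dny = (rx * n2x + ry * n2y + rz * n2z) * invr3;
            const double dnx = -(rx * n1x + ry * n1y + rz * n1z) * invr3;
            const double *wp = &wphi[3 * k2];
            s0 += far.w[k2] * invr;
            for (int b = 0; b < 3; ++b) {
              sV[b] += wp[b] * invr;
              sK[b] += wp[b] * dny;
              s2[b] += wp[b] * dnx;
            }
          }
          const double *wa = &wphi[3 * k1];
          for (int a = 0; a < 3; ++a) {
            for (int b = 0; b < 3; ++b) {
              Vloc[a][b] += wa[a] * sV[b];
              Kloc[a][b] += wa[a] * sK[b];
              K2loc[b][a] += wa[a] * s2[b];
            }
          }
          Dsc += far.w[k1] * s0;
        }
        const double sc = F1.area * F2.area;
        for (int a = 0; a < 3; ++a)
          for (int b = 0; b < 3; ++b) {
            Vloc[a][b] *= sc; Kloc[a][b] *= sc; K2loc[a][b] *= sc;
          }
        Dsc *= sc;
      } else {
        // ---- near/singular: adaptive outer, exact inner ----
        // direction 1: outer x over T1, inner analytic over T2 (V, K, D)
        // direction 2: outer x over T2, inner analytic over T1 (K only)
        for (int dir = 0; dir < 2; ++dir) {
          if (dir == 1 && t1 == t2) break;   // coincident: K block is zero
          const Face &Fo = (dir == 0) ? F1 : F2;
          const Face &Fi = (dir == 0) ? F2 : F1;
          std::vector<SubTri> stack;
          SubTri root;
          root.q0 = Fo.p0; root.q1 = Fo.p1; root.q2 = Fo.p2;
          for (int k = 0; k < 3; ++k) { root.b0[k] = (k == 0); root.b1[k] = (k == 1); root.b2[k] = (k == 2); }
          root.depth = 0;
          stack.push_back(root);
          while (!stack.empty()) {
            SubTri s = stack.back();
            stack.pop_back();
            V3 sc_ctr = scl(add(add(s.q0, s.q1), s.q2), 1.0 / 3.0);
            double srad = std::max(nrm(sub(s.q0, sc_ctr)),
                                   std::max(nrm(sub(s.q1, sc_ctr)), nrm(sub(s.q2, sc_ctr))));
            double sd = nrm(sub(sc_ctr, Fi.ctr));
            bool leaf = (s.depth >= max_subdiv) || (sd > eta * (srad + Fi.rad));
            if (!leaf) {
              V3 m01 = scl(add(s.q0, s.q1), 0.5);
              V3 m12 = scl(add(s.q1, s.q2), 0.5);
              V3 m20 = scl(add(s.q2, s.q0), 0.5);
              double c01[3], c12[3], c20[3];
              for (int k = 0; k < 3; ++k) {
                c01[k] = 0.5 * (s.b0[k] + s.b1[k]);
                c12[k] = 0.5 * (s.b1[k] + s.b2[k]);
                c20[k] = 0.5 * (s.b2[k] + s.b0[k]);
              }
              SubTri c;
              c.depth = s.depth + 1;
              c.q0 = s.q0; c.q1 = m01; c.q2 = m20;
              for (int k = 0; k < 3; ++k) { c.b0[k] = s.b0[k]; c.b1[k] = c01[k]; c.b2[k] = c20[k]; }
              stack.push_back(c);
              c.q0 = m01; c.q1 = s.q1; c.q2 = m12;
              for (int k = 0; k < 3; ++k) { c.b0[k] = c01[k]; c.b1[k] = s.b1[k]; c.b2[k] = c12[k]; }
              stack.push_back(c);
              c.q0 = m20; c.q1 = m12; c.q2 = s.q2;
              for (int k = 0; k < 3; ++k) { c.b0[k] = c20[k]; c.b1[k] = c12[k]; c.b2[k] = s.b2[k]; }
              stack.push_back(c);
              c.q0 = m01; c.q1 = m12; c.q2 = m20;
              for (int k = 0; k < 3; ++k) { c.b0[k] = c01[k]; c.b1[k] = c12[k]; c.b2[k] = c20[k]; }
              stack.push_back(c);
              continue;
            }
            double sa = tri_area(s.q0, s.q1, s.q2);
            for (int k = 0; k < nearR.n; ++k) {
              V3 x = add(add(scl(s.q0, nearR.b1[k]), scl(s.q1, nearR.b2[k])),
                         scl(s.q2, nearR.b3[k]));
              double bo[3];
              for (int c = 0; c < 3; ++c)
                bo[c] = nearR.b1[k] * s.b0[c] + nearR.b2[k] * s.b1[c] + nearR.b3[k] * s.b2[c];
              double SV[3], SK[3];
              panel_shape_integrals(Fi, x, SV, SK, cop_tol);
              double wk = sa * nearR.w[k];
              if (dir == 0) {
                for (int a = 0; a < 3; ++a) {
                  double wa = wk * bo[a];
                  for (int b = 0; b < 3; ++b) {
                    Vloc[a][b] += wa * SV[b];
                    Kloc[a][b] += wa * SK[b];
                  }
                }
                Dsc += wk * (SV[0] + SV[1] + SV[2]);
              } else {
                for (int b = 0; b < 3; ++b) {
                  double wb = wk * bo[b];
                  for (int a = 0; a < 3; ++a)
                    K2loc[b][a] += wb * SK[a];
                }
              }
            }
          }
        }
      }

      if (t1 == t2) {
        // symmetrize the diagonal block (outer-quadrature asymmetry)
        for (int a = 0; a < 3; ++a)
          for (int b = a + 1; b < 3; ++b) {
            double s = 0.5 * (Vloc[a][b] + Vloc[b][a]);
            Vloc[a][b] = s; Vloc[b][a] = s;
          }
      }

      // scatter with the 1/4pi factor; D uses curl dot products
      const V3 *c1[3] = {&F1.c0, &F1.c1, &F1.c2};
      const V3 *c2[3] = {&F2.c0, &F2.c1, &F2.c2};
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          const int i = id1[a], j = id2[b];
          const double vab = inv4pi * Vloc[a][b];
          const double dab = inv4pi * Dsc * dot(*c1[a], *c2[b]);
          Vm(i, j) += vab;
          Dm(i, j) += dab;
          Km(i, j) += inv4pi * Kloc[a][b];
          if (t1 != t2) {
            Vm(j, i) += vab;
            Dm(j, i) += dab;
            Km(j, i) += inv4pi * K2loc[b][a];
          }
        }
    }
  }

  return List::create(Rcpp::Named("V") = Vm,
                      Rcpp::Named("K") = Km,
                      Rcpp::Named("D") = Dm,
                      Rcpp::Named("far_points") = far.n,
                      Rcpp::Named("near_points") = nearR.n);
}

// Independent brute-force oracle for a single triangle pair: tensor conical
// (Duffy-mapped Gauss-Legendre) product rule with n x n points per triangle.
// Returns the 3x3 single-layer and double-layer blocks (and the D scalar).
// [[Rcpp::export(name = ".bem_pair_oracle")]]
List bem_pair_oracle(NumericMatrix T1, NumericMatrix T2, int n_gl = 8) {
  TriRule r = conical_rule(n_gl);
  Face f1, f2;
  {
    NumericMatrix Vb(6, 3);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) { Vb(i, j) = T1(i, j); Vb(i + 3, j) = T2(i, j); }
    f1 = make_face(Vb, 0, 1, 2);
    f2 = make_face(Vb, 3, 4, 5);
  }
  arma::mat Vloc(3, 3, arma::fill::zeros), Kloc(3, 3, arma::fill::zeros);
  double Dsc = 0.0;
  for (int k1 = 0; k1 < r.n; ++k1) {
    V3 x = add(add(scl(f1.p0, r.b1[k1]), scl(f1.p1, r.b2[k1])), scl(f1.p2, r.b3[k1]));
    double ba[3] = {r.b1[k1], r.b2[k1], r.b3[k1]};
    for (int k2 = 0; k2 < r.n; ++k2) {
      V3 y = add(add(scl(f2.p0, r.b1[k2]), scl(f2.p1, r.b2[k2])), scl(f2.p2, r.b3[k2]));
      double bb[3] = {r.b1[k2], r.b2[k2], r.b3[k2]};
      V3 d = sub(x, y);
      double rr = nrm(d);
      double w = r.w[k1] * r.w[k2];
      double invr = 1.0 / rr;
      double kk = dot(d, f2.n) * invr * invr * invr;
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          Vloc(a, b) += w * ba[a] * bb[b] * invr;
          Kloc(a, b) += w * ba[a] * bb[b] * kk;
        }
      Dsc += w * invr;
    }
  }
  double sc = f1.area * f2.area / (4.0 * M_PI);
  return List::create(Rcpp::Named("V") = Vloc * sc,
                      Rcpp::Named("K") = Kloc * sc,
                      Rcpp::Named("D_scalar") = Dsc * sc,
                      Rcpp::Named("points") = r.n);
}

// Exposed for unit testing of the closed-form panel integrals.
// [[Rcpp::export(name = ".panel_moments")]]
List panel_moments_R(NumericMatrix T, Rcpp::NumericVector p) {
  NumericMatrix Vb(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Vb(i, j) = T(i, j);
  Face f = make_face(Vb, 0, 1, 2);
  Moments M = panel_moments(f, v3(p[0], p[1], p[2]));
  double SV[3], SK[3];
  panel_shape_integrals(f, v3(p[0], p[1], p[2]), SV, SK, 0.0);
  return List::create(
    Rcpp::Named("I0") = M.I0,
    Rcpp::Named("Omega") = M.Omega,
    Rcpp::Named("Iv") = Rcpp::NumericVector::create(M.Iv.x, M.Iv.y, M.Iv.z),
    Rcpp::Named("Jv") = Rcpp::NumericVector::create(M.Jv.x, M.Jv.y, M.Jv.z),
    Rcpp::Named("h") = M.h,
    Rcpp::Named("SV") = Rcpp::NumericVector::create(SV[0], SV[1], SV[2]),
    Rcpp::Named("SK") = Rcpp::NumericVector::create(SK[0], SK[1], SK[2]));
}
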