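// Explicit-dynamics plane-strain solver core.
//
// 4-node bilinear quadrilaterals, 2x2 Gauss quadrature, small-strain
// kinematics.  Deviatoric response is linear viscoelastic (two-term Prony
// series, exact exponential internal-variable update with strain increments
// treated as jumps at the step start), volumetric response elastic.
// Central-difference (leapfrog) time integration with lumped masses,
// frictionless node-to-segment penalty contact against static walls or a
// vertically translating rigid body, and an energy ledger.
//
// Units are SI throughout (m, s, kg, Pa).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const double GS = 0.5773502691896258; // 1/sqrt(3)
// Gauss point corner signs, order (-,-), (+,-), (+,+), (-,+)
static const double SX[4] = {-1.0, 1.0, 1.0, -1.0};
static const double SY[4] = {-1.0, -1.0, 1.0, 1.0};

// emat columns
enum { M_G0 = 0, M_G1, M_G2, M_GL, M_T1, M_T2, M_K, M_RHO };

struct Pre {
  int ne, nn;
  std::vector<double> dndx; // ne*4gp*4node
  std::vector<double> dndy;
  std::vector<double> w;    // ne*4gp (detJ, unit gauss weights)
  std::vector<double> len;  // ne characteristic length (area / max diagonal)
};

static void shape_deriv(double xi, double eta, double* dxi, double* deta) {
  dxi[0] = -0.25 * (1 - eta); dxi[1] = 0.25 * (1 - eta);
  dxi[2] = 0.25 * (1 + eta);  dxi[3] = -0.25 * (1 + eta);
  deta[0] = -0.25 * (1 - xi); deta[1] = -0.25 * (1 + xi);
  deta[2] = 0.25 * (1 + xi);  deta[3] = 0.25 * (1 - xi);
}

// Corner Jacobians of one element given its 4 node coords.
static void corner_jacobians(const double* ex, const double* ey, double* dets) {
  for (int c = 0; c < 4; ++c) {
    double dxi[4], deta[4];
    shape_deriv(SX[c], SY[c], dxi, deta);
    double j11 = 0, j12 = 0, j21 = 0, j22 = 0;
    for (int a = 0; a < 4; ++a) {
      j11 += dxi[a] * ex[a];  j12 += dxi[a] * ey[a];
      j21 += deta[a] * ex[a]; j22 += deta[a] * ey[a];
    }
    dets[c] = j11 * j22 - j12 * j21;
  }
}

static void precompute(const NumericMatrix& nodes, const IntegerMatrix& elems,
                       Pre& pre) {
  pre.ne = elems.nrow();
  pre.nn = nodes.nrow();
  pre.dndx.assign((size_t)pre.ne * 16, 0.0);
  pre.dndy.assign((size_t)pre.ne * 16, 0.0);
  pre.w.assign((size_t)pre.ne * 4, 0.0);
  pre.len.assign((size_t)pre.ne, 0.0);
  for (int e = 0; e < pre.ne; ++e) {
    double ex[4], ey[4];
    for (int a = 0; a < 4; ++a) {
      int n = elems(e, a) - 1;
      ex[a] = nodes(n, 0);
      ey[a] = nodes(n, 1);
    }
    {
      double d1 = std::sqrt((ex[2] - ex[0]) * (ex[2] - ex[0]) +
                            (ey[2] - ey[0]) * (ey[2] - ey[0]));
      double d2 = std::sqrt((ex[3] - ex[1]) * (ex[3] - ex[1]) +
                            (ey[3] - ey[1]) * (ey[3] - ey[1]));
      double area = 0.5 * std::fabs((ex[0] * ey[1] - ex[1] * ey[0]) +
                                    (ex[1] * ey[2] - ex[2] * ey[1]) +
                                    (ex[2] * ey[3] - ex[3] * ey[2]) +
                                    (ex[3] * ey[0] - ex[0] * ey[3]));
      pre.len[e] = area / std::max(d1, d2);
    }
    for (int g = 0; g < 4; ++g) {
      double xi = SX[g] * GS, eta = SY[g] * GS;
      double dxi[4], deta[4];
      shape_deriv(xi, eta, dxi, deta);
      double j11 = 0, j12 = 0, j21 = 0, j22 = 0;
      for (int a = 0; a < 4; ++a) {
        j11 += dxi[a] * ex[a];  j12 += dxi[a] * ey[a];
        j21 += deta[a] * ex[a]; j22 += deta[a] * ey[a];
      }
      double det = j11 * j22 - j12 * j21;
      if (det <= 0.0)
        stop("non-positive Jacobian in element %d (gauss point %d)", e + 1, g + 1);
      double i11 = j22 / det, i12 = -j12 / det, i21 = -j21 / det, i22 = j11 / det;
      for (int a = 0; a < 4; ++a) {
        pre.dndx[(size_t)e * 16 + g * 4 + a] = i11 * dxi[a] + i12 * deta[a];
        pre.dndy[(size_t)e * 16 + g * 4 + a] = i21 * dxi[a] + i22 * deta[a];
      }
      pre.w[(size_t)e * 4 + g] = det;
    }
  }
}

// Gauss-point state layout per gp (12 doubles):
// 0-2 prev strain (exx, eyy, gxy); 3-5 branch-1 dev stress (xx, yy, xy);
// 6-8 branch-2 dev stress; 9-11 prev in-plane stress (sxx, syy, sxy).
static const int NST = 12;

// Assemble internal forces, update gauss-point states, accumulate internal
// work by midpoint rule.  sig (4/gp: sxx syy sxy szz) and eps (3/gp) are
// always filled.  Returns internal-work increment.
static double assemble_internal(const Pre& pre, const IntegerMatrix& elems,
                                const NumericMatrix& emat,
                                const std::vector<double>& ux,
                                const std::vector<double>& uy, double dt,
                                double bvisc,
                                std::vector<double>& st,
                                std::vector<double>& fx, std::vector<double>& fy,
                                std::vector<double>& sig,
                                std::vector<double>& eps) {
  double dW = 0.0;
  for (int e = 0; e < pre.ne; ++e) {
    int nd[4];
    double eux[4], euy[4];
    for (int a = 0; a < 4; ++a) {
      nd[a] = elems(e, a) - 1;
      eux[a] = ux[nd[a]];
      euy[a] = uy[nd[a]];
    }
    const double G0 = emat(e, M_G0), g1 = emat(e, M_G1), g2 = emat(e, M_G2),
                 gL = emat(e, M_GL), t1 = emat(e, M_T1), t2 = emat(e, M_T2),
                 K = emat(e, M_K), rho = emat(e, M_RHO);
    const double f1 = (g1 > 0.0 && dt > 0.0) ? std::exp(-dt / t1) : 1.0;
    const double f2 = (g2 > 0.0 && dt > 0.0) ? std::exp(-dt / t2) : 1.0;
    // linear bulk-viscosity coefficient (damps volumetric ringing, the
    // standard explicit-dynamics regularization): q = b1 rho c L devdt
    double bvc = 0.0;
    if (bvisc > 0.0 && dt > 0.0) {
      const double Ginst = G0 * (g1 + g2 + gL);
      const double cw = std::sqrt((K + 4.0 * Ginst / 3.0) / rho);
      bvc = bvisc * rho * cw * pre.len[e] / dt;
    }
    for (int g = 0; g < 4; ++g) {
      const double* dnx = &pre.dndx[(size_t)e * 16 + g * 4];
      const double* dny = &pre.dndy[(size_t)e * 16 + g * 4];
      const double w = pre.w[(size_t)e * 4 + g];
      double* s = &st[((size_t)e * 4 + g) * NST];
      double exx = 0, eyy = 0, gxy = 0;
      for (int a = 0; a < 4; ++a) {
        exx += dnx[a] * eux[a];
        eyy += dny[a] * euy[a];
        gxy += dny[a] * eux[a] + dnx[a] * euy[a];
      }
      const double ev = exx + eyy;
      const double dxx = exx - ev / 3.0, dyy = eyy - ev / 3.0, dxy = 0.5 * gxy;
      const double pev = s[0] + s[1];
      const double pdxx = s[0] - pev / 3.0, pdyy = s[1] - pev / 3.0,
                   pdxy = 0.5 * s[2];
      const double ddxx = dxx - pdxx, ddyy = dyy - pdyy, ddxy = dxy - pdxy;
      if (g1 > 0.0) {
        s[3] = f1 * (s[3] + 2.0 * G0 * g1 * ddxx);
        s[4] = f1 * (s[4] + 2.0 * G0 * g1 * ddyy);
        s[5] = f1 * (s[5] + 2.0 * G0 * g1 * ddxy);
      }
      if (g2 > 0.0) {
        s[6] = f2 * (s[6] + 2.0 * G0 * g2 * ddxx);
        s[7] = f2 * (s[7] + 2.0 * G0 * g2 * ddyy);
        s[8] = f2 * (s[8] + 2.0 * G0 * g2 * ddxy);
      }
      const double sLxx = 2.0 * G0 * gL * dxx, sLyy = 2.0 * G0 * gL * dyy,
                   sLxy = 2.0 * G0 * gL * dxy;
      const double stxx = sLxx + s[3] + s[6];
      const double styy = sLyy + s[4] + s[7];
      const double stxy = sLxy + s[5] + s[8];
      const double stzz = -(stxx + styy);
      const double p = K * ev + bvc * (ev - pev);
      const double sigxx = stxx + p, sigyy = styy + p, sigxy = stxy,
                   sigzz = stzz + p;
      for (int a = 0; a < 4; ++a) {
        fx[nd[a]] -= (dnx[a] * sigxx + dny[a] * sigxy) * w;
        fy[nd[a]] -= (dny[a] * sigyy + dnx[a] * sigxy) * w;
      }
      dW += 0.5 * w * ((sigxx + s[9]) * (exx - s[0]) +
                       (sigyy + s[10]) * (eyy - s[1]) +
                       (sigxy + s[11]) * (gxy - s[2]));
      s[0] = exx; s[1] = eyy; s[2] = gxy;
      s[9] = sigxx; s[10] = sigyy; s[11] = sigxy;
      double* so = &sig[((size_t)e * 4 + g) * 4];
      so[0] = sigxx; so[1] = sigyy; so[2] = sigxy; so[3] = sigzz;
      double* eo = &eps[((size_t)e * 4 + g) * 3];
      eo[0] = exx; eo[1] = eyy; eo[2] = gxy;
    }
  }
  return dW;
}

// Stored (recoverable) strain energy: volumetric + per-branch deviatoric.
static double stored_energy(const Pre& pre, const NumericMatrix& emat,
                            const std::vector<double>& st) {
  double U = 0.0;
  for (int e = 0; e < pre.ne; ++e) {
    const double G0 = emat(e, M_G0), g1 = emat(e, M_G1), g2 = emat(e, M_G2),
                 gL = emat(e, M_GL), K = emat(e, M_K);
    for (int g = 0; g < 4; ++g) {
      const double w = pre.w[(size_t)e * 4 + g];
      const double* s = &st[((size_t)e * 4 + g) * NST];
      const double ev = s[0] + s[1];
      const double dxx = s[0] - ev / 3.0, dyy = s[1] - ev / 3.0,
                   dxy = 0.5 * s[2];
      const double sLxx = 2.0 * G0 * gL * dxx, sLyy = 2.0 * G0 * gL * dyy,
                   sLxy = 2.0 * G0 * gL * dxy;
      double u = 0.5 * K * ev * ev;
      const double szzL = -(sLxx + sLyy);
      u += (sLxx * sLxx + sLyy * sLyy + szzL * szzL + 2.0 * sLxy * sLxy) /
           (4.0 * G0 * gL);
      if (g1 > 0.0) {
        const double zz = -(s[3] + s[4]);
        u += (s[3] * s[3] + s[4] * s[4] + zz * zz + 2.0 * s[5] * s[5]) /
             (4.0 * G0 * g1);
      }
      if (g2 > 0.0) {
        const double zz = -(s[6] + s[7]);
        u += (s[6] * s[6] + s[7] * s[7] + zz * zz + 2.0 * s[8] * s[8]) /
             (4.0 * G0 * g2);
      }
      U += w * u;
    }
  }
  return U;
}

// Node-to-segment frictionless penalty contact of points `px,py` (current
// positions of slave nodes) against segments (+ vertical offset yoff).
// Master outward normal is the segment direction rotated 90 deg CCW
// ((tx,ty) -> (-ty,tx)); order segments so normals point at the slave side.
static void contact_apply(const NumericMatrix& segs, double yoff,
                          const std::vector<int>& slaves,
                          const std::vector<double>& kn,
                          const std::vector<double>& px,
                          const std::vector<double>& py,
                          std::vector<double>& fx, std::vector<double>& fy,
                          double& Fmaster_y, double& estore, double& maxpen) {
  const int ns = segs.nrow();
  for (size_t i = 0; i < slaves.size(); ++i) {
    const int n = slaves[i];
    const double x = px[n], y = py[n];
    double gmin = 0.0, nxb = 0.0, nyb = 0.0;
    bool hit = false;
    for (int sgm = 0; sgm < ns; ++sgm) {
      const double ax = segs(sgm, 0), ay = segs(sgm, 1) + yoff;
      const double bx = segs(sgm, 2), by = segs(sgm, 3) + yoff;
      const double tx = bx - ax, ty = by - ay;
      const double L2 = tx * tx + ty * ty;
      if (L2 <= 0) continue;
      double xi = ((x - ax) * tx + (y - ay) * ty) / L2;
      if (xi < 0.0) xi = 0.0;
      if (xi > 1.0) xi = 1.0;
      const double qx = ax + xi * tx, qy = ay + xi * ty;
      const double L = std::sqrt(L2);
      const double nx = -ty / L, ny = tx / L;
      const double g = (x - qx) * nx + (y - qy) * ny;
      if (g < gmin) {
        gmin = g; nxb = nx; nyb = ny; hit = true;
      }
    }
    if (hit && gmin < 0.0) {
      const double delta = -gmin;
      const double F = kn[i] * delta;
      fx[n] += F * nxb;
      fy[n] += F * nyb;
      Fmaster_y -= F * nyb;
      estore += 0.5 * kn[i] * delta * delta;
      if (delta > maxpen) maxpen = delta;
    }
  }
}

static void monitor_weights(double xi, double eta, double* wt) {
  // bilinear extrapolation from the 2x2 gauss grid to local point (xi,eta)
  const double xe = xi / GS, ye = eta / GS;
  for (int g = 0; g < 4; ++g)
    wt[g] = 0.25 * (1.0 + SX[g] * xe) * (1.0 + SY[g] * ye);
}

static double vmises(double sxx, double syy, double sxy, double szz) {
  return std::sqrt(0.5 * ((sxx - syy) * (sxx - syy) +
                          (syy - szz) * (syy - szz) +
                          (szz - sxx) * (szz - sxx)) +
                   3.0 * sxy * sxy);
}

static double principal_max(double axx, double ayy, double axy) {
  return 0.5 * (axx + ayy) +
         std::sqrt(0.25 * (axx - ayy) * (axx - ayy) + axy * axy);
}

// [[Rcpp::export]]
List fem_forces_once(NumericMatrix nodes, IntegerMatrix elems,
                     NumericMatrix emat, NumericVector ux, NumericVector uy,
                     double dt, Nullable<NumericMatrix> state, double bvisc) {
  Pre pre;
  precompute(nodes, elems, pre);
  const int nn = pre.nn, ne = pre.ne;
  std::vector<double> st((size_t)ne * 4 * NST, 0.0);
  if (state.isNotNull()) {
    NumericMatrix sm(state);
    if (sm.nrow() != ne * 4 || sm.ncol() != NST)
      stop("state must be a (4*n_elements) x %d matrix", NST);
    for (int i = 0; i < ne * 4; ++i)
      for (int j = 0; j < NST; ++j) st[(size_t)i * NST + j] = sm(i, j);
  }
  std::vector<double> vx(ux.begin(), ux.end()), vy(uy.begin(), uy.end());
  std::vector<double> fx(nn, 0.0), fy(nn, 0.0);
  std::vector<double> sig((size_t)ne * 4 * 4, 0.0), eps((size_t)ne * 4 * 3, 0.0);
  double dW = assemble_internal(pre, elems, emat, vx, vy, dt, bvisc, st, fx, fy,
                                sig, eps);
  double U = stored_energy(pre, emat, st);
  NumericMatrix stout(ne * 4, NST), sigout(ne * 4, 4), epsout(ne * 4, 3);
  for (int i = 0; i < ne * 4; ++i) {
    for (int j = 0; j < NST; ++j) stout(i, j) = st[(size_t)i * NST + j];
    for (int j = 0; j < 4; ++j) sigout(i, j) = sig[(size_t)i * 4 + j];
    for (int j = 0; j < 3; ++j) epsout(i, j) = eps[(size_t)i * 3 + j];
  }
  return List::create(_["fx"] = NumericVector(fx.begin(), fx.end()),
                      _["fy"] = NumericVector(fy.begin(), fy.end()),
                      _["sigma"] = sigout, _["eps"] = epsout,
                      _["state"] = stout, _["work_increment"] = dW,
                      _["stored_energy"] = U);
}

// [[Rcpp::export]]
List fem_contact_once(NumericMatrix segs, double yoff, NumericMatrix pts,
                      NumericVector kn) {
  const int np = pts.nrow();
  std::vector<int> slaves(np);
  std::vector<double> knv(kn.begin(), kn.end());
  std::vector<double> px(np), py(np), fx(np, 0.0), fy(np, 0.0);
  for (int i = 0; i < np; ++i) {
    slaves[i] = i;
    px[i] = pts(i, 0);
    py[i] = pts(i, 1);
  }
  double Fm = 0, es = 0, mp = 0;
  contact_apply(segs, yoff, slaves, knv, px, py, fx, fy, Fm, es, mp);
  NumericMatrix f(np, 2);
  for (int i = 0; i < np; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; }
  return List::create(_["force"] = f, _["master_fy"] = Fm,
                      _["stored_energy"] = es, _["max_penetration"] = mp);
}

// [[Rcpp::export]]
NumericVector fem_jacobian_min(NumericMatrix nodes, IntegerMatrix elems) {
  const int ne = elems.nrow();
  NumericVector out(ne);
  for (int e = 0; e < ne; ++e) {
    double ex[4], ey[4], dets[4];
    for (int a = 0; a < 4; ++a) {
      int n = elems(e, a) - 1;
      ex[a] = nodes(n, 0);
      ey[a] = nodes(n, 1);
    }
    corner_jacobians(ex, ey, dets);
    out[e] = std::min(std::min(dets[0], dets[1]), std::min(dets[2], dets[3]));
  }
  return out;
}

// [[Rcpp::export]]
List fem_run(NumericMatrix nodes, IntegerMatrix elems, NumericMatrix emat,
             NumericVector mass, LogicalVector fixx, LogicalVector fixy,
             NumericVector ux0, NumericVector uy0, NumericVector vx0,
             NumericVector vy0, List contacts, double dt, int nsteps,
             int out_every, IntegerVector mon_elem, NumericVector mon_xi,
             NumericVector mon_eta, IntegerVector probes, int snap_every,
             int jac_every, double bvisc) {
  Pre pre;
  precompute(nodes, elems, pre);
  const int nn = pre.nn, ne = pre.ne;
  const int nmon = mon_elem.size(), nprb = probes.size(), nct = contacts.size();

  std::vector<double> ux(ux0.begin(), ux0.end()), uy(uy0.begin(), uy0.end());
  std::vector<double> vx(vx0.begin(), vx0.end()), vy(vy0.begin(), vy0.end());
  std::vector<double> ax(nn, 0.0), ay(nn, 0.0);
  std::vector<double> fx(nn), fy(nn);
  std::vector<double> st((size_t)ne * 4 * NST, 0.0);
  std::vector<double> sig((size_t)ne * 4 * 4, 0.0), eps((size_t)ne * 4 * 3, 0.0);
  std::vector<double> pxc(nn), pyc(nn); // current positions

  // contact bookkeeping
  std::vector<NumericMatrix> csegs;
  std::vector<bool> crigid;
  std::vector<double> cmass, cy, cv, ca;
  std::vector<std::vector<int> > cslaves;
  std::vector<std::vector<double> > ckn;
  for (int c = 0; c < nct; ++c) {
    List ct = contacts[c];
    csegs.push_back(as<NumericMatrix>(ct["segs"]));
    crigid.push_back(as<bool>(ct["rigid"]));
    cmass.push_back(crigid[c] ? as<double>(ct["mass"]) : R_PosInf);
    cy.push_back(0.0);
    cv.push_back(crigid[c] ? as<double>(ct["v0"]) : 0.0);
    ca.push_back(0.0);
    IntegerVector sl = ct["slaves"];
    std::vector<int> sv(sl.size());
    for (int i = 0; i < sl.size(); ++i) sv[i] = sl[i] - 1;
    cslaves.push_back(sv);
    NumericVector k = ct["kn"];
    ckn.push_back(std::vector<double>(k.begin(), k.end()));
  }

  const int nout = (nsteps > 0) ? 1 + (nsteps - 1) / out_every : 0;
  NumericVector times(nout);
  NumericMatrix mvm(nmon, nout), me1(nmon, nout), ms1(nmon, nout);
  NumericMatrix energy(nout, 8); // ke, U, D, contact, Wint, px, py, t
  NumericMatrix rigidY(nct, nout), rigidV(nct, nout);
  NumericMatrix prbU(2 * nprb, nout), prbV(2 * nprb, nout);
  int nsnap = 0;
  if (snap_every > 0) nsnap = 1 + (nsteps - 1) / snap_every;
  NumericMatrix snapU(snap_every > 0 ? 2 * nn : 0, nsnap);
  NumericMatrix snapVel(snap_every > 0 ? 2 * nn : 0, nsnap);
  NumericMatrix snapVM(snap_every > 0 ? ne : 0, nsnap);
  NumericMatrix snapE1(snap_every > 0 ? ne : 0, nsnap);
  NumericVector snapT(nsnap);

  double t = 0.0, Wint = 0.0, maxpen = 0.0;
  int outcol = 0, snapcol = 0;
  bool ok = true;
  std::string msg = "completed";
  int bad_elem = NA_INTEGER;
  double bad_time = NA_REAL;

  for (int s = 0; s < nsteps; ++s) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    Wint += assemble_internal(pre, elems, emat, ux, uy, dt, bvisc, st, fx, fy,
                              sig, eps);

    double cstore = 0.0;
    for (int i = 0; i < nn; ++i) {
      pxc[i] = nodes(i, 0) + ux[i];
      pyc[i] = nodes(i, 1) + uy[i];
    }
    for (int c = 0; c < nct; ++c) {
      double Fm = 0.0;
      contact_apply(csegs[c], cy[c], cslaves[c], ckn[c], pxc, pyc, fx, fy, Fm,
                    cstore, maxpen);
      ca[c] = crigid[c] ? Fm / cmass[c] : 0.0;
    }

    for (int i = 0; i < nn; ++i) {
      ax[i] = fixx[i] ? 0.0 : fx[i] / mass[i];
      ay[i] = fixy[i] ? 0.0 : fy[i] / mass[i];
      if (fixx[i]) vx[i] = 0.0;
      if (fixy[i]) vy[i] = 0.0;
    }

    const double hf = (s == 0) ? 0.0 : 0.5 * dt;
    if (s % out_every == 0) {
      double ke = 0.0, px = 0.0, py = 0.0;
      for (int i = 0; i < nn; ++i) {
        const double vix = vx[i] + hf * ax[i], viy = vy[i] + hf * ay[i];
        ke += 0.5 * mass[i] * (vix * vix + viy * viy);
        px += mass[i] * vix;
        py += mass[i] * viy;
      }
      for (int c = 0; c < nct; ++c) {
        if (!crigid[c]) continue;
        const double vi = cv[c] + hf * ca[c];
        ke += 0.5 * cmass[c] * vi * vi;
        py += cmass[c] * vi;
        rigidY(c, outcol) = cy[c];
        rigidV(c, outcol) = vi;
      }
      const double U = stored_energy(pre, emat, st);
      times[outcol] = t;
      energy(outcol, 0) = ke;
      energy(outcol, 1) = U;
      energy(outcol, 2) = Wint - U;
      energy(outcol, 3) = cstore;
      energy(outcol, 4) = Wint;
      energy(outcol, 5) = px;
      energy(outcol, 6) = py;
      energy(outcol, 7) = t;
      for (int m = 0; m < nmon; ++m) {
        double wt[4];
        monitor_weights(mon_xi[m], mon_eta[m], wt);
        const int e = mon_elem[m] - 1;
        double s4[4] = {0, 0, 0, 0}, e3[3] = {0, 0, 0};
        for (int g = 0; g < 4; ++g) {
          const double* so = &sig[((size_t)e * 4 + g) * 4];
          const double* eo = &eps[((size_t)e * 4 + g) * 3];
          for (int j = 0; j < 4; ++j) s4[j] += wt[g] * so[j];
          for (int j = 0; j < 3; ++j) e3[j] += wt[g] * eo[j];
        }
        mvm(m, outcol) = vmises(s4[0], s4[1], s4[2], s4[3]);
        me1(m, outcol) = principal_max(e3[0], e3[1], 0.5 * e3[2]);
        ms1(m, outcol) = principal_max(s4[0], s4[1], s4[2]);
      }
      for (int p = 0; p < nprb; ++p) {
        const int n = probes[p] - 1;
        prbU(2 * p, outcol) = ux[n];
        prbU(2 * p + 1, outcol) = uy[n];
        prbV(2 * p, outcol) = vx[n] + hf * ax[n];
        prbV(2 * p + 1, outcol) = vy[n] + hf * ay[n];
      }
      ++outcol;
    }
    if (snap_every > 0 && s % snap_every == 0) {
      for (int i = 0; i < nn; ++i) {
        snapU(2 * i, snapcol) = ux[i];
        snapU(2 * i + 1, snapcol) = uy[i];
        snapVel(2 * i, snapcol) = vx[i] + hf * ax[i];
        snapVel(2 * i + 1, snapcol) = vy[i] + hf * ay[i];
      }
      for (int e = 0; e < ne; ++e) {
        double vmv = 0.0, e1v = 0.0;
        for (int g = 0; g < 4; ++g) {
          const double* so = &sig[((size_t)e * 4 + g) * 4];
          const double* eo = &eps[((size_t)e * 4 + g) * 3];
          vmv += 0.25 * vmises(so[0], so[1], so[2], so[3]);
          e1v += 0.25 * principal_max(eo[0], eo[1], 0.5 * eo[2]);
        }
        snapVM(e, snapcol) = vmv;
        snapE1(e, snapcol) = e1v;
      }
      snapT[snapcol] = t;
      ++snapcol;
    }
    if (jac_every > 0 && s % jac_every == 0) {
      bool bad = false;
      for (int i = 0; i < nn && !bad; ++i)
        if (std::isnan(ux[i]) || std::isnan(uy[i])) bad = true;
      if (bad) {
        ok = false;
        msg = "NaN detected in displacement field";
        bad_time = t;
        break;
      }
      for (int e = 0; e < ne; ++e) {
        double ex[4], ey[4], dets[4];
        for (int a = 0; a < 4; ++a) {
          int n = elems(e, a) - 1;
          ex[a] = nodes(n, 0) + ux[n];
          ey[a] = nodes(n, 1) + uy[n];
        }
        corner_jacobians(ex, ey, dets);
        if (dets[0] <= 0 || dets[1] <= 0 || dets[2] <= 0 || dets[3] <= 0) {
          ok = false;
          msg = "element inverted during motion";
          bad_elem = e + 1;
          bad_time = t;
          break;
        }
      }
      if (!ok) break;
    }

    const double fac = (s == 0) ? 0.5 : 1.0;
    for (int i = 0; i < nn; ++i) {
      vx[i] += fac * dt * ax[i];
      vy[i] += fac * dt * ay[i];
      ux[i] += dt * vx[i];
      uy[i] += dt * vy[i];
    }
    for (int c = 0; c < nct; ++c) {
      if (!crigid[c]) continue;
      cv[c] += fac * dt * ca[c];
      cy[c] += dt * cv[c];
    }
    t += dt;
  }

  NumericMatrix stout(ne * 4, NST);
  for (int i = 0; i < ne * 4; ++i)
    for (int j = 0; j < NST; ++j) stout(i, j) = st[(size_t)i * NST + j];

  return List::create(
      _["times"] = times, _["mon_vm"] = mvm, _["mon_e1"] = me1,
      _["mon_s1"] = ms1, _["energy"] = energy, _["rigid_y"] = rigidY,
      _["rigid_v"] = rigidV, _["probe_u"] = prbU, _["probe_v"] = prbV,
      _["snap_t"] = snapT, _["snap_u"] = snapU, _["snap_vel"] = snapVel,
      _["snap_vm"] = snapVM, _["snap_e1"] = snapE1,
      _["n_out"] = outcol, _["n_snap"] = snapcol,
      _["ux"] = NumericVector(ux.begin(), ux.end()),
      _["uy"] = NumericVector(uy.begin(), uy.end()),
      _["vx"] = NumericVector(vx.begin(), vx.end()),
      _["vy"] = NumericVector(vy.begin(), vy.end()),
      _["state"] = stout, _["max_penetration"] = maxpen,
      _["ok"] = ok, _["message"] = msg, _["bad_elem"] = bad_elem,
      _["bad_time"] = bad_time);
}
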