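// Planar articulated-body forward dynamics in reduced (joint-space)
// coordinates.  Bodies form a tree rooted at a free (3-DOF) trunk; hinge
// joints contribute one generalized coordinate each, weld joints none.
// Hinge anchor constraints are therefore satisfied exactly by construction.
//
// The generalized equations of motion are assembled each step from body
// Jacobians:  M(q) qdd = Q(q, qd)  with
//   M = sum_b [ m_b Jc_b' Jc_b + I_b Jw_b Jw_b' ]
//   Q = sum_b [ Jc_b' (F_b - m_b abias_b) + Jw_b tau_b ] + joint torques
// where Jc_b maps qd to the COM velocity of body b, Jw_b to its angular
// velocity, and abias_b is the COM acceleration at qdd = 0 (centripetal
// terms only in the plane).  Integration is fixed-step semi-implicit Euler.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec2 perp(const arma::vec2& v) {
  return arma::vec2({-v(1), v(0)});
}
static inline double cross2(const arma::vec2& a, const arma::vec2& b) {
  return a(0) * b(1) - a(1) * b(0);
}

// Direct-form II transposed biquad with steady-state initialisation, so a
// constant input passes through without a start-up transient.
struct Biquad {
  double b0, b1, b2, a1, a2, z1, z2;
  bool primed;
  Biquad() : b0(1), b1(0), b2(0), a1(0), a2(0), z1(0), z2(0), primed(false) {}
  void prime(double s) {
    z1 = (1.0 - b0) * s;
    z2 = (b2 - a2) * s;
    primed = true;
  }
  double step(double x) {
    if (!primed) prime(x);
    double y = b0 * x + z1;
    z1 = b1 * x - a1 * y + z2;
    z2 = b2 * x - a2 * y;
    return y;
  }
};

// Hill-type force-length / force-velocity / passive curves.
static inline double curveFL(double lnorm) {
  double d = (lnorm - 1.0) / 0.45;
  return std::exp(-d * d);
}
static inline double curveFV(double vnorm) {
  // vnorm = fibre velocity / vmax, shortening negative.
  if (vnorm <= -1.0) return 0.0;
  if (vnorm <= 0.0) return (1.0 + vnorm) / (1.0 - vnorm / 0.25);
  return (0.135 + 1.8 * vnorm) / (0.135 + vnorm);
}
// No passive fibre element in the forward-dynamics muscle model: fibre and
// tendon lengths are tuned so the working range spans the full force-length
// curve, and a passive exponential there would lock the joints at their
// range ends.  Passive joint structures are represented by the joint-range
// torsional springs; a small fibre damping term stabilises fast stretch.

// [[Rcpp::export(name = ".engineSimulate")]]
List engineSimulate(List bodyL, List musL, List conL, List boneL,
                    List ctrlL, List cfgL) {
  // ---- bodies -------------------------------------------------------------
  arma::ivec parent = as<arma::ivec>(bodyL["parent"]);   // 0-based, -1 root
  arma::ivec jtype  = as<arma::ivec>(bodyL["jtype"]);    // 0 root,1 hinge,2 weld
  arma::ivec dof    = as<arma::ivec>(bodyL["dof"]);      // 0-based into q, -1
  arma::mat ap      = as<arma::mat>(bodyL["anchorParent"]); // 2 x nb
  arma::mat ac      = as<arma::mat>(bodyL["anchorChild"]);  // 2 x nb
  arma::vec refAng  = as<arma::vec>(bodyL["refAngle"]);
  arma::vec mass    = as<arma::vec>(bodyL["mass"]);
  arma::vec inertia = as<arma::vec>(bodyL["inertia"]);
  arma::mat comL    = as<arma::mat>(bodyL["comLocal"]);     // 2 x nb
  const int nb = parent.n_elem;
  const int nq = as<int>(bodyL["nq"]);
  arma::vec q  = as<arma::vec>(bodyL["q0"]);
  arma::vec qd = as<arma::vec>(bodyL["qd0"]);

  arma::ivec limDof = as<arma::ivec>(bodyL["limDof"]);   // 0-based dof index
  arma::vec limMin  = as<arma::vec>(bodyL["limMin"]);
  arma::vec limMax  = as<arma::vec>(bodyL["limMax"]);
  arma::vec limK    = as<arma::vec>(bodyL["limK"]);
  arma::vec limC    = as<arma::vec>(bodyL["limC"]);
  arma::vec jdamp   = as<arma::vec>(bodyL["jointDamping"]);
  const int nlim = limDof.n_elem;

  // ---- muscles ------------------------------------------------------------
  const int nm = as<int>(musL["nm"]);
  arma::ivec musNpts, musBody;
  arma::mat musPt;
  arma::vec fmax, lopt, lslack, tauAct, act, vmax;
  double musDamp = 0.0;
  if (nm > 0) {
    musNpts = as<arma::ivec>(musL["npts"]);
    musBody = as<arma::ivec>(musL["body"]);
    musPt   = as<arma::mat>(musL["pts"]);
    fmax    = as<arma::vec>(musL["fmax"]);
    lopt    = as<arma::vec>(musL["lopt"]);
    lslack  = as<arma::vec>(musL["lslack"]);
    tauAct  = as<arma::vec>(musL["tauAct"]);
    act     = as<arma::vec>(musL["act0"]);
    vmax    = as<arma::vec>(musL["vmax"]);
    musDamp = as<double>(musL["damping"]);
  }
  arma::ivec musOff(nm > 0 ? nm + 1 : 1, arma::fill::zeros);
  for (int m = 0; m < nm; ++m) musOff(m + 1) = musOff(m) + musNpts(m);

  // ---- contacts -----------------------------------------------------------
  const int ncon = as<int>(conL["ncon"]);
  arma::ivec conBody;
  arma::mat conPos;
  arma::vec conR, conK, conC, conMu;
  if (ncon > 0) {
    conBody = as<arma::ivec>(conL["body"]);
    conPos  = as<arma::mat>(conL["pos"]);
    conR    = as<arma::vec>(conL["radius"]);
    conK    = as<arma::vec>(conL["k"]);
    conC    = as<arma::vec>(conL["c"]);
    conMu   = as<arma::vec>(conL["mu"]);
  }

  // ---- monitored bones ----------------------------------------------------
  const int nbone = as<int>(boneL["nbone"]);
  arma::ivec cutBody;
  arma::mat cutLocal, axisLocal;
  arma::vec boneA, boneGmax, boneGmin;
  std::vector<arma::ivec> subtree;
  std::vector<Biquad> filt(nbone);
  if (nbone > 0) {
    cutBody   = as<arma::ivec>(boneL["cutBody"]);
    cutLocal  = as<arma::mat>(boneL["cutLocal"]);
    axisLocal = as<arma::mat>(boneL["axisLocal"]);
    boneA     = as<arma::vec>(boneL["A"]);
    boneGmax  = as<arma::vec>(boneL["gmax"]);
    boneGmin  = as<arma::vec>(boneL["gmin"]);
    List sub  = boneL["subtree"];
    arma::vec fc = as<arma::vec>(boneL["filter"]); // b0 b1 b2 a1 a2
    for (int k = 0; k < nbone; ++k) {
      subtree.push_back(as<arma::ivec>(sub[k]));
      filt[k].b0 = fc(0); filt[k].b1 = fc(1); filt[k].b2 = fc(2);
      filt[k].a1 = fc(3); filt[k].a2 = fc(4);
    }
  }

  // ---- controller ---------------------------------------------------------
  arma::mat U;      // nm x nphase excitation levels
  double cycle = 1.0;
  int nphase = 0;
  if (nm > 0) {
    U = as<arma::mat>(ctrlL["levels"]);
    cycle = as<double>(ctrlL["cycleDuration"]);
    nphase = U.n_cols;
  }

  // ---- config -------------------------------------------------------------
  const double dt = as<double>(cfgL["dt"]);
  const double duration = as<double>(cfgL["duration"]);
  const int recEvery = as<int>(cfgL["recordEvery"]);
  const double slimit = as<double>(cfgL["stressLimit"]);
  arma::vec2 grav = as<arma::vec>(cfgL["gravity"]);
  const double vreg = as<double>(cfgL["frictionVreg"]);
  const double fallY = as<double>(cfgL["fallHeight"]);   // NA -> disabled
  const bool fallOn = R_finite(fallY);
  const double maxSpeed = as<double>(cfgL["maxComSpeed"]); // divergence guard
  const int hipBody = as<int>(cfgL["hipBody"]);          // 0-based
  arma::vec2 hipLocal = as<arma::vec>(cfgL["hipLocal"]);

  const int nsteps = (int)std::lround(duration / dt);

  // ---- per-step work arrays ----------------------------------------------
  arma::vec phi(nb), omg(nb);
  arma::mat xo(2, nb), vo(2, nb), cw(2, nb), cv(2, nb);
  arma::mat abo(2, nb), abc(2, nb);          // origin / COM bias accel
  arma::cube Jo(2, nq, nb), Jc(2, nq, nb);   // origin / COM Jacobians
  arma::mat Jw(nq, nb);
  arma::mat M(nq, nq);
  arma::vec Q(nq), qdd(nq, arma::fill::zeros);
  arma::mat Facc(2, nb);                     // applied ext force (no gravity)
  arma::vec Tacc(nb);                        // applied ext torque about COM
  arma::mat mwpts;                           // world muscle points
  if (nm > 0) mwpts.set_size(2, musOff(nm));
  arma::vec mforce(std::max(nm, 1), arma::fill::zeros);
  arma::mat cfrc(2, std::max(ncon, 1), arma::fill::zeros);
  arma::ivec cflag(std::max(ncon, 1), arma::fill::zeros);
  arma::vec boneFax(std::max(nbone, 1)), boneShear(std::max(nbone, 1)),
            boneM(std::max(nbone, 1)), sRaw(std::max(nbone, 1)),
            sFilt(std::max(nbone, 1));
  boneFax.zeros(); boneShear.zeros(); boneM.zeros(); sRaw.zeros(); sFilt.zeros();

  // ---- recording ----------------------------------------------------------
  const int maxrec = nsteps / std::max(recEvery, 1) + 3;
  arma::vec rT(maxrec);
  arma::mat rQ(maxrec, nq), rQd(maxrec, nq);
  arma::mat rCom(maxrec, 2), rComv(maxrec, 2);
  arma::vec rHip(maxrec), rKE(maxrec), rPE(maxrec);
  arma::mat rAct(maxrec, std::max(nm, 1)), rMF(maxrec, std::max(nm, 1));
  arma::mat rCF(maxrec, 2 * std::max(ncon, 1));
  arma::imat rCFl(maxrec, std::max(ncon, 1));
  arma::mat rBF(maxrec, std::max(nbone, 1)), rBS(maxrec, std::max(nbone, 1)),
            rBM(maxrec, std::max(nbone, 1)), rSR(maxrec, std::max(nbone, 1)),
            rSF(maxrec, std::max(nbone, 1));
  int nrec = 0;

  int termCode = 0;       // 0 duration, 1 fall, 2 stress fail
  double termTime = duration;
  int termBone = -1;

  const double mtot = arma::accu(mass);

  for (int step = 0; step <= nsteps; ++step) {
    const double t = step * dt;

    // ---- kinematics, velocities, Jacobians, bias accelerations ----------
    Jo.zeros(); Jc.zeros(); Jw.zeros();
    for (int b = 0; b < nb; ++b) {
      const int p = parent(b);
      if (p < 0 && jtype(b) == 3) {
        // fixed (grounded) root: pose stored in anchorParent / refAngle
        phi(b) = refAng(b);
        xo.col(b) = ap.col(b);
        omg(b) = 0.0;
        vo.col(b).zeros();
        abo.col(b).zeros();
      } else if (p < 0) {
        phi(b) = q(2) + refAng(b);
        xo.col(b) = q.subvec(0, 1);
        omg(b) = qd(2);
        vo.col(b) = qd.subvec(0, 1);
        abo.col(b).zeros();
        Jo(0, 0, b) = 1.0; Jo(1, 1, b) = 1.0;
        Jw(2, b) = 1.0;
      } else {
        const double th = (jtype(b) == 1) ? q(dof(b)) : 0.0;
        phi(b) = phi(p) + refAng(b) + th;
        const double cp = std::cos(phi(p)), sp = std::sin(phi(p));
        const double cb = std::cos(phi(b)), sb = std::sin(phi(b));
        arma::vec2 rp = {cp * ap(0, b) - sp * ap(1, b),
                         sp * ap(0, b) + cp * ap(1, b)};
        arma::vec2 rc = {cb * ac(0, b) - sb * ac(1, b),
                         sb * ac(0, b) + cb * ac(1, b)};
        arma::vec2 anchorW = xo.col(p) + rp;
        xo.col(b) = anchorW - rc;
        omg(b) = omg(p) + ((jtype(b) == 1) ? qd(dof(b)) : 0.0);
        arma::vec2 vanch = vo.col(p) + omg(p) * perp(rp);
        vo.col(b) = vanch - omg(b) * perp(rc);
        // bias accelerations (qdd = 0): centripetal only
        arma::vec2 abAnch = abo.col(p) - omg(p) * omg(p) * rp;
        abo.col(b) = abAnch + omg(b) * omg(b) * rc;
        // Jacobians
        arma::vec2 prp = perp(rp), prc = perp(rc);
        for (int k = 0; k < nq; ++k) {
          double jwp = Jw(k, p);
          Jw(k, b) = jwp;
          Jo(0, k, b) = Jo(0, k, p) + jwp * prp(0);
          Jo(1, k, b) = Jo(1, k, p) + jwp * prp(1);
        }
        if (jtype(b) == 1) {
          Jw(dof(b), b) += 1.0;
        }
        for (int k = 0; k < nq; ++k) {
          double jwb = Jw(k, b);
          Jo(0, k, b) -= jwb * prc(0);
          Jo(1, k, b) -= jwb * prc(1);
        }
      }
      const double cb = std::cos(phi(b)), sb = std::sin(phi(b));
      arma::vec2 rcom = {cb * comL(0, b) - sb * comL(1, b),
                         sb * comL(0, b) + cb * comL(1, b)};
      cw.col(b) = xo.col(b) + rcom;
      cv.col(b) = vo.col(b) + omg(b) * perp(rcom);
      abc.col(b) = abo.col(b) - omg(b) * omg(b) * rcom;
      arma::vec2 prcom = perp(rcom);
      for (int k = 0; k < nq; ++k) {
        double jwb = Jw(k, b);
        Jc(0, k, b) = Jo(0, k, b) + jwb * prcom(0);
        Jc(1, k, b) = Jo(1, k, b) + jwb * prcom(1);
      }
    }

    // ---- generalized forces ---------------------------------------------
    Q.zeros();
    Facc.zeros();
    Tacc.zeros();

    // gravity
    for (int b = 0; b < nb; ++b) {
      const arma::vec2 Fg = mass(b) * grav;
      for (int k = 0; k < nq; ++k)
        Q(k) += Jc(0, k, b) * Fg(0) + Jc(1, k, b) * Fg(1);
    }

    // applies F at world point pw on body b (and bookkeeping for load cuts)
    auto applyForce = [&](int b, const arma::vec2& pw, const arma::vec2& F) {
      arma::vec2 r = pw - xo.col(b);
      double tq = cross2(r, F);
      for (int k = 0; k < nq; ++k)
        Q(k) += Jo(0, k, b) * F(0) + Jo(1, k, b) * F(1) + Jw(k, b) * tq;
      Facc.col(b) += F;
      Tacc(b) += cross2(pw - cw.col(b), F);
    };

    // muscles
    if (nm > 0) {
      // activation dynamics (exact first-order update over dt)
      if (step > 0) {
        for (int m = 0; m < nm; ++m) {
          double tc = t / cycle;
          double frac = tc - std::floor(tc);
          int ph = (nphase > 1) ? (int)std::floor(nphase * frac) : 0;
          if (ph >= nphase) ph = nphase - 1;
          double u = U(m, ph);
          act(m) = u + (act(m) - u) * std::exp(-dt / tauAct(m));
        }
      }
      // world points
      for (int i = 0; i < musOff(nm); ++i) {
        int b = musBody(i);
        const double cb = std::cos(phi(b)), sb = std::sin(phi(b));
        mwpts(0, i) = xo(0, b) + cb * musPt(0, i) - sb * musPt(1, i);
        mwpts(1, i) = xo(1, b) + sb * musPt(0, i) + cb * musPt(1, i);
      }
      for (int m = 0; m < nm; ++m) {
        double L = 0.0, Ldot = 0.0;
        for (int i = musOff(m); i < musOff(m + 1) - 1; ++i) {
          arma::vec2 d = mwpts.col(i + 1) - mwpts.col(i);
          double len = arma::norm(d);
          if (len < 1e-12) continue;
          arma::vec2 u = d / len;
          int b0i = musBody(i), b1i = musBody(i + 1);
          arma::vec2 v0 = vo.col(b0i) + omg(b0i) * perp(mwpts.col(i) - xo.col(b0i));
          arma::vec2 v1 = vo.col(b1i) + omg(b1i) * perp(mwpts.col(i + 1) - xo.col(b1i));
          L += len;
          Ldot += arma::dot(u, v1 - v0);
        }
        // stiff-tendon Hill model
        double lf = L - lslack(m);
        double F = 0.0;
        if (lf > 0.01 * lopt(m)) {
          double ln = lf / lopt(m);
          double vn = Ldot / vmax(m);
          double f = act(m) * curveFL(ln) * curveFV(vn) + musDamp * vn;
          F = std::max(0.0, fmax(m) * f);
        }
        mforce(m) = F;
        if (F > 0.0) {
          for (int i = musOff(m); i < musOff(m + 1) - 1; ++i) {
            arma::vec2 d = mwpts.col(i + 1) - mwpts.col(i);
            double len = arma::norm(d);
            if (len < 1e-12) continue;
            arma::vec2 u = d / len;
            applyForce(musBody(i), mwpts.col(i), F * u);
            applyForce(musBody(i + 1), mwpts.col(i + 1), -F * u);
          }
        }
      }
    }

    // contacts (ground plane at y = 0; spring-damper normal, regularised
    // Coulomb friction; never tensile)
    for (int c = 0; c < ncon; ++c) {
      int b = conBody(c);
      const double cb = std::cos(phi(b)), sb = std::sin(phi(b));
      arma::vec2 ctr = {xo(0, b) + cb * conPos(0, c) - sb * conPos(1, c),
                        xo(1, b) + sb * conPos(0, c) + cb * conPos(1, c)};
      double pen = conR(c) - ctr(1);
      cfrc.col(c).zeros();
      cflag(c) = 0;
      if (pen > 0.0) {
        arma::vec2 vctr = vo.col(b) + omg(b) * perp(ctr - xo.col(b));
        double N = conK(c) * pen - conC(c) * vctr(1);
        if (N > 0.0) {
          arma::vec2 cpt = {ctr(0), ctr(1) - conR(c)};
          arma::vec2 vcpt = vo.col(b) + omg(b) * perp(cpt - xo.col(b));
          double s = vcpt(0) / vreg;
          if (s > 1.0) s = 1.0; else if (s < -1.0) s = -1.0;
          arma::vec2 F = {-conMu(c) * N * s, N};
          applyForce(b, cpt, F);
          cfrc.col(c) = F;
          cflag(c) = 1;
        }
      }
    }

    // joint range limits (one-sided torsional spring-damper) + damping
    for (int j = 0; j < nlim; ++j) {
      int k = limDof(j);
      double th = q(k), w = qd(k), tq = -jdamp(j) * w;
      if (th > limMax(j))      tq += -limK(j) * (th - limMax(j)) - limC(j) * w;
      else if (th < limMin(j)) tq += -limK(j) * (th - limMin(j)) - limC(j) * w;
      Q(k) += tq;
    }

    // inertial bias
    for (int b = 0; b < nb; ++b)
      for (int k = 0; k < nq; ++k)
        Q(k) -= mass(b) * (Jc(0, k, b) * abc(0, b) + Jc(1, k, b) * abc(1, b));

    // ---- mass matrix and solve -------------------------------------------
    M.zeros();
    for (int b = 0; b < nb; ++b) {
      const double mb = mass(b), Ib = inertia(b);
      for (int k = 0; k < nq; ++k) {
        double j0 = Jc(0, k, b), j1 = Jc(1, k, b), jw = Jw(k, b);
        if (j0 == 0.0 && j1 == 0.0 && jw == 0.0) continue;
        for (int l = k; l < nq; ++l) {
          M(k, l) += mb * (j0 * Jc(0, l, b) + j1 * Jc(1, l, b))
                     + Ib * jw * Jw(l, b);
        }
      }
    }
    M = arma::symmatu(M);
    bool ok = arma::solve(qdd, M, Q, arma::solve_opts::likely_sympd);
    bool diverged = !ok || !qdd.is_finite() || !q.is_finite();

    // ---- internal loads at monitored cuts, stress, monitors --------------
    bool stressFail = false;
    if (diverged) qdd.zeros();
    for (int k = 0; k < nbone; ++k) {
      int cb = cutBody(k);
      const double cph = std::cos(phi(cb)), sph = std::sin(phi(cb));
      arma::vec2 pcut = {xo(0, cb) + cph * cutLocal(0, k) - sph * cutLocal(1, k),
                         xo(1, cb) + sph * cutLocal(0, k) + cph * cutLocal(1, k)};
      arma::vec2 axis = {cph * axisLocal(0, k) - sph * axisLocal(1, k),
                         sph * axisLocal(0, k) + cph * axisLocal(1, k)};
      arma::vec2 Fcut = {0.0, 0.0};
      double Mcut = 0.0;
      const arma::ivec& sub = subtree[k];
      for (arma::uword si = 0; si < sub.n_elem; ++si) {
        int b = sub(si);
        arma::vec2 acom = abc.col(b);
        double alpha = 0.0;
        for (int kk = 0; kk < nq; ++kk) {
          acom(0) += Jc(0, kk, b) * qdd(kk);
          acom(1) += Jc(1, kk, b) * qdd(kk);
          alpha += Jw(kk, b) * qdd(kk);
        }
        arma::vec2 inertF = mass(b) * (acom - grav) - Facc.col(b);
        Fcut += inertF;
        Mcut += inertia(b) * alpha
                + cross2(cw.col(b) - pcut, mass(b) * (acom - grav))
                - (Tacc(b) + cross2(cw.col(b) - pcut, Facc.col(b)));
      }
      double fax = -arma::dot(Fcut, axis);                 // tension positive
      double shear = -cross2(axis, Fcut);
      boneFax(k) = fax;
      boneShear(k) = shear;
      boneM(k) = Mcut;
      double s0 = fax / boneA(k);
      double bmax = (Mcut >= 0.0) ? Mcut * boneGmax(k) : Mcut * boneGmin(k);
      double bmin = (Mcut >= 0.0) ? Mcut * boneGmin(k) : Mcut * boneGmax(k);
      double smax = s0 + bmax, smin = s0 + bmin;
      sRaw(k) = std::max(std::fabs(smax), std::fabs(smin));
      sFilt(k) = filt[k].step(sRaw(k));
      if (sFilt(k) > slimit && !stressFail) {
        stressFail = true;
        termBone = k;
      }
    }

    // ---- COM, energy, hip ------------------------------------------------
    arma::vec2 com = {0, 0}, comv = {0, 0};
    double ke = 0.0, pe = 0.0;
    for (int b = 0; b < nb; ++b) {
      com += mass(b) * cw.col(b);
      comv += mass(b) * cv.col(b);
      ke += 0.5 * mass(b) * arma::dot(cv.col(b), cv.col(b))
            + 0.5 * inertia(b) * omg(b) * omg(b);
      pe += -mass(b) * arma::dot(grav, cw.col(b));
    }
    com /= mtot; comv /= mtot;
    const double chb = std::cos(phi(hipBody)), shb = std::sin(phi(hipBody));
    double hipY = xo(1, hipBody) + shb * hipLocal(0) + chb * hipLocal(1);

    if (arma::norm(comv) > maxSpeed || !std::isfinite(hipY)) diverged = true;
    bool fell = fallOn && (hipY < fallY);
    bool last = (step == nsteps) || stressFail || fell || diverged;

    if (step % recEvery == 0 || last) {
      rT(nrec) = t;
      rQ.row(nrec) = q.t();
      rQd.row(nrec) = qd.t();
      rCom.row(nrec) = com.t();
      rComv.row(nrec) = comv.t();
      rHip(nrec) = hipY; rKE(nrec) = ke; rPE(nrec) = pe;
      if (nm > 0) { rAct.row(nrec) = act.t(); rMF.row(nrec) = mforce.t(); }
      for (int c = 0; c < ncon; ++c) {
        rCF(nrec, 2 * c) = cfrc(0, c);
        rCF(nrec, 2 * c + 1) = cfrc(1, c);
        rCFl(nrec, c) = cflag(c);
      }
      for (int k = 0; k < nbone; ++k) {
        rBF(nrec, k) = boneFax(k); rBS(nrec, k) = boneShear(k);
        rBM(nrec, k) = boneM(k); rSR(nrec, k) = sRaw(k);
        rSF(nrec, k) = sFilt(k);
      }
      ++nrec;
    }

    if (diverged)   { termCode = 3; termTime = t; break; }
    if (stressFail) { termCode = 2; termTime = t; break; }
    if (fell)       { termCode = 1; termTime = t; break; }
    if (step == nsteps) { termCode = 0; termTime = t; break; }

    // ---- semi-implicit Euler step ----------------------------------------
    qd += dt * qdd;
    q += dt * qd;
  }

  auto takeM = [&](const arma::mat& Mx) { return Mx.rows(0, nrec - 1); };
  auto takeV = [&](const arma::vec& Vx) { return Vx.subvec(0, nrec - 1); };

  return List::create(
    _["time"] = takeV(rT),
    _["q"] = takeM(rQ), _["qd"] = takeM(rQd),
    _["com"] = takeM(rCom), _["comVel"] = takeM(rComv),
    _["hipHeight"] = takeV(rHip),
    _["kineticEnergy"] = takeV(rKE), _["potentialEnergy"] = takeV(rPE),
    _["activation"] = nm > 0 ? wrap(takeM(rAct)) : wrap(arma::mat(nrec, 0)),
    _["muscleForce"] = nm > 0 ? wrap(takeM(rMF)) : wrap(arma::mat(nrec, 0)),
    _["contactForce"] = ncon > 0 ? wrap(takeM(rCF)) : wrap(arma::mat(nrec, 0)),
    _["contactFlag"] = ncon > 0 ? wrap(rCFl.rows(0, nrec - 1))
                                : wrap(arma::imat(nrec, 0)),
    _["boneAxial"] = nbone > 0 ? wrap(takeM(rBF)) : wrap(arma::mat(nrec, 0)),
    _["boneShear"] = nbone > 0 ? wrap(takeM(rBS)) : wrap(arma::mat(nrec, 0)),
    _["boneMoment"] = nbone > 0 ? wrap(takeM(rBM)) : wrap(arma::mat(nrec, 0)),
    _["stressRaw"] = nbone > 0 ? wrap(takeM(rSR)) : wrap(arma::mat(nrec, 0)),
    _["stressFiltered"] = nbone > 0 ? wrap(takeM(rSF)) : wrap(arma::mat(nrec, 0)),
    _["termCode"] = termCode,
    _["termTime"] = termTime,
    _["termBone"] = termBone + 1);
}
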