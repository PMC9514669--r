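// Compiled core: model vector fields with analytic first and (contracted)
// second derivatives, Hermite-Simpson collocation residuals, and the
// penalty-annealed objectives (least squares / DSPE / OC-DSPE) with exact
// gradients in states, momenta, controls and parameters.
//
// Model ids: 1 = Lorenz96 (theta = F), 2 = Morris-Lecar family
// (theta = C, g_fast, g_slow, g_leak, E_Na, E_K, E_leak, phi_w, beta_w,
//  beta_m, gamma_m, gamma_w, g_NaP, E_NaP; the K+Na model is g_NaP = 0).
// Method ids: 1 = LSQ, 2 = DSPE, 3 = OC-DSPE.
//
// The interval loop is the hot path of every optimizer iteration, so the
// inner kernels use explicit scalar loops on preallocated buffers; no
// temporaries are created per interval.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const int ML_NP = 14;

// ---------------------------------------------------------------------------
// Lorenz96: f_d = (x_{d+1} - x_{d-2}) x_{d-1} - x_d + F, cyclic indices.
// ---------------------------------------------------------------------------
static void lorenz96_eval(const vec& x, const vec& th, vec& f,
                          mat* Jx, mat* Jth,
                          const vec* p, mat* Hxx, mat* Hxth) {
  const int D = x.n_elem;
  const double F = th(0);
  f.set_size(D);
  for (int d = 0; d < D; ++d) {
    const int ip1 = (d + 1) % D, im1 = (d - 1 + D) % D, im2 = (d - 2 + D) % D;
    f(d) = (x(ip1) - x(im2)) * x(im1) - x(d) + F;
  }
  if (Jx) {
    Jx->zeros(D, D);
    for (int d = 0; d < D; ++d) {
      const int ip1 = (d + 1) % D, im1 = (d - 1 + D) % D, im2 = (d - 2 + D) % D;
      (*Jx)(d, ip1) += x(im1);
      (*Jx)(d, im2) += -x(im1);
      (*Jx)(d, im1) += x(ip1) - x(im2);
      (*Jx)(d, d)   += -1.0;
    }
  }
  if (Jth) Jth->ones(D, 1);
  if (p) {
    // Hxx(d,e) = sum_j p_j d2 f_j / dx_d dx_e ; only cross terms survive.
    Hxx->zeros(D, D);
    for (int j = 0; j < D; ++j) {
      const int ip1 = (j + 1) % D, im1 = (j - 1 + D) % D, im2 = (j - 2 + D) % D;
      (*Hxx)(ip1, im1) += (*p)(j);
      (*Hxx)(im1, ip1) += (*p)(j);
      (*Hxx)(im2, im1) -= (*p)(j);
      (*Hxx)(im1, im2) -= (*p)(j);
    }
    if (Hxth) Hxth->zeros(D, 1);
  }
}

// ---------------------------------------------------------------------------
// Morris-Lecar (K+Na, optional persistent-Na term). State (V, w).
// ---------------------------------------------------------------------------
static void ml_eval(const vec& x, const vec& th, double I, vec& f,
                    mat* Jx, mat* Jth,
                    const vec* p, mat* Hxx, mat* Hxth) {
  const double V = x(0), w = x(1);
  const double C = th(0), gf = th(1), gs = th(2), gl = th(3);
  const double ENa = th(4), EK = th(5), El = th(6);
  const double phiw = th(7), bw = th(8), bm = th(9);
  const double gm = th(10), gw = th(11), gnp = th(12), Enp = th(13);

  const double u  = (V - bm) / gm;
  const double tu = std::tanh(u), s2u = 1.0 - tu * tu;
  const double m   = 0.5 * (1.0 + tu);
  const double mp  = 0.5 * s2u / gm;
  const double mpp = -s2u * tu / (gm * gm);

  // v2 enters through cosh/sinh (the gating rate 1/tau_w). Clamp it: for
  // |v2| > 10 the implied tau_w < 1e-4 ms is physically meaningless, and
  // the exponential wall otherwise produces curvature that defeats the
  // bounded line search at extreme (but in-bounds) parameter samples.
  const double v1 = (V - bw) / gw;
  double v2 = 0.5 * v1;
  if (v2 > 10.0) v2 = 10.0; else if (v2 < -10.0) v2 = -10.0;
  const double tv = std::tanh(v1), s2v = 1.0 - tv * tv;
  const double winf   = 0.5 * (1.0 + tv);
  const double winfp  = 0.5 * s2v / gw;
  const double winfpp = -s2v * tv / (gw * gw);
  const double ch = std::cosh(v2), sh = std::sinh(v2);

  const double S = -gf * m * (V - ENa) - gs * w * (V - EK)
                   - gl * (V - El) - gnp * m * (V - Enp) + I;
  const double fV = S / C;
  const double fw = phiw * (winf - w) * ch;
  f.set_size(2);
  f(0) = fV;
  f(1) = fw;

  const double a = -gf * (mp * (V - ENa) + m) - gs * w - gl
                   - gnp * (mp * (V - Enp) + m);   // dS/dV
  const double bb = phiw * (winfp * ch + (winf - w) * sh / (2.0 * gw)); // dfw/dV

  if (Jx) {
    Jx->set_size(2, 2);
    (*Jx)(0, 0) = a / C;
    (*Jx)(0, 1) = -gs * (V - EK) / C;
    (*Jx)(1, 0) = bb;
    (*Jx)(1, 1) = -phiw * ch;
  }
  if (Jth) {
    Jth->zeros(2, ML_NP);
    (*Jth)(0, 0)  = -fV / C;
    (*Jth)(0, 1)  = -m * (V - ENa) / C;
    (*Jth)(0, 2)  = -w * (V - EK) / C;
    (*Jth)(0, 3)  = -(V - El) / C;
    (*Jth)(0, 4)  = gf * m / C;
    (*Jth)(0, 5)  = gs * w / C;
    (*Jth)(0, 6)  = gl / C;
    (*Jth)(0, 9)  = (gf * (V - ENa) + gnp * (V - Enp)) * mp / C;
    (*Jth)(0, 10) = (gf * (V - ENa) + gnp * (V - Enp)) * mp * u / C;
    (*Jth)(0, 12) = -m * (V - Enp) / C;
    (*Jth)(0, 13) = gnp * m / C;
    (*Jth)(1, 7)  = (winf - w) * ch;
    (*Jth)(1, 8)  = -bb;
    (*Jth)(1, 11) = -(phiw / gw) * (0.5 * s2v * v1 * ch + (winf - w) * v2 * sh);
  }
  if (p) {
    const double pV = (*p)(0), pw = (*p)(1);
    const double d2fV_VV = (-gf * (mpp * (V - ENa) + 2.0 * mp)
                            - gnp * (mpp * (V - Enp) + 2.0 * mp)) / C;
    const double d2fV_Vw = -gs / C;
    const double d2fw_VV = phiw * (winfpp * ch + winfp * sh / gw
                                   + (winf - w) * ch / (4.0 * gw * gw));
    const double d2fw_Vw = -phiw * sh / (2.0 * gw);
    Hxx->set_size(2, 2);
    (*Hxx)(0, 0) = pV * d2fV_VV + pw * d2fw_VV;
    (*Hxx)(0, 1) = pV * d2fV_Vw + pw * d2fw_Vw;
    (*Hxx)(1, 0) = (*Hxx)(0, 1);
    (*Hxx)(1, 1) = 0.0;
    if (!Hxth) return;

    // second derivatives wrt (state, theta), contracted with p
    const double dm_dgm  = -mp * u;
    const double dmp_dgm = -mpp * u - mp / gm;
    double gV[ML_NP] = {0}, gw_[ML_NP] = {0}, hV[ML_NP] = {0}, hw[ML_NP] = {0};
    gV[0]  = -a / (C * C);
    gV[1]  = -(mp * (V - ENa) + m) / C;
    gV[2]  = -w / C;
    gV[3]  = -1.0 / C;
    gV[4]  = gf * mp / C;
    gV[9]  = (gf * (mpp * (V - ENa) + mp) + gnp * (mpp * (V - Enp) + mp)) / C;
    gV[10] = (-gf * (dmp_dgm * (V - ENa) + dm_dgm)
              - gnp * (dmp_dgm * (V - Enp) + dm_dgm)) / C;
    gV[12] = -(mp * (V - Enp) + m) / C;
    gV[13] = gnp * mp / C;
    gw_[0] = gs * (V - EK) / (C * C);
    gw_[2] = -(V - EK) / C;
    gw_[5] = gs / C;
    const double dwinf_dgw  = -winfp * v1;
    const double dwinfp_dgw = -winfpp * v1 - winfp / gw;
    hV[7]  = bb / phiw;
    hV[8]  = -d2fw_VV;
    hV[11] = phiw * (dwinfp_dgw * ch - winfp * sh * v2 / gw
                     + dwinf_dgw * sh / (2.0 * gw)
                     + (winf - w) * (-ch * v2 / (2.0 * gw * gw)
                                     - sh / (2.0 * gw * gw)));
    hw[7]  = -ch;
    hw[8]  = phiw * sh / (2.0 * gw);
    hw[11] = phiw * sh * v2 / gw;

    Hxth->set_size(2, ML_NP);
    for (int k = 0; k < ML_NP; ++k) {
      (*Hxth)(0, k) = pV * gV[k] + pw * hV[k];
      (*Hxth)(1, k) = pV * gw_[k] + pw * hw[k];
    }
  }
}

static void model_eval(int model_id, const vec& x, const vec& th, double I,
                       vec& f, mat* Jx, mat* Jth,
                       const vec* p, mat* Hxx, mat* Hxth) {
  if (model_id == 1) lorenz96_eval(x, th, f, Jx, Jth, p, Hxx, Hxth);
  else               ml_eval(x, th, I, f, Jx, Jth, p, Hxx, Hxth);
}

// [[Rcpp::export]]
arma::vec cpp_model_rhs(int model_id, const arma::vec& x,
                        const arma::vec& theta, double stim) {
  vec f;
  model_eval(model_id, x, theta, stim, f, nullptr, nullptr,
             nullptr, nullptr, nullptr);
  return f;
}

// [[Rcpp::export]]
arma::mat cpp_model_jac(int model_id, const arma::vec& x,
                        const arma::vec& theta, double stim) {
  vec f;
  mat Jx;
  model_eval(model_id, x, theta, stim, f, &Jx, nullptr,
             nullptr, nullptr, nullptr);
  return Jx;
}

// ---------------------------------------------------------------------------
// Workspace for one objective evaluation; all buffers sized once.
// ---------------------------------------------------------------------------
struct ObjWork {
  vec x, p, f, phi, zm, wv, sv, t1, t2;
  mat Jx, Jth, Hxx, Hxth, A, B, Cu;
  void init(int D, int M, int P, int L) {
    x.set_size(D); p.set_size(D); f.set_size(D);
    phi.set_size(M); zm.set_size(M);
    wv.set_size(M); sv.set_size(M); t1.set_size(M); t2.set_size(M);
    A.set_size(M, M); B.zeros(M, P);
    if (L > 0) Cu.zeros(M, L);
  }
};

// Constrained dynamics phi(z) per method, with Jacobians wrt z, theta, U.
// z layout: rows 0..D-1 are states x; OC-DSPE appends momenta p in rows
// D..2D-1.  "obs" holds 0-based observed state indices; y follows the
// convention of zeros in unobserved rows.  Results land in wk.phi / wk.A /
// wk.B / wk.Cu.
static void phi_eval(int method, int model_id, const double* z,
                     const double* Ucol, const double* ycol,
                     const uvec& obs, double I, const vec& th, bool grad,
                     ObjWork& wk) {
  const int M = wk.phi.n_elem;
  const int D = (method == 3) ? M / 2 : M;
  const int L = obs.n_elem;

  for (int d = 0; d < D; ++d) wk.x(d) = z[d];

  if (method != 3) {
    model_eval(model_id, wk.x, th, I, wk.f,
               grad ? &wk.Jx : nullptr, grad ? &wk.Jth : nullptr,
               nullptr, nullptr, nullptr);
    for (int d = 0; d < D; ++d) wk.phi(d) = wk.f(d);
    if (method == 2) {
      for (int l = 0; l < L; ++l) {
        const int d = obs(l);
        wk.phi(d) += Ucol[l] * (ycol[d] - z[d]);
      }
    }
    if (grad) {
      wk.A = wk.Jx;
      wk.B = wk.Jth;
      if (method == 2) {
        wk.Cu.zeros();
        for (int l = 0; l < L; ++l) {
          const int d = obs(l);
          wk.A(d, d) -= Ucol[l];
          wk.Cu(d, l) = ycol[d] - z[d];
        }
      }
    }
    return;
  }

  // OC-DSPE estimation dynamics
  for (int d = 0; d < D; ++d) wk.p(d) = z[D + d];
  model_eval(model_id, wk.x, th, I, wk.f,
             &wk.Jx, grad ? &wk.Jth : nullptr,
             &wk.p, &wk.Hxx, grad ? &wk.Hxth : nullptr);
  // r_d = [y - Hx]_d (zero on unobserved rows)
  double r[64];  // D <= 32 for OC-DSPE problems handled here
  for (int d = 0; d < D; ++d) r[d] = 0.0;
  for (int l = 0; l < L; ++l) {
    const int d = obs(l);
    r[d] = ycol[d] - z[d];
  }
  for (int d = 0; d < D; ++d) {
    wk.phi(d) = wk.f(d) - wk.p(d) * r[d] * r[d];
    double s = 0.0;
    for (int j = 0; j < D; ++j) s += wk.Jx(j, d) * wk.p(j);
    wk.phi(D + d) = -s + r[d] * (1.0 - wk.p(d) * wk.p(d));
  }
  if (grad) {
    wk.A.zeros();
    for (int e = 0; e < D; ++e)
      for (int d = 0; d < D; ++d) {
        wk.A(d, e) = wk.Jx(d, e);
        wk.A(D + d, e) = -wk.Hxx(d, e);
        wk.A(D + d, D + e) = -wk.Jx(e, d);
      }
    for (int d = 0; d < D; ++d) {
      wk.A(d, D + d) += -r[d] * r[d];
      wk.A(D + d, D + d) += -2.0 * wk.p(d) * r[d];
    }
    for (int l = 0; l < L; ++l) {
      const int d = obs(l);
      wk.A(d, d) += 2.0 * wk.p(d) * r[d];
      wk.A(D + d, d) += -(1.0 - wk.p(d) * wk.p(d));
    }
    const int P = wk.B.n_cols;
    for (int k = 0; k < P; ++k)
      for (int d = 0; d < D; ++d) {
        wk.B(d, k) = wk.Jth(d, k);
        wk.B(D + d, k) = -wk.Hxth(d, k);
      }
  }
}

// out += A^T v  (A is M x M, column-major)
static inline void add_atv(const double* A, int M, const double* v,
                           double* out) {
  for (int c = 0; c < M; ++c) {
    double s = 0.0;
    const double* col = A + (size_t)c * M;
    for (int rIdx = 0; rIdx < M; ++rIdx) s += col[rIdx] * v[rIdx];
    out[c] += s;
  }
}

// ---------------------------------------------------------------------------
// Penalized objective and gradient.
//   value = cost(method) + lambda * sum_{i,n} R_i g_{i,n}^2
// with compressed Hermite-Simpson residuals
//   g_n = z_{n+1} - z_n - dt/6 (phi_n + 4 phi_mid + phi_{n+1}),
//   z_mid = (z_n + z_{n+1})/2 + dt/8 (phi_n - phi_{n+1}),
// time-dependent data (y, stimulus, U) linearly interpolated at midpoints.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cpp_objective(int method, int model_id,
                         const arma::mat& z, const arma::mat& U,
                         const arma::vec& theta,
                         const arma::mat& y, const arma::uvec& obs,
                         const arma::vec& stim, double dt, double lambda,
                         const arma::vec& Rscale,
                         bool want_grad, bool want_resid) {
  const int M = z.n_rows, N = z.n_cols;
  const int D = (method == 3) ? M / 2 : M;
  const int L = obs.n_elem;
  const int P = theta.n_elem;

  ObjWork wk;
  wk.init(D, M, P, method == 2 ? L : 0);

  // measurement cost (and gradients) at the nodes
  double cost = 0.0;
  mat gz, gU;
  vec gth;
  if (want_grad) {
    gz.zeros(M, N);
    gth.zeros(P);
    if (method == 2) gU.zeros(L, N);
  }
  for (int n = 0; n < N; ++n) {
    for (int l = 0; l < L; ++l) {
      const int d = obs(l);
      const double r = z(d, n) - y(d, n);
      if (method == 3) {
        const double pd = z(D + d, n);
        cost += 0.5 * r * r * (1.0 + pd * pd);
        if (want_grad) {
          gz(d, n) += r * (1.0 + pd * pd);
          gz(D + d, n) += r * r * pd;
        }
      } else {
        cost += r * r;
        if (want_grad) gz(d, n) += 2.0 * r;
      }
    }
    if (method == 2) {
      for (int l = 0; l < L; ++l) {
        cost += U(l, n) * U(l, n);
        if (want_grad) gU(l, n) += 2.0 * U(l, n);
      }
    }
  }

  // Rolling node buffers: each node is evaluated once; the interval loop
  // uses the (n, n+1) pair and the Hermite midpoint.
  ObjWork nodeA, nodeB, wkm;
  nodeA.init(D, M, P, method == 2 ? L : 0);
  nodeB.init(D, M, P, method == 2 ? L : 0);
  wkm.init(D, M, P, method == 2 ? L : 0);
  ObjWork* cur = &nodeA;
  ObjWork* nxt = &nodeB;

  const double* yptr = y.memptr();
  const double* zptr = z.memptr();
  const double* Uptr = (method == 2) ? U.memptr() : nullptr;
  phi_eval(method, model_id, zptr, Uptr, yptr, obs, stim(0), theta,
           want_grad, *cur);

  double penalty = 0.0;
  mat resid;
  if (want_resid) resid.set_size(M, N - 1);
  vec ym(D), Um(L > 0 ? L : 1), g(M);

  for (int n = 0; n < N - 1; ++n) {
    const double* z0 = zptr + (size_t)n * M;
    const double* z1 = zptr + (size_t)(n + 1) * M;
    phi_eval(method, model_id, z1,
             Uptr ? Uptr + (size_t)(n + 1) * L : nullptr,
             yptr + (size_t)(n + 1) * D, obs, stim(n + 1), theta,
             want_grad, *nxt);
    const double* phi0 = cur->phi.memptr();
    const double* phi1 = nxt->phi.memptr();
    for (int i = 0; i < M; ++i)
      wkm.zm(i) = 0.5 * (z0[i] + z1[i]) + (dt / 8.0) * (phi0[i] - phi1[i]);
    const double* y0 = yptr + (size_t)n * D;
    const double* y1 = yptr + (size_t)(n + 1) * D;
    for (int d = 0; d < D; ++d) ym(d) = 0.5 * (y0[d] + y1[d]);
    const double Im = 0.5 * (stim(n) + stim(n + 1));
    if (method == 2)
      for (int l = 0; l < L; ++l)
        Um(l) = 0.5 * (U(l, n) + U(l, n + 1));
    phi_eval(method, model_id, wkm.zm.memptr(),
             method == 2 ? Um.memptr() : nullptr,
             ym.memptr(), obs, Im, theta, want_grad, wkm);
    double pen_n = 0.0;
    for (int i = 0; i < M; ++i) {
      g(i) = z1[i] - z0[i]
             - (dt / 6.0) * (phi0[i] + 4.0 * wkm.phi(i) + phi1[i]);
      pen_n += Rscale(i) * g(i) * g(i);
    }
    penalty += pen_n;
    if (want_resid) resid.col(n) = g;
    if (want_grad) {
      // w = 2 lambda (R o g); s = Am^T w; then
      //   d/dz_n   : -w - dt/6 (An^T w + 2 s + dt/2 An^T s)
      //   d/dz_n+1 :  w - dt/6 (An1^T w + 2 s - dt/2 An1^T s)
      for (int i = 0; i < M; ++i) wk.wv(i) = 2.0 * lambda * Rscale(i) * g(i);
      wk.sv.zeros();
      add_atv(wkm.A.memptr(), M, wk.wv.memptr(), wk.sv.memptr());
      const double* A0 = cur->A.memptr();
      const double* A1 = nxt->A.memptr();
      wk.t1.zeros(); wk.t2.zeros();
      add_atv(A0, M, wk.wv.memptr(), wk.t1.memptr());   // An^T w
      add_atv(A0, M, wk.sv.memptr(), wk.t2.memptr());   // An^T s
      double* gz0 = gz.colptr(n);
      double* gz1 = gz.colptr(n + 1);
      for (int i = 0; i < M; ++i)
        gz0[i] += -wk.wv(i) - (dt / 6.0) * (wk.t1(i) + 2.0 * wk.sv(i)
                                            + (dt / 2.0) * wk.t2(i));
      wk.t1.zeros(); wk.t2.zeros();
      add_atv(A1, M, wk.wv.memptr(), wk.t1.memptr());   // An1^T w
      add_atv(A1, M, wk.sv.memptr(), wk.t2.memptr());   // An1^T s
      for (int i = 0; i < M; ++i)
        gz1[i] += wk.wv(i) - (dt / 6.0) * (wk.t1(i) + 2.0 * wk.sv(i)
                                           - (dt / 2.0) * wk.t2(i));
      // theta: -dt/6 (Bn^T w + Bn1^T w + 4 Bm^T w + dt/2 (Bn - Bn1)^T s)
      const double* B0 = cur->B.memptr();
      const double* B1 = nxt->B.memptr();
      const double* Bmp = wkm.B.memptr();
      for (int k = 0; k < P; ++k) {
        double s0w = 0.0, s1w = 0.0, smw = 0.0, s0s = 0.0, s1s = 0.0;
        const double* b0 = B0 + (size_t)k * M;
        const double* b1 = B1 + (size_t)k * M;
        const double* bm = Bmp + (size_t)k * M;
        for (int i = 0; i < M; ++i) {
          s0w += b0[i] * wk.wv(i);
          s1w += b1[i] * wk.wv(i);
          smw += bm[i] * wk.wv(i);
          s0s += b0[i] * wk.sv(i);
          s1s += b1[i] * wk.sv(i);
        }
        gth(k) += -(dt / 6.0) * (s0w + s1w + 4.0 * smw
                                 + (dt / 2.0) * (s0s - s1s));
      }
      if (method == 2) {
        // dU_n: -dt/6 (Cn^T w + 2 Cm^T w + dt/2 Cn^T s); mirrored for n+1
        const double* C0 = cur->Cu.memptr();
        const double* C1 = nxt->Cu.memptr();
        const double* Cmp = wkm.Cu.memptr();
        double* gU0 = gU.colptr(n);
        double* gU1 = gU.colptr(n + 1);
        for (int l = 0; l < L; ++l) {
          double c0w = 0.0, c1w = 0.0, cmw = 0.0, c0s = 0.0, c1s = 0.0;
          const double* cc0 = C0 + (size_t)l * M;
          const double* cc1 = C1 + (size_t)l * M;
          const double* ccm = Cmp + (size_t)l * M;
          for (int i = 0; i < M; ++i) {
            c0w += cc0[i] * wk.wv(i);
            c1w += cc1[i] * wk.wv(i);
            cmw += ccm[i] * wk.wv(i);
            c0s += cc0[i] * wk.sv(i);
            c1s += cc1[i] * wk.sv(i);
          }
          gU0[l] += -(dt / 6.0) * (c0w + 2.0 * cmw + (dt / 2.0) * c0s);
          gU1[l] += -(dt / 6.0) * (c1w + 2.0 * cmw - (dt / 2.0) * c1s);
        }
      }
    }
    std::swap(cur, nxt);
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("value") = cost + lambda * penalty,
    Rcpp::Named("cost") = cost,
    Rcpp::Named("penalty") = penalty);
  if (want_grad) {
    out["gz"] = gz;
    out["gtheta"] = gth;
    if (method == 2) out["gU"] = gU;
  }
  if (want_resid) out["resid"] = resid;
  return out;
}

// ---------------------------------------------------------------------------
// Damped Gauss-Newton direction for the penalized objective.  The residual
// system stacks the weighted collocation defects (one M-block per interval,
// coupling the node variables at n and n+1 and theta) and the measurement
// residuals (per node, diagonal).  The node variable is z_n for LSQ and
// OC-DSPE and [z_n; U_n] for DSPE, so the GN normal equations are block
// tridiagonal in the path with a dense theta border; they are solved by
// block-Thomas elimination plus a Schur complement in theta.  Levenberg
// damping mu is added per-variable in the optimizer's scaled coordinates
// (row_scale = per-row variable scale, length Ma).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
Rcpp::List cpp_gn_direction(int method, int model_id,
                            const arma::mat& z, const arma::mat& U,
                            const arma::vec& theta,
                            const arma::uvec& free_idx,
                            const arma::mat& y, const arma::uvec& obs,
                            const arma::vec& stim, double dt, double lambda,
                            const arma::vec& Rscale,
                            const arma::vec& row_scale, double mu) {
  const int M = z.n_rows, N = z.n_cols;
  const int D = (method == 3) ? M / 2 : M;
  const int L = obs.n_elem;
  const int P = theta.n_elem;
  const int Pf = free_idx.n_elem;
  const bool dspe = (method == 2);
  const int Ma = M + (dspe ? L : 0);    // augmented node dimension

  cube Dn(Ma, Ma, N, fill::zeros);      // diagonal blocks of H
  cube En(Ma, Ma, N > 1 ? N - 1 : 1, fill::zeros);  // super-diagonal blocks
  mat Hzt(Ma * (size_t)N, Pf, fill::zeros);
  mat Htt(Pf, Pf, fill::zeros);
  vec gz(Ma * (size_t)N, fill::zeros);
  vec gt(Pf, fill::zeros);

  // measurement cost contributions (nodes)
  for (int n = 0; n < N; ++n) {
    for (int l = 0; l < L; ++l) {
      const int d = obs(l);
      const double r = z(d, n) - y(d, n);
      if (method == 3) {
        const double p = z(D + d, n);
        const double s = std::sqrt(1.0 + p * p);
        // cost = 1/2 rho^2 with rho = r sqrt(1 + p^2)
        const double drx = s, drp = r * p / s;
        Dn(d, d, n) += drx * drx;
        Dn(d, D + d, n) += drx * drp;
        Dn(D + d, d, n) += drx * drp;
        Dn(D + d, D + d, n) += drp * drp;
        gz(n * (size_t)Ma + d) += r * (1.0 + p * p);
        gz(n * (size_t)Ma + D + d) += r * r * p;
      } else {
        Dn(d, d, n) += 2.0;
        gz(n * (size_t)Ma + d) += 2.0 * r;
      }
      if (dspe) {
        Dn(M + l, M + l, n) += 2.0;
        gz(n * (size_t)Ma + M + l) += 2.0 * U(l, n);
      }
    }
  }

  // collocation contributions (intervals)
  ObjWork nodeA, nodeB, wkm;
  nodeA.init(D, M, P, dspe ? L : 0);
  nodeB.init(D, M, P, dspe ? L : 0);
  wkm.init(D, M, P, dspe ? L : 0);
  ObjWork* cur = &nodeA;
  ObjWork* nxt = &nodeB;
  const double* yptr = y.memptr();
  const double* zptr = z.memptr();
  const double* Uptr = dspe ? U.memptr() : nullptr;
  phi_eval(method, model_id, zptr, Uptr, yptr, obs, stim(0), theta,
           true, *cur);
  vec ym(D), g(M), Um(L > 0 ? L : 1), wgt = 2.0 * lambda * Rscale;
  mat J0(M, Ma), J1(M, Ma), Gt(M, Pf), Bsub0(M, Pf), Bsub1(M, Pf),
      Bsubm(M, Pf);
  const mat I = eye(M, M);
  for (int n = 0; n < N - 1; ++n) {
    const double* z0 = zptr + (size_t)n * M;
    const double* z1 = zptr + (size_t)(n + 1) * M;
    phi_eval(method, model_id, z1,
             Uptr ? Uptr + (size_t)(n + 1) * L : nullptr,
             yptr + (size_t)(n + 1) * D, obs, stim(n + 1), theta,
             true, *nxt);
    for (int i = 0; i < M; ++i)
      wkm.zm(i) = 0.5 * (z0[i] + z1[i])
                  + (dt / 8.0) * (cur->phi(i) - nxt->phi(i));
    const double* y0 = yptr + (size_t)n * D;
    const double* y1 = yptr + (size_t)(n + 1) * D;
    for (int d = 0; d < D; ++d) ym(d) = 0.5 * (y0[d] + y1[d]);
    if (dspe)
      for (int l = 0; l < L; ++l) Um(l) = 0.5 * (U(l, n) + U(l, n + 1));
    phi_eval(method, model_id, wkm.zm.memptr(),
             dspe ? Um.memptr() : nullptr, ym.memptr(), obs,
             0.5 * (stim(n) + stim(n + 1)), theta, true, wkm);
    for (int i = 0; i < M; ++i)
      g(i) = z1[i] - z0[i]
             - (dt / 6.0) * (cur->phi(i) + 4.0 * wkm.phi(i) + nxt->phi(i));
    // interval Jacobians wrt the augmented node variables
    J0.cols(0, M - 1) =
      -I - (dt / 6.0) * (cur->A + 4.0 * wkm.A * (0.5 * I + (dt / 8.0) * cur->A));
    J1.cols(0, M - 1) =
       I - (dt / 6.0) * (nxt->A + 4.0 * wkm.A * (0.5 * I - (dt / 8.0) * nxt->A));
    if (dspe) {
      J0.cols(M, Ma - 1) =
        -(dt / 6.0) * (cur->Cu + 2.0 * wkm.Cu + (dt / 2.0) * wkm.A * cur->Cu);
      J1.cols(M, Ma - 1) =
        -(dt / 6.0) * (nxt->Cu + 2.0 * wkm.Cu - (dt / 2.0) * wkm.A * nxt->Cu);
    }
    for (int k = 0; k < Pf; ++k) {
      const int kk = free_idx(k);
      Bsub0.col(k) = cur->B.col(kk);
      Bsub1.col(k) = nxt->B.col(kk);
      Bsubm.col(k) = wkm.B.col(kk);
    }
    Gt = -(dt / 6.0) * (Bsub0 + Bsub1
                        + 4.0 * (Bsubm + (dt / 8.0) * wkm.A * (Bsub0 - Bsub1)));
    // H += J^T diag(wgt) J (each_col scales element (i, j) by wgt(i))
    mat L0 = J0; L0.each_col() %= wgt;
    mat L1 = J1; L1.each_col() %= wgt;
    mat Lt = Gt; Lt.each_col() %= wgt;
    Dn.slice(n)     += J0.t() * L0;
    Dn.slice(n + 1) += J1.t() * L1;
    En.slice(n)     += J0.t() * L1;
    Htt += Gt.t() * Lt;
    Hzt.rows((size_t)n * Ma, (size_t)n * Ma + Ma - 1) += J0.t() * Lt;
    Hzt.rows((size_t)(n + 1) * Ma, (size_t)(n + 1) * Ma + Ma - 1) +=
      J1.t() * Lt;
    const vec wg = wgt % g;
    gz.subvec((size_t)n * Ma, (size_t)n * Ma + Ma - 1) += J0.t() * wg;
    gz.subvec((size_t)(n + 1) * Ma, (size_t)(n + 1) * Ma + Ma - 1) +=
      J1.t() * wg;
    gt += Gt.t() * wg;
    std::swap(cur, nxt);
  }

  // Levenberg damping in scaled coordinates
  for (int n = 0; n < N; ++n)
    for (int i = 0; i < Ma; ++i)
      Dn(i, i, n) += mu / (row_scale(i) * row_scale(i));
  Htt.diag() += mu;

  // block-Thomas elimination with multi-RHS [ -gz | -Hzt ]
  mat Rhs(Ma * (size_t)N, Pf + 1);
  Rhs.col(0) = -gz;
  if (Pf > 0) Rhs.cols(1, Pf) = -Hzt;
  cube Sinv(Ma, Ma, N);
  mat S = Dn.slice(0);
  bool ok = true;
  for (int n = 0; n < N; ++n) {
    if (n > 0) {
      const mat& Em = En.slice(n - 1);
      const mat W = Em.t() * Sinv.slice(n - 1);
      S = Dn.slice(n) - W * Em;
      Rhs.rows((size_t)n * Ma, (size_t)n * Ma + Ma - 1) -=
        W * Rhs.rows((size_t)(n - 1) * Ma, (size_t)(n - 1) * Ma + Ma - 1);
    }
    mat Si;
    if (!inv_sympd(Si, symmatu(S))) {
      if (!inv(Si, S)) { ok = false; break; }
    }
    Sinv.slice(n) = Si;
  }
  if (!ok)
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  mat X(Ma * (size_t)N, Pf + 1);
  X.rows((size_t)(N - 1) * Ma, (size_t)(N - 1) * Ma + Ma - 1) =
    Sinv.slice(N - 1) *
    Rhs.rows((size_t)(N - 1) * Ma, (size_t)(N - 1) * Ma + Ma - 1);
  for (int n = N - 2; n >= 0; --n) {
    X.rows((size_t)n * Ma, (size_t)n * Ma + Ma - 1) =
      Sinv.slice(n) * (Rhs.rows((size_t)n * Ma, (size_t)n * Ma + Ma - 1)
                       - En.slice(n) * X.rows((size_t)(n + 1) * Ma,
                                              (size_t)(n + 1) * Ma + Ma - 1));
  }
  vec v = X.col(0);               // H^{-1} (-g)
  vec dtheta(Pf, fill::zeros);
  if (Pf > 0) {
    mat Uh = -X.cols(1, Pf);      // H^{-1} Hzt
    mat Schur = Htt - Hzt.t() * Uh;
    vec rhs_t = -gt - Hzt.t() * v;
    if (!solve(dtheta, symmatu(Schur), rhs_t))
      return Rcpp::List::create(Rcpp::Named("ok") = false);
    v -= Uh * dtheta;
  }
  mat Daug(v.memptr(), Ma, N);
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("ok") = true,
    Rcpp::Named("dz") = mat(Daug.rows(0, M - 1)),
    Rcpp::Named("dtheta") = dtheta);
  if (dspe) out["dU"] = mat(Daug.rows(M, Ma - 1));
  return out;
}

// ---------------------------------------------------------------------------
// Fixed-step RK4 of the nudged dynamics xdot = f + U (y(t) - Hx), with the
// observation record y interpolated linearly between grid points.  Used by
// the cost scans, where thousands of bounded controlled integrations are
// evaluated and adaptive stepping buys nothing.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
arma::mat cpp_rk4_nudged(int model_id, const arma::vec& x0,
                         const arma::vec& theta, double dt,
                         const arma::vec& stim, const arma::mat& y,
                         const arma::uvec& obs, const arma::vec& gains,
                         int substeps) {
  const int N = stim.n_elem;
  const int D = x0.n_elem;
  const int L = obs.n_elem;
  mat X(D, N);
  X.col(0) = x0;
  vec k1, k2, k3, k4, x = x0, xt(D);
  const double h = dt / substeps;
  for (int n = 0; n < N - 1; ++n) {
    const double I = stim(n);
    for (int s = 0; s < substeps; ++s) {
      const double frac0 = (double)s / substeps;
      auto ctrl = [&](const vec& xs, double frac, vec& k) {
        model_eval(model_id, xs, theta, I, k, nullptr, nullptr,
                   nullptr, nullptr, nullptr);
        for (int l = 0; l < L; ++l) {
          const int d = obs(l);
          const double yt = (1.0 - frac) * y(d, n) + frac * y(d, n + 1);
          k(d) += gains(l) * (yt - xs(d));
        }
      };
      ctrl(x, frac0, k1);
      xt = x + 0.5 * h * k1; ctrl(xt, frac0 + 0.5 / substeps, k2);
      xt = x + 0.5 * h * k2; ctrl(xt, frac0 + 0.5 / substeps, k3);
      xt = x + h * k3;       ctrl(xt, frac0 + 1.0 / substeps, k4);
      x += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      if (!x.is_finite()) { X.fill(datum::nan); return X; }
    }
    X.col(n + 1) = x;
  }
  return X;
}

// ---------------------------------------------------------------------------
// Fixed-step RK4 with zero-order-hold stimulus plus a per-step additive
// current perturbation (process noise, drawn in R for seed control).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
arma::mat cpp_rk4(int model_id, const arma::vec& x0, const arma::vec& theta,
                  double dt, const arma::vec& stim, const arma::vec& noise,
                  int substeps) {
  const int N = stim.n_elem;
  const int D = x0.n_elem;
  mat X(D, N);
  X.col(0) = x0;
  vec k1, k2, k3, k4, x = x0, xt(D);
  const double h = dt / substeps;
  for (int n = 0; n < N - 1; ++n) {
    const double I = stim(n) + noise(n);
    for (int s = 0; s < substeps; ++s) {
      model_eval(model_id, x, theta, I, k1, nullptr, nullptr,
                 nullptr, nullptr, nullptr);
      xt = x + 0.5 * h * k1;
      model_eval(model_id, xt, theta, I, k2, nullptr, nullptr,
                 nullptr, nullptr, nullptr);
      xt = x + 0.5 * h * k2;
      model_eval(model_id, xt, theta, I, k3, nullptr, nullptr,
                 nullptr, nullptr, nullptr);
      xt = x + h * k3;
      model_eval(model_id, xt, theta, I, k4, nullptr, nullptr,
                 nullptr, nullptr, nullptr);
      x += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    }
    X.col(n + 1) = x;
  }
  return X;
}
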