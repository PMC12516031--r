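// Simulated likelihood and analytic score for the integrated choice and
// latent variable (hybrid choice) model: sequential structural equations for
// three latent constructs, ordered-logit measurement of Likert indicators,
// and a panel mixed logit over tasks with two insurance alternatives plus an
// opt-out. One joint draw r supplies the three structural disturbances and
// the random-coefficient shocks; the per-person likelihood is the average
// over draws of (choice product x measurement product), accumulated in log
// space. All inner operations are vectorized over the draw dimension.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Raw parameter layout (must match the R side):
//   gamma (3*C, column-major), lambda (3), zeta (I), tau (I*4, column-major),
//   b (K), sigma (K), theta (M), delta (1), phi (3)
// [[Rcpp::export]]
Rcpp::List hcm_engine(
    const arma::mat& X,        // (N*T*2) x K coded attributes
    const arma::ivec& chosen,  // N*T in {1,2,3}; 3 = opt-out
    int N, int T, int K,
    const arma::mat& Z,        // N x C
    const arma::imat& Y,       // N x I (0 = missing); I may be 0
    const arma::ivec& ind_lat, // I in {0,1,2}
    const arma::imat& inter,   // M x 2: var (0..2 latent, 3+c covariate), level
    const arma::mat& eta,      // (N*R) x 3 when use_lat, else ignored
    const arma::mat& xi,       // (N*R) x K
    int R,
    const arma::mat& gamma,    // 3 x C
    const arma::vec& lambda,   // 3
    const arma::vec& zeta,     // I
    const arma::mat& tau,      // I x 4
    const arma::vec& b,
    const arma::vec& sigma,
    const arma::vec& theta,
    double delta,
    const arma::vec& phi,
    bool use_lat,
    bool want_grad,
    bool want_scores) {

  const int C = Z.n_cols;
  const int I = Y.n_cols;
  const int M = inter.n_rows;

  const int o_gamma = 0;
  const int o_lambda = o_gamma + 3 * C;
  const int o_zeta = o_lambda + 3;
  const int o_tau = o_zeta + I;
  const int o_b = o_tau + 4 * I;
  const int o_sigma = o_b + K;
  const int o_theta = o_sigma + K;
  const int o_delta = o_theta + M;
  const int o_phi = o_delta + 1;
  const int P = o_phi + 3;

  vec pl(N, fill::zeros);
  vec grad(want_grad ? P : 1, fill::zeros);
  mat scores;
  if (want_scores) scores.zeros(N, P);

  const double l0 = lambda.n_elem ? lambda(0) : 0.0;
  const double l1 = lambda.n_elem ? lambda(1) : 0.0;
  const double l2 = lambda.n_elem ? lambda(2) : 0.0;

  // reusable per-person buffers
  mat Cm(R, K), U, S(R, 2 * T), gC, ZetaG, TauU, TauL, dlvm;
  vec hr(R), aw(R), va(R), vopt(R), logC(R), logM(R), gOpt(R), logA(R);
  vec e1(R), e2(R), e3(R), ssum(R), mx(R), gn(want_grad ? P : 1);
  if (want_grad && use_lat) {
    ZetaG.set_size(R, I); TauU.set_size(R, I); TauL.set_size(R, I);
    dlvm.set_size(R, 3);
  }

  for (int n = 0; n < N; ++n) {
    const int r0 = n * R;
    const span rows(r0, r0 + R - 1);

    if (use_lat) {
      double zgHR = 0, zgAW = 0, zgVAL = 0;
      for (int c = 0; c < C; ++c) {
        zgHR += gamma(0, c) * Z(n, c);
        zgAW += gamma(1, c) * Z(n, c);
        zgVAL += gamma(2, c) * Z(n, c);
      }
      hr = zgHR + eta(rows, 0);
      aw = zgAW + l0 * hr + eta(rows, 1);
      va = zgVAL + l1 * hr + l2 * aw + eta(rows, 2);
      vopt = delta + phi(0) * hr + phi(1) * aw + phi(2) * va;
    } else {
      vopt.fill(delta);
    }

    // effective coefficients: R x K
    Cm = xi.rows(rows);
    Cm.each_row() %= sigma.t();
    Cm.each_row() += b.t();
    for (int m = 0; m < M; ++m) {
      const int vr = inter(m, 0), lev = inter(m, 1);
      if (vr < 3) {
        const vec& lvv = (vr == 0) ? hr : (vr == 1 ? aw : va);
        Cm.col(lev) += theta(m) * lvv;
      } else {
        Cm.col(lev) += theta(m) * Z(n, vr - 3);
      }
    }

    // choice utilities for all tasks at once: R x 2T
    const mat Xp = X.rows(n * 2 * T, n * 2 * T + 2 * T - 1);  // 2T x K
    U = Cm * Xp.t();

    logC.zeros();
    gOpt.zeros();
    for (int t = 0; t < T; ++t) {
      const int y = chosen(n * T + t);
      vec u1 = U.col(2 * t), u2 = U.col(2 * t + 1);
      mx = max(max(u1, u2), vopt);
      // exponent floors avoid denormal results, whose hardware-assisted
      // arithmetic is orders of magnitude slower; exp(-700) is still a
      // normal double and zero relative to the leading term
      e1 = exp(clamp(u1 - mx, -700.0, 0.0));
      e2 = exp(clamp(u2 - mx, -700.0, 0.0));
      e3 = exp(clamp(vopt - mx, -700.0, 0.0));
      ssum = e1 + e2 + e3;
      const vec& uy = (y == 1) ? u1 : (y == 2 ? u2 : vopt);
      logC += (uy - mx) - log(ssum);
      if (want_grad) {
        S.col(2 * t) = -e1 / ssum;
        S.col(2 * t + 1) = -e2 / ssum;
        if (y == 1) S.col(2 * t) += 1.0;
        else if (y == 2) S.col(2 * t + 1) += 1.0;
        gOpt -= e3 / ssum;
        if (y == 3) gOpt += 1.0;
      }
    }
    if (want_grad) gC = S * Xp;  // R x K choice score w.r.t. coefficients

    // measurement component
    logM.zeros();
    if (use_lat && I > 0) {
      if (want_grad) { ZetaG.zeros(); TauU.zeros(); TauL.zeros(); dlvm.zeros(); }
      for (int i = 0; i < I; ++i) {
        const int y = Y(n, i);
        if (y == 0) continue;  // missing indicator: contributes nothing
        const vec& lvv = (ind_lat(i) == 0) ? hr : (ind_lat(i) == 1 ? aw : va);
        vec lin = zeta(i) * lvv;
        vec FU(R), FL(R);
        if (y == 5) FU.ones();
        else FU = 1.0 / (1.0 + exp(clamp(lin - tau(i, y - 1), -700.0, 700.0)));
        if (y == 1) FL.zeros();
        else FL = 1.0 / (1.0 + exp(clamp(lin - tau(i, y - 2), -700.0, 700.0)));
        vec p = FU - FL;
        p.transform([](double v) { return v < 1e-300 ? 1e-300 : v; });
        logM += log(p);
        if (want_grad) {
          vec dU = (y == 5) ? vec(R, fill::zeros) : vec(FU % (1.0 - FU));
          vec dL = (y == 1) ? vec(R, fill::zeros) : vec(FL % (1.0 - FL));
          vec dlin = (dL - dU) / p;
          ZetaG.col(i) = dlin % lvv;
          dlvm.col(ind_lat(i)) += zeta(i) * dlin;
          if (y < 5) TauU.col(i) = dU / p;
          if (y > 1) TauL.col(i) = -dL / p;
        }
      }
    }

    logA = logC + logM;
    const double amx = logA.max();
    vec a = exp(clamp(logA - amx, -700.0, 0.0));
    const double asum = accu(a);
    pl(n) = amx + std::log(asum / R);

    if (want_grad) {
      vec wts = a / asum;
      gn.zeros();
      const rowvec wgC = wts.t() * gC;          // 1 x K
      for (int k = 0; k < K; ++k) {
        gn(o_b + k) = wgC(k);
        gn(o_sigma + k) = dot(wts, gC.col(k) % xi.col(k).subvec(r0, r0 + R - 1));
      }
      for (int m = 0; m < M; ++m) {
        const int vr = inter(m, 0), lev = inter(m, 1);
        if (vr < 3) {
          const vec& lvv = (vr == 0) ? hr : (vr == 1 ? aw : va);
          gn(o_theta + m) = dot(wts, gC.col(lev) % lvv);
        } else {
          gn(o_theta + m) = Z(n, vr - 3) * wgC(lev);
        }
      }
      gn(o_delta) = dot(wts, gOpt);
      if (use_lat) {
        gn(o_phi + 0) = dot(wts, gOpt % hr);
        gn(o_phi + 1) = dot(wts, gOpt % aw);
        gn(o_phi + 2) = dot(wts, gOpt % va);
        // d logA / d lv, choice + measurement parts, per draw
        vec dlv0 = (I > 0) ? vec(dlvm.col(0)) : vec(R, fill::zeros);
        vec dlv1 = (I > 0) ? vec(dlvm.col(1)) : vec(R, fill::zeros);
        vec dlv2 = (I > 0) ? vec(dlvm.col(2)) : vec(R, fill::zeros);
        for (int m = 0; m < M; ++m) {
          const int vr = inter(m, 0);
          if (vr >= 3) continue;
          vec contrib = theta(m) * gC.col(inter(m, 1));
          if (vr == 0) dlv0 += contrib;
          else if (vr == 1) dlv1 += contrib;
          else dlv2 += contrib;
        }
        dlv0 += phi(0) * gOpt; dlv1 += phi(1) * gOpt; dlv2 += phi(2) * gOpt;
        // backpropagate through the structural recursion
        vec t_val = dlv2;
        vec t_aw = dlv1 + l2 * t_val;
        vec t_hr = dlv0 + l0 * t_aw + l1 * t_val;
        const double wthr = dot(wts, t_hr), wtaw = dot(wts, t_aw),
                     wtval = dot(wts, t_val);
        for (int c = 0; c < C; ++c) {
          gn(o_gamma + 0 + 3 * c) = wthr * Z(n, c);
          gn(o_gamma + 1 + 3 * c) = wtaw * Z(n, c);
          gn(o_gamma + 2 + 3 * c) = wtval * Z(n, c);
        }
        gn(o_lambda + 0) = dot(wts, t_aw % hr);
        gn(o_lambda + 1) = dot(wts, t_val % hr);
        gn(o_lambda + 2) = dot(wts, t_val % aw);
        for (int i = 0; i < I; ++i) {
          const int y = Y(n, i);
          if (y == 0) continue;
          gn(o_zeta + i) = dot(wts, ZetaG.col(i));
          if (y < 5) gn(o_tau + i + I * (y - 1)) = dot(wts, TauU.col(i));
          if (y > 1) gn(o_tau + i + I * (y - 2)) = dot(wts, TauL.col(i));
        }
      }
      grad += gn;
      if (want_scores) scores.row(n) = gn.t();
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = accu(pl),
      Rcpp::Named("pl") = pl);
  if (want_grad) out["grad"] = grad;
  if (want_scores) out["scores"] = scores;
  return out;
}
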