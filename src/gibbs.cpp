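// Single-site / per-block Gibbs sampler for the trivariate animal model:
// y_t = X b_t + beta_t x_t + Z a_t + S p_t + e_t,  t in (ADFI, ADG, LMP),
// Var(a) = A (x) G0, Var(p) = I (x) K0, Var(e) = I (x) R0.
// Location effects with shared incidence across the three traits (factor
// levels, pens, animals) are drawn as 3-trait blocks; covariate regressions
// (trait-specific incidence) are drawn as scalars. Covariance matrices are
// drawn from their inverse-Wishart full conditionals. All randomness comes
// from R's RNG stream, so set.seed() in R gives bit-identical chains.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---- fixed-size 3x3 helpers (row-major double[9]) ----

static inline bool chol3(const double* A, double* L) {
  double a00 = A[0], a10 = A[3], a11 = A[4], a20 = A[6], a21 = A[7],
         a22 = A[8];
  if (a00 <= 0.0) return false;
  double l00 = std::sqrt(a00);
  double l10 = a10 / l00;
  double l20 = a20 / l00;
  double d1 = a11 - l10 * l10;
  if (d1 <= 0.0) return false;
  double l11 = std::sqrt(d1);
  double l21 = (a21 - l20 * l10) / l11;
  double d2 = a22 - l20 * l20 - l21 * l21;
  if (d2 <= 0.0) return false;
  L[0] = l00; L[1] = 0.0; L[2] = 0.0;
  L[3] = l10; L[4] = l11; L[5] = 0.0;
  L[6] = l20; L[7] = l21; L[8] = std::sqrt(d2);
  return true;
}

static inline bool inv3(const double* A, double* out) {
  // symmetric positive definite inverse via adjugate
  double a = A[0], b = A[1], c = A[2], d = A[4], e = A[5], f = A[8];
  // rows: [a b c; b d e; c e f]
  double A11 = d * f - e * e;
  double A12 = c * e - b * f;
  double A13 = b * e - c * d;
  double det = a * A11 + b * A12 + c * A13;
  if (!(det > 0.0) || !std::isfinite(det)) return false;
  double A22 = a * f - c * c;
  double A23 = b * c - a * e;
  double A33 = a * d - b * b;
  out[0] = A11 / det; out[1] = A12 / det; out[2] = A13 / det;
  out[3] = A12 / det; out[4] = A22 / det; out[5] = A23 / det;
  out[6] = A13 / det; out[7] = A23 / det; out[8] = A33 / det;
  return true;
}

// draw x ~ N(C^{-1} rhs, C^{-1}) given precision C (SPD) and rhs
static inline bool mvn3(const double* C, const double* rhs, double* out) {
  double L[9];
  if (!chol3(C, L)) return false;
  // forward solve L w = rhs
  double w0 = rhs[0] / L[0];
  double w1 = (rhs[1] - L[3] * w0) / L[4];
  double w2 = (rhs[2] - L[6] * w0 - L[7] * w1) / L[8];
  double v0 = w0 + norm_rand();
  double v1 = w1 + norm_rand();
  double v2 = w2 + norm_rand();
  // backward solve L' out = v
  out[2] = v2 / L[8];
  out[1] = (v1 - L[7] * out[2]) / L[4];
  out[0] = (v0 - L[3] * out[1] - L[6] * out[2]) / L[0];
  return true;
}

// draw Sigma ~ InvWishart(df, S) (density |Sigma|^{-(df+p+1)/2}
// exp(-tr(S Sigma^{-1})/2)): Sigma^{-1} ~ Wishart(df, S^{-1}) via Bartlett.
static inline bool invWishart3(const double* S, double df, double* out) {
  double Sinv[9], L[9];
  if (!inv3(S, Sinv)) return false;
  if (!chol3(Sinv, L)) return false;
  double t00 = std::sqrt(Rf_rchisq(df));
  double t11 = std::sqrt(Rf_rchisq(df - 1.0));
  double t22 = std::sqrt(Rf_rchisq(df - 2.0));
  double t10 = norm_rand(), t20 = norm_rand(), t21 = norm_rand();
  // M = L T (both lower)
  double m00 = L[0] * t00;
  double m10 = L[3] * t00 + L[4] * t10;
  double m11 = L[4] * t11;
  double m20 = L[6] * t00 + L[7] * t10 + L[8] * t20;
  double m21 = L[7] * t11 + L[8] * t21;
  double m22 = L[8] * t22;
  double W[9];
  W[0] = m00 * m00;
  W[1] = m00 * m10;
  W[2] = m00 * m20;
  W[3] = W[1];
  W[4] = m10 * m10 + m11 * m11;
  W[5] = m10 * m20 + m11 * m21;
  W[6] = W[2];
  W[7] = W[5];
  W[8] = m20 * m20 + m21 * m21 + m22 * m22;
  return inv3(W, out);
}

static inline void copy9(const NumericMatrix& src, double* dst) {
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) dst[r * 3 + c] = src(r, c);
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(NumericMatrix y,          // n x 3
                IntegerMatrix fixBlock,   // n x nFac, 1-based block id, 0=ref
                int nBlocks,
                NumericMatrix covX,       // n x 3 centered covariate columns
                IntegerVector penIdx,     // n, 1-based
                int nPen,
                IntegerVector aniIdx,     // n, 1-based pedigree position
                int q,
                IntegerVector ainvP,      // CSC col pointers, length q+1
                IntegerVector ainvI,      // 0-based row indices
                NumericVector ainvX,
                NumericMatrix G0init, NumericMatrix K0init,
                NumericMatrix R0init,
                double nu0,
                NumericMatrix VG, NumericMatrix VK, NumericMatrix VR,
                int nIter, int burnIn, int thin,
                bool updateCov, bool storeResiduals) {
  const int n = y.nrow();
  const int nFac = fixBlock.ncol();

  // observation lists per fixed block and per pen
  std::vector<std::vector<int>> blockObs(nBlocks), penObs(nPen);
  for (int i = 0; i < n; ++i) {
    for (int f = 0; f < nFac; ++f) {
      int b = fixBlock(i, f);
      if (b > 0) blockObs[b - 1].push_back(i);
    }
    penObs[penIdx[i] - 1].push_back(i);
  }
  std::vector<int> aniObs(q, -1);
  for (int i = 0; i < n; ++i) aniObs[aniIdx[i] - 1] = i;

  double Sxx[3] = {0.0, 0.0, 0.0};
  for (int t = 0; t < 3; ++t)
    for (int i = 0; i < n; ++i) Sxx[t] += covX(i, t) * covX(i, t);

  // state
  std::vector<double> e(n * 3), a(q * 3, 0.0), pen(nPen * 3, 0.0),
      bfix(nBlocks * 3, 0.0);
  double bcov[3] = {0.0, 0.0, 0.0};
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < 3; ++t) e[i * 3 + t] = y(i, t);
  double G0[9], K0[9], R0[9];
  copy9(G0init, G0);
  copy9(K0init, K0);
  copy9(R0init, R0);
  double vg[9], vk[9], vr[9];
  copy9(VG, vg);
  copy9(VK, vk);
  copy9(VR, vr);

  const int nSave =
      (nIter > burnIn) ? (nIter - burnIn + thin - 1) / thin : 0;
  NumericVector g0s(nSave * 9), k0s(nSave * 9), r0s(nSave * 9);
  NumericVector fixs((R_xlen_t)nSave * nBlocks * 3), covs(nSave * 3);
  NumericVector as((R_xlen_t)nSave * q * 3);
  NumericVector es(storeResiduals ? (R_xlen_t)nSave * n * 3 : 0);

  int saved = 0;
  for (int iter = 1; iter <= nIter; ++iter) {
    if (iter % 512 == 0) Rcpp::checkUserInterrupt();
    double Q[9], Ginv[9], Kinv[9], LR[9];
    if (!inv3(R0, Q) || !chol3(R0, LR))
      stop("residual covariance not SPD at iteration %d", iter);
    if (!inv3(G0, Ginv))
      stop("genetic covariance not SPD at iteration %d", iter);
    if (!inv3(K0, Kinv))
      stop("pen covariance not SPD at iteration %d", iter);

    // 1. fixed-factor blocks (flat prior, shared incidence):
    //    theta | . ~ N(mean of (e + theta), R0 / n_b)
    for (int b = 0; b < nBlocks; ++b) {
      const std::vector<int>& obs = blockObs[b];
      const int nb = (int)obs.size();
      if (nb == 0) continue;
      double s[3] = {0.0, 0.0, 0.0};
      for (int k = 0; k < nb; ++k) {
        const double* ei = &e[obs[k] * 3];
        s[0] += ei[0];
        s[1] += ei[1];
        s[2] += ei[2];
      }
      double* th = &bfix[b * 3];
      double z0 = norm_rand(), z1 = norm_rand(), z2 = norm_rand();
      double rt = std::sqrt((double)nb);
      double nw[3];
      nw[0] = s[0] / nb + th[0] + LR[0] * z0 / rt;
      nw[1] = s[1] / nb + th[1] + (LR[3] * z0 + LR[4] * z1) / rt;
      nw[2] = s[2] / nb + th[2] +
              (LR[6] * z0 + LR[7] * z1 + LR[8] * z2) / rt;
      double d0 = nw[0] - th[0], d1 = nw[1] - th[1], d2 = nw[2] - th[2];
      for (int k = 0; k < nb; ++k) {
        double* ei = &e[obs[k] * 3];
        ei[0] -= d0;
        ei[1] -= d1;
        ei[2] -= d2;
      }
      th[0] = nw[0];
      th[1] = nw[1];
      th[2] = nw[2];
    }

    // 2. covariate regressions, one scalar per trait (flat prior)
    for (int t = 0; t < 3; ++t) {
      if (Sxx[t] <= 0.0) continue;
      double num = 0.0;
      for (int i = 0; i < n; ++i) {
        const double* ei = &e[i * 3];
        double qe = Q[t * 3] * ei[0] + Q[t * 3 + 1] * ei[1] +
                    Q[t * 3 + 2] * ei[2];
        num += covX(i, t) * qe;
      }
      double prec = Q[t * 3 + t] * Sxx[t];
      num += bcov[t] * prec;
      double nb = num / prec + norm_rand() / std::sqrt(prec);
      double d = nb - bcov[t];
      for (int i = 0; i < n; ++i) e[i * 3 + t] -= covX(i, t) * d;
      bcov[t] = nb;
    }

    // 3. pen blocks: precision n_k Q + K0^{-1}
    for (int k = 0; k < nPen; ++k) {
      const std::vector<int>& obs = penObs[k];
      const int nk = (int)obs.size();
      if (nk == 0) continue;
      double s[3] = {0.0, 0.0, 0.0};
      for (int u = 0; u < nk; ++u) {
        const double* ei = &e[obs[u] * 3];
        s[0] += ei[0];
        s[1] += ei[1];
        s[2] += ei[2];
      }
      double* pk = &pen[k * 3];
      double r[3] = {s[0] + nk * pk[0], s[1] + nk * pk[1],
                     s[2] + nk * pk[2]};
      double rhs[3], C[9], nw[3];
      for (int t = 0; t < 3; ++t) {
        rhs[t] = Q[t * 3] * r[0] + Q[t * 3 + 1] * r[1] + Q[t * 3 + 2] * r[2];
        for (int u = 0; u < 3; ++u)
          C[t * 3 + u] = nk * Q[t * 3 + u] + Kinv[t * 3 + u];
      }
      if (!mvn3(C, rhs, nw))
        stop("pen-effect conditional not SPD at iteration %d", iter);
      double d0 = nw[0] - pk[0], d1 = nw[1] - pk[1], d2 = nw[2] - pk[2];
      for (int u = 0; u < nk; ++u) {
        double* ei = &e[obs[u] * 3];
        ei[0] -= d0;
        ei[1] -= d1;
        ei[2] -= d2;
      }
      pk[0] = nw[0];
      pk[1] = nw[1];
      pk[2] = nw[2];
    }

    // 4. per-animal 3-trait blocks with A^{-1} prior coupling
    for (int i = 0; i < q; ++i) {
      double off[3] = {0.0, 0.0, 0.0};
      double adg = 0.0;
      for (int idx = ainvP[i]; idx < ainvP[i + 1]; ++idx) {
        int j = ainvI[idx];
        double v = ainvX[idx];
        if (j == i) {
          adg = v;
        } else {
          const double* aj = &a[j * 3];
          off[0] += v * aj[0];
          off[1] += v * aj[1];
          off[2] += v * aj[2];
        }
      }
      double rhs[3], C[9];
      for (int t = 0; t < 3; ++t) {
        rhs[t] = -(Ginv[t * 3] * off[0] + Ginv[t * 3 + 1] * off[1] +
                   Ginv[t * 3 + 2] * off[2]);
        for (int u = 0; u < 3; ++u) C[t * 3 + u] = adg * Ginv[t * 3 + u];
      }
      double* ai = &a[i * 3];
      int o = aniObs[i];
      if (o >= 0) {
        double* eo = &e[o * 3];
        double r[3] = {eo[0] + ai[0], eo[1] + ai[1], eo[2] + ai[2]};
        for (int t = 0; t < 3; ++t) {
          rhs[t] += Q[t * 3] * r[0] + Q[t * 3 + 1] * r[1] +
                    Q[t * 3 + 2] * r[2];
          for (int u = 0; u < 3; ++u) C[t * 3 + u] += Q[t * 3 + u];
        }
      }
      double nw[3];
      if (!mvn3(C, rhs, nw))
        stop("animal-effect conditional not SPD at iteration %d", iter);
      if (o >= 0) {
        double* eo = &e[o * 3];
        eo[0] -= nw[0] - ai[0];
        eo[1] -= nw[1] - ai[1];
        eo[2] -= nw[2] - ai[2];
      }
      ai[0] = nw[0];
      ai[1] = nw[1];
      ai[2] = nw[2];
    }

    // 5. covariance updates from inverse-Wishart full conditionals
    if (updateCov) {
      double S[9];
      // genetic: S = a' A^{-1} a
      for (int t = 0; t < 9; ++t) S[t] = vg[t];
      for (int i = 0; i < q; ++i) {
        double v0 = 0.0, v1 = 0.0, v2 = 0.0;
        for (int idx = ainvP[i]; idx < ainvP[i + 1]; ++idx) {
          const double* aj = &a[ainvI[idx] * 3];
          double w = ainvX[idx];
          v0 += w * aj[0];
          v1 += w * aj[1];
          v2 += w * aj[2];
        }
        const double* ai = &a[i * 3];
        S[0] += ai[0] * v0;
        S[1] += ai[0] * v1;
        S[2] += ai[0] * v2;
        S[4] += ai[1] * v1;
        S[5] += ai[1] * v2;
        S[8] += ai[2] * v2;
        S[3] += ai[1] * v0;
        S[6] += ai[2] * v0;
        S[7] += ai[2] * v1;
      }
      // symmetrize (exact in infinite precision)
      S[1] = S[3] = 0.5 * (S[1] + S[3]);
      S[2] = S[6] = 0.5 * (S[2] + S[6]);
      S[5] = S[7] = 0.5 * (S[5] + S[7]);
      if (!invWishart3(S, q + nu0, G0))
        stop("genetic-scale matrix not SPD at iteration %d", iter);

      for (int t = 0; t < 9; ++t) S[t] = vk[t];
      for (int k = 0; k < nPen; ++k) {
        const double* pk = &pen[k * 3];
        S[0] += pk[0] * pk[0];
        S[1] += pk[0] * pk[1];
        S[2] += pk[0] * pk[2];
        S[4] += pk[1] * pk[1];
        S[5] += pk[1] * pk[2];
        S[8] += pk[2] * pk[2];
      }
      S[3] = S[1];
      S[6] = S[2];
      S[7] = S[5];
      if (!invWishart3(S, nPen + nu0, K0))
        stop("pen-scale matrix not SPD at iteration %d", iter);

      for (int t = 0; t < 9; ++t) S[t] = vr[t];
      for (int i = 0; i < n; ++i) {
        const double* ei = &e[i * 3];
        S[0] += ei[0] * ei[0];
        S[1] += ei[0] * ei[1];
        S[2] += ei[0] * ei[2];
        S[4] += ei[1] * ei[1];
        S[5] += ei[1] * ei[2];
        S[8] += ei[2] * ei[2];
      }
      S[3] = S[1];
      S[6] = S[2];
      S[7] = S[5];
      if (!invWishart3(S, n + nu0, R0))
        stop("residual-scale matrix not SPD at iteration %d", iter);
    }

    // 6. save
    if (iter > burnIn && (iter - burnIn - 1) % thin == 0) {
      for (int t = 0; t < 9; ++t) {
        // stored sample-major: element [saved + nSave * t]
        g0s[saved + nSave * t] = G0[t];
        k0s[saved + nSave * t] = K0[t];
        r0s[saved + nSave * t] = R0[t];
      }
      for (int b = 0; b < nBlocks; ++b)
        for (int t = 0; t < 3; ++t)
          fixs[saved + (R_xlen_t)nSave * (b + nBlocks * t)] =
              bfix[b * 3 + t];
      for (int t = 0; t < 3; ++t) covs[saved + nSave * t] = bcov[t];
      R_xlen_t aoff = (R_xlen_t)saved * q * 3;
      for (int i = 0; i < q; ++i)
        for (int t = 0; t < 3; ++t) as[aoff + i + (R_xlen_t)q * t] = a[i * 3 + t];
      if (storeResiduals) {
        R_xlen_t eoff = (R_xlen_t)saved * n * 3;
        for (int i = 0; i < n; ++i)
          for (int t = 0; t < 3; ++t)
            es[eoff + i + (R_xlen_t)n * t] = e[i * 3 + t];
      }
      ++saved;
    }
  }

  return List::create(_["g0"] = g0s, _["k0"] = k0s, _["r0"] = r0s,
                      _["fixed"] = fixs, _["betaCov"] = covs,
                      _["additive"] = as, _["residuals"] = es,
                      _["nSave"] = saved);
}
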