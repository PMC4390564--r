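// Gibbs sampler engine for the epigenetic animal model.
//
// The mixed-model coefficient matrix is held as one fixed sparsity pattern
// (CSC, full symmetric storage) whose values are the linear combination
//   C = Vdata + alpha * V_A + psi * V_T(lambda) + sum_k ratio_k * I_k
// (+ the G^-1 sigma_e^2 blocks for a correlated direct/maternal pair).
// Only the T values depend on lambda, through seven fixed base vectors, so
// the per-iteration rebuild of T^-1 is a handful of axpy passes over the
// T-block entries. All randomness comes from R's RNG so set.seed() governs
// the whole chain.

#include <Rcpp.h>
using namespace Rcpp;

static inline double quadform(const NumericVector& val,
                              const IntegerVector& qi,
                              const IntegerVector& qj,
                              const NumericVector& s) {
  double acc = 0.0;
  const int m = val.size();
  for (int k = 0; k < m; ++k) acc += val[k] * s[qi[k]] * s[qj[k]];
  return acc;
}

// One single-site sweep over C s = r in fixed ascending order.
static void sweep_location_impl(const IntegerVector& Cp,
                                const IntegerVector& Ci,
                                const NumericVector& Cv,
                                const NumericVector& r,
                                NumericVector& s, double sige2) {
  const int dim = r.size();
  for (int i = 0; i < dim; ++i) {
    double acc = 0.0, cii = 0.0;
    for (int k = Cp[i]; k < Cp[i + 1]; ++k) {
      const int row = Ci[k];
      if (row == i) cii = Cv[k];
      else acc += Cv[k] * s[row];
    }
    if (!(cii > 0.0))
      stop("nonpositive diagonal in the mixed-model equations (equation %d)",
           i + 1);
    const double mu = (r[i] - acc) / cii;
    s[i] = mu + norm_rand() * std::sqrt(sige2 / cii);
  }
}

// [[Rcpp::export]]
NumericVector cpp_sweep_location(IntegerVector Cp, IntegerVector Ci,
                                 NumericVector Cv, NumericVector r,
                                 NumericVector s, double sige2) {
  NumericVector out = clone(s);
  sweep_location_impl(Cp, Ci, Cv, r, out, sige2);
  return out;
}

// Sufficient statistics for the lambda update: cross- and squared-parent
// sums, split by whether both parents or exactly one parent are known.
// sire/dam are 1-based with 0 = unknown; w is in pedigree order.
static void lambda_stats_impl(const IntegerVector& sire,
                              const IntegerVector& dam,
                              const double* w,
                              double& cross_both, double& sq_both,
                              double& cross_one, double& sq_one) {
  cross_both = sq_both = cross_one = sq_one = 0.0;
  const int n = sire.size();
  for (int i = 0; i < n; ++i) {
    const int f = sire[i], m = dam[i];
    if (f > 0 && m > 0) {
      const double pa = w[f - 1] + w[m - 1];
      cross_both += pa * w[i];
      sq_both += pa * pa;
    } else if (f > 0 || m > 0) {
      const double wp = w[(f > 0 ? f : m) - 1];
      cross_one += wp * w[i];
      sq_one += wp * wp;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_lambda_stats(IntegerVector sire, IntegerVector dam,
                               NumericVector w) {
  double cb, sb, co, so;
  lambda_stats_impl(sire, dam, REAL(w), cb, sb, co, so);
  return NumericVector::create(_["cross_both"] = cb, _["sq_both"] = sb,
                               _["cross_one"] = co, _["sq_one"] = so);
}

// Exact log full conditional of lambda (up to a constant): product over
// non-founders of Normal(w_i; lambda * (parental sum), d_i(lambda) sigw2),
// keeping the lambda-dependence of the d_i normalising factors.
static double lambda_logdens_impl(double lam, const IntegerVector& sire,
                                  const IntegerVector& dam, const double* w,
                                  double sigw2) {
  const double db = 1.0 - 2.0 * lam * lam, dn = 1.0 - lam * lam;
  double ll = 0.0;
  const int n = sire.size();
  for (int i = 0; i < n; ++i) {
    const int f = sire[i], m = dam[i];
    if (f > 0 && m > 0) {
      const double r = w[i] - lam * (w[f - 1] + w[m - 1]);
      ll += -0.5 * std::log(db) - r * r / (2.0 * sigw2 * db);
    } else if (f > 0 || m > 0) {
      const double r = w[i] - lam * w[(f > 0 ? f : m) - 1];
      ll += -0.5 * std::log(dn) - r * r / (2.0 * sigw2 * dn);
    }
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_lambda_logdens(double lam, IntegerVector sire, IntegerVector dam,
                          NumericVector w, double sigw2) {
  return lambda_logdens_impl(lam, sire, dam, REAL(w), sigw2);
}

// Truncated-normal draw on [0, 0.5] by inverse CDF, with safe tails.
static double tn_draw(double mu, double sd) {
  if (!R_finite(mu) || !R_finite(sd) || sd <= 0.0)
    return 0.5 * unif_rand();
  const double pa = Rf_pnorm5((0.0 - mu) / sd, 0.0, 1.0, 1, 0);
  const double pb = Rf_pnorm5((0.5 - mu) / sd, 0.0, 1.0, 1, 0);
  if (!(pb - pa > 1e-300))
    return (mu <= 0.25) ? 1e-10 : 0.5 - 1e-10;
  const double u = pa + unif_rand() * (pb - pa);
  double x = mu + sd * Rf_qnorm5(u, 0.0, 1.0, 1, 0);
  if (x < 1e-12) x = 1e-12;
  if (x > 0.5 - 1e-12) x = 0.5 - 1e-12;
  return x;
}

static double tn_logdens(double x, double mu, double sd) {
  const double pa = Rf_pnorm5((0.0 - mu) / sd, 0.0, 1.0, 1, 0);
  const double pb = Rf_pnorm5((0.5 - mu) / sd, 0.0, 1.0, 1, 0);
  const double z = (pb - pa > 1e-300) ? (pb - pa) : 1e-300;
  return Rf_dnorm4(x, mu, sd, 1) - std::log(z);
}

// [[Rcpp::export]]
NumericVector cpp_tn_draw(int n, double mu, double sd) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tn_draw(mu, sd);
  return out;
}

static double rinvchisq(double quadratic, double s2, double df) {
  return (quadratic + s2) / Rf_rchisq(df);
}

// Inverse-Wishart 2x2 draw: W ~ Wishart(df, S^-1) by Bartlett, G = W^-1,
// so E[G] = S / (df - 3). S and out are (s11, s12, s22).
static void riw2(double df, const double S[3], double out[3]) {
  const double det = S[0] * S[2] - S[1] * S[1];
  if (!(det > 0.0) || !(S[0] > 0.0))
    stop("inverse-Wishart scale matrix is not positive definite");
  const double si11 = S[2] / det, si12 = -S[1] / det, si22 = S[0] / det;
  const double l11 = std::sqrt(si11), l21 = si12 / l11;
  const double l22 = std::sqrt(si22 - l21 * l21);
  const double a11 = std::sqrt(Rf_rchisq(df));
  const double a21 = norm_rand();
  const double a22 = std::sqrt(Rf_rchisq(df - 1.0));
  const double w11 = l11 * a11;
  const double w21 = l21 * a11 + l22 * a21;
  const double w22 = l22 * a22;
  const double W11 = w11 * w11, W12 = w11 * w21;
  const double W22 = w21 * w21 + w22 * w22;
  const double dW = W11 * W22 - W12 * W12;
  out[0] = W22 / dW; out[1] = -W12 / dW; out[2] = W11 / dW;
}

// Refresh the T^-1 values from lambda via the seven base patterns.
static void refresh_T(NumericVector& valT, double lam,
                      const NumericVector& bbd, const NumericVector& bbl,
                      const NumericVector& bbq, const NumericVector& bod,
                      const NumericVector& bol, const NumericVector& boq,
                      const NumericVector& bf) {
  const double db = 1.0 / (1.0 - 2.0 * lam * lam);
  const double dn = 1.0 / (1.0 - lam * lam);
  const int m = valT.size();
  for (int k = 0; k < m; ++k) {
    valT[k] = db * (bbd[k] - lam * bbl[k] + lam * lam * bbq[k]) +
              dn * (bod[k] - lam * bol[k] + lam * lam * boq[k]) + bf[k];
  }
}

// [[Rcpp::export]]
NumericVector cpp_tinv_values(double lam, NumericVector bbd, NumericVector bbl,
                              NumericVector bbq, NumericVector bod,
                              NumericVector bol, NumericVector boq,
                              NumericVector bf) {
  NumericVector out(bbd.size());
  refresh_T(out, lam, bbd, bbl, bbq, bod, bol, boq, bf);
  return out;
}

// [[Rcpp::export]]
List cpp_run_gibbs(List plan, List priors, List config, List init) {
  // --- plan pieces -------------------------------------------------------
  const IntegerVector Cp = plan["Cp"], Ci = plan["Ci"];
  const NumericVector Vdata = plan["Vdata"], r = plan["r"], y = plan["y"];
  const IntegerVector Wp = plan["Wp"], Wj = plan["Wj"];
  const NumericVector Wx = plan["Wx"];
  const int dim = r.size(), nnz = Vdata.size(), ndat = y.size();
  const int n_ind = as<int>(plan["n_ind"]);

  const bool has_gen = !Rf_isNull(plan["gen"]);
  IntegerVector g_idx, g_qi, g_qj;
  NumericVector g_val;
  if (has_gen) {
    List g = plan["gen"];
    g_idx = g["idx"]; g_val = g["val"]; g_qi = g["qi"]; g_qj = g["qj"];
  }

  const bool has_pair = !Rf_isNull(plan["pair"]);
  IntegerVector p_iuu, p_qiuu, p_qjuu, p_ium, p_qium, p_qjum,
      p_imm, p_qimm, p_qjmm;
  NumericVector p_vuu, p_vum, p_vmm;
  if (has_pair) {
    List p = plan["pair"];
    p_iuu = p["idx_uu"]; p_vuu = p["val_uu"];
    p_qiuu = p["qi_uu"]; p_qjuu = p["qj_uu"];
    p_ium = p["idx_um"]; p_vum = p["val_um"];
    p_qium = p["qi_um"]; p_qjum = p["qj_um"];
    p_imm = p["idx_mm"]; p_vmm = p["val_mm"];
    p_qimm = p["qi_mm"]; p_qjmm = p["qj_mm"];
  }

  List iid = plan["iid"];
  const int n_iid = iid.size();
  std::vector<IntegerVector> iid_idx(n_iid);
  std::vector<int> iid_off(n_iid), iid_size(n_iid);
  for (int k = 0; k < n_iid; ++k) {
    List comp = iid[k];
    iid_idx[k] = as<IntegerVector>(comp["idx"]);
    iid_off[k] = as<int>(comp["off"]);
    iid_size[k] = as<int>(comp["size"]);
  }

  const bool has_epi = !Rf_isNull(plan["epi"]);
  IntegerVector e_idx, e_qi, e_qj, sire, dam;
  NumericVector bbd, bbl, bbq, bod, bol, boq, bf;
  int w_off = 0;
  if (has_epi) {
    List e = plan["epi"];
    e_idx = e["idx"]; e_qi = e["qi"]; e_qj = e["qj"];
    bbd = e["bbd"]; bbl = e["bbl"]; bbq = e["bbq"];
    bod = e["bod"]; bol = e["bol"]; boq = e["boq"]; bf = e["bf"];
    sire = e["sire"]; dam = e["dam"];
    w_off = as<int>(e["w_off"]);
  }

  // --- priors ------------------------------------------------------------
  const double s2_e = priors["s2_e"], n_e = priors["n_e"];
  double s2_u = 0, n_u = 0, s2_w = 0, n_w = 0, nG = 0;
  double G0[3] = {0, 0, 0};
  if (has_gen) { s2_u = priors["s2_u"]; n_u = priors["n_u"]; }
  if (has_pair) {
    nG = priors["n_G"];
    NumericMatrix G0m = priors["G0"];
    G0[0] = G0m(0, 0); G0[1] = G0m(0, 1); G0[2] = G0m(1, 1);
  }
  if (has_epi) { s2_w = priors["s2_w"]; n_w = priors["n_w"]; }
  NumericVector s2_iid, n_iid_df;
  if (n_iid > 0) { s2_iid = priors["s2_iid"]; n_iid_df = priors["n_iid"]; }

  // --- config ------------------------------------------------------------
  const int n_iter = as<int>(config["n_iter"]);
  const int burn_in = as<int>(config["burn_in"]);
  const int thin = as<int>(config["thin"]);
  const int lambda_mode = as<int>(config["lambda_mode"]); // 0 TN, 1 MH
  const bool store_effects = as<bool>(config["store_effects"]);
  const bool store_fitted = as<bool>(config["store_fitted"]);

  // --- state -------------------------------------------------------------
  NumericVector s = clone(as<NumericVector>(init["s"]));
  double lam = has_epi ? as<double>(init["lambda"]) : 0.0;
  double sigu = has_gen ? as<double>(init["sigma_u2"]) : 0.0;
  double G[3] = {0, 0, 0};
  if (has_pair) {
    NumericMatrix Gi = init["G"];
    G[0] = Gi(0, 0); G[1] = Gi(0, 1); G[2] = Gi(1, 1);
  }
  double sigw = has_epi ? as<double>(init["sigma_w2"]) : 0.0;
  double sige = as<double>(init["sigma_e2"]);
  NumericVector sig_iid(n_iid);
  if (n_iid > 0) sig_iid = clone(as<NumericVector>(init["sigma_iid"]));

  const int n_stored = (n_iter > burn_in)
      ? (n_iter - burn_in + thin - 1) / thin : 0;
  const int ncol = (has_gen ? 1 : 0) + (has_pair ? 3 : 0) + n_iid +
                   (has_epi ? 2 : 0) + 1;
  NumericMatrix draws(n_stored, ncol);
  NumericMatrix effects(store_effects ? n_stored : 0,
                        store_effects ? dim : 0);
  NumericMatrix fitted(store_fitted ? n_stored : 0,
                       store_fitted ? ndat : 0);

  NumericVector Cv(nnz), valT(has_epi ? e_idx.size() : 0);
  NumericVector fit(ndat);
  if (has_epi) refresh_T(valT, lam, bbd, bbl, bbq, bod, bol, boq, bf);

  const bool lambda_informative = has_epi &&
      [&]() {
        for (int i = 0; i < n_ind; ++i)
          if (sire[i] > 0 || dam[i] > 0) return true;
        return false;
      }();

  int row = 0;
  int n_accept = 0, n_mh = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    // -- assemble C values ------------------------------------------------
    std::copy(Vdata.begin(), Vdata.end(), Cv.begin());
    if (has_gen) {
      const double alpha = sige / sigu;
      for (int k = 0; k < g_idx.size(); ++k) Cv[g_idx[k]] += alpha * g_val[k];
    }
    if (has_pair) {
      const double detG = G[0] * G[2] - G[1] * G[1];
      if (!(detG > 0.0)) stop("G became non positive definite");
      const double c11 = sige * G[2] / detG;
      const double c12 = sige * (-G[1] / detG);
      const double c22 = sige * G[0] / detG;
      for (int k = 0; k < p_iuu.size(); ++k) Cv[p_iuu[k]] += c11 * p_vuu[k];
      for (int k = 0; k < p_ium.size(); ++k) Cv[p_ium[k]] += c12 * p_vum[k];
      for (int k = 0; k < p_imm.size(); ++k) Cv[p_imm[k]] += c22 * p_vmm[k];
    }
    for (int k = 0; k < n_iid; ++k) {
      const double ratio = sige / sig_iid[k];
      const IntegerVector& idx = iid_idx[k];
      for (int t = 0; t < idx.size(); ++t) Cv[idx[t]] += ratio;
    }
    if (has_epi) {
      const double psi = sige / sigw;
      for (int k = 0; k < e_idx.size(); ++k) Cv[e_idx[k]] += psi * valT[k];
    }

    // -- location sweep ---------------------------------------------------
    sweep_location_impl(Cp, Ci, Cv, r, s, sige);

    // -- lambda and T^-1 --------------------------------------------------
    if (has_epi) {
      const double* w = REAL(s) + w_off;
      if (!lambda_informative) {
        lam = 0.5 * unif_rand();
      } else {
        double cb, sb, co, so;
        lambda_stats_impl(sire, dam, w, cb, sb, co, so);
        const double db = 1.0 - 2.0 * lam * lam, dn = 1.0 - lam * lam;
        const double den = sb / db + so / dn;
        if (lambda_mode == 0) {
          if (den <= 0.0) {
            lam = 0.5 * unif_rand();
          } else {
            const double mu = (cb / db + co / dn) / den;
            lam = tn_draw(mu, std::sqrt(sigw / den));
          }
        } else {
          // Metropolis-Hastings with the TN as proposal, exact target.
          double prop, log_fwd, log_bwd;
          if (den <= 0.0) {
            prop = 0.5 * unif_rand();
            log_fwd = log_bwd = 0.0;  // uniform proposal is symmetric
          } else {
            const double mu = (cb / db + co / dn) / den;
            const double sd = std::sqrt(sigw / den);
            prop = tn_draw(mu, sd);
            log_fwd = tn_logdens(prop, mu, sd);
            const double dbp = 1.0 - 2.0 * prop * prop;
            const double dnp = 1.0 - prop * prop;
            const double denp = sb / dbp + so / dnp;
            const double mup = (cb / dbp + co / dnp) / denp;
            const double sdp = std::sqrt(sigw / denp);
            log_bwd = tn_logdens(lam, mup, sdp);
          }
          const double log_acc =
              lambda_logdens_impl(prop, sire, dam, w, sigw) -
              lambda_logdens_impl(lam, sire, dam, w, sigw) +
              log_bwd - log_fwd;
          ++n_mh;
          if (std::log(unif_rand()) < log_acc) { lam = prop; ++n_accept; }
        }
      }
      refresh_T(valT, lam, bbd, bbl, bbq, bod, bol, boq, bf);
    }

    // -- variance components ---------------------------------------------
    if (has_epi) {
      const double qw = quadform(valT, e_qi, e_qj, s);
      sigw = rinvchisq(qw, s2_w, n_ind + n_w);
    }
    if (has_gen) {
      const double qu = quadform(g_val, g_qi, g_qj, s);
      sigu = rinvchisq(qu, s2_u, n_ind + n_u);
    }
    if (has_pair) {
      const double Suu = quadform(p_vuu, p_qiuu, p_qjuu, s) + G0[0];
      const double Sum = 0.5 * quadform(p_vum, p_qium, p_qjum, s) + G0[1];
      const double Smm = quadform(p_vmm, p_qimm, p_qjmm, s) + G0[2];
      const double S[3] = {Suu, Sum, Smm};
      riw2(n_ind + nG, S, G);
    }
    for (int k = 0; k < n_iid; ++k) {
      double q = 0.0;
      for (int t = 0; t < iid_size[k]; ++t) {
        const double v = s[iid_off[k] + t];
        q += v * v;
      }
      sig_iid[k] = rinvchisq(q, s2_iid[k], iid_size[k] + n_iid_df[k]);
    }
    double sse = 0.0;
    for (int i = 0; i < ndat; ++i) {
      double f = 0.0;
      for (int k = Wp[i]; k < Wp[i + 1]; ++k) f += Wx[k] * s[Wj[k]];
      fit[i] = f;
      const double e = y[i] - f;
      sse += e * e;
    }
    sige = rinvchisq(sse, s2_e, ndat + n_e);

    if (!R_finite(sige) || (has_gen && !R_finite(sigu)) ||
        (has_epi && (!R_finite(sigw) || !R_finite(lam))))
      stop("divergence at iteration %d: a variance draw is non-finite",
           iter + 1);

    // -- store ------------------------------------------------------------
    if (iter >= burn_in && (iter - burn_in) % thin == 0) {
      int c = 0;
      if (has_gen) draws(row, c++) = sigu;
      if (has_pair) {
        draws(row, c++) = G[0];
        draws(row, c++) = G[2];
        draws(row, c++) = G[1];
      }
      for (int k = 0; k < n_iid; ++k) draws(row, c++) = sig_iid[k];
      if (has_epi) { draws(row, c++) = sigw; draws(row, c++) = lam; }
      draws(row, c++) = sige;
      if (store_effects) effects(row, _) = s;
      if (store_fitted) fitted(row, _) = fit;
      ++row;
    }
  }

  List state = List::create(
      _["s"] = s, _["lambda"] = lam, _["sigma_u2"] = sigu,
      _["G"] = NumericMatrix(2, 2,
                             NumericVector::create(G[0], G[1], G[1],
                                                   G[2]).begin()),
      _["sigma_w2"] = sigw, _["sigma_e2"] = sige, _["sigma_iid"] = sig_iid);
  return List::create(
      _["draws"] = draws,
      _["effects"] = store_effects ? (SEXP)effects : R_NilValue,
      _["fitted"] = store_fitted ? (SEXP)fitted : R_NilValue,
      _["state"] = state,
      _["n_stored"] = n_stored,
      _["lambda_acceptance"] =
          (n_mh > 0) ? (double)n_accept / n_mh : NA_REAL);
}
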