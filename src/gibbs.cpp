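// Single-site Gibbs sampler for the repeated-record GBLUP model
//
//   y = X beta + f b + sum_t Z g_t + Z pe + e
//
// with Var(g_t) = G_t sigma2_t, Var(pe) = I sigma2_pe, Var(e) = I
// sigma2_e, flat priors on location effects and scaled-inverse-chi-square
// priors on variances.
//
// Each genetic block is sampled in the eigenbasis of its (regularized)
// relationship matrix: g_t = V_t u_t with V_t = U diag(sqrt(d)) from
// G_t = U diag(d) U', so the prior on the working coordinates u_t is
// i.i.d. N(0, sigma2_t). This keeps single-site updates well mixed even
// though centered genomic relationship matrices are near-singular along
// the ones vector (their columns sum to ~0), and it makes the variance
// full conditional (u'u + nu S)/chisq_{n+nu}, algebraically identical to
// the g'Ginv g form. A running residual vector and per-individual
// residual sums are maintained so one coordinate update costs O(n).
// R's RNG is used throughout: set.seed() makes chains bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List gibbs_sampler_cpp(const arma::vec& y,
                       const arma::mat& X,
                       const arma::vec& fcov,
                       bool has_f,
                       const arma::uvec& id0,
                       int n_ind,
                       const List& V_list,
                       bool has_pe,
                       const arma::vec& prior_S,
                       const arma::vec& prior_nu,
                       int n_iter, int burn_in, int thin,
                       bool update_location,
                       bool update_variances,
                       const arma::vec& init_var,
                       double var_floor) {
  RNGScope scope;
  const int N = y.n_elem;
  const int p = X.n_cols;
  const int k = V_list.size();
  const int n = n_ind;

  std::vector<arma::mat> V(k);
  for (int t = 0; t < k; ++t) V[t] = as<arma::mat>(V_list[t]);

  std::vector<std::vector<int>> recs(n);
  for (int r = 0; r < N; ++r) recs[id0[r]].push_back(r);
  arma::vec nrec(n);
  for (int i = 0; i < n; ++i) nrec[i] = (double)recs[i].size();

  // w_j'w_j for the record-level incidence of eigen-coordinate j:
  // sum_i nrec_i V(i,j)^2 (constant through the run)
  std::vector<arma::vec> wtw(k);
  for (int t = 0; t < k; ++t) {
    wtw[t].set_size(n);
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += nrec[i] * V[t](i, j) * V[t](i, j);
      wtw[t][j] = s;
    }
  }

  arma::vec beta(p, arma::fill::zeros);
  double bcov = 0.0;
  arma::mat u(n, k, arma::fill::zeros);   // eigenbasis coordinates
  arma::mat g(n, k, arma::fill::zeros);   // g_t = V_t u_t
  arma::vec pe(n, arma::fill::zeros);
  const int nvar = k + (has_pe ? 1 : 0) + 1;
  arma::vec v = init_var;
  if ((int)v.n_elem != nvar) stop("init_var has wrong length");

  arma::vec xtx(p);
  for (int j = 0; j < p; ++j) xtx[j] = arma::dot(X.col(j), X.col(j));
  double ftf = has_f ? arma::dot(fcov, fcov) : 0.0;

  arma::vec e = y;                        // all location effects start at 0

  for (int t = 0; t < k; ++t)
    if (n + prior_nu[t] <= 0) stop("non-positive chi-square df for a genetic term");
  if (has_pe && n + prior_nu[k] <= 0) stop("non-positive chi-square df for pe");
  if (N + prior_nu[nvar - 1] <= 0) stop("non-positive chi-square df for residual");

  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep <= 0) stop("chain configuration retains no samples");
  arma::mat var_samples(n_keep, nvar);
  arma::vec b_samples(n_keep, arma::fill::zeros);
  arma::mat beta_samples(n_keep, p);
  arma::vec dev_samples(n_keep);

  arma::vec beta_sum(p, arma::fill::zeros);
  double b_sum = 0.0;
  arma::mat g_sum(n, k, arma::fill::zeros);
  arma::vec pe_sum(n, arma::fill::zeros);
  arma::vec fitted_sum(N, arma::fill::zeros);

  const double LOG2PI = std::log(2.0 * M_PI);
  int keep = 0;

  for (int it = 1; it <= n_iter; ++it) {
    double ve = v[nvar - 1];

    if (update_location) {
      for (int j = 0; j < p; ++j) {
        if (xtx[j] <= 0) continue;
        double old = beta[j];
        double mean = (arma::dot(X.col(j), e) + xtx[j] * old) / xtx[j];
        double draw = mean + norm_rand() * std::sqrt(ve / xtx[j]);
        beta[j] = draw;
        e += X.col(j) * (old - draw);
      }
      if (has_f && ftf > 0) {
        double old = bcov;
        double mean = (arma::dot(fcov, e) + ftf * old) / ftf;
        double draw = mean + norm_rand() * std::sqrt(ve / ftf);
        bcov = draw;
        e += fcov * (old - draw);
      }
      for (int t = 0; t < k; ++t) {
        double vt = v[t];
        // per-individual residual sums
        arma::vec se(n, arma::fill::zeros);
        for (int r = 0; r < N; ++r) se[id0[r]] += e[r];
        arma::vec ut = u.col(t);
        arma::vec g_old = g.col(t);
        for (int j = 0; j < n; ++j) {
          double ww = wtw[t][j];
          double old = ut[j];
          double c = ww / ve + 1.0 / vt;
          double wte = arma::dot(V[t].col(j), se);   // w_j' e
          double mean = ((wte + ww * old) / ve) / c;
          double draw = mean + norm_rand() / std::sqrt(c);
          if (!std::isfinite(draw)) stop("non-finite draw at iteration %d", it);
          ut[j] = draw;
          double diff = old - draw;
          if (diff != 0.0 && ww > 0.0) {
            // se_i -= nrec_i V(i,j) (draw - old)
            for (int i = 0; i < n; ++i) se[i] += nrec[i] * V[t](i, j) * diff;
          }
        }
        u.col(t) = ut;
        arma::vec g_new = V[t] * ut;
        g.col(t) = g_new;
        for (int r = 0; r < N; ++r) e[r] += g_old[id0[r]] - g_new[id0[r]];
      }
      if (has_pe) {
        double vpe = v[k];
        for (int i = 0; i < n; ++i) {
          double old = pe[i];
          if (nrec[i] == 0) {                 // no records: prior draw
            pe[i] = norm_rand() * std::sqrt(vpe);
            continue;
          }
          double ri = nrec[i] * old;
          for (int r : recs[i]) ri += e[r];
          double c = nrec[i] / ve + 1.0 / vpe;
          double mean = (ri / ve) / c;
          double draw = mean + norm_rand() / std::sqrt(c);
          pe[i] = draw;
          double diff = old - draw;
          for (int r : recs[i]) e[r] += diff;
        }
      }
    }

    if (update_variances) {
      for (int t = 0; t < k; ++t) {
        double ss = arma::dot(u.col(t), u.col(t)) + prior_nu[t] * prior_S[t];
        double draw = ss / R::rchisq(n + prior_nu[t]);
        if (!std::isfinite(draw)) stop("non-finite variance draw at iteration %d", it);
        v[t] = std::max(draw, var_floor);
      }
      if (has_pe) {
        double ss = arma::dot(pe, pe) + prior_nu[k] * prior_S[k];
        double draw = ss / R::rchisq(n + prior_nu[k]);
        if (!std::isfinite(draw)) stop("non-finite variance draw at iteration %d", it);
        v[k] = std::max(draw, var_floor);
      }
      double ss = arma::dot(e, e) + prior_nu[nvar - 1] * prior_S[nvar - 1];
      double draw = ss / R::rchisq(N + prior_nu[nvar - 1]);
      if (!std::isfinite(draw)) stop("non-finite variance draw at iteration %d", it);
      v[nvar - 1] = std::max(draw, var_floor);
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      double ve_now = v[nvar - 1];
      double dev = N * (LOG2PI + std::log(ve_now)) + arma::dot(e, e) / ve_now;
      var_samples.row(keep) = v.t();
      if (has_f) b_samples[keep] = bcov;
      beta_samples.row(keep) = beta.t();
      dev_samples[keep] = dev;
      beta_sum += beta;
      b_sum += bcov;
      g_sum += g;
      pe_sum += pe;
      fitted_sum += (y - e);
      ++keep;
    }
  }

  return List::create(
    _["var_samples"] = var_samples,
    _["b_samples"] = b_samples,
    _["beta_samples"] = beta_samples,
    _["deviance"] = dev_samples,
    _["beta_mean"] = beta_sum / keep,
    _["b_mean"] = b_sum / keep,
    _["g_mean"] = g_sum / keep,
    _["pe_mean"] = pe_sum / keep,
    _["fitted_mean"] = fitted_sum / keep,
    _["n_retained"] = keep);
}
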