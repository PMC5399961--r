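// Natural-gradient Infomax rotation on pre-whitened data.
//
// Classic logistic update (runica convention, block-scaled):
//   W <- W + lrate * (block*I + (1 - 2*g(U)) * U') * W,  g = logistic
// Extended update with a per-component sub/super-Gaussian sign matrix K:
//   W <- W + lrate * (block*I - K*tanh(U)*U' - U*U') * W
// Annealing: lrate *= 0.98 whenever the angle between successive weight
// updates exceeds 60 degrees; on numerical blow-up the rotation restarts from
// identity with lrate * 0.9. Sample order is re-permuted every pass with a
// Mersenne Twister seeded from `seed` (own Fisher-Yates, so results are
// bit-reproducible across platforms).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void fisher_yates(std::vector<uword>& idx, std::mt19937& rng) {
  for (uword i = idx.size() - 1; i > 0; --i) {
    uword j = static_cast<uword>(rng() % (i + 1));
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export(name = ".infomax_core")]]
Rcpp::List infomax_core(const arma::mat& Xw, int block, double lrate0,
                        double tol, int max_iter, int seed, bool extended) {
  const uword k = Xw.n_rows, n = Xw.n_cols;
  const double max_weight = 1e8, anneal_step = 0.98, anneal_deg = 60.0,
               restart_fac = 0.9;
  const int max_restarts = 20;

  mat W = eye<mat>(k, k), oldW = W, BI = double(block) * eye<mat>(k, k);
  vec olddelta(k * k, fill::zeros);
  double oldchange = 0.0, lrate = lrate0, change = datum::inf;
  bool converged = false;
  int iter = 0, restarts = 0;

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::vector<uword> perm(n);
  for (uword i = 0; i < n; ++i) perm[i] = i;

  vec signs(k, fill::ones);  // +1 super-Gaussian, -1 sub-Gaussian

  while (iter < max_iter) {
    fisher_yates(perm, rng);
    bool blowup = false;

    if (extended) {
      // estimate kurtosis signs from current sources over the whole trial
      mat U = W * Xw;
      for (uword c = 0; c < k; ++c) {
        rowvec u = U.row(c);
        double m2 = mean(square(u));
        double m4 = mean(square(square(u)));
        signs(c) = (m4 / (m2 * m2) - 3.0 >= 0.0) ? 1.0 : -1.0;
      }
    }

    for (uword t = 0; t + block <= n; t += block) {
      mat Xb(k, block);
      for (int c = 0; c < block; ++c) Xb.col(c) = Xw.col(perm[t + c]);
      mat U = W * Xb;
      mat G;
      if (extended) {
        G = BI - (tanh(U) * U.t()).eval().each_col() % signs - U * U.t();
      } else {
        mat Y = 1.0 / (1.0 + exp(-U));
        G = BI + (1.0 - 2.0 * Y) * U.t();
      }
      W += lrate * G * W;
      if (!W.is_finite() || abs(W).max() > max_weight) { blowup = true; break; }
    }

    if (blowup) {
      if (++restarts > max_restarts) break;
      W = eye<mat>(k, k); oldW = W;
      olddelta.zeros(); oldchange = 0.0;
      lrate *= restart_fac;
      iter = 0;
      continue;
    }

    mat D = W - oldW;
    vec delta = vectorise(D);
    change = dot(delta, delta);
    ++iter;
    if (iter > 1 && oldchange > 0 && change > 0) {
      double cosang = dot(delta, olddelta) / std::sqrt(change * oldchange);
      cosang = std::max(-1.0, std::min(1.0, cosang));
      double angle = std::acos(cosang) * 180.0 / datum::pi;
      if (angle > anneal_deg) {
        lrate *= anneal_step;
        olddelta = delta;
        oldchange = change;
      }
    } else {
      olddelta = delta;
      oldchange = change;
    }
    oldW = W;
    if (std::sqrt(change) < tol) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("lrate_final") = lrate,
    Rcpp::Named("restarts") = restarts,
    Rcpp::Named("signs") = signs);
}
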