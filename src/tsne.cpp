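// Exact t-SNE with a multi-scale Gaussian input kernel, Manhattan input
// metric, an early-exaggeration phase, and a KL-divergence plateau stopping
// rule evaluated every `check_interval` iterations in both phases.
//
// Sized for the binning use case: a few hundred to a few thousand contigs
// per embedding round, where the O(n^2) exact gradient is fast and simpler
// than tree or interpolation approximations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat manhattan_dist(const mat& X) {
  const uword n = X.n_rows;
  mat D(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    for (uword j = i + 1; j < n; ++j) {
      double d = accu(abs(X.row(i) - X.row(j)));
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// conditional affinities P(j|i) for one perplexity via binary search on the
// Gaussian bandwidth; D2 holds squared input distances
static mat conditional_p(const mat& D2, double perplexity) {
  const uword n = D2.n_rows;
  const double log_perp = std::log(perplexity);
  mat P(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    double beta = 1.0, beta_lo = -datum::inf, beta_hi = datum::inf;
    rowvec Di = D2.row(i);
    Di(i) = 0.0;  // self excluded by zeroing Pi(i) below
    rowvec Pi(n, fill::zeros);
    for (int iter = 0; iter < 64; ++iter) {
      Pi = exp(-Di * beta);
      Pi(i) = 0.0;
      double sumP = accu(Pi);
      if (sumP <= 0) sumP = datum::eps;
      double H = std::log(sumP) + beta * accu(Di % Pi) / sumP;
      double diff = H - log_perp;
      if (std::abs(diff) < 1e-7) break;
      if (diff > 0) {  // entropy too high -> narrow kernel
        beta_lo = beta;
        beta = std::isinf(beta_hi) ? beta * 2.0 : (beta + beta_hi) / 2.0;
      } else {
        beta_hi = beta;
        beta = std::isinf(beta_lo) ? beta / 2.0 : (beta + beta_lo) / 2.0;
      }
    }
    double sumP = accu(Pi);
    if (sumP <= 0) { Pi.fill(1.0 / (n - 1)); Pi(i) = 0; sumP = 1.0; }
    P.row(i) = Pi / sumP;
  }
  return P;
}

static double kl_divergence(const mat& P, const mat& Q) {
  double kld = 0.0;
  const uword n = P.n_rows;
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < n; ++j)
      if (P(i, j) > 0)
        kld += P(i, j) * std::log(P(i, j) / std::max(Q(i, j), 1e-12));
  return kld;
}

// one block of gradient-descent iterations; returns KLD at the end
static double optimize_block(const mat& P, mat& Y, mat& dY, mat& gains,
                             int n_iter, double eta, double momentum) {
  const uword n = Y.n_rows;
  mat Q(n, n);
  double kld = 0.0;
  for (int it = 0; it < n_iter; ++it) {
    // student-t affinities in the embedding
    mat num(n, n, fill::zeros);
    for (uword i = 0; i < n; ++i) {
      for (uword j = i + 1; j < n; ++j) {
        double d2 = std::pow(Y(i, 0) - Y(j, 0), 2) +
                    std::pow(Y(i, 1) - Y(j, 1), 2);
        double v = 1.0 / (1.0 + d2);
        num(i, j) = v;
        num(j, i) = v;
      }
    }
    double Z = accu(num);
    if (Z <= 0) Z = datum::eps;
    Q = num / Z;

    mat grad(n, 2, fill::zeros);
    mat PQnum = (P - Q) % num;
    for (uword i = 0; i < n; ++i) {
      rowvec g(2, fill::zeros);
      for (uword j = 0; j < n; ++j) {
        if (i == j) continue;
        g += PQnum(i, j) * (Y.row(i) - Y.row(j));
      }
      grad.row(i) = 4.0 * g;
    }
    // adaptive gains as in the reference implementations
    for (uword i = 0; i < n; ++i) {
      for (uword k = 0; k < 2; ++k) {
        bool same_sign = (grad(i, k) > 0) == (dY(i, k) > 0);
        gains(i, k) = same_sign ? gains(i, k) * 0.8 : gains(i, k) + 0.2;
        if (gains(i, k) < 0.01) gains(i, k) = 0.01;
      }
    }
    dY = momentum * dY - eta * (gains % grad);
    Y += dY;
    Y.each_row() -= mean(Y, 0);
    if (it == n_iter - 1) kld = kl_divergence(P, Q);
  }
  return kld;
}

// [[Rcpp::export(name = ".tsne_core")]]
Rcpp::List tsne_core(const arma::mat& X, const arma::mat& Y0,
                     double perp_small, double perp_large,
                     double exaggeration, double eta_early, double eta_main,
                     int check_interval, int max_iter_early,
                     int max_iter_main, double kld_ratio) {
  const uword n = X.n_rows;
  mat D = manhattan_dist(X);
  mat D2 = square(D);

  // multi-scale kernel: average of the conditional affinities at the two
  // perplexities, then symmetrize and normalize
  mat Pc = 0.5 * (conditional_p(D2, perp_small) + conditional_p(D2, perp_large));
  mat P = (Pc + Pc.t()) / (2.0 * n);
  P /= accu(P);

  mat Y = Y0;
  mat dY(n, 2, fill::zeros);
  mat gains(n, 2, fill::ones);
  std::vector<double> kld_trace;

  // early exaggeration phase
  mat Pex = P * exaggeration;
  double prev = datum::inf;
  int done = 0;
  while (done < max_iter_early) {
    double momentum = (done < 250) ? 0.5 : 0.8;
    double kld = optimize_block(Pex, Y, dY, gains, check_interval, eta_early,
                                momentum);
    kld_trace.push_back(kld);
    done += check_interval;
    if (std::isfinite(prev) && (prev - kld) < kld * kld_ratio) break;
    prev = kld;
  }
  // main phase
  prev = datum::inf;
  done = 0;
  while (done < max_iter_main) {
    double kld = optimize_block(P, Y, dY, gains, check_interval, eta_main, 0.8);
    kld_trace.push_back(kld);
    done += check_interval;
    if (std::isfinite(prev) && (prev - kld) < kld * kld_ratio) break;
    prev = kld;
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("kld") = kld_trace);
}

// [[Rcpp::export(name = ".markov_sequence")]]
Rcpp::String markov_sequence(int len, const arma::mat& trans, int order,
                             int seed) {
  // trans: 4^order rows (context index, base-4 big-endian) x 4 cols
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const char* alph = "ACGT";
  std::string s;
  s.reserve(len);
  int ctx = 0;
  int mod = 1;
  for (int i = 0; i < order; ++i) mod *= 4;
  for (int i = 0; i < len; ++i) {
    int b;
    if (i < order) {
      b = static_cast<int>(unif(rng) * 4.0);
      if (b > 3) b = 3;
    } else {
      double u = unif(rng), acc = 0.0;
      b = 3;
      for (int k = 0; k < 4; ++k) {
        acc += trans(ctx, k);
        if (u <= acc) { b = k; break; }
      }
    }
    s.push_back(alph[b]);
    ctx = (ctx * 4 + b) % mod;
  }
  return Rcpp::String(s);
}
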