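// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Exact zero-order-hold discretization of the single-pole interface path
// y' = (Z_f x - y) / tau  ->  y[n] = alpha y[n-1] + (1 - alpha) Z_f x[n],
// alpha = exp(-dt / tau).
// [[Rcpp::export]]
NumericVector zec_filter_cpp(NumericVector x, double alpha, double Zf) {
  int n = x.size();
  NumericVector y(n);
  double state = 0.0;
  double gain = (1.0 - alpha) * Zf;
  for (int i = 0; i < n; ++i) {
    state = alpha * state + gain * x[i];
    y[i] = state;
  }
  return y;
}

// Second-order synaptic kernel state: y'' = G w u - 2 w y' - w^2 y
struct Psp {
  double y = 0.0, yd = 0.0;
  inline void step(double G, double w, double u, double dt) {
    double ydd = G * w * u - 2.0 * w * yd - w * w * y;
    y += dt * yd;
    yd += dt * ydd;
  }
  // Euler-Maruyama: white-noise intensity sd enters the acceleration term
  inline void step_noise(double G, double w, double u, double sd, double dt,
                         double xi) {
    double ydd = G * w * u - 2.0 * w * yd - w * w * y;
    y += dt * yd;
    yd += dt * ydd + G * w * sd * std::sqrt(dt) * xi;
  }
};

static inline double sigm(double v, double e0, double v0, double r) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v)));
}

// Integrate the five-module auditory network (brainstem, thalamus L/R,
// primary auditory cortex L/R) driven by the auditory-nerve firing rate.
//
// par: named parameter vector (kernel constants, sigmoid, connectivity).
// noise_mean / noise_sd: length-5 (bs, th_l, th_r, a1_l, a1_r).
// Returns a 5 x n matrix of principal-cell mean membrane potentials.
// Uses the R RNG (seed set by the caller) so runs are reproducible.
// [[Rcpp::export]]
NumericMatrix simulate_network_cpp(NumericVector nerve_rate, double dt,
                                   List par, NumericVector noise_mean,
                                   NumericVector noise_sd) {
  int n = nerve_rate.size();
  double A = par["A"], a = par["a"], B = par["B"], b = par["b"],
         G = par["G"], g = par["g"];
  double a_bs = par["a_bs"], A_bs = A * (a_bs / a); // same DC gain A/a
  double a_th = par["a_th"], A_th = A * (a_th / a);
  double e0 = par["e0"], v0 = par["v0"], r = par["r"];
  double c_coch_bs = par["coch_bs"], c_coch_th = par["coch_th"],
         c_coch_a1 = par["coch_a1"], c_bs_th = par["bs_th"],
         c_th_a1 = par["th_a1"], c_bs_a1 = par["bs_a1"],
         c_th_bs = par["th_bs"], c_a1_bs = par["a1_bs"];
  double c_p_i = par["p_i"], c_i_p = par["i_p"], c_p_is = par["p_is"],
         c_is_p = par["is_p"], c_p_ibs = par["p_ibs"], c_ibs_p = par["ibs_p"];
  double guard = par["guard"];

  // brainstem: excitatory on P, slow inhibitory on P, excitatory on I
  Psp bs_e, bs_inh, bs_i;
  // four cortical/thalamic modules: order th_l, th_r, a1_l, a1_r
  Psp m_e[4], m_if[4], m_is[4], m_i[4], m_ip[4];

  NumericMatrix out(5, n);
  RNGScope scope;

  for (int t = 0; t < n; ++t) {
    // potentials from current states
    double v_bs = bs_e.y - bs_inh.y;
    double v_ibs = bs_i.y;
    double v_p[4], v_i[4], v_is[4];
    for (int j = 0; j < 4; ++j) {
      v_p[j] = m_e[j].y - m_if[j].y - m_is[j].y;
      v_i[j] = m_i[j].y;
      v_is[j] = m_ip[j].y;
    }

    out(0, t) = v_bs;
    out(1, t) = v_p[0];
    out(2, t) = v_p[1];
    out(3, t) = v_p[2];
    out(4, t) = v_p[3];

    if (std::abs(v_bs) > guard || std::abs(v_p[0]) > guard ||
        std::abs(v_p[2]) > guard || !std::isfinite(v_bs)) {
      stop("Neural simulation diverged (|v| exceeded guard bound %g at step %d).",
           guard, t + 1);
    }

    double s_bs = sigm(v_bs, e0, v0, r);
    double s_p[4];
    for (int j = 0; j < 4; ++j) s_p[j] = sigm(v_p[j], e0, v0, r);

    // brainstem drive: cochlear nerve rate + excitatory feedback
    double u_bs = c_coch_bs * nerve_rate[t] +
                  c_th_bs * (s_p[0] + s_p[1]) + c_a1_bs * (s_p[2] + s_p[3]) +
                  noise_mean[0];
    bs_e.step_noise(A_bs, a_bs, u_bs, noise_sd[0], dt, norm_rand());
    bs_inh.step(B, b, c_ibs_p * sigm(v_ibs, e0, v0, r), dt);
    bs_i.step(A, a, c_p_ibs * s_bs, dt);

    for (int j = 0; j < 4; ++j) {
      double drive;
      if (j < 2) { // thalamic: brainstem relay (+ optional direct cochlear)
        drive = c_bs_th * s_bs + c_coch_th * nerve_rate[t];
      } else {     // cortical: thalamo-cortical relay + direct brainstem
        drive = c_th_a1 * s_p[j - 2] + c_bs_a1 * s_bs +
                c_coch_a1 * nerve_rate[t];
      }
      double Ge = (j < 2) ? A_th : A, we = (j < 2) ? a_th : a;
      m_e[j].step_noise(Ge, we, drive + noise_mean[j + 1], noise_sd[j + 1], dt,
                        norm_rand());
      m_if[j].step(G, g, c_i_p * sigm(v_i[j], e0, v0, r), dt);
      m_is[j].step(B, b, c_is_p * sigm(v_is[j], e0, v0, r), dt);
      m_i[j].step(A, a, c_p_i * s_p[j], dt);
      m_ip[j].step(A, a, c_p_is * s_p[j], dt);
    }
  }
  return out;
}

// Natural-gradient infomax / extended infomax on whitened data (n x T).
// Block updates over a shuffled permutation (BLAS-backed); learning-rate
// annealing on update-direction oscillation (> anneal_deg); extended rule
// re-estimates per-component kurtosis signs every 5 passes on a strided
// subsample. Uses the R RNG (caller seeds it), so results are reproducible.
// [[Rcpp::export]]
List infomax_cpp(arma::mat X, bool extended, int max_iter, double tol,
                 int block, double lrate, double anneal, double anneal_deg,
                 int max_restarts) {
  int n = X.n_rows;
  int T = X.n_cols;
  RNGScope scope;
  arma::mat W(n, n), oldW, dw, olddw, Xb(n, block), u, G, M, dW;
  arma::vec signs(n, arma::fill::ones);
  arma::mat I_n(n, n, arma::fill::eye);
  std::vector<int> perm(T);
  double delta = R_PosInf;
  int iter = 0, restarts = 0;
  bool have_olddw = false;
  double cos_thresh = std::cos(anneal_deg * M_PI / 180.0);

  auto init_W = [&]() {
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) W(i, j) = 0.01 * norm_rand();
    W.diag() += 1.0;
    oldW = W;
    have_olddw = false;
  };
  init_W();

  while (iter < max_iter) {
    ++iter;
    for (int i = 0; i < T; ++i) perm[i] = i;
    for (int i = T - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      std::swap(perm[i], perm[j]);
    }
    bool bad = false;
    for (int b0 = 0; b0 + block <= T; b0 += block) {
      for (int c = 0; c < block; ++c) Xb.col(c) = X.col(perm[b0 + c]);
      u = W * Xb;
      if (extended) {
        G = arma::tanh(u);
        G.each_col() %= signs;
        M = I_n - (G * u.t() + u * u.t()) / block;
      } else {
        G = 1.0 - 2.0 / (1.0 + arma::exp(-u));
        M = I_n + (G * u.t()) / block;
      }
      W += lrate * (M * W);
      double wmax = arma::abs(W).max();
      if (wmax > 1e8 || !std::isfinite(wmax)) { bad = true; break; }
    }
    if (bad) {
      if (++restarts > max_restarts)
        stop("Infomax diverged repeatedly; data may be degenerate.");
      lrate *= 0.5;
      init_W();
      continue;
    }
    if (extended && iter % 5 == 0) {
      int stride = std::max(1, T / 50000);
      arma::uvec idx = arma::regspace<arma::uvec>(0, stride, T - 1);
      arma::mat us = W * X.cols(idx);
      arma::mat th = arma::tanh(us);
      arma::vec s1 = arma::mean(1.0 - arma::square(th), 1);
      arma::vec s2 = arma::mean(arma::square(us), 1);
      arma::vec s3 = arma::mean(us % th, 1);
      for (int r = 0; r < n; ++r)
        signs(r) = (s1(r) * s2(r) - s3(r)) > 0 ? 1.0 : -1.0;
    }
    dw = W - oldW;
    delta = arma::norm(dw, "fro");
    if (delta < tol * std::max(1.0, arma::norm(W, "fro"))) {
      return List::create(_["W"] = W, _["converged"] = true,
                          _["iterations"] = iter, _["delta"] = delta);
    }
    if (have_olddw) {
      double dot = arma::accu(dw % olddw);
      double n1 = arma::norm(dw, "fro"), n2 = arma::norm(olddw, "fro");
      if (dot / (n1 * n2) < cos_thresh) lrate *= anneal;
    }
    olddw = dw;
    have_olddw = true;
    oldW = W;
  }
  // at the iteration cap, judge settledness on the same relative scale as
  // the in-loop criterion
  bool settled = delta < 1e-3 * std::max(1.0, arma::norm(W, "fro"));
  return List::create(_["W"] = W, _["converged"] = settled,
                      _["iterations"] = iter, _["delta"] = delta);
}
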