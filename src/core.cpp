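// Simulation cores for the two-pathway learning model.
//
// All stochastic draws go through R's RNG (norm_rand/unif_rand), so results
// are reproducible with set.seed() from the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sgn1(double v) { return (v >= 0.0) ? 1.0 : -1.0; }

// One margin-perceptron step on w given precomputed summed input u.
// Returns true when an update was applied (u * zhat < kappa).
static inline bool margin_step(arma::vec &w, const arma::vec &x, double zhat,
                               double u, double kappa, bool by_input_norm) {
  if (u * zhat >= kappa) return false;
  double D = by_input_norm ? arma::dot(x, x) : (double)x.n_elem;
  w += ((kappa * zhat - u) / D) * x;
  return true;
}

// [[Rcpp::export]]
List cpp_train_seq_single(const arma::mat &X, const arma::vec &zhat,
                          arma::vec w, double kappa, bool by_input_norm,
                          const IntegerVector &order, bool snapshots) {
  const int n_pres = order.size();
  arma::mat snaps;
  if (snapshots) snaps.set_size(n_pres, w.n_elem);
  int n_updates = 0;
  for (int k = 0; k < n_pres; ++k) {
    int mu = order[k] - 1;
    arma::rowvec xr = X.row(mu);
    arma::vec x = xr.t();
    double u = arma::dot(w, x);
    if (margin_step(w, x, zhat[mu], u, kappa, by_input_norm)) ++n_updates;
    if (snapshots) snaps.row(k) = w.t();
  }
  List out = List::create(_["w"] = w, _["n_updates"] = n_updates);
  if (snapshots) out["snapshots"] = snaps;
  return out;
}

// Cycled training.  The projection update drives violated margins exactly to
// kappa, so margins of other patterns can hover infinitesimally below kappa
// for many passes; convergence is therefore declared when no pattern
// violates the margin by more than `tol` in a full pass (the update rule
// itself is unchanged and still fires on any strict violation).
// [[Rcpp::export]]
List cpp_train_cycled(const arma::mat &X, const arma::vec &zhat, arma::vec w,
                      double kappa, bool by_input_norm, int max_epochs,
                      double tol) {
  const int P = X.n_rows;
  bool converged = false;
  int epoch = 0;
  for (epoch = 0; epoch < max_epochs; ++epoch) {
    int n_violations = 0;
    for (int mu = 0; mu < P; ++mu) {
      arma::vec x = X.row(mu).t();
      double u = arma::dot(w, x);
      if (u * zhat[mu] < kappa - tol) ++n_violations;
      margin_step(w, x, zhat[mu], u, kappa, by_input_norm);
    }
    if (n_violations == 0) { converged = true; break; }
  }
  return List::create(_["w"] = w, _["converged"] = converged,
                      _["epochs"] = converged ? (epoch + 1) : max_epochs);
}

// [[Rcpp::export]]
arma::vec cpp_train_gd(const arma::mat &X, const arma::vec &zhat, arma::vec w,
                       double kappa, double lr, int n_steps,
                       const IntegerVector &order) {
  const int N_x = X.n_cols;
  for (int k = 0; k < order.size(); ++k) {
    int mu = order[k] - 1;
    arma::vec x = X.row(mu).t();
    for (int s = 0; s < n_steps; ++s) {
      double u = arma::dot(w, x);
      if (u * zhat[mu] < kappa) w += (lr * zhat[mu] / N_x) * x; // hinge gradient
    }
  }
  return w;
}

// One full forgetting-curve run: stream burn-in patterns (trained, not
// tested), then train P test patterns sequentially and classify each with the
// final weights.  Patterns are generated on the fly from R's RNG; only the
// tested ones are stored.
// [[Rcpp::export]]
IntegerVector cpp_forgetting_run(int N_x, int P, int burn_in, double kappa,
                                 bool by_input_norm) {
  arma::vec w(N_x, arma::fill::zeros);
  arma::vec x(N_x);
  for (int b = 0; b < burn_in; ++b) {
    for (int j = 0; j < N_x; ++j) x[j] = norm_rand();
    double z = (unif_rand() < 0.5) ? -1.0 : 1.0;
    double u = arma::dot(w, x);
    margin_step(w, x, z, u, kappa, by_input_norm);
  }
  arma::mat Xt(P, N_x);
  arma::vec zt(P);
  for (int mu = 0; mu < P; ++mu) {
    for (int j = 0; j < N_x; ++j) Xt(mu, j) = norm_rand();
    zt[mu] = (unif_rand() < 0.5) ? -1.0 : 1.0;
    arma::vec xv = Xt.row(mu).t();
    double u = arma::dot(w, xv);
    margin_step(w, xv, zt[mu], u, kappa, by_input_norm);
  }
  IntegerVector err(P);
  arma::vec u_all = Xt * w;
  for (int mu = 0; mu < P; ++mu) err[mu] = (sgn1(u_all[mu]) != zt[mu]) ? 1 : 0;
  return err;
}

// Two-pathway trainer over an arbitrary presentation sequence.
// pres[k] is the (1-based) pattern index of presentation k and n_pres[k] the
// repetition factor n_mu entering the Hebbian rule for that presentation
// (all 1 in per-repetition mode; the pattern's total count in aggregated
// mode, where the pattern then appears once in pres).
// [[Rcpp::export]]
List cpp_train_two(const arma::mat &X, const arma::mat &Y,
                   const arma::mat &Zhat, const IntegerVector &pres,
                   const NumericVector &n_pres, arma::mat W, arma::mat V,
                   double kappa, double alpha, double beta, double nbar,
                   bool by_input_norm, bool record) {
  const int N_x = X.n_cols, N_y = Y.n_cols, N_z = W.n_rows;
  const int K = pres.size();
  arma::mat traces;
  if (record) traces.set_size(K, 4); // pattern, alignment, control, error
  for (int k = 0; k < K; ++k) {
    int mu = pres[k] - 1;
    arma::vec x = X.row(mu).t();
    arma::vec z = Zhat.row(mu).t();
    arma::vec m = W * x;
    arma::vec h(N_z, arma::fill::zeros);
    arma::vec y;
    if (N_y > 0) { y = Y.row(mu).t(); h = V * y; }
    // supervised step, row-wise, on the total current
    double D = by_input_norm ? arma::dot(x, x) : (double)N_x;
    arma::vec gain(N_z, arma::fill::zeros);
    for (int i = 0; i < N_z; ++i) {
      double u = m[i] + h[i];
      if (u * z[i] < kappa) gain[i] = (kappa * z[i] - u) / D;
    }
    W += gain * x.t();
    m += gain * D; // gain * (x.x)/D adjusts; exact for by_input_norm
    if (!by_input_norm) m = W * x;
    // Hebbian step on the slow pathway
    if (N_y > 0 && (alpha > 0.0 || beta > 0.0)) {
      double a = alpha * n_pres[k] / (N_y * nbar);
      double b = std::sqrt(2.0) * beta * n_pres[k] / (N_y * nbar);
      V *= (1.0 - a);
      V += b * z * y.t();
    }
    if (record) {
      arma::vec h2(N_z, arma::fill::zeros);
      if (N_y > 0) h2 = V * y;
      double nm = arma::norm(m), nh = arma::norm(h2);
      double align = (nm > 0 && nh > 0) ? arma::dot(m, h2) / (nm * nh) : 0.0;
      double tot = arma::dot(m + h2, z);
      double ctrl = (tot != 0.0) ? arma::dot(h2, z) / tot : NA_REAL;
      int nerr = 0;
      for (int i = 0; i < N_z; ++i)
        if (sgn1(m[i] + h2[i]) != z[i]) ++nerr;
      traces(k, 0) = mu + 1;
      traces(k, 1) = align;
      traces(k, 2) = ctrl;
      traces(k, 3) = (double)nerr / N_z;
    }
  }
  List out = List::create(_["W"] = W, _["V"] = V);
  if (record) out["traces"] = traces;
  return out;
}

// Streaming two-pathway forgetting run (N_z = 1 readout).  Burn-in patterns
// are trained once each and discarded; the P tested patterns follow, with
// pattern mu repeated reps[mu] times consecutively.  Returns the error
// indicator per tested pattern under sign(m + h) with the final weights.
// [[Rcpp::export]]
IntegerVector cpp_two_forgetting_run(int N_x, int N_y, int P,
                                     const IntegerVector &reps, int burn_in,
                                     double kappa, double alpha, double beta,
                                     double nbar, bool by_input_norm) {
  arma::vec w(N_x, arma::fill::zeros), v(N_y, arma::fill::zeros);
  arma::vec x(N_x), y(N_y);
  const double ay = alpha / (N_y * nbar);
  const double by = std::sqrt(2.0) * beta / (N_y * nbar);
  for (int b = 0; b < burn_in; ++b) {
    for (int j = 0; j < N_x; ++j) x[j] = norm_rand();
    for (int j = 0; j < N_y; ++j) y[j] = norm_rand();
    double z = (unif_rand() < 0.5) ? -1.0 : 1.0;
    double u = arma::dot(w, x) + arma::dot(v, y);
    margin_step(w, x, z, u, kappa, by_input_norm);
    v = (1.0 - ay) * v + (by * z) * y;
  }
  arma::mat Xt(P, N_x), Yt(P, N_y);
  arma::vec zt(P);
  for (int mu = 0; mu < P; ++mu) {
    for (int j = 0; j < N_x; ++j) Xt(mu, j) = norm_rand();
    for (int j = 0; j < N_y; ++j) Yt(mu, j) = norm_rand();
    zt[mu] = (unif_rand() < 0.5) ? -1.0 : 1.0;
    arma::vec xv = Xt.row(mu).t(), yv = Yt.row(mu).t();
    for (int r = 0; r < reps[mu]; ++r) {
      double u = arma::dot(w, xv) + arma::dot(v, yv);
      margin_step(w, xv, zt[mu], u, kappa, by_input_norm);
      v = (1.0 - ay) * v + (by * zt[mu]) * yv;
    }
  }
  IntegerVector err(P);
  arma::vec u_all = Xt * w + Yt * v;
  for (int mu = 0; mu < P; ++mu) err[mu] = (sgn1(u_all[mu]) != zt[mu]) ? 1 : 0;
  return err;
}

// REINFORCE trainer on a single fixed input pattern.
// variant: 0 = RL only (W trained), 1 = RL + HL (W REINFORCE, V Hebbian),
//          2 = RL + RL (W with eta, V with eta2 REINFORCE).
// Returns per-trial traces: reward, baseline, alignment, control ratio, and
// the match fraction of the realized readout with zhat.
// [[Rcpp::export]]
List cpp_rl_train(arma::mat W, arma::mat V, const arma::vec &x,
                  const arma::vec &y, const arma::vec &zhat, int n_trials,
                  int variant, double eta, double eta2, double beta,
                  double alpha, double tau_R, double Rbar0, bool use_realized) {
  const int N_x = x.n_elem, N_y = y.n_elem, N_z = W.n_rows;
  const double sqNz = std::sqrt((double)N_z);
  double Rbar = Rbar0;
  arma::mat tr(n_trials, 5);
  arma::vec z(N_z);
  for (int t = 0; t < n_trials; ++t) {
    arma::vec m = W * x;
    arma::vec h = (N_y > 0) ? arma::vec(V * y) : arma::vec(N_z, arma::fill::zeros);
    double Rv = 0.0;
    int match = 0;
    for (int i = 0; i < N_z; ++i) {
      double p = 1.0 / (1.0 + std::exp(-(m[i] + h[i])));
      z[i] = (unif_rand() < p) ? 1.0 : -1.0;
      Rv += z[i] * zhat[i];
      if (z[i] == zhat[i]) ++match;
    }
    Rv /= sqNz;
    // REINFORCE on the fast pathway
    arma::vec gi(N_z);
    for (int i = 0; i < N_z; ++i) {
      double s = 1.0 / (1.0 + std::exp(z[i] * (m[i] + h[i])));
      gi[i] = (eta / N_x) * (Rv - Rbar) * z[i] * s;
    }
    W += gi * x.t();
    if (N_y > 0) {
      if (variant == 1) { // slow Hebbian pathway
        double a = alpha / N_y, b = std::sqrt(2.0) * beta / N_y;
        const arma::vec &post = use_realized ? z : zhat;
        V *= (1.0 - a);
        V += b * post * y.t();
      } else if (variant == 2) { // slow REINFORCE pathway
        arma::vec g2(N_z);
        for (int i = 0; i < N_z; ++i) {
          double s = 1.0 / (1.0 + std::exp(z[i] * (m[i] + h[i])));
          g2[i] = (eta2 / N_y) * (Rv - Rbar) * z[i] * s;
        }
        V += g2 * y.t();
      }
    }
    Rbar = (1.0 - 1.0 / tau_R) * Rbar + Rv / tau_R;
    double nm = arma::norm(m), nh = arma::norm(h);
    tr(t, 0) = Rv;
    tr(t, 1) = Rbar;
    tr(t, 2) = (nm > 0 && nh > 0) ? arma::dot(m, h) / (nm * nh) : 0.0;
    double tot = arma::dot(m + h, zhat);
    tr(t, 3) = (tot != 0.0) ? arma::dot(h, zhat) / tot : NA_REAL;
    tr(t, 4) = (double)match / N_z;
  }
  return List::create(_["W"] = W, _["V"] = V, _["Rbar"] = Rbar,
                      _["traces"] = tr);
}

// ---- Center-out reaching network -------------------------------------------
//
// x_t = Bx * f_{t-1} + cue_x ; y_t = By * f_{t-1} + cue_y, where f is the
// cursor position (feedback_mode 0) or the previous velocity command (1).
// Hidden layer z = tanh(W x + V y); readout u = A z drives the cursor with
// dt = 1/T.  Supervised learning: per-trial batch gradient descent on W
// against the squared velocity error (gradient truncated at the feedback
// loop).  Hebbian learning: dV = eta_hl * (-V + z y^T) at every step.

struct ReachStep {
  arma::vec x, y, z, u;
};

static void reach_trial(const arma::mat &W, const arma::mat &V,
                        const arma::mat &A, const arma::mat &Bx,
                        const arma::mat &By, const arma::vec &cue_x,
                        const arma::vec &cue_y, const arma::vec &target,
                        int T, int feedback_mode, arma::mat &pos,
                        arma::mat &vel, arma::vec &step_loss,
                        std::vector<ReachStep> &steps) {
  arma::vec r(2, arma::fill::zeros), uprev(2, arma::fill::zeros);
  pos.row(0) = r.t();
  for (int t = 1; t <= T; ++t) {
    arma::vec f = (feedback_mode == 0) ? r : uprev;
    arma::vec x = Bx * f + cue_x;
    arma::vec y = By * f + cue_y;
    arma::vec z = arma::tanh(W * x + V * y);
    arma::vec u = A * z;
    double tt = (double)t / T;
    arma::vec uhat = target * (30.0 * tt * tt - 60.0 * tt * tt * tt +
                               30.0 * tt * tt * tt * tt);
    arma::vec e = u - uhat;
    step_loss[t - 1] = arma::dot(e, e) / 2.0; // mean over the 2 output dims
    vel.row(t - 1) = u.t();
    r += u / T;
    pos.row(t) = r.t();
    uprev = u;
    steps.push_back({x, y, z, u});
  }
}

// [[Rcpp::export]]
List cpp_reach_run(arma::mat W, arma::mat V, const arma::mat &A,
                   const arma::mat &Bx, const arma::mat &By,
                   const arma::mat &CueX, const arma::mat &CueY,
                   const arma::mat &targets_pos, const IntegerVector &trial_targets,
                   int T, double eta_sl, double eta_hl, bool hl_on, bool learn,
                   int feedback_mode, bool record_last) {
  const int n_trials = trial_targets.size();
  NumericVector loss(n_trials);
  arma::mat pos(T + 1, 2), vel(T, 2);
  arma::vec step_loss(T);
  List last;
  for (int tr = 0; tr < n_trials; ++tr) {
    int tg = trial_targets[tr] - 1;
    arma::vec target = targets_pos.row(tg).t();
    std::vector<ReachStep> steps;
    steps.reserve(T);
    reach_trial(W, V, A, Bx, By, CueX.col(tg), CueY.col(tg), target, T,
                feedback_mode, pos, vel, step_loss, steps);
    // reported loss: mean over steps and output dimensions of squared error
    loss[tr] = 2.0 * arma::mean(step_loss) / 2.0; // = mean squared error
    if (learn) {
      arma::mat gW(W.n_rows, W.n_cols, arma::fill::zeros);
      for (int t = 1; t <= T; ++t) {
        const ReachStep &s = steps[t - 1];
        double tt = (double)t / T;
        arma::vec uhat = target * (30.0 * tt * tt - 60.0 * tt * tt * tt +
                                   30.0 * tt * tt * tt * tt);
        arma::vec du = s.u - uhat;   // gradient of the summed step losses
        arma::vec dz = (A.t() * du) % (1.0 - s.z % s.z);
        gW += dz * s.x.t();
        if (hl_on && eta_hl > 0.0) {
          V += eta_hl * (-V + s.z * s.y.t());
        }
      }
      W -= eta_sl * gW;
    }
    if (record_last && tr == n_trials - 1) {
      last = List::create(_["positions"] = pos, _["velocities"] = vel,
                          _["step_loss"] = step_loss);
    }
  }
  List out = List::create(_["W"] = W, _["V"] = V, _["loss"] = loss);
  if (record_last) out["last_trial"] = last;
  return out;
}
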