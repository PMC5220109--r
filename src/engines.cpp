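// Compiled inner loops of the simulator. Each function mirrors its pure-R
// reference implementation (see R/cognitive.R, R/motor.R) operation for
// operation and RNG draw for RNG draw, so the two engines are exchangeable
// and are cross-checked for exact equality in the test suite.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double logistic(double x, double lambda) {
  return 1.0 / (1.0 + std::exp(-lambda * x));
}

// [[Rcpp::export]]
List cog_train_cpp(NumericMatrix W1_in, NumericMatrix W2_in,
                   NumericMatrix S, IntegerVector correct,
                   NumericVector p1, NumericVector p2,
                   int n1, int n2,
                   double lambda, double A_Q, double eta, double tau,
                   double delta_star, double delta_med) {
  NumericMatrix W1 = clone(W1_in), W2 = clone(W2_in);
  const int n_hidden = W1.nrow(), n_in = W1.ncol(), n_cue = S.ncol();
  std::vector<double> c1(n_cue), c2(n_cue);
  double a = 0.0, b2 = 0.0;
  for (int k = 0; k < n_cue; ++k) { a += p1[k]; c1[k] = a; b2 += p2[k]; c2[k] = b2; }

  RNGScope scope;
  std::vector<double> net1(n_hidden), M(n_hidden);
  for (int t = 1; t <= n1 + n2; ++t) {
    const std::vector<double>& cp = (t <= n1) ? c1 : c2;
    double u = unif_rand();
    int k = 0;
    while (k < n_cue - 1 && u >= cp[k]) ++k;
    for (int j = 0; j < n_hidden; ++j) {
      double acc = 0.0;
      for (int i = 0; i < n_in; ++i) acc += W1(j, i) * S(i, k);
      net1[j] = acc;
      M[j] = logistic(acc, lambda);
    }
    double Q[2];
    for (int o = 0; o < 2; ++o) {
      double acc = 0.0;
      for (int j = 0; j < n_hidden; ++j) acc += W2(o, j) * M[j];
      Q[o] = A_Q * logistic(acc, lambda);
    }
    double mx = std::max(Q[0], Q[1]);
    double e0 = std::exp((Q[0] - mx) / tau), e1 = std::exp((Q[1] - mx) / tau);
    int sel = (unif_rand() < e0 / (e0 + e1)) ? 0 : 1;
    double r = ((sel == 0) == (correct[k] == 1)) ? 1.0 : 0.0;
    double delta = r - Q[sel];
    delta = std::min(delta, delta_star) + delta_med;
    for (int j = 0; j < n_hidden; ++j) {
      double gp = lambda * M[j] * (1.0 - M[j]);
      double d2 = W2(sel, j) * gp * delta;
      for (int i = 0; i < n_in; ++i) W1(j, i) += eta * (d2 * S(i, k));
      W2(sel, j) += eta * delta * M[j];
    }
  }
  return List::create(Named("W1") = W1, Named("W2") = W2);
}

// view vector of the upcoming doorway; matches compute_view_vector()
static void view_vector(double x, double y, double hx, double hy,
                        double yd, double half_gap, double height,
                        double* phi) {
  const int n = 50;
  for (int i = 0; i < 2 * n; ++i) phi[i] = -1.0;
  double th0 = std::atan2(hx, hy);
  for (int i = 0; i < n; ++i) {
    double aoff = (i + 1) - 0.5;                 // seq_len(n) - 0.5
    double off = (M_PI / 180.0) * (-120.0 / 2.0 + 120.0 * aoff / n);
    double ang = th0 + off;
    double dy = std::cos(ang), dx = std::sin(ang);
    if (dy > 0) {
      double tt = (yd - y) / dy;
      double xi = x + tt * dx;
      if (std::isfinite(xi) && std::fabs(xi) < half_gap) phi[i] = 1.0;
    }
  }
  double d_along = yd - y;
  if (d_along > 0) {
    double top = std::atan2(height, d_along);
    for (int i = 0; i < n; ++i) {
      double elev = (M_PI / 180.0) * 90.0 * ((i + 1) - 0.5) / n;
      if (elev < top) phi[n + i] = 1.0;
    }
  }
}

// [[Rcpp::export]]
List motor_run_cpp(NumericVector Wv_in, NumericVector Wr_in,
                   NumericVector center_y, NumericVector half_gap,
                   double height, double half_width,
                   NumericVector onset_y, NumericVector drive,
                   NumericVector par,
                   bool learn, bool risk_residual, int step_cap,
                   bool record_steps) {
  NumericVector Wv = clone(Wv_in), Wr = clone(Wr_in);
  const int dim = Wv.size(), n_door = center_y.size();
  const double lambda = par[0], A_Q = par[1], A_h = par[2], eta = par[3],
               gamma = par[4], alpha = par[5], A_G = par[6], A_N = par[7],
               A_E = par[8], lam_G = par[9], lam_N = par[10],
               sig_E = par[11], lam_vel = par[12], b = par[13],
               th = par[14], ds = par[15], dmed = par[16];
  const double radius = 0.5;
  const bool clamp_on = std::isfinite(ds);

  std::vector<double> phi(dim);
  double px = 0.0, py = 0.0, vx = 0.0, vy = 0.1, hdx = 0.0, hdy = 1.0;
  double Q_prev = 0.0, U_prev = 0.0, r_pending = 0.0;
  bool fresh = true;
  double s_acc = 0.0;
  int since = 0;
  bool cue_live = false;
  double cue_u = NA_REAL;
  int post_cue = -1, cue_seg = 0;
  long t = 0;
  const long t_max = (long)n_door * (step_cap + 4) + 1000;

  IntegerVector seg_steps(n_door), seg_coll(n_door);
  LogicalVector seg_pass(n_door), seg_cap(n_door);
  std::vector<double> f_step, f_lat, f_y, f_seg, f_cueseg, f_post, f_cued,
      f_capped, f_umot, f_ucog;
  std::vector<double> log_rows;

  RNGScope scope;
  int target = 0;
  while (true) {
    while (target < n_door && center_y[target] <= py) ++target;
    if (target >= n_door || t >= t_max) break;
    ++t;
    view_vector(px, py, hdx, hdy, center_y[target], half_gap[target],
                height, phi.data());
    double accv = 0.0, accr = 0.0;
    for (int i = 0; i < dim; ++i) { accv += Wv[i] * phi[i]; accr += Wr[i] * phi[i]; }
    double Q = A_Q * logistic(accv, lambda);
    double h = A_h * logistic(accr, lambda);
    double sgn = (Q > 0) - (Q < 0);
    double U = Q - alpha * sgn * h;
    double dU;
    if (!fresh) {
      double delta = r_pending + gamma * Q - Q_prev;
      if (clamp_on) delta = std::min(delta, ds);
      delta += dmed;
      if (learn) {
        double rerr = risk_residual ? delta * delta - h : delta * delta;
        for (int i = 0; i < dim; ++i) {
          Wv[i] += eta * delta * phi[i];
          Wr[i] += eta * rerr * phi[i];
        }
      }
      dU = U - U_prev;
    } else {
      dU = 0.0;
      fresh = false;
    }
    double chi0 = norm_rand(), chi1 = norm_rand();
    double go = A_G * logistic(lam_G * dU, 1.0);
    double nogo = A_N * logistic(-lam_N * dU, 1.0);
    double explore = A_E * std::exp(-dU * dU / (sig_E * sig_E));
    double rx = (go - nogo) * vx + explore * chi0;
    double ry = (go - nogo) * vy + explore * chi1;
    double dx = rx, dy = logistic(lam_vel * ry, 1.0);
    double y_before = py;
    double nx = px + dx, ny = py + dy;
    int event = 0; // 0 none, 1 passed, 2 collided
    double reward = 0.0;
    if (ny >= center_y[target]) {
      double yd = center_y[target];
      double xc = (ny > py) ? px + (nx - px) * (yd - py) / (ny - py) : px;
      if (std::fabs(xc) < half_gap[target] - radius) {
        event = 1; reward = 1.0;
      } else {
        event = 2; reward = -1.0;
        nx = px; ny = py;
      }
    }
    double lat_max = half_width - radius;
    nx = std::min(std::max(nx, -lat_max), lat_max);
    double nrm = std::sqrt(dx * dx + dy * dy);
    if (nrm > 0 && event != 2) { hdx = dx / nrm; hdy = dy / nrm; }
    px = nx; py = ny;
    vx = dx; vy = dy;
    r_pending = reward;
    double speed = nrm;
    double kappa = cue_live ? b + cue_u : b;
    s_acc += std::max(kappa * speed, 0.0);
    ++since;
    seg_steps[target] += 1;
    if (event == 2) seg_coll[target] += 1;
    bool crossed = s_acc >= th;
    bool capped_now = seg_steps[target] >= step_cap && !crossed && event != 1;
    if (crossed || capped_now) {
      if (post_cue >= 0) ++post_cue;
      f_step.push_back((double)t);
      f_lat.push_back((double)since);
      f_y.push_back(py);
      f_seg.push_back((double)(target + 1));
      f_cueseg.push_back((double)cue_seg);
      f_post.push_back((double)post_cue);
      f_cued.push_back(cue_live ? 1.0 : 0.0);
      f_capped.push_back(capped_now ? 1.0 : 0.0);
      f_umot.push_back(U);
      f_ucog.push_back(cue_live ? cue_u : NA_REAL);
      s_acc = 0.0; since = 0;
      cue_live = false;
    }
    if (record_steps) {
      double row[13] = {(double)t, px, py, dx, dy, speed, Q, h, U, dU,
                        reward, (double)event, kappa};
      log_rows.insert(log_rows.end(), row, row + 13);
    }
    if (!ISNA(onset_y[target]) && onset_y[target] > y_before &&
        onset_y[target] <= py) {
      if (cue_live && since > 0) { // censor the still-pending previous cue
        f_step.push_back((double)t);
        f_lat.push_back((double)since);
        f_y.push_back(py);
        f_seg.push_back((double)(target + 1));
        f_cueseg.push_back((double)cue_seg);
        f_post.push_back(1.0);
        f_cued.push_back(1.0);
        f_capped.push_back(1.0);
        f_umot.push_back(U);
        f_ucog.push_back(cue_u);
        s_acc = 0.0; since = 0;
      }
      cue_live = true; cue_u = drive[target]; post_cue = 0;
      cue_seg = target + 1;
    }
    if (event == 1) {
      seg_pass[target] = true;
    } else if (capped_now) {
      seg_cap[target] = true;
      px = 0.0; py = center_y[target] + 0.01;
      vx = 0.0; vy = 0.1; hdx = 0.0; hdy = 1.0;
      fresh = true; r_pending = 0.0;
    }
    Q_prev = Q; U_prev = U;
  }
  if (cue_live && since > 0) { // run ended with the last cue still pending
    f_step.push_back((double)t);
    f_lat.push_back((double)since);
    f_y.push_back(py);
    f_seg.push_back((double)cue_seg);
    f_cueseg.push_back((double)cue_seg);
    f_post.push_back(1.0);
    f_cued.push_back(1.0);
    f_capped.push_back(1.0);
    f_umot.push_back(U_prev);
    f_ucog.push_back(cue_u);
  }

  int nf = f_step.size();
  NumericMatrix fs(nf, 10);
  for (int i = 0; i < nf; ++i) {
    fs(i, 0) = f_step[i]; fs(i, 1) = f_lat[i]; fs(i, 2) = f_y[i];
    fs(i, 3) = f_seg[i]; fs(i, 4) = f_cueseg[i]; fs(i, 5) = f_post[i];
    fs(i, 6) = f_cued[i]; fs(i, 7) = f_capped[i]; fs(i, 8) = f_umot[i];
    fs(i, 9) = f_ucog[i];
  }
  NumericMatrix sg(n_door, 4);
  for (int i = 0; i < n_door; ++i) {
    sg(i, 0) = seg_steps[i]; sg(i, 1) = seg_coll[i];
    sg(i, 2) = seg_pass[i] ? 1.0 : 0.0; sg(i, 3) = seg_cap[i] ? 1.0 : 0.0;
  }
  List out = List::create(Named("W_value") = Wv, Named("W_risk") = Wr,
                          Named("footsteps") = fs, Named("segments") = sg);
  if (record_steps) {
    int nr = log_rows.size() / 13;
    NumericMatrix lg(nr, 13);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < 13; ++j) lg(i, j) = log_rows[i * 13 + j];
    out["steps"] = lg;
  }
  return out;
}
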