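// Event-driven burst-and-coast school simulator.
//
// Each agent alternates instantaneous "kicks" (heading/step decisions) with
// passive straight glides whose traveled fraction follows the exponential
// speed decay f(dt) = (1 - exp(-dt/tau0)) / (1 - exp(-tau/tau0)). The event
// agenda processes kick-end times in increasing order (ties broken by agent
// index). All randomness comes from R's RNG so runs are reproducible from
// set.seed(); the per-kick draw order is: [random-strategy selection],
// noise variate g, kick length, then the bounded-domain rejection ladder.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

static inline double wrap_angle(double a) {
  double w = a - TWO_PI * std::round(a / TWO_PI);
  if (w <= -M_PI) w = M_PI;
  return w;
}

struct Params {
  double gamma_R, alpha, gamma_w, l_w, beta_w;
  double gamma_Att, l_Att, d_Att, beta_Att, lambda_Att;
  double gamma_Ali, l_Ali, d_Ali, beta_Ali, lambda_Ali;
  double v0, tau0, mean_kick_length, arena_radius, d_cut;
  double kick_shape, tau_mean, kick_scale;
  int kick_law;   // 0 = gamma, 1 = constant
  int tau_mode;   // 0 = from_length, 1 = sampled, 2 = constant
  int noise_convention; // 0 = boundary (factor 1-alpha everywhere), 1 = local (r_w-dependent)
  int reject_order;    // 0 = lengths first then noise redraws, 1 = joint redraw
};

static Params unpack_params(const List& p) {
  Params q;
  q.gamma_R = p["gamma_R"]; q.alpha = p["alpha"];
  q.gamma_w = p["gamma_w"]; q.l_w = p["l_w"]; q.beta_w = p["beta_w"];
  q.gamma_Att = p["gamma_Att"]; q.l_Att = p["l_Att"]; q.d_Att = p["d_Att"];
  q.beta_Att = p["beta_Att"]; q.lambda_Att = p["lambda_Att"];
  q.gamma_Ali = p["gamma_Ali"]; q.l_Ali = p["l_Ali"]; q.d_Ali = p["d_Ali"];
  q.beta_Ali = p["beta_Ali"]; q.lambda_Ali = p["lambda_Ali"];
  q.v0 = p["v0"]; q.tau0 = p["tau0"];
  q.mean_kick_length = p["mean_kick_length"];
  q.arena_radius = p["arena_radius"];
  q.d_cut = p["d_cut"];
  q.kick_shape = p["kick_shape"]; q.tau_mean = p["tau_mean"];
  q.kick_scale = p["kick_scale"];
  std::string law = as<std::string>(p["kick_law"]);
  q.kick_law = (law == "constant") ? 1 : 0;
  std::string tm = as<std::string>(p["tau_mode"]);
  q.tau_mode = (tm == "sampled") ? 1 : (tm == "constant" ? 2 : 0);
  std::string nc = as<std::string>(p["noise_convention"]);
  q.noise_convention = (nc == "local") ? 1 : 0;
  std::string ro = as<std::string>(p["boundary_rejection"]);
  q.reject_order = (ro == "joint") ? 1 : 0;
  return q;
}

static inline double att_turn(const Params& p, double d, double psi, double phi) {
  if (d == 0.0 || d > p.d_cut) return 0.0;
  double f = p.gamma_Att * (d / p.d_Att - 1.0) / (1.0 + (d / p.l_Att) * (d / p.l_Att));
  double o = p.beta_Att * std::sin(psi) * (1.0 - 0.33 * std::cos(psi));
  double e = p.lambda_Att * (1.0 - 0.48 * std::cos(phi) - 0.31 * std::cos(2.0 * phi));
  return f * o * e;
}

static inline double ali_turn(const Params& p, double d, double psi, double phi) {
  if (d == 0.0) return 0.0;
  double f = p.gamma_Ali * (d / p.d_Ali + 1.0) * std::exp(-(d / p.l_Ali) * (d / p.l_Ali));
  double e = p.beta_Ali * (1.0 + 0.6 * std::cos(psi) - 0.32 * std::cos(2.0 * psi));
  double o = p.lambda_Ali * std::sin(phi) * (1.0 + 0.3 * std::cos(2.0 * phi));
  return f * e * o;
}

static inline double wall_turn_c(const Params& p, double r_w, double theta_w) {
  double f = p.gamma_w * std::exp(-(r_w / p.l_w) * (r_w / p.l_w));
  return f * p.beta_w * std::sin(theta_w) * (1.0 + 0.7 * std::cos(2.0 * theta_w));
}

// kick length draw (truncated to (0, 0.99 v0 tau0) for the gamma law)
static inline double draw_length(const Params& p) {
  if (p.kick_law == 1) return p.mean_kick_length;
  double hi = 0.99 * p.v0 * p.tau0;
  double scale = p.kick_scale;
  for (int it = 0; it < 1000; ++it) {
    double l = R::rgamma(p.kick_shape, scale);
    if (l > 0.0 && l < hi) return l;
  }
  stop("kick-length sampling failed (truncation bounds too tight)");
  return NA_REAL; // not reached
}

static inline double kick_duration(const Params& p, double l) {
  switch (p.tau_mode) {
  case 2: return p.tau_mean;
  case 1: {
    double scale = p.tau_mean / p.kick_shape;
    for (int it = 0; it < 1000; ++it) {
      double tau = R::rgamma(p.kick_shape, scale);
      if (tau > 1e-3) return tau;
    }
    stop("kick-duration sampling failed");
  }
  default: return -p.tau0 * std::log(1.0 - l / (p.v0 * p.tau0));
  }
}

struct Agent {
  double x0, y0;      // kick start position
  double heading;
  double len, tau;    // kick length and duration
  double t0;          // kick onset time
  double t_end;       // scheduled end of the current glide
};

static inline void glide_xy(const Agent& a, const Params& p, double t,
                            double& x, double& y) {
  double dt = t - a.t0;
  double f;
  if (dt <= 0.0) {
    f = 0.0;
  } else if (dt >= a.tau) {
    f = 1.0;
  } else {
    f = (1.0 - std::exp(-dt / p.tau0)) / (1.0 - std::exp(-a.tau / p.tau0));
  }
  x = a.x0 + f * a.len * std::cos(a.heading);
  y = a.y0 + f * a.len * std::sin(a.heading);
}

// k distinct uniform picks among `others` (partial Fisher-Yates);
// consumes no RNG when k == others.size()
static std::vector<int> random_subset(std::vector<int> others, int k) {
  int n = (int)others.size();
  if (k >= n) return others;
  for (int m = 0; m < k; ++m) {
    int j = m + (int)std::floor(unif_rand() * (n - m));
    if (j > n - 1) j = n - 1;
    std::swap(others[m], others[j]);
  }
  others.resize(k);
  return others;
}

// [[Rcpp::export(name = ".simulate_school_cpp")]]
List simulate_school_cpp(NumericMatrix init, List params, int strategy_code,
                         int k, bool bounded, int total_kicks,
                         double frame_dt, bool record_kicks,
                         double noise_sign, bool influence_truncated) {
  const Params p = unpack_params(params);
  const int N = init.nrow();
  if (N < 1) stop("need at least one agent");
  if (k > N - 1) stop("k exceeds N - 1");

  std::vector<Agent> ag(N);
  for (int i = 0; i < N; ++i) {
    ag[i].x0 = init(i, 0); ag[i].y0 = init(i, 1);
    ag[i].heading = init(i, 2);
    ag[i].len = init(i, 3); ag[i].tau = init(i, 4);
    ag[i].t0 = 0.0; ag[i].t_end = init(i, 5);
  }

  // kick log
  NumericMatrix kicks(record_kicks ? total_kicks : 0, 8);
  List nbr_log(record_kicks ? total_kicks : 0);

  // frame buffer (grown as needed)
  std::vector<double> fr_t, fr_x, fr_y, fr_h;
  std::vector<int> fr_agent;
  double next_frame = 0.0;
  const bool frames = frame_dt > 0.0;

  std::vector<int> others;
  others.reserve(N);
  std::vector<double> dist2(N), infl(N);
  std::vector<double> cx(N), cy(N); // interpolated positions

  auto emit_frames_until = [&](double t_stop) {
    while (frames && next_frame <= t_stop) {
      for (int j = 0; j < N; ++j) {
        double xj, yj;
        glide_xy(ag[j], p, next_frame, xj, yj);
        fr_t.push_back(next_frame);
        fr_agent.push_back(j + 1);
        fr_x.push_back(xj); fr_y.push_back(yj);
        fr_h.push_back(ag[j].heading);
      }
      next_frame += frame_dt;
    }
  };

  double t = 0.0;
  for (int ev = 0; ev < total_kicks; ++ev) {
    // next event: smallest t_end, ties to lowest index
    int i = 0;
    for (int j = 1; j < N; ++j) if (ag[j].t_end < ag[i].t_end) i = j;
    t = ag[i].t_end;
    if (!std::isfinite(t)) stop("non-finite event time (divergence)");
    emit_frames_until(std::nextafter(t, 0.0)); // frames strictly before t

    // focal moves to its glide endpoint at t
    double xi, yi;
    glide_xy(ag[i], p, t, xi, yi);

    // interpolate everyone (focal included, for the log)
    for (int j = 0; j < N; ++j) glide_xy(ag[j], p, t, cx[j], cy[j]);
    cx[i] = xi; cy[i] = yi;

    // --- neighbor selection ---------------------------------------------
    others.clear();
    for (int j = 0; j < N; ++j) if (j != i) others.push_back(j);
    std::vector<int> sel;
    if (k == 0 || strategy_code == 0) {
      // none
    } else if (k == N - 1 || strategy_code == 4) {
      sel = others;
    } else if (strategy_code == 1) { // nearest
      for (int j : others) {
        double dx = cx[j] - xi, dy = cy[j] - yi;
        dist2[j] = dx * dx + dy * dy;
      }
      std::stable_sort(others.begin(), others.end(),
                       [&](int a, int b) { return dist2[a] < dist2[b]; });
      sel.assign(others.begin(), others.begin() + k);
    } else if (strategy_code == 2) { // random
      sel = random_subset(others, k);
    } else if (strategy_code == 3) { // most influential
      Params pr = p;
      if (!influence_truncated) pr.d_cut = R_PosInf;
      for (int j : others) {
        double dx = cx[j] - xi, dy = cy[j] - yi;
        double d = std::sqrt(dx * dx + dy * dy);
        double psi = wrap_angle(std::atan2(dy, dx) - ag[i].heading);
        double phi = wrap_angle(ag[j].heading - ag[i].heading);
        infl[j] = std::fabs(att_turn(pr, d, psi, phi) + ali_turn(pr, d, psi, phi));
      }
      std::stable_sort(others.begin(), others.end(),
                       [&](int a, int b) { return infl[a] > infl[b]; });
      sel.assign(others.begin(), others.begin() + k);
    } else {
      stop("unknown strategy code");
    }
    std::sort(sel.begin(), sel.end()); // canonical summation order

    // --- heading increment ----------------------------------------------
    double r_w = 0.0, theta_w = 0.0;
    if (bounded) {
      double r = std::sqrt(xi * xi + yi * yi);
      r_w = p.arena_radius - r;
      if (r_w < 0.0) r_w = 0.0;
      theta_w = wrap_angle(ag[i].heading - std::atan2(yi, xi));
    }
    double social = 0.0;
    for (int j : sel) {
      double dx = cx[j] - xi, dy = cy[j] - yi;
      double d = std::sqrt(dx * dx + dy * dy);
      double psi = wrap_angle(std::atan2(dy, dx) - ag[i].heading);
      double phi = wrap_angle(ag[j].heading - ag[i].heading);
      social += att_turn(p, d, psi, phi) + ali_turn(p, d, psi, phi);
    }
    double g = noise_sign * norm_rand();
    double dphi, new_heading = 0.0, len = 0.0;
    bool placed = false;
    int n_l = p.reject_order == 0 ? 50 : 1;   // lengths tried per heading
    int n_g = p.reject_order == 0 ? 51 : 2550; // heading (noise) redraws
    for (int gtry = 0; gtry < n_g && !placed; ++gtry) {
      if (gtry > 0) g = noise_sign * norm_rand(); // rejection ladder: redraw noise
      double noise;
      if (p.noise_convention == 1) {
        // literal printed form: damping follows the local wall distance
        noise = bounded
          ? p.gamma_R * (1.0 - p.alpha * std::exp(-(r_w / p.l_w) * (r_w / p.l_w))) * g
          : p.gamma_R * g;
      } else {
        // damping factor held at its boundary value everywhere
        noise = p.gamma_R * (1.0 - p.alpha) * g;
      }
      dphi = (bounded ? wall_turn_c(p, r_w, theta_w) : 0.0) + noise + social;
      new_heading = wrap_angle(ag[i].heading + dphi);
      for (int ltry = 0; ltry < n_l; ++ltry) {
        len = draw_length(p);
        if (!bounded) { placed = true; break; }
        double ex = xi + len * std::cos(new_heading);
        double ey = yi + len * std::sin(new_heading);
        if (ex * ex + ey * ey <= p.arena_radius * p.arena_radius) {
          placed = true; break;
        }
      }
    }
    if (!placed) {
      // Terminal fallback: when the heading points outward too steeply,
      // no admissible noise/length redraw can succeed. Reflect the heading
      // specularly off the wall tangent (deterministic, mirror-symmetric),
      // then resample the length; as a last resort use half the free chord
      // along the reflected heading, which always lies inside the arena.
      double theta_pos = std::atan2(yi, xi);
      new_heading = wrap_angle(2.0 * theta_pos - ag[i].heading + M_PI);
      dphi = wrap_angle(new_heading - ag[i].heading);
      for (int ltry = 0; ltry < 50 && !placed; ++ltry) {
        len = draw_length(p);
        double ex = xi + len * std::cos(new_heading);
        double ey = yi + len * std::sin(new_heading);
        if (ex * ex + ey * ey <= p.arena_radius * p.arena_radius) placed = true;
      }
      if (!placed) {
        double r = std::sqrt(xi * xi + yi * yi);
        double cr = std::cos(new_heading - theta_pos); // radial component
        double disc = p.arena_radius * p.arena_radius - r * r * (1.0 - cr * cr);
        double chord = -r * cr + std::sqrt(std::max(disc, 0.0));
        len = std::max(0.5 * chord, 1e-6);
        len = std::min(len, 0.99 * p.v0 * p.tau0); // keep the glide relation valid
        placed = true;
      }
    }
    if (!std::isfinite(new_heading) || !std::isfinite(len)) {
      stop("non-finite kick state (agent %d at t = %.3f s)", i + 1, t);
    }
    double tau = kick_duration(p, len);

    if (record_kicks) {
      kicks(ev, 0) = t; kicks(ev, 1) = i + 1;
      kicks(ev, 2) = xi; kicks(ev, 3) = yi;
      kicks(ev, 4) = dphi; kicks(ev, 5) = new_heading;
      kicks(ev, 6) = len; kicks(ev, 7) = tau;
      IntegerVector nb(sel.size());
      for (size_t s = 0; s < sel.size(); ++s) nb[s] = sel[s] + 1;
      nbr_log[ev] = nb;
    }

    ag[i].x0 = xi; ag[i].y0 = yi;
    ag[i].heading = new_heading;
    ag[i].len = len; ag[i].tau = tau;
    ag[i].t0 = t; ag[i].t_end = t + tau;

    if (ev % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  emit_frames_until(t); // frames up to and including the last event time

  List out = List::create(
    _["kicks"] = kicks,
    _["neighbors"] = nbr_log,
    _["duration"] = t,
    _["frame_time"] = NumericVector(fr_t.begin(), fr_t.end()),
    _["frame_agent"] = IntegerVector(fr_agent.begin(), fr_agent.end()),
    _["frame_x"] = NumericVector(fr_x.begin(), fr_x.end()),
    _["frame_y"] = NumericVector(fr_y.begin(), fr_y.end()),
    _["frame_heading"] = NumericVector(fr_h.begin(), fr_h.end())
  );
  return out;
}
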