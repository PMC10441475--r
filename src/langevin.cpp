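#include <Rcpp.h>
using namespace Rcpp;

// Parametric potential fields the integrator understands. The R-level
// PotentialField object mirrors these formulas (see R/landscape.R); a test
// cross-checks the two on random points.
//
// kinds: 0 flat, 1 harmonic, 2 funnel (truncated Gaussian well + optional
// radial Gaussian barrier shell), 3 quartic double well along x.

struct FieldPars {
  int kind;
  int dim;
  double box;          // reflecting wall at +/- box per coordinate
  std::vector<double> center;
  double k;            // harmonic spring constant
  double depth, width, r_cut, e_cut;   // funnel well
  double b_height, b_radius, b_width;  // barrier shell
  double dw_height, dw_scale;          // double well
};

static FieldPars parse_field(const List& field) {
  FieldPars f;
  std::string kind = as<std::string>(field["kind"]);
  f.dim = as<int>(field["dimension"]);
  f.box = as<double>(field["box_half_width"]);
  f.k = 0; f.depth = 0; f.width = 1; f.r_cut = 0; f.e_cut = 0;
  f.b_height = 0; f.b_radius = 0; f.b_width = 1;
  f.dw_height = 0; f.dw_scale = 1;
  f.center.assign(f.dim, 0.0);
  if (kind == "flat") {
    f.kind = 0;
  } else if (kind == "harmonic") {
    f.kind = 1;
    NumericVector c = field["center"];
    for (int i = 0; i < f.dim; ++i) f.center[i] = c[i];
    f.k = as<double>(field["k"]);
  } else if (kind == "funnel") {
    f.kind = 2;
    NumericVector c = field["center"];
    for (int i = 0; i < f.dim; ++i) f.center[i] = c[i];
    f.depth = as<double>(field["well_depth"]);
    f.width = as<double>(field["well_width"]);
    f.r_cut = as<double>(field["r_cut"]);
    f.e_cut = std::exp(-f.r_cut * f.r_cut / (2.0 * f.width * f.width));
    f.b_height = as<double>(field["barrier_height"]);
    f.b_radius = as<double>(field["barrier_radius"]);
    f.b_width = as<double>(field["barrier_width"]);
  } else if (kind == "double_well") {
    f.kind = 3;
    f.dw_height = as<double>(field["height"]);
    f.dw_scale = as<double>(field["scale"]);
  } else {
    stop("unknown field kind: %s", kind.c_str());
  }
  return f;
}

// force into fout; returns potential energy (cheap to compute jointly)
static double force(const FieldPars& f, const double* x, double* fout) {
  for (int i = 0; i < f.dim; ++i) fout[i] = 0.0;
  switch (f.kind) {
  case 0:
    return 0.0;
  case 1: {
    double u = 0.0;
    for (int i = 0; i < f.dim; ++i) {
      double dx = x[i] - f.center[i];
      u += 0.5 * f.k * dx * dx;
      fout[i] = -f.k * dx;
    }
    return u;
  }
  case 2: {
    double r2 = 0.0;
    for (int i = 0; i < f.dim; ++i) {
      double dx = x[i] - f.center[i];
      r2 += dx * dx;
    }
    double r = std::sqrt(r2);
    double u = 0.0;
    double w2 = f.width * f.width;
    if (r < f.r_cut) {
      double e = std::exp(-r2 / (2.0 * w2));
      double norm = 1.0 - f.e_cut;
      u += -f.depth * (e - f.e_cut) / norm;
      // dU/dr = depth * r/w2 * e / norm ; F = -dU/dr * (x-c)/r
      double coef = -f.depth * e / (norm * w2); // F_i = coef * (x_i - c_i)
      for (int i = 0; i < f.dim; ++i) fout[i] += coef * (x[i] - f.center[i]);
    }
    if (f.b_height > 0.0) {
      double s2 = f.b_width * f.b_width;
      double dr = r - f.b_radius;
      double eb = std::exp(-dr * dr / (2.0 * s2));
      u += f.b_height * eb;
      if (r > 1e-12) {
        double dudr = -f.b_height * dr / s2 * eb;
        for (int i = 0; i < f.dim; ++i)
          fout[i] += -dudr * (x[i] - f.center[i]) / r;
      }
    }
    return u;
  }
  case 3: {
    double s = x[0] / f.dw_scale;
    double q = s * s - 1.0;
    double u = f.dw_height * q * q;
    fout[0] = -f.dw_height * 4.0 * q * s / f.dw_scale;
    return u;
  }
  }
  return 0.0;
}

// reflect coordinate into [-box, box]; flips *v on an odd number of bounces
static inline void reflect(double& x, double& v, double box) {
  while (x > box || x < -box) {
    if (x > box)  { x = 2.0 * box - x; v = -v; }
    if (x < -box) { x = -2.0 * box - x; v = -v; }
  }
}

// Overdamped Euler-Maruyama or underdamped BAOAB (unit mass) stepper.
// Uses R's RNG stream so .Random.seed is the restart token.
// [[Rcpp::export]]
List advance_cpp(NumericVector position, NumericVector velocity, List field,
                 double dt, double friction, double temperature, int mode,
                 int n_steps, int stride, double t0) {
  FieldPars f = parse_field(field);
  int d = f.dim;
  if (position.size() != d) stop("position has wrong dimension");
  bool underdamped = (mode == 1);
  std::vector<double> x(position.begin(), position.end());
  std::vector<double> v(d, 0.0);
  if (underdamped) {
    if (velocity.size() != d) stop("velocity has wrong dimension");
    for (int i = 0; i < d; ++i) v[i] = velocity[i];
  }
  std::vector<double> frc(d);

  int n_save = n_steps / stride;
  NumericMatrix frames(n_save, d);
  NumericVector frame_times(n_save);

  // overdamped constants: dx = F*dt/friction + sqrt(2*kT*dt/friction)*xi
  double od_drift = dt / friction;
  double od_noise = std::sqrt(2.0 * temperature * dt / friction);
  // BAOAB O-step constants (unit mass)
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(temperature * (1.0 - c1 * c1));

  int save_i = 0;
  force(f, x.data(), frc.data());
  for (int step = 1; step <= n_steps; ++step) {
    if (!underdamped) {
      for (int i = 0; i < d; ++i) {
        double xi = (temperature > 0.0) ? norm_rand() : 0.0;
        x[i] += frc[i] * od_drift + od_noise * xi;
        double dummy = 0.0;
        reflect(x[i], dummy, f.box);
      }
      force(f, x.data(), frc.data());
    } else {
      for (int i = 0; i < d; ++i) v[i] += 0.5 * dt * frc[i];
      for (int i = 0; i < d; ++i) {
        x[i] += 0.5 * dt * v[i];
        reflect(x[i], v[i], f.box);
      }
      for (int i = 0; i < d; ++i) {
        double xi = (temperature > 0.0) ? norm_rand() : 0.0;
        v[i] = c1 * v[i] + c2 * xi;
      }
      for (int i = 0; i < d; ++i) {
        x[i] += 0.5 * dt * v[i];
        reflect(x[i], v[i], f.box);
      }
      force(f, x.data(), frc.data());
      for (int i = 0; i < d; ++i) v[i] += 0.5 * dt * frc[i];
    }
    for (int i = 0; i < d; ++i) {
      if (!R_finite(x[i]))
        stop("integration failure: non-finite position at step %d", step);
    }
    if (step % stride == 0 && save_i < n_save) {
      for (int i = 0; i < d; ++i) frames(save_i, i) = x[i];
      frame_times[save_i] = t0 + step * dt;
      ++save_i;
    }
  }

  NumericVector fpos(x.begin(), x.end());
  NumericVector fvel;
  if (underdamped) fvel = NumericVector(v.begin(), v.end());
  return List::create(_["frames"] = frames, _["frame_times"] = frame_times,
                      _["final_position"] = fpos, _["final_velocity"] = fvel,
                      _["final_time"] = t0 + n_steps * dt);
}

// Squared displacement of n free overdamped particles after n_steps
// (flat potential, no walls) -- backend validation utility.
// [[Rcpp::export]]
NumericVector free_sq_disp_cpp(int n_particles, int dim, int n_steps,
                               double dt, double friction,
                               double temperature) {
  double sd1 = std::sqrt(2.0 * temperature * dt / friction);
  NumericVector out(n_particles);
  for (int p = 0; p < n_particles; ++p) {
    double r2 = 0.0;
    for (int i = 0; i < dim; ++i) {
      double xi = 0.0;
      for (int s = 0; s < n_steps; ++s) xi += sd1 * norm_rand();
      r2 += xi * xi;
    }
    out[p] = r2;
  }
  return out;
}

// Potential energy at a single point (exported for cross-checks against the
// R-side field closures).
// [[Rcpp::export]]
double potential_cpp(NumericVector position, List field) {
  FieldPars f = parse_field(field);
  std::vector<double> frc(f.dim);
  return force(f, REAL(position), frc.data());
}
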