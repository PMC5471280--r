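// Overdamped Langevin / ABF inner loop and grid path search.
//
// The sampler evaluates preset potentials (harmonic, 1D/2D channel
// profiles) natively; arbitrary R potentials are supported through a
// gradient callback.  All random numbers come from R's RNG stream so runs
// are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

namespace {

// piecewise smoothstep profile through stationary points (t_i, U_i)
double profile_grad(double t, const NumericMatrix &st, double wall) {
  const int n = st.nrow();
  if (t <= st(0, 0)) return 2.0 * wall * (t - st(0, 0));
  if (t >= st(n - 1, 0)) return 2.0 * wall * (t - st(n - 1, 0));
  for (int k = 0; k < n - 1; ++k) {
    if (t <= st(k + 1, 0)) {
      const double t0 = st(k, 0), u0 = st(k, 1);
      const double t1 = st(k + 1, 0), u1 = st(k + 1, 1);
      const double z = (t - t0) / (t1 - t0);
      return (u1 - u0) * 6.0 * z * (1.0 - z) / (t1 - t0);
    }
  }
  return 0.0;
}

struct PotentialSpec {
  int type;  // 0 harmonic, 1 channel1d, 2 channel2d, 3 R callback
  int dim;
  double k;                 // harmonic
  NumericMatrix stations;   // channels
  double wall;
  double p0x, p0y, ux, uy;  // channel2d frame
  double kperp;
  Function grad_fun;

  PotentialSpec(const List &spec, const Function &gf, int d)
      : type(3), dim(d), k(0), stations(0, 0), wall(0), p0x(0), p0y(0),
        ux(0), uy(0), kperp(0), grad_fun(gf) {
    std::string ty = spec.containsElementNamed("type")
                         ? as<std::string>(spec["type"])
                         : "callback";
    if (ty == "harmonic") {
      type = 0;
      k = as<double>(spec["k"]);
    } else if (ty == "channel1d") {
      type = 1;
      stations = as<NumericMatrix>(spec["stations"]);
      wall = as<double>(spec["wall"]);
    } else if (ty == "channel2d") {
      type = 2;
      stations = as<NumericMatrix>(spec["stations"]);
      wall = as<double>(spec["wall"]);
      NumericVector p0 = spec["p0"], u = spec["u"];
      p0x = p0[0]; p0y = p0[1]; ux = u[0]; uy = u[1];
      kperp = as<double>(spec["kperp"]);
    }
  }

  // writes -grad U into f
  void sysForce(const double *x, double *f) const {
    switch (type) {
      case 0:
        for (int i = 0; i < dim; ++i) f[i] = -k * x[i];
        break;
      case 1:
        f[0] = -profile_grad(x[0], stations, wall);
        break;
      case 2: {
        const double rx = x[0] - p0x, ry = x[1] - p0y;
        const double t = rx * ux + ry * uy;
        const double sx = rx - t * ux, sy = ry - t * uy;
        const double dudt = profile_grad(t, stations, wall);
        f[0] = -(dudt * ux + kperp * sx);
        f[1] = -(dudt * uy + kperp * sy);
        break;
      }
      default: {
        NumericVector xv(dim);
        for (int i = 0; i < dim; ++i) xv[i] = x[i];
        NumericVector g = grad_fun(xv);
        for (int i = 0; i < dim; ++i) f[i] = -g[i];
      }
    }
  }
};

inline int bin_index(double x, double lo, double w, int n) {
  // half-open [edge_i, edge_{i+1}); tiny nudge absorbs representation
  // error so that e.g. (1.1 - 1.0)/0.1 lands in bin 1
  const double z = (x - lo) / w + 1e-9;
  if (z < 0.0) return -1;
  const int i = static_cast<int>(std::floor(z));
  return (i >= n) ? -1 : i;
}

}  // namespace

// [[Rcpp::export]]
List run_dynamics_cpp(List spec, Function grad_fun, NumericVector x0,
                      int n_steps, double dt, double gamma, double kT,
                      List abf, bool record) {
  const int dim = x0.size();
  PotentialSpec pot(spec, grad_fun, dim);

  const bool abf_on = as<bool>(abf["enabled"]);
  bool bias_on = false;
  int nx = 0, ny = 0, nbins = 0, n_full = 0;
  double lo0 = 0, lo1 = 0, w0 = 0, w1 = 0, bk = 0;
  NumericVector dom_lo, dom_hi;
  IntegerVector counts;
  NumericMatrix fsums;  // nbins x dim
  if (abf_on) {
    bias_on = as<bool>(abf["bias"]);
    IntegerVector nb = abf["n_bins"];
    NumericVector lo = abf["lo"], wid = abf["width"];
    nx = nb[0];
    ny = (dim == 2) ? nb[1] : 1;
    nbins = nx * ny;
    lo0 = lo[0]; w0 = wid[0];
    if (dim == 2) { lo1 = lo[1]; w1 = wid[1]; }
    n_full = as<int>(abf["n_full"]);
    bk = as<double>(abf["boundary_k"]);
    dom_lo = as<NumericVector>(abf["dom_lo"]);
    dom_hi = as<NumericVector>(abf["dom_hi"]);
    counts = as<IntegerVector>(abf["counts"]);
    fsums = as<NumericMatrix>(abf["force_sums"]);
  }

  NumericMatrix pos, frc;
  if (record) {
    pos = NumericMatrix(n_steps, dim);
    frc = NumericMatrix(n_steps, dim);
  }

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> f(dim), ext(dim);
  const double sig = std::sqrt(2.0 * kT * dt / gamma);

  RNGScope rng;
  for (int s = 0; s < n_steps; ++s) {
    pot.sysForce(x.data(), f.data());
    for (int i = 0; i < dim; ++i) {
      if (!std::isfinite(f[i]))
        stop("non-finite systematic force at step %d", s + 1);
      ext[i] = 0.0;
    }

    if (abf_on) {
      // accrue the instantaneous systematic force, then bias from the
      // updated running mean (current sample included)
      const int i0 = bin_index(x[0], lo0, w0, nx);
      int idx = -1;
      if (dim == 1) {
        idx = i0;
      } else {
        const int i1 = bin_index(x[1], lo1, w1, ny);
        if (i0 >= 0 && i1 >= 0) idx = i0 + nx * i1;
      }
      if (idx >= 0) {
        counts[idx] += 1;
        for (int i = 0; i < dim; ++i) fsums(idx, i) += f[i];
        if (bias_on) {
          const int n = counts[idx];
          const double ramp =
              (n >= n_full) ? 1.0 : static_cast<double>(n) / n_full;
          for (int i = 0; i < dim; ++i)
            ext[i] -= ramp * fsums(idx, i) / n;
        }
      }
      // harmonic boundary restraints outside the domain
      for (int i = 0; i < dim; ++i) {
        if (x[i] > dom_hi[i]) ext[i] += -bk * (x[i] - dom_hi[i]);
        else if (x[i] < dom_lo[i]) ext[i] += -bk * (x[i] - dom_lo[i]);
      }
    }

    for (int i = 0; i < dim; ++i) {
      x[i] += (f[i] + ext[i]) * dt / gamma + sig * norm_rand();
      if (!std::isfinite(x[i]))
        stop("non-finite position at step %d: timestep too large", s + 1);
    }
    if (record) {
      for (int i = 0; i < dim; ++i) {
        pos(s, i) = x[i];
        frc(s, i) = f[i];
      }
    }
  }

  List out = List::create(_["final"] = NumericVector(x.begin(), x.end()));
  if (record) {
    out["positions"] = pos;
    out["forces"] = frc;
  }
  if (abf_on) {
    out["counts"] = counts;
    out["force_sums"] = fsums;
  }
  return out;
}

// Minimax ("widest") path between two cells of a gridded surface: among all
// 8-connected paths through finite-G cells it minimises the maximum G, with
// ties broken by minimal summed G, then by lexicographic predecessor order.
// g is the column-major nx*ny surface with NA for unusable cells.
// [[Rcpp::export]]
List minimax_path_cpp(NumericVector g, int nx, int ny, int start, int goal) {
  const int n = nx * ny;
  if (start < 0 || start >= n || goal < 0 || goal >= n)
    stop("start or goal outside grid");
  if (NumericVector::is_na(g[start]) || NumericVector::is_na(g[goal]))
    stop("start or goal cell is unsampled");

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> best_max(n, INF), best_sum(n, INF);
  std::vector<int> pred(n, -1);
  std::vector<char> done(n, 0);

  typedef std::tuple<double, double, int, int> Node;  // maxG, sumG, idx, pred
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  best_max[start] = g[start];
  best_sum[start] = g[start];
  pq.emplace(g[start], g[start], start, -1);

  const int dxs[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dys[8] = {0, 0, 1, -1, 1, -1, 1, -1};

  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    const int u = std::get<2>(nd);
    if (done[u]) continue;
    done[u] = 1;
    pred[u] = std::get<3>(nd);
    if (u == goal) break;
    const int ux = u % nx, uy = u / nx;
    for (int k = 0; k < 8; ++k) {
      const int vx = ux + dxs[k], vy = uy + dys[k];
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny) continue;
      const int v = vx + nx * vy;
      if (done[v] || NumericVector::is_na(g[v])) continue;
      const double nm = std::max(best_max[u], static_cast<double>(g[v]));
      const double ns = best_sum[u] + g[v];
      if (nm < best_max[v] ||
          (nm == best_max[v] && ns < best_sum[v]) ||
          (nm == best_max[v] && ns == best_sum[v] && pred[v] == -1)) {
        best_max[v] = nm;
        best_sum[v] = ns;
        pq.emplace(nm, ns, v, u);
      }
    }
  }

  if (!done[goal]) stop("goal not reachable within the sampled mask");

  std::vector<int> path;
  for (int v = goal; v != -1; v = pred[v]) path.push_back(v);
  std::reverse(path.begin(), path.end());
  return List::create(_["path"] = IntegerVector(path.begin(), path.end()),
                      _["max_g"] = best_max[goal],
                      _["sum_g"] = best_sum[goal]);
}
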