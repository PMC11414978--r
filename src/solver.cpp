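// Proximal-gradient solver for lasso / group-lasso penalized Cox partial
// likelihood (Breslow ties) and its squared-error analogue.
// Smooth part f(b) = (1/n) * negative log partial likelihood (Cox) or
// (1/(2n)) * ||y - Xb||^2 (gaussian); penalty lambda*sum|b_j| or
// lambda*sum_g m_g*||b_g||_2. Accelerated proximal gradient with
// backtracking line search and a monotone safeguard, so the objective is
// non-increasing across iterations.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// negative log partial likelihood (scaled by 1/n) and gradient wrt eta.
// ord: indices sorted by time ascending (0-based), precomputed once.
static double cox_nll_grad(const vec& eta, const vec& time, const vec& status,
                           const uvec& ord, vec& grad) {
  const int n = eta.n_elem;
  double shift = mean(eta);
  vec ee = exp(eta - shift);
  // risk-set sums: S(i) = sum of ee over samples with time >= time[ord[i]]
  vec rsk(n);
  double acc = 0.0;
  for (int i = n - 1; i >= 0; --i) {
    acc += ee(ord(i));
    rsk(i) = acc;
  }
  // tied times share the risk-set sum at the first index of the tie run
  for (int i = 1; i < n; ++i)
    if (time(ord(i)) == time(ord(i - 1))) rsk(i) = rsk(i - 1);
  double nll = 0.0;
  double cumhaz = 0.0;            // sum over event times <= t of d/S
  int nev = 0;
  grad.set_size(n);
  int i = 0;
  while (i < n) {
    int j = i;
    int d = 0;
    double eta_sum = 0.0;
    while (j < n && time(ord(j)) == time(ord(i))) {
      if (status(ord(j)) > 0.5) { d++; eta_sum += eta(ord(j)) - shift; }
      ++j;
    }
    if (d > 0) {
      nll -= eta_sum - d * std::log(rsk(i));
      cumhaz += d / rsk(i);
      nev += d;
    }
    for (int k = i; k < j; ++k)
      grad(ord(k)) = (ee(ord(k)) * cumhaz - status(ord(k))) / n;
    i = j;
  }
  return nll / n;
}

static double gauss_obj_grad(const vec& eta, const vec& y, vec& grad) {
  const int n = eta.n_elem;
  vec r = eta - y;
  grad = r / n;
  return 0.5 * dot(r, r) / n;
}

static double smooth_obj(const mat& X, const vec& b, const vec& time,
                         const vec& status, const uvec& ord, int family,
                         vec& grad_eta) {
  vec eta = X * b;
  if (family == 0) return cox_nll_grad(eta, time, status, ord, grad_eta);
  return gauss_obj_grad(eta, time, grad_eta);  // time holds y for gaussian
}

static double penalty_value(const vec& b, double lambda, int pen,
                            const ivec& grp, const vec& gmult) {
  if (lambda <= 0.0) return 0.0;
  if (pen == 0) return lambda * norm(b, 1);
  double s = 0.0;
  for (unsigned g = 0; g < gmult.n_elem; ++g) {
    double nr = 0.0;
    for (unsigned j = 0; j < b.n_elem; ++j)
      if (grp(j) == (int)g) nr += b(j) * b(j);
    s += gmult(g) * std::sqrt(nr);
  }
  return lambda * s;
}

static vec prox_step(const vec& v, double t, double lambda, int pen,
                     const ivec& grp, const vec& gmult) {
  if (lambda <= 0.0) return v;
  vec out(v.n_elem);
  if (pen == 0) {
    double thr = t * lambda;
    for (unsigned j = 0; j < v.n_elem; ++j) {
      double a = std::abs(v(j)) - thr;
      out(j) = a > 0 ? (v(j) > 0 ? a : -a) : 0.0;
    }
    return out;
  }
  out = v;
  for (unsigned g = 0; g < gmult.n_elem; ++g) {
    double nr = 0.0;
    for (unsigned j = 0; j < v.n_elem; ++j)
      if (grp(j) == (int)g) nr += v(j) * v(j);
    nr = std::sqrt(nr);
    double shrink = nr > 0 ? std::max(0.0, 1.0 - t * lambda * gmult(g) / nr) : 0.0;
    for (unsigned j = 0; j < v.n_elem; ++j)
      if (grp(j) == (int)g) out(j) *= shrink;
  }
  return out;
}

// [[Rcpp::export(name = ".cox_obj_grad_eta")]]
Rcpp::List cox_obj_grad_eta(const arma::vec& eta, const arma::vec& time,
                            const arma::vec& status) {
  uvec ord = stable_sort_index(time);
  vec grad;
  double nll = cox_nll_grad(eta, time, status, ord, grad);
  return Rcpp::List::create(Rcpp::Named("nll") = nll,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export(name = ".solve_penalized")]]
Rcpp::List solve_penalized(const arma::mat& X, const arma::vec& time,
                           const arma::vec& status, int family, double lambda,
                           int pen, const arma::ivec& grp,
                           const arma::vec& gmult, double tol, int maxit,
                           const arma::vec& beta_init, bool trace) {
  const int p = X.n_cols;
  uvec ord = stable_sort_index(time);
  vec x = beta_init, x_prev = beta_init, y = beta_init;
  vec grad_eta;
  double tk = 1.0;
  double step = 1.0;
  double Fx = smooth_obj(X, x, time, status, ord, family, grad_eta) +
              penalty_value(x, lambda, pen, grp, gmult);
  std::vector<double> obj_path;
  if (trace) obj_path.push_back(Fx);
  int it = 0;
  bool converged = false;
  bool plain = true;  // whether the next prox step starts from x itself
  double grad_norm = 0.0;
  for (it = 1; it <= maxit; ++it) {
    double fy = smooth_obj(X, y, time, status, ord, family, grad_eta);
    vec gb = X.t() * grad_eta;          // gradient wrt beta at y
    grad_norm = norm(gb, 2);
    // backtracking line search on the proximal step from y
    vec z;
    double fz;
    for (int bt = 0; bt < 60; ++bt) {
      z = prox_step(y - step * gb, step, lambda, pen, grp, gmult);
      vec dz = z - y;
      vec dummy;
      fz = smooth_obj(X, z, time, status, ord, family, dummy);
      if (fz <= fy + dot(gb, dz) + dot(dz, dz) / (2.0 * step) + 1e-14) break;
      step *= 0.5;
    }
    double Fz = fz + penalty_value(z, lambda, pen, grp, gmult);
    if (Fz > Fx) {
      if (plain) {
        // a momentum-free prox step cannot improve the objective further
        converged = true;
        break;
      }
      // momentum overshot: function-value restart, redo a plain step from x
      tk = 1.0;
      y = x;
      plain = true;
      if (trace) obj_path.push_back(Fx);
      continue;
    }
    double rel = (Fx - Fz) / std::max(1e-10, std::abs(Fx));
    x_prev = x;
    x = z;
    Fx = Fz;
    if (trace) obj_path.push_back(Fx);
    if (rel < tol) {
      if (plain) { converged = true; break; }
      // confirm convergence on a momentum-free proximal step
      tk = 1.0;
      y = x;
      plain = true;
      continue;
    }
    double tk1 = (1.0 + std::sqrt(1.0 + 4.0 * tk * tk)) / 2.0;
    y = x + ((tk - 1.0) / tk1) * (x - x_prev);
    tk = tk1;
    plain = false;
    step *= 1.1;  // allow the step to grow back after conservative shrinks
  }
  return Rcpp::List::create(
      Rcpp::Named("beta") = x, Rcpp::Named("objective") = Fx,
      Rcpp::Named("iterations") = it, Rcpp::Named("converged") = converged,
      Rcpp::Named("grad_norm") = grad_norm,
      Rcpp::Named("obj_path") = obj_path);
}
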