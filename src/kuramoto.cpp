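#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// compiled without fast-math in guard.cpp
extern "C" bool kuranet_all_finite(const double *x, int n);

// Sparse Kuramoto right-hand side.
//
// dtheta_i = omega_i + K * sum_j W_ij sin(theta_j - theta_i)
//
// Expanding sin(theta_j - theta_i) = sin th_j cos th_i - cos th_j sin th_i
// turns the coupling sum into two sparse matrix-vector products over the
// same sparsity pattern, so the cost per evaluation is O(N) trig calls plus
// O(nnz) multiply-adds instead of O(nnz) trig calls.
//
// W is passed in dgCMatrix (compressed sparse column) layout: for column j,
// entries k in [p[j], p[j+1]) sit at rows i[k] with value x[k].  Row =
// receiving node, column = sending node.
static void rhs_sparse(const int n,
                       const int *p, const int *ri, const double *wx,
                       const double *omega, const double K,
                       const double *theta, double *dtheta,
                       double *s, double *c,
                       double *sumS, double *sumC) {
    // split loops: each vectorizes to the libm vector sin/cos under
    // fast-math
    for (int i = 0; i < n; ++i) s[i] = std::sin(theta[i]);
    for (int i = 0; i < n; ++i) c[i] = std::cos(theta[i]);
    for (int i = 0; i < n; ++i) { sumS[i] = 0.0; sumC[i] = 0.0; }
    for (int j = 0; j < n; ++j) {
        const double vs = s[j], vc = c[j];
        const int k1 = p[j + 1];
        for (int k = p[j]; k < k1; ++k) {
            const int row = ri[k];
            sumS[row] += wx[k] * vs;
            sumC[row] += wx[k] * vc;
        }
    }
    for (int i = 0; i < n; ++i)
        dtheta[i] = omega[i] + K * (c[i] * sumS[i] - s[i] * sumC[i]);
}

// Mean-field fast path for the uniform complete graph, W_ij = w (i != j):
//   sum_{j != i} w sin(th_j - th_i) = w (S cos th_i - C sin th_i)
// with S = sum_j sin th_j, C = sum_j cos th_j (the i = j term vanishes).
static void rhs_meanfield(const int n, const double w,
                          const double *omega, const double K,
                          const double *theta, double *dtheta,
                          double *s, double *c) {
    for (int i = 0; i < n; ++i) s[i] = std::sin(theta[i]);
    for (int i = 0; i < n; ++i) c[i] = std::cos(theta[i]);
    double S = 0.0, C = 0.0;
    for (int i = 0; i < n; ++i) { S += s[i]; C += c[i]; }
    const double Kw = K * w;
    for (int i = 0; i < n; ++i)
        dtheta[i] = omega[i] + Kw * (S * c[i] - C * s[i]);
}

struct KuramotoSystem {
    int n;
    bool mean_field;
    double mf_weight;
    const int *p;
    const int *ri;
    const double *wx;
    const double *omega;
    double K;
    // workspaces
    std::vector<double> s, c, sumS, sumC;

    void rhs(const double *theta, double *dtheta) {
        if (mean_field)
            rhs_meanfield(n, mf_weight, omega, K, theta, dtheta,
                          s.data(), c.data());
        else
            rhs_sparse(n, p, ri, wx, omega, K, theta, dtheta,
                       s.data(), c.data(), sumS.data(), sumC.data());
    }
};

// One classical RK4 step of size h, in place.
static void rk4_step(KuramotoSystem &sys, std::vector<double> &theta,
                     const double h,
                     std::vector<double> &k1, std::vector<double> &k2,
                     std::vector<double> &k3, std::vector<double> &k4,
                     std::vector<double> &tmp) {
    const int n = sys.n;
    sys.rhs(theta.data(), k1.data());
    for (int i = 0; i < n; ++i) tmp[i] = theta[i] + 0.5 * h * k1[i];
    sys.rhs(tmp.data(), k2.data());
    for (int i = 0; i < n; ++i) tmp[i] = theta[i] + 0.5 * h * k2[i];
    sys.rhs(tmp.data(), k3.data());
    for (int i = 0; i < n; ++i) tmp[i] = theta[i] + h * k3[i];
    sys.rhs(tmp.data(), k4.data());
    const double h6 = h / 6.0;
    for (int i = 0; i < n; ++i)
        theta[i] += h6 * (k1[i] + 2.0 * (k2[i] + k3[i]) + k4[i]);
}

// Advance from t to t_target with fixed steps dt, the last partial step
// shortened to land exactly on t_target.
static void advance_to(KuramotoSystem &sys, std::vector<double> &theta,
                       double &t, const double t_target, const double dt,
                       std::vector<double> &k1, std::vector<double> &k2,
                       std::vector<double> &k3, std::vector<double> &k4,
                       std::vector<double> &tmp) {
    const double eps = 1e-12;
    while (t_target - t > eps) {
        const double h = std::min(dt, t_target - t);
        rk4_step(sys, theta, h, k1, k2, k3, k4, tmp);
        t += h;
    }
    t = t_target;
}

static double order_param(const std::vector<double> &theta) {
    double S = 0.0, C = 0.0;
    const int n = (int)theta.size();
    for (int i = 0; i < n; ++i) {
        S += std::sin(theta[i]);
        C += std::cos(theta[i]);
    }
    return std::sqrt(S * S + C * C) / n;
}

// [[Rcpp::export]]
List kuramoto_run_cpp(const int n,
                      const IntegerVector &Wp, const IntegerVector &Wi,
                      const NumericVector &Wx,
                      const bool mean_field, const double mf_weight,
                      const NumericVector &omega, const NumericVector &theta0,
                      const double K, const double dt,
                      const NumericVector &sample_times,
                      const double threshold, const bool early_exit,
                      const bool return_theta) {
    if ((int)omega.size() != n || (int)theta0.size() != n)
        stop("dimension mismatch between network, omega and theta0");

    KuramotoSystem sys;
    sys.n = n;
    sys.mean_field = mean_field;
    sys.mf_weight = mf_weight;
    sys.p = mean_field ? nullptr : INTEGER(Wp);
    sys.ri = mean_field ? nullptr : INTEGER(Wi);
    sys.wx = mean_field ? nullptr : REAL(Wx);
    sys.omega = REAL(omega);
    sys.K = K;
    sys.s.resize(n);
    sys.c.resize(n);
    if (!mean_field) {
        sys.sumS.resize(n);
        sys.sumC.resize(n);
    }

    std::vector<double> theta(theta0.begin(), theta0.end());
    std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);

    const int ns = sample_times.size();
    NumericVector Rvals(ns, NA_REAL);
    int first_below = NA_INTEGER;
    double t = 0.0;

    for (int m = 0; m < ns; ++m) {
        advance_to(sys, theta, t, sample_times[m], dt, k1, k2, k3, k4, tmp);
        if (!kuranet_all_finite(theta.data(), n))
            stop("integration blow-up: non-finite state at t = %f", t);
        const double R = order_param(theta);
        Rvals[m] = R;
        if (R < threshold && first_below == NA_INTEGER) {
            first_below = m + 1;  // 1-based for R
            if (early_exit) break;
        }
    }

    List out = List::create(_["R"] = Rvals, _["first_below"] = first_below);
    if (return_theta) out["theta"] = NumericVector(theta.begin(), theta.end());
    return out;
}

// Plain RK4 advance exposed for the integrator surface and cross-checks.
// [[Rcpp::export]]
NumericVector kuramoto_rk4_cpp(const int n,
                               const IntegerVector &Wp,
                               const IntegerVector &Wi,
                               const NumericVector &Wx,
                               const bool mean_field, const double mf_weight,
                               const NumericVector &omega,
                               const NumericVector &theta0,
                               const double K, const double dt,
                               const double t0, const double t_target) {
    if ((int)omega.size() != n || (int)theta0.size() != n)
        stop("dimension mismatch between network, omega and theta0");
    KuramotoSystem sys;
    sys.n = n;
    sys.mean_field = mean_field;
    sys.mf_weight = mf_weight;
    sys.p = mean_field ? nullptr : INTEGER(Wp);
    sys.ri = mean_field ? nullptr : INTEGER(Wi);
    sys.wx = mean_field ? nullptr : REAL(Wx);
    sys.omega = REAL(omega);
    sys.K = K;
    sys.s.resize(n);
    sys.c.resize(n);
    if (!mean_field) {
        sys.sumS.resize(n);
        sys.sumC.resize(n);
    }
    std::vector<double> theta(theta0.begin(), theta0.end());
    std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
    double t = t0;
    advance_to(sys, theta, t, t_target, dt, k1, k2, k3, k4, tmp);
    if (!kuranet_all_finite(theta.data(), n))
        stop("integration blow-up: non-finite state at t = %f", t);
    return NumericVector(theta.begin(), theta.end());
}
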