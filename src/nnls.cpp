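// Lawson-Hanson active-set non-negative least squares.
// Solves min ||A x - b||_2 subject to x >= 0.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".nnls_cpp")]]
Rcpp::List nnls_cpp(const arma::mat& A, const arma::vec& b,
                    const double tol_rel = 1e-10, const int max_iter = 0) {
    const uword n = A.n_cols;
    int itmax = max_iter > 0 ? max_iter : 3 * static_cast<int>(n);

    vec x(n, fill::zeros);
    std::vector<bool> passive(n, false);
    vec w = A.t() * (b - A * x);
    const double tol = tol_rel * std::max(1.0, norm(A.t() * b, "inf"));

    int outer = 0;
    while (outer++ < itmax) {
        // pick the most violated KKT multiplier among the zero set
        int t = -1;
        double wmax = tol;
        for (uword j = 0; j < n; ++j) {
            if (!passive[j] && w(j) > wmax) { wmax = w(j); t = static_cast<int>(j); }
        }
        if (t < 0) break;
        passive[t] = true;

        for (int inner = 0; inner < itmax * 2; ++inner) {
            uvec P(n);
            uword np = 0;
            for (uword j = 0; j < n; ++j) if (passive[j]) P(np++) = j;
            P.resize(np);

            vec z;
            bool ok = solve(z, A.cols(P), b);
            if (!ok) z = pinv(A.cols(P)) * b;

            if (z.min() > 0) {
                x.zeros();
                x.elem(P) = z;
                break;
            }
            // step back along (x -> z) to the first bound that is hit
            double alpha = datum::inf;
            for (uword k = 0; k < np; ++k) {
                if (z(k) <= 0) {
                    double xk = x(P(k));
                    double a = xk / (xk - z(k));
                    if (a < alpha) alpha = a;
                }
            }
            for (uword k = 0; k < np; ++k)
                x(P(k)) += alpha * (z(k) - x(P(k)));
            for (uword k = 0; k < np; ++k) {
                if (x(P(k)) <= tol) { x(P(k)) = 0.0; passive[P(k)] = false; }
            }
        }
        w = A.t() * (b - A * x);
    }

    return Rcpp::List::create(
        Rcpp::Named("x") = x,
        Rcpp::Named("resid_norm") = norm(b - A * x, 2));
}
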