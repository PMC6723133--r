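#include <Rcpp.h>

// Ma-Sandri-Sarkar recursion for the Lea-Coulson (Luria-Delbruck) pmf.
//   p_0 = exp(-m)
//   p_n = (m/n) * sum_{j=0}^{n-1} p_j / (n - j + 1)
// O(k_max^2); kept in C++ because the likelihood optimiser and the
// profile-CI bisections call it hundreds of times per experiment.
// [[Rcpp::export]]
Rcpp::NumericVector ld_pmf_cpp(double m, int k_max) {
    if (m < 0) Rcpp::stop("m must be non-negative");
    if (k_max < 0) Rcpp::stop("k_max must be non-negative");
    Rcpp::NumericVector p(k_max + 1);
    p[0] = std::exp(-m);
    for (int n = 1; n <= k_max; ++n) {
        double s = 0.0;
        for (int j = 0; j < n; ++j) {
            s += p[j] / (double)(n - j + 1);
        }
        p[n] = (m / (double)n) * s;
    }
    return p;
}
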