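#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh three-state DP).
//
// Gap run of length k costs gap_open + (k - 1) * gap_extend.
// States: M  (a[i] aligned to b[j])
//         X  (gap in b: a[i] against '-')
//         Y  (gap in a: b[j] against '-')
// Tie-break, both for the final state and for each predecessor choice:
// prefer M over X over Y.  This makes the backtrace fully deterministic.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".alignAffine")]]
List alignAffine(std::string a, std::string b,
                 NumericMatrix scores, std::string alpha,
                 double gap_open, double gap_extend) {
    const int n = a.size(), m = b.size();
    if (n == 0 || m == 0) stop("sequences must be non-empty");

    // residue -> row index of the substitution matrix
    std::vector<int> code(256, -1);
    for (int i = 0; i < (int) alpha.size(); ++i)
        code[(unsigned char) alpha[i]] = i;
    std::vector<int> ai(n), bj(m);
    for (int i = 0; i < n; ++i) {
        ai[i] = code[(unsigned char) a[i]];
        if (ai[i] < 0) stop("character '%s' not in substitution alphabet",
                            std::string(1, a[i]));
    }
    for (int j = 0; j < m; ++j) {
        bj[j] = code[(unsigned char) b[j]];
        if (bj[j] < 0) stop("character '%s' not in substitution alphabet",
                            std::string(1, b[j]));
    }

    const int W = m + 1;
    std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
        Y((n + 1) * W, NEG_INF);
    M[0] = 0.0;
    for (int i = 1; i <= n; ++i) X[i * W] = -gap_open - (i - 1) * gap_extend;
    for (int j = 1; j <= m; ++j) Y[j] = -gap_open - (j - 1) * gap_extend;

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const int c = i * W + j;
            const double s = scores(ai[i - 1], bj[j - 1]);
            const int d = (i - 1) * W + (j - 1);
            double best = M[d];
            if (X[d] > best) best = X[d];
            if (Y[d] > best) best = Y[d];
            M[c] = best + s;
            const int up = (i - 1) * W + j;
            X[c] = std::max(std::max(M[up] - gap_open, X[up] - gap_extend),
                            Y[up] - gap_open);
            const int lf = i * W + (j - 1);
            Y[c] = std::max(std::max(M[lf] - gap_open, Y[lf] - gap_extend),
                            X[lf] - gap_open);
        }
    }

    const int e = n * W + m;
    int state;  // 0 = M, 1 = X, 2 = Y
    double score;
    if (M[e] >= X[e] && M[e] >= Y[e]) { state = 0; score = M[e]; }
    else if (X[e] >= Y[e])            { state = 1; score = X[e]; }
    else                              { state = 2; score = Y[e]; }

    std::string ra, rb;
    ra.reserve(n + m); rb.reserve(n + m);
    int i = n, j = m;
    const double eps = 1e-9;
    while (i > 0 || j > 0) {
        if (i == 0) { state = 2; }
        else if (j == 0) { state = 1; }
        const int c = i * W + j;
        if (state == 0) {
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            const double s = scores(ai[i - 1], bj[j - 1]);
            const int d = (i - 1) * W + (j - 1);
            const double want = M[c] - s;
            if (std::abs(M[d] - want) < eps)      state = 0;
            else if (std::abs(X[d] - want) < eps) state = 1;
            else                                  state = 2;
            --i; --j;
        } else if (state == 1) {
            ra.push_back(a[i - 1]); rb.push_back('-');
            const int up = (i - 1) * W + j;
            if (std::abs(M[up] - gap_open - X[c]) < eps)        state = 0;
            else if (std::abs(X[up] - gap_extend - X[c]) < eps) state = 1;
            else                                                state = 2;
            --i;
        } else {
            ra.push_back('-'); rb.push_back(b[j - 1]);
            const int lf = i * W + (j - 1);
            if (std::abs(M[lf] - gap_open - Y[c]) < eps)        state = 0;
            else if (std::abs(Y[lf] - gap_extend - Y[c]) < eps) state = 2;
            else                                                state = 1;
            --j;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());

    return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}
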