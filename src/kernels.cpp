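#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Token-level Levenshtein distance: unit-cost insert/delete/substitute over
// whole tokens.
static int lev(const std::vector<std::string>& a,
               const std::vector<std::string>& b) {
    const size_t n = a.size(), m = b.size();
    std::vector<int> prev(m + 1), cur(m + 1);
    for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
    for (size_t i = 1; i <= n; ++i) {
        cur[0] = (int)i;
        for (size_t j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            int del = prev[j] + 1;
            int ins = cur[j - 1] + 1;
            cur[j] = std::min(sub, std::min(del, ins));
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

static std::vector<std::string> as_vec(const CharacterVector& x) {
    std::vector<std::string> out(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = std::string(x[i]);
    return out;
}

// [[Rcpp::export]]
int lev_dist_cpp(CharacterVector a, CharacterVector b) {
    return lev(as_vec(a), as_vec(b));
}

// Distance matrix between two lists of token sequences.
// [[Rcpp::export]]
IntegerMatrix lev_dist_matrix_cpp(List xs, List ys) {
    const R_xlen_t n = xs.size(), m = ys.size();
    std::vector<std::vector<std::string> > ax(n), ay(m);
    for (R_xlen_t i = 0; i < n; ++i) ax[i] = as_vec(xs[i]);
    for (R_xlen_t j = 0; j < m; ++j) ay[j] = as_vec(ys[j]);
    IntegerMatrix out(n, m);
    for (R_xlen_t i = 0; i < n; ++i)
        for (R_xlen_t j = 0; j < m; ++j)
            out(i, j) = lev(ax[i], ay[j]);
    return out;
}

// ---- Convolution (shared-subtree counting) tree kernel -------------------
//
// Trees arrive as node tables: labels plus 1-based parent ids (0 = root),
// nodes in preorder so children are encountered in order.  A fragment must
// contain entire productions; each production contributes a factor lambda,
// so a fragment with d productions is counted with weight lambda^d.

struct Tree {
    std::vector<std::string> label;
    std::vector<std::vector<int> > kids;  // 0-based child indices, in order
    std::vector<std::string> prod;        // production signature (non-leaves)
};

static Tree build_tree(const List& t) {
    CharacterVector lab = t["label"];
    IntegerVector parent = t["parent"];
    Tree tr;
    int n = lab.size();
    tr.label = as_vec(lab);
    tr.kids.assign(n, std::vector<int>());
    for (int i = 0; i < n; ++i) {
        int p = parent[i];
        if (p > 0) tr.kids[p - 1].push_back(i);
    }
    tr.prod.assign(n, "");
    for (int i = 0; i < n; ++i) {
        if (tr.kids[i].empty()) continue;
        std::string s = tr.label[i];
        s += " ->";
        for (size_t k = 0; k < tr.kids[i].size(); ++k) {
            s += " ";
            s += tr.label[tr.kids[i][k]];
        }
        tr.prod[i] = s;
    }
    return tr;
}

static double tk_pair(const Tree& a, const Tree& b, double lambda) {
    const int n = (int)a.label.size(), m = (int)b.label.size();
    std::vector<std::vector<double> > C(n, std::vector<double>(m, -1.0));
    // iterate in reverse preorder: children have larger indices than parents,
    // so compute from the back.
    for (int i = n - 1; i >= 0; --i) {
        for (int j = m - 1; j >= 0; --j) {
            if (a.kids[i].empty() || b.kids[j].empty() ||
                a.prod[i] != b.prod[j]) {
                C[i][j] = 0.0;
                continue;
            }
            double v = lambda;
            for (size_t k = 0; k < a.kids[i].size(); ++k) {
                int ci = a.kids[i][k], cj = b.kids[j][k];
                v *= (1.0 + C[ci][cj]);
            }
            C[i][j] = v;
        }
    }
    double K = 0.0;
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < m; ++j) K += C[i][j];
    return K;
}

// [[Rcpp::export]]
double tree_kernel_cpp(List t1, List t2, double lambda) {
    Tree a = build_tree(t1), b = build_tree(t2);
    return tk_pair(a, b, lambda);
}

// [[Rcpp::export]]
NumericMatrix tree_kernel_matrix_cpp(List trees1, List trees2, double lambda) {
    const R_xlen_t n = trees1.size(), m = trees2.size();
    std::vector<Tree> A(n), B(m);
    for (R_xlen_t i = 0; i < n; ++i) A[i] = build_tree(trees1[i]);
    for (R_xlen_t j = 0; j < m; ++j) B[j] = build_tree(trees2[j]);
    NumericMatrix out(n, m);
    for (R_xlen_t i = 0; i < n; ++i)
        for (R_xlen_t j = 0; j < m; ++j)
            out(i, j) = tk_pair(A[i], B[j], lambda);
    return out;
}
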