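#include <Rcpp.h>
using namespace Rcpp;

// Directed pair-link counts and "A cells with >= 1 B neighbor" counts for
// the observed labeling and for n_perm uniform label permutations.
//
// edges: m x 2 integer matrix, 1-based node indices (undirected, i < j)
// labels: length-n integer vector of type codes in 1..K
//
// Returns a list with
//   num:   (n_perm + 1) x K*K matrix, row r, column (a-1)*K + b =
//          number of directed a->b neighbor links (each undirected edge
//          contributes to both directions)
//   denom: same layout, number of cells of type a with at least one
//          neighbor of type b
// Row 1 is the observed labeling; rows 2.. are permutations. Permutations
// use R's RNG (Fisher-Yates with unif_rand), so set.seed() in R governs
// reproducibility.
// [[Rcpp::export]]
List perm_pair_counts(IntegerMatrix edges, IntegerVector labels, int K,
                      int n_perm) {
    const int n = labels.size();
    const int m = edges.nrow();
    const int KK = K * K;
    IntegerMatrix num(n_perm + 1, KK);
    IntegerMatrix denom(n_perm + 1, KK);

    std::vector<int> lab(n);
    for (int i = 0; i < n; ++i) lab[i] = labels[i] - 1;

    std::vector<int> e1(m), e2(m);
    for (int j = 0; j < m; ++j) {
        e1[j] = edges(j, 0) - 1;
        e2[j] = edges(j, 1) - 1;
    }

    std::vector<int> cellcnt((size_t) n * K);
    std::vector<int> paircnt(KK);

    RNGScope scope;
    for (int r = 0; r <= n_perm; ++r) {
        if (r > 0) {  // in-place Fisher-Yates shuffle of the label vector
            for (int i = n - 1; i > 0; --i) {
                int j = (int) (unif_rand() * (i + 1));
                if (j > i) j = i;
                std::swap(lab[i], lab[j]);
            }
        }
        std::fill(cellcnt.begin(), cellcnt.end(), 0);
        std::fill(paircnt.begin(), paircnt.end(), 0);
        for (int j = 0; j < m; ++j) {
            const int a = lab[e1[j]], b = lab[e2[j]];
            ++paircnt[a * K + b];
            ++paircnt[b * K + a];
            ++cellcnt[(size_t) e1[j] * K + b];
            ++cellcnt[(size_t) e2[j] * K + a];
        }
        for (int c = 0; c < KK; ++c) num(r, c) = paircnt[c];
        for (int i = 0; i < n; ++i) {
            const int a = lab[i];
            const size_t off = (size_t) i * K;
            for (int b = 0; b < K; ++b)
                if (cellcnt[off + b] > 0) ++denom(r, a * K + b);
        }
    }
    return List::create(_["num"] = num, _["denom"] = denom);
}
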