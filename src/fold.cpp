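#include <Rcpp.h>
#include <vector>
#include <string>
#include <array>
using namespace Rcpp;

// Secondary-structure DP under a stacked-pair energy model.
//
// A base pair contributes energy only when it is stacked directly inside an
// adjacent enclosing pair (i-1, j+1): -2 for G:C, -1 for A:U and G:U.
// Isolated pairs and loop-closing pairs contribute 0, so every score is <= 0
// and a perfect helix of k pairs scores the sum over its k-1 inner pairs.
// Minimum hairpin loop size is 3 unpaired bases; pseudoknots are excluded.
//
// Bases are encoded upstream as integers: A=0, C=1, G=2, U/T=3.

static const int INF = 1000000000;
static const int MINLOOP = 3;

static inline bool pairable(int a, int b, bool gu) {
    if (a > b) std::swap(a, b);
    if (a == 0 && b == 3) return true;           // A:U
    if (a == 1 && b == 2) return true;           // C:G
    if (gu && a == 2 && b == 3) return true;     // G:U
    return false;
}

static inline int pair_energy(int a, int b) {
    if (a > b) std::swap(a, b);
    if (a == 1 && b == 2) return -2;             // G:C stack
    return -1;                                   // A:U or G:U stack
}

struct FoldDP {
    int n;
    bool gu;
    const std::vector<int>& s;
    // E: best energy on [i,j]; C: best given (i,j) paired (its own stack
    // bonus, if any, is added by the enclosing context); F: best with i,j
    // not paired to each other.
    std::vector<int> E, C, F;
    FoldDP(const std::vector<int>& seq, bool allow_gu)
        : n((int)seq.size()), gu(allow_gu), s(seq),
          E((size_t)seq.size() * seq.size(), 0),
          C((size_t)seq.size() * seq.size(), INF),
          F((size_t)seq.size() * seq.size(), 0) {}
    inline size_t idx(int i, int j) const { return (size_t)i * n + j; }

    void fill() {
        for (int span = MINLOOP + 1; span < n; ++span) {
            for (int i = 0; i + span < n; ++i) {
                int j = i + span;
                // C(i,j)
                if (pairable(s[i], s[j], gu)) {
                    int best = 0; // empty interior (hairpin loop)
                    int fi = (j - 1) - (i + 1) >= 1 ? F[idx(i + 1, j - 1)] : 0;
                    if (fi < best) best = fi;
                    if ((j - 1) - (i + 1) > MINLOOP) {
                        int ci = C[idx(i + 1, j - 1)];
                        if (ci < INF) {
                            int v = ci + pair_energy(s[i + 1], s[j - 1]);
                            if (v < best) best = v;
                        }
                    }
                    C[idx(i, j)] = best;
                }
                // F(i,j): j unpaired, or j paired to k in (i, j-MINLOOP-1]
                int best = E[idx(i, j - 1)];
                for (int k = i + 1; k <= j - MINLOOP - 1; ++k) {
                    int ck = C[idx(k, j)];
                    if (ck >= INF) continue;
                    int left = (k - 1 >= i) ? E[idx(i, k - 1)] : 0;
                    if (left + ck < best) best = left + ck;
                }
                F[idx(i, j)] = best;
                int e = best;
                if (C[idx(i, j)] < e) e = C[idx(i, j)];
                E[idx(i, j)] = e;
            }
        }
    }

    void traceback(std::vector<int>& partner) {
        partner.assign(n, -1);
        if (n <= MINLOOP + 1) return;
        std::vector<std::array<int, 3>> stack; // {state, i, j}; 0=E,1=C,2=F
        stack.push_back({0, 0, n - 1});
        while (!stack.empty()) {
            auto fr = stack.back();
            stack.pop_back();
            int st = fr[0], i = fr[1], j = fr[2];
            if (j - i < MINLOOP + 1) continue;
            if (st == 0) {
                if (C[idx(i, j)] < INF && E[idx(i, j)] == C[idx(i, j)] &&
                    C[idx(i, j)] <= F[idx(i, j)])
                    stack.push_back({1, i, j});
                else
                    stack.push_back({2, i, j});
            } else if (st == 1) {
                partner[i] = j;
                partner[j] = i;
                int target = C[idx(i, j)];
                int ii = i + 1, jj = j - 1;
                bool done = false;
                if (jj - ii > MINLOOP && C[idx(ii, jj)] < INF &&
                    C[idx(ii, jj)] + pair_energy(s[ii], s[jj]) == target) {
                    stack.push_back({1, ii, jj});
                    done = true;
                }
                if (!done && jj - ii >= MINLOOP + 1 &&
                    F[idx(ii, jj)] == target) {
                    stack.push_back({2, ii, jj});
                    done = true;
                }
                // else: hairpin loop, nothing inside
            } else {
                int target = F[idx(i, j)];
                if (E[idx(i, j - 1)] == target) {
                    stack.push_back({0, i, j - 1});
                    continue;
                }
                for (int k = i + 1; k <= j - MINLOOP - 1; ++k) {
                    int ck = C[idx(k, j)];
                    if (ck >= INF) continue;
                    int left = (k - 1 >= i) ? E[idx(i, k - 1)] : 0;
                    if (left + ck == target) {
                        if (k - 1 >= i) stack.push_back({0, i, k - 1});
                        stack.push_back({1, k, j});
                        break;
                    }
                }
            }
        }
    }
};

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(IntegerVector seq_codes, bool allow_gu) {
    int n = seq_codes.size();
    if (n > 2000) stop("sequence longer than 2000 nt not supported");
    std::vector<int> s(seq_codes.begin(), seq_codes.end());
    for (int i = 0; i < n; ++i)
        if (s[i] < 0 || s[i] > 3)
            stop("invalid base code at position %d", i + 1);
    if (n <= MINLOOP + 1) {
        return List::create(_["mfe"] = 0.0,
                            _["structure"] = std::string((size_t)n, '.'),
                            _["partner"] = IntegerVector(n, 0));
    }
    FoldDP dp(s, allow_gu);
    dp.fill();
    std::vector<int> partner;
    dp.traceback(partner);
    std::string db((size_t)n, '.');
    IntegerVector pt(n, 0);
    for (int i = 0; i < n; ++i) {
        if (partner[i] >= 0) {
            db[i] = partner[i] > i ? '(' : ')';
            pt[i] = partner[i] + 1; // 1-based, 0 = unpaired
        }
    }
    return List::create(_["mfe"] = (double)dp.E[dp.idx(0, n - 1)],
                        _["structure"] = db, _["partner"] = pt);
}
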