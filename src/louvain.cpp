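#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Seeded Louvain maximization of weighted Newman modularity
//   Q = (1/2m) sum_ij [w_ij - gamma s_i s_j / (2m)] delta(c_i, c_j).
// A hand-rolled xorshift generator + Fisher-Yates keeps restart shuffles
// bit-identical across platforms (std::shuffle is implementation-defined).

namespace {

struct XorShift {
    uint64_t state;
    explicit XorShift(uint32_t seed) : state(seed ? seed : 0x9e3779b9u) {}
    uint64_t next() {
        state ^= state << 13;
        state ^= state >> 7;
        state ^= state << 17;
        return state;
    }
    int below(int n) { return static_cast<int>(next() % n); }
};

void fisher_yates(std::vector<int>& v, XorShift& rng) {
    for (int i = static_cast<int>(v.size()) - 1; i > 0; --i)
        std::swap(v[i], v[rng.below(i + 1)]);
}

// greedy local moving on the (aggregated) graph; diagonal = self-loops.
// init gives the starting membership (identity for a fresh level, the
// current partition for the refinement pass); nodes may also escape to an
// empty community when every merge has negative gain.
std::vector<int> local_move(const std::vector<double>& W, int n,
                            double gamma, double m2, XorShift& rng,
                            const std::vector<int>& init) {
    std::vector<double> s(n, 0.0), stot(n, 0.0);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) s[i] += W[i * n + j];
    std::vector<int> comm(init), order(n), csize(n, 0);
    for (int i = 0; i < n; ++i) {
        order[i] = i;
        stot[comm[i]] += s[i];
        ++csize[comm[i]];
    }
    std::vector<double> k_ic(n, 0.0);
    std::vector<int> touched;
    touched.reserve(n);
    bool improved = true;
    while (improved) {
        improved = false;
        fisher_yates(order, rng);
        for (int oi = 0; oi < n; ++oi) {
            const int i = order[oi];
            const int ci = comm[i];
            stot[ci] -= s[i];
            --csize[ci];
            touched.clear();
            k_ic[ci] = 0.0;
            touched.push_back(ci);
            for (int j = 0; j < n; ++j) {
                const double w = W[i * n + j];
                if (j == i || w <= 0.0) continue;
                const int cj = comm[j];
                if (k_ic[cj] == 0.0 && cj != ci) touched.push_back(cj);
                k_ic[cj] += w;
            }
            int best = ci;
            double best_gain = k_ic[ci] - gamma * s[i] * stot[ci] / m2;
            for (size_t t = 1; t < touched.size(); ++t) {
                const int c = touched[t];
                const double gain = k_ic[c] - gamma * s[i] * stot[c] / m2;
                if (gain > best_gain + 1e-12) {
                    best_gain = gain;
                    best = c;
                }
            }
            if (best_gain < -1e-12 && csize[ci] > 0) {
                // leaving for an empty community beats every merge
                for (int c = 0; c < n; ++c)
                    if (csize[c] == 0) { best = c; break; }
            }
            for (size_t t = 0; t < touched.size(); ++t)
                k_ic[touched[t]] = 0.0;
            if (best != ci) improved = true;
            comm[i] = best;
            stot[best] += s[i];
            ++csize[best];
        }
    }
    return comm;
}

std::vector<int> relabel(const std::vector<int>& comm, int& k) {
    std::vector<int> map(comm.size(), -1), out(comm.size());
    k = 0;
    for (size_t i = 0; i < comm.size(); ++i) {
        if (map[comm[i]] < 0) map[comm[i]] = k++;
        out[i] = map[comm[i]];
    }
    return out;
}

// random_init seeds the first level from a random partition instead of
// singletons: greedy merging from singletons always follows the strongest
// edges, which can never reach optima that cut a strong edge, so half the
// restarts explore from random starting partitions instead.
std::vector<int> louvain_once(const NumericMatrix& W0, double gamma,
                              XorShift& rng, bool random_init) {
    const int n0 = W0.nrow();
    double m2 = 0.0;
    std::vector<double> cur(n0 * n0);
    for (int i = 0; i < n0; ++i)
        for (int j = 0; j < n0; ++j) {
            cur[i * n0 + j] = W0(i, j);
            m2 += W0(i, j);
        }
    std::vector<int> node_comm(n0), init;
    for (int i = 0; i < n0; ++i) node_comm[i] = i;
    int n = n0;
    bool first_level = true;
    while (true) {
        init.resize(n);
        for (int i = 0; i < n; ++i) init[i] = i;
        if (first_level && random_init) {
            const int k0 = 2 + rng.below(std::max(1, n / 2));
            for (int i = 0; i < n; ++i) init[i] = rng.below(k0);
            first_level = false;
        }
        std::vector<int> memb = local_move(cur, n, gamma, m2, rng, init);
        int k = 0;
        memb = relabel(memb, k);
        for (int i = 0; i < n0; ++i) node_comm[i] = memb[node_comm[i]];
        if (k == n) break;
        std::vector<double> agg(k * k, 0.0);
        for (int i = 0; i < n; ++i)
            for (int j = 0; j < n; ++j)
                agg[memb[i] * k + memb[j]] += cur[i * n + j];
        cur = agg;
        n = k;
    }
    // refinement: single-node moves on the original graph can correct
    // merges the aggregation hierarchy cannot undo
    std::vector<double> flat(n0 * n0);
    for (int i = 0; i < n0; ++i)
        for (int j = 0; j < n0; ++j) flat[i * n0 + j] = W0(i, j);
    node_comm = local_move(flat, n0, gamma, m2, rng, node_comm);
    int k = 0;
    return relabel(node_comm, k);
}

double modularity_q(const NumericMatrix& W, const std::vector<int>& comm,
                    double gamma) {
    const int n = W.nrow();
    double m2 = 0.0;
    std::vector<double> s(n, 0.0);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
            s[i] += W(i, j);
            m2 += W(i, j);
        }
    double q = 0.0;
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            if (comm[i] == comm[j])
                q += W(i, j) - gamma * s[i] * s[j] / m2;
    return q / m2;
}

}  // namespace

// [[Rcpp::export]]
List cpp_louvain(NumericMatrix W, double gamma, IntegerVector seeds) {
    std::vector<int> best;
    double best_q = R_NegInf;
    for (int r = 0; r < seeds.size(); ++r) {
        XorShift rng(static_cast<uint32_t>(seeds[r]));
        std::vector<int> memb = louvain_once(W, gamma, rng, r % 2 == 1);
        const double q = modularity_q(W, memb, gamma);
        if (q > best_q + 1e-12) {
            best_q = q;
            best = memb;
        }
    }
    IntegerVector membership(best.size());
    for (size_t i = 0; i < best.size(); ++i) membership[i] = best[i] + 1;
    return List::create(Named("membership") = membership,
                        Named("Q") = best_q);
}
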