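#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest paths over edge lengths 1/w (an edge exists iff
// w > 0). Plain O(n^2) Dijkstra per source; n here is a parcel count
// (tens of nodes), so the simple selection loop beats heap overhead.
// Unreachable pairs come back as +Inf.
// [[Rcpp::export]]
NumericMatrix cpp_shortest_paths(NumericMatrix W) {
    const int n = W.nrow();
    NumericMatrix D(n, n);
    std::vector<double> dist(n);
    std::vector<bool> done(n);
    for (int s = 0; s < n; ++s) {
        std::fill(dist.begin(), dist.end(), R_PosInf);
        std::fill(done.begin(), done.end(), false);
        dist[s] = 0.0;
        for (int iter = 0; iter < n; ++iter) {
            int u = -1;
            double best = R_PosInf;
            for (int v = 0; v < n; ++v)
                if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
            if (u < 0) break;
            done[u] = true;
            for (int v = 0; v < n; ++v) {
                const double w = W(u, v);
                if (v != u && w > 0.0) {
                    const double nd = dist[u] + 1.0 / w;
                    if (nd < dist[v]) dist[v] = nd;
                }
            }
        }
        for (int v = 0; v < n; ++v) D(s, v) = dist[v];
        D(s, s) = 0.0;
    }
    return D;
}

// Local efficiency: for each node, the global efficiency of the weighted
// subgraph induced on its neighbors (0 when fewer than 2 neighbors).
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(NumericMatrix W) {
    const int n = W.nrow();
    NumericVector out(n);
    std::vector<int> nb;
    nb.reserve(n);
    std::vector<double> sub, dist;
    std::vector<bool> done;
    for (int i = 0; i < n; ++i) {
        nb.clear();
        for (int j = 0; j < n; ++j)
            if (j != i && W(i, j) > 0.0) nb.push_back(j);
        const int k = static_cast<int>(nb.size());
        if (k < 2) { out[i] = 0.0; continue; }
        sub.assign(k * k, 0.0);
        for (int a = 0; a < k; ++a)
            for (int b = 0; b < k; ++b)
                sub[a * k + b] = W(nb[a], nb[b]);
        dist.assign(k, 0.0);
        done.assign(k, false);
        double inv_sum = 0.0;
        for (int s = 0; s < k; ++s) {
            std::fill(dist.begin(), dist.end(), R_PosInf);
            std::fill(done.begin(), done.end(), false);
            dist[s] = 0.0;
            for (int iter = 0; iter < k; ++iter) {
                int u = -1;
                double best = R_PosInf;
                for (int v = 0; v < k; ++v)
                    if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
                if (u < 0) break;
                done[u] = true;
                for (int v = 0; v < k; ++v) {
                    const double w = sub[u * k + v];
                    if (v != u && w > 0.0) {
                        const double nd = dist[u] + 1.0 / w;
                        if (nd < dist[v]) dist[v] = nd;
                    }
                }
            }
            for (int v = 0; v < k; ++v)
                if (v != s && dist[v] < R_PosInf) inv_sum += 1.0 / dist[v];
        }
        out[i] = inv_sum / (static_cast<double>(k) * (k - 1));
    }
    return out;
}
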