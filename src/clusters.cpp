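#include <Rcpp.h>
using namespace Rcpp;

// Connected components over a channel x time grid: two samples are
// neighbours if they share the channel and are consecutive in time, or
// share the time index and their channels are spatially adjacent.
// For each row of `tmaps` (a flattened map, channel-major: index =
// ch + nchan * t) return the largest positive and most negative cluster
// masses of suprathreshold samples.  Used inside the permutation loop.

// [[Rcpp::export]]
NumericMatrix perm_cluster_extremes(NumericMatrix tmaps, int nchan, int ntime,
                                    LogicalMatrix adj, double thr) {
  int nperm = tmaps.nrow();
  int S = nchan * ntime;
  NumericMatrix out(nperm, 2);
  std::vector<int> stack(S);
  std::vector<char> visited(S);
  // adjacency lists per channel
  std::vector<std::vector<int>> nb(nchan);
  for (int c = 0; c < nchan; ++c)
    for (int d = 0; d < nchan; ++d)
      if (c != d && adj(c, d)) nb[c].push_back(d);

  for (int p = 0; p < nperm; ++p) {
    double maxpos = 0.0, minneg = 0.0;
    std::fill(visited.begin(), visited.end(), 0);
    for (int s0 = 0; s0 < S; ++s0) {
      double v0 = tmaps(p, s0);
      if (visited[s0] || !(v0 > thr || v0 < -thr)) continue;
      bool pos = v0 > 0;
      double mass = 0.0;
      int top = 0;
      stack[top++] = s0;
      visited[s0] = 1;
      while (top > 0) {
        int s = stack[--top];
        mass += tmaps(p, s);
        int c = s % nchan, t = s / nchan;
        // temporal neighbours
        for (int dt = -1; dt <= 1; dt += 2) {
          int t2 = t + dt;
          if (t2 < 0 || t2 >= ntime) continue;
          int s2 = c + nchan * t2;
          double v = tmaps(p, s2);
          if (!visited[s2] && ((pos && v > thr) || (!pos && v < -thr))) {
            visited[s2] = 1;
            stack[top++] = s2;
          }
        }
        // spatial neighbours
        for (size_t k = 0; k < nb[c].size(); ++k) {
          int s2 = nb[c][k] + nchan * t;
          double v = tmaps(p, s2);
          if (!visited[s2] && ((pos && v > thr) || (!pos && v < -thr))) {
            visited[s2] = 1;
            stack[top++] = s2;
          }
        }
      }
      if (pos && mass > maxpos) maxpos = mass;
      if (!pos && mass < minneg) minneg = mass;
    }
    out(p, 0) = maxpos;
    out(p, 1) = minneg;
  }
  return out;
}
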