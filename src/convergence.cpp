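#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Maximum-likelihood ancestral states under Brownian motion, by Gaussian
// belief propagation on the tree (equivalent to the GLS reconstruction).
// Edges must be in ape "postorder" order; node numbering follows ape:
// tips 1..ntip, root ntip+1. Returns states for all ntip+nnode nodes.
static void asr_bm_core(const IntegerMatrix &edge, const NumericVector &elen,
                        int ntip, int nnode, const double *x,
                        std::vector<double> &state) {
  const int ntot = ntip + nnode;
  const int ne = edge.nrow();
  std::vector<double> m(ntot), v(ntot), sw(ntot, 0.0), swm(ntot, 0.0);
  std::vector<double> dmean(ntot, 0.0), dvar(ntot, -1.0); // -1 = no message
  for (int i = 0; i < ntip; ++i) { m[i] = x[i]; v[i] = 0.0; }

  // upward pass (postorder: child messages ready before parent edge)
  for (int e = 0; e < ne; ++e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    if (c >= ntip) { v[c] = 1.0 / sw[c]; m[c] = swm[c] / sw[c]; }
    double w = 1.0 / (v[c] + elen[e]);
    sw[p] += w;
    swm[p] += w * m[c];
  }
  int root = ntip; // ape convention
  v[root] = 1.0 / sw[root];
  m[root] = swm[root] / sw[root];

  // downward pass (reverse postorder = preorder)
  for (int e = ne - 1; e >= 0; --e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    double wc = 1.0 / (v[c] + elen[e]);
    double gx = sw[p] - wc, hx = swm[p] - wc * m[c];
    if (dvar[p] >= 0.0) { // parent has a downward message
      gx += 1.0 / dvar[p];
      hx += dmean[p] / dvar[p];
    }
    // gx > 0 except for a root with a single child, which ape forbids
    dmean[c] = hx / gx;
    dvar[c] = 1.0 / gx + elen[e];
  }

  for (int i = 0; i < ntip; ++i) state[i] = x[i];
  state[root] = m[root];
  for (int i = ntip; i < ntot; ++i) {
    if (i == root) continue;
    double a = 1.0 / v[i], b = 1.0 / dvar[i];
    state[i] = (a * m[i] + b * dmean[i]) / (a + b);
  }
}

// [[Rcpp::export]]
NumericVector cpp_asr_bm(IntegerMatrix edge, NumericVector elen, int ntip,
                         int nnode, NumericVector x) {
  std::vector<double> state(ntip + nnode);
  asr_bm_core(edge, elen, ntip, nnode, REAL(x), state);
  return NumericVector(state.begin(), state.end());
}

// C1 pair decomposition. paths is a flattened encoding of the focal pairs:
// for pair q, nodes path_nodes[path_start[2q] .. path_start[2q+1]-1] run from
// tip i back to (and including) the MRCA, and the next slot holds tip j's
// path. Node indices are 1-based. Returns a matrix with columns Dtip, Dmax.
static void c1_pairs_core(const std::vector<double> &state,
                          const IntegerVector &path_nodes,
                          const IntegerVector &path_start, int npair,
                          double *dtip, double *dmax) {
  for (int q = 0; q < npair; ++q) {
    int a0 = path_start[2 * q] - 1, a1 = path_start[2 * q + 1] - 1;
    int b0 = a1, b1 = path_start[2 * q + 2] - 1;
    double dt = std::fabs(state[path_nodes[a0] - 1] - state[path_nodes[b0] - 1]);
    double dm = 0.0;
    for (int ia = a0; ia < a1; ++ia) {
      double su = state[path_nodes[ia] - 1];
      for (int ib = b0; ib < b1; ++ib) {
        double d = std::fabs(su - state[path_nodes[ib] - 1]);
        if (d > dm) dm = d;
      }
    }
    dtip[q] = dt;
    dmax[q] = dm;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_c1_pairs(NumericVector state, IntegerVector path_nodes,
                           IntegerVector path_start, int npair) {
  std::vector<double> st(state.begin(), state.end());
  NumericMatrix out(npair, 2);
  std::vector<double> dt(npair), dm(npair);
  c1_pairs_core(st, path_nodes, path_start, npair, dt.data(), dm.data());
  for (int q = 0; q < npair; ++q) { out(q, 0) = dt[q]; out(q, 1) = dm[q]; }
  return out;
}

// Batch C1 over simulated tip-trait replicates (columns of xmat); used by the
// simulation null. Returns one C1 per replicate, NA when sum(Dmax) == 0.
// [[Rcpp::export]]
NumericVector cpp_c1_batch(IntegerMatrix edge, NumericVector elen, int ntip,
                           int nnode, NumericMatrix xmat,
                           IntegerVector path_nodes, IntegerVector path_start,
                           int npair) {
  const int nsim = xmat.ncol();
  NumericVector out(nsim);
  std::vector<double> state(ntip + nnode), dt(npair), dm(npair);
  for (int s = 0; s < nsim; ++s) {
    asr_bm_core(edge, elen, ntip, nnode, &xmat(0, s), state);
    c1_pairs_core(state, path_nodes, path_start, npair, dt.data(), dm.data());
    double st = 0.0, sm = 0.0;
    for (int q = 0; q < npair; ++q) { st += dt[q]; sm += dm[q]; }
    out[s] = (sm > 0.0) ? 1.0 - st / sm : NA_REAL;
  }
  return out;
}
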