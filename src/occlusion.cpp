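#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Batched evaluation of a node's output logits under row-i input deltas.
//
// For a 2-layer GCN, perturbing only row i of X changes the hidden state
// H1[j,] = relu(B[j,] + At[j,i] * (delta %*% W0)) exactly for the
// neighbors j of i (At is symmetric), and the node's logits are
//   b1 + W1' * sum_j At[i,j] * H1[j,].
// Bn holds the unperturbed pre-activations B[j,] for the neighbor rows,
// a the (positive) edge weights At[i,j], and D the per-evaluation
// delta %*% W0 matrix.  Returns an M x C matrix of logits.
//
// The accumulator sum_j a_j * relu(B_jh + a_j * d) is piecewise linear
// in d with breakpoints t_j = -B_jh / a_j: neighbor j is active iff
// d > t_j.  Sorting the breakpoints once per hidden component and
// storing suffix sums of a_j * B_jh and a_j^2 reduces each evaluation
// from O(nb) to O(log nb), which matters on dense population graphs.
// [[Rcpp::export(name = ".occl_logits")]]
NumericMatrix occl_logits(const NumericMatrix& Bn, const NumericVector& a,
                          const NumericMatrix& D, const NumericMatrix& W1,
                          const NumericVector& b1) {
  const int nb = Bn.nrow(), H = Bn.ncol(), M = D.nrow(), C = W1.ncol();
  if (a.size() != nb) stop("weight vector does not match neighbor count");
  if (D.ncol() != H || W1.nrow() != H || b1.size() != C)
    stop("inconsistent kernel dimensions");

  // per hidden component: breakpoints sorted ascending plus suffix sums
  // s1[k] = sum_{j >= k} a_j * B_jh, s2[k] = sum_{j >= k} a_j^2 over the
  // sorted order (neighbors active for large d sit at the low end)
  std::vector<double> thr(static_cast<size_t>(H) * nb);
  std::vector<double> s1(static_cast<size_t>(H) * (nb + 1));
  std::vector<double> s2(static_cast<size_t>(H) * (nb + 1));
  std::vector<std::pair<double, int> > ord(nb);
  for (int h = 0; h < H; ++h) {
    for (int j = 0; j < nb; ++j)
      ord[j] = std::make_pair(-Bn(j, h) / a[j], j);
    std::sort(ord.begin(), ord.end());
    double* th = &thr[static_cast<size_t>(h) * nb];
    double* sh1 = &s1[static_cast<size_t>(h) * (nb + 1)];
    double* sh2 = &s2[static_cast<size_t>(h) * (nb + 1)];
    sh1[nb] = 0.0; sh2[nb] = 0.0;
    for (int k = nb - 1; k >= 0; --k) {
      const int j = ord[k].second;
      th[k] = ord[k].first;
      sh1[k] = sh1[k + 1] + a[j] * Bn(j, h);
      sh2[k] = sh2[k + 1] + a[j] * a[j];
    }
  }

  NumericMatrix out(M, C);
  std::vector<double> acc(H);
  for (int m = 0; m < M; ++m) {
    for (int h = 0; h < H; ++h) {
      const double d = D(m, h);
      const double* th = &thr[static_cast<size_t>(h) * nb];
      // active set: strictly positive pre-activation, i.e. d > t_j
      const int k = static_cast<int>(
        std::upper_bound(th, th + nb, d) - th) - 1;
      const int from = k + 1 <= nb ? (k + 1) : nb;
      // neighbors with t_j <= d come first; active ones are those with
      // t_j < d -- ties at exactly zero pre-activation contribute zero
      const double* sh1 = &s1[static_cast<size_t>(h) * (nb + 1)];
      const double* sh2 = &s2[static_cast<size_t>(h) * (nb + 1)];
      // suffix over sorted order holds INACTIVE tail; active prefix is
      // total minus suffix
      acc[h] = (sh1[0] - sh1[from]) + d * (sh2[0] - sh2[from]);
    }
    for (int c = 0; c < C; ++c) {
      double s = b1[c];
      for (int h = 0; h < H; ++h) s += acc[h] * W1(h, c);
      out(m, c) = s;
    }
  }
  return out;
}
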