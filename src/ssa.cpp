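#include <Rcpp.h>
using namespace Rcpp;

// One Gillespie (direct-method) trajectory of a single molecule on a small
// CTMC. Q holds transition rates (off-diagonal entries only are read);
// `state` and `absorb` are 0-based indices. Returns the occupation time of
// every state before absorption. Uses R's RNG so set.seed() controls it.
static void one_trajectory(const NumericMatrix& Q, int state, int absorb,
                           double* occ) {
  const int n = Q.nrow();
  const long max_events = 500000000L;  // hard guard against runaway chains
  for (long ev = 0; ev < max_events; ++ev) {
    if (state == absorb) return;
    double lam = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != state) lam += Q(state, j);
    if (!(lam > 0.0)) stop("state with no outgoing transitions reached");
    double u1 = unif_rand();
    // guard against log(0)
    while (u1 <= 0.0) u1 = unif_rand();
    occ[state] += -std::log(u1) / lam;
    double u2 = unif_rand() * lam;
    double cum = 0.0;
    int nxt = absorb;
    for (int j = 0; j < n; ++j) {
      if (j == state) continue;
      cum += Q(state, j);
      if (u2 <= cum) { nxt = j; break; }
    }
    state = nxt;
  }
  stop("trajectory exceeded the maximum event count");
}

// [[Rcpp::export]]
NumericVector ssa_trajectory_cpp(NumericMatrix Q, int init, int absorb) {
  NumericVector occ(Q.nrow());
  RNGScope scope;
  one_trajectory(Q, init, absorb, REAL(occ));
  return occ;
}

// Batch of replicates. `seq_idx` optionally names two transitions (4 values,
// 0-based: from1,to1,from2,to2) whose rates are replaced per replicate by
// the rows of `seq_rates` (n_reps x 2), used to propagate sampled
// sequential-binding rate pairs through AP-junction replicates. Pass
// seq_idx of length 0 to disable.
// [[Rcpp::export]]
NumericMatrix ssa_batch_cpp(NumericMatrix Q, int init, int absorb, int n_reps,
                            IntegerVector seq_idx, NumericMatrix seq_rates) {
  const int n = Q.nrow();
  NumericMatrix occ(n_reps, n);
  NumericMatrix Qr(clone(Q));
  const bool resample = seq_idx.size() == 4;
  if (resample && seq_rates.nrow() != n_reps)
    stop("seq_rates must have one row per replicate");
  RNGScope scope;
  std::vector<double> buf(n);
  for (int r = 0; r < n_reps; ++r) {
    if (resample) {
      Qr(seq_idx[0], seq_idx[1]) = seq_rates(r, 0);
      Qr(seq_idx[2], seq_idx[3]) = seq_rates(r, 1);
    }
    std::fill(buf.begin(), buf.end(), 0.0);
    one_trajectory(Qr, init, absorb, buf.data());
    for (int j = 0; j < n; ++j) occ(r, j) = buf[j];
  }
  return occ;
}
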