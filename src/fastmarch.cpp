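#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <tuple>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Upwind fast marching on the 6-neighbourhood with physical spacings (mm).
// Solves |grad T| * F = 1 from one seed voxel, with one-sided second-order
// differences where the stencil allows (first-order fallback).  Heap ties
// are broken by insertion order so results are fully deterministic.

namespace {

struct HeapEntry {
  double t;
  unsigned long order;
  int idx;
};
struct HeapCmp {
  bool operator()(const HeapEntry &a, const HeapEntry &b) const {
    if (a.t != b.t) return a.t > b.t;       // min-heap on time
    return a.order > b.order;               // FIFO tie-break
  }
};

class Marcher {
public:
  Marcher(const double *speed, const int *dim, const double *spacing,
          int order = 2)
      : f_(speed), spacing_(spacing), order_scheme_(order) {
    nx_ = dim[0]; ny_ = dim[1]; nz_ = dim[2];
    n_ = static_cast<long>(nx_) * ny_ * nz_;
    time_.assign(n_, std::numeric_limits<double>::infinity());
    state_.assign(n_, 0);  // 0 far, 1 trial, 2 accepted
    order_ = 0;
  }

  void seed(int idx) {
    time_[idx] = 0.0;
    state_[idx] = 1;
    heap_.push({0.0, order_++, idx});
  }

  // Exact initialisation of a small ball around the seed (source
  // factorisation): the first-order upwind scheme has O(1) relative error
  // next to a point source, so voxels within `radius` (in units of the
  // smallest spacing) are initialised with the analytic distance times the
  // slowness at the seed.
  void seedBall(int idx, double radius) {
    int si, sj, sk;
    coords(idx, si, sj, sk);
    const double slowness = 1.0 / f_[idx];
    const double rmm = radius * std::min(spacing_[0],
                          std::min(spacing_[1], spacing_[2]));
    const int ri = static_cast<int>(std::ceil(rmm / spacing_[0]));
    const int rj = static_cast<int>(std::ceil(rmm / spacing_[1]));
    const int rk = static_cast<int>(std::ceil(rmm / spacing_[2]));
    std::vector<int> ball;
    for (int k = sk - rk; k <= sk + rk; ++k) {
      if (k < 0 || k >= nz_) continue;
      for (int j = sj - rj; j <= sj + rj; ++j) {
        if (j < 0 || j >= ny_) continue;
        for (int i = si - ri; i <= si + ri; ++i) {
          if (i < 0 || i >= nx_) continue;
          const double dx = (i - si) * spacing_[0];
          const double dy = (j - sj) * spacing_[1];
          const double dz = (k - sk) * spacing_[2];
          const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d > rmm) continue;
          const int nidx = i + nx_ * (j + static_cast<long>(ny_) * k);
          const double t = d * slowness;
          if (t < time_[nidx]) {
            // frozen: exact values must never be overwritten by the scheme
            time_[nidx] = t;
            state_[nidx] = 2;
            ball.push_back(nidx);
          }
        }
      }
    }
    for (size_t b = 0; b < ball.size(); ++b) relaxNeighbours(ball[b]);
  }

  // Pop-accept one voxel; returns accepted index or -1 when exhausted.
  int step() {
    while (!heap_.empty()) {
      HeapEntry e = heap_.top();
      heap_.pop();
      if (state_[e.idx] == 2 || e.t != time_[e.idx]) continue;  // stale
      state_[e.idx] = 2;
      relaxNeighbours(e.idx);
      return e.idx;
    }
    return -1;
  }

  double peek() const {
    // smallest non-stale tentative time (heap top may be stale; good enough
    // as a lower bound since stale entries are >= live ones)
    return heap_.empty() ? std::numeric_limits<double>::infinity()
                         : heap_.top().t;
  }

  const std::vector<double> &times() const { return time_; }
  const std::vector<unsigned char> &states() const { return state_; }

private:
  void coords(int idx, int &i, int &j, int &k) const {
    i = idx % nx_;
    j = (idx / nx_) % ny_;
    k = idx / (nx_ * ny_);
  }

  // Solve the upwind quadratic at voxel (i,j,k) from accepted neighbours.
  // With order 2, axes with two accepted in-line upwind neighbours
  // (T2 <= T1, the usual causality condition) use the one-sided
  // second-order difference (3T - 4T1 + T2)/(2h); other axes, and the
  // whole update when the second-order discriminant fails, fall back to
  // first order.
  double solve(int i, int j, int k) const {
    const int idx = i + nx_ * (j + static_cast<long>(ny_) * k);
    double a1[3];      // first-order upwind value per included axis
    double alpha[3];   // gradient coefficient of T
    double beta[3];    // gradient constant term
    int m = 0;
    bool any_second = false;
    for (int ax = 0; ax < 3; ++ax) {
      double best = std::numeric_limits<double>::infinity();
      double second = std::numeric_limits<double>::infinity();
      for (int s = -1; s <= 1; s += 2) {
        int ci = i, cj = j, ck = k;
        if (ax == 0) ci += s;
        if (ax == 1) cj += s;
        if (ax == 2) ck += s;
        if (ci < 0 || ci >= nx_ || cj < 0 || cj >= ny_ || ck < 0 || ck >= nz_)
          continue;
        const int nidx = ci + nx_ * (cj + static_cast<long>(ny_) * ck);
        if (state_[nidx] != 2 || time_[nidx] >= best) continue;
        best = time_[nidx];
        second = std::numeric_limits<double>::infinity();
        if (order_scheme_ >= 2) {
          int c2i = ci + (ci - i), c2j = cj + (cj - j), c2k = ck + (ck - k);
          if (c2i >= 0 && c2i < nx_ && c2j >= 0 && c2j < ny_ &&
              c2k >= 0 && c2k < nz_) {
            const int n2 = c2i + nx_ * (c2j + static_cast<long>(ny_) * c2k);
            if (state_[n2] == 2 && time_[n2] <= time_[nidx])
              second = time_[n2];
          }
        }
      }
      if (!std::isfinite(best)) continue;
      const double h = spacing_[ax];
      a1[m] = best;
      if (std::isfinite(second)) {
        alpha[m] = 1.5 / h;
        beta[m] = (2.0 * best - 0.5 * second) / h;
        any_second = true;
      } else {
        alpha[m] = 1.0 / h;
        beta[m] = best / h;
      }
      ++m;
    }
    if (m == 0) return std::numeric_limits<double>::infinity();
    const double finv = 1.0 / f_[idx];
    double t = solveQuadratic(m, a1, alpha, beta, finv);
    if (!std::isfinite(t) && any_second) {
      // second-order stencil inconsistent here: redo all-first-order
      int mm = 0;
      for (int ax = 0; ax < 3; ++ax) {
        double best = std::numeric_limits<double>::infinity();
        for (int s = -1; s <= 1; s += 2) {
          int ci = i, cj = j, ck = k;
          if (ax == 0) ci += s;
          if (ax == 1) cj += s;
          if (ax == 2) ck += s;
          if (ci < 0 || ci >= nx_ || cj < 0 || cj >= ny_ || ck < 0 || ck >= nz_)
            continue;
          const int nidx = ci + nx_ * (cj + static_cast<long>(ny_) * ck);
          if (state_[nidx] == 2 && time_[nidx] < best) best = time_[nidx];
        }
        if (!std::isfinite(best)) continue;
        a1[mm] = best;
        alpha[mm] = 1.0 / spacing_[ax];
        beta[mm] = best / spacing_[ax];
        ++mm;
      }
      t = solveQuadratic(mm, a1, alpha, beta, finv);
    }
    return t;
  }

  // Solve sum_d (alpha_d T - beta_d)^2 = finv^2 over the causal subset of
  // axes (included while T exceeds the axis' upwind value), taking the
  // larger root. Returns +inf when no causal solution exists.
  double solveQuadratic(int m, const double *a1, const double *alpha,
                        const double *beta, double finv) const {
    // sort axes by upwind value ascending (m <= 3: bubble)
    int ord[3] = {0, 1, 2};
    for (int x = 0; x < m - 1; ++x)
      for (int y = 0; y < m - 1 - x; ++y)
        if (a1[ord[y]] > a1[ord[y + 1]]) std::swap(ord[y], ord[y + 1]);
    double t = std::numeric_limits<double>::infinity();
    for (int take = 1; take <= m; ++take) {
      double A = 0, B = 0, C = -finv * finv;
      for (int d = 0; d < take; ++d) {
        const int o = ord[d];
        A += alpha[o] * alpha[o];
        B -= 2.0 * alpha[o] * beta[o];
        C += beta[o] * beta[o];
      }
      const double disc = B * B - 4 * A * C;
      if (disc < 0) {
        if (take == 1) return std::numeric_limits<double>::infinity();
        break;  // keep the previous (smaller-subset) solution
      }
      const double cand = (-B + std::sqrt(disc)) / (2 * A);
      // causality: candidate must not precede any included upwind value
      if (cand < a1[ord[take - 1]] && take > 1) break;
      t = cand;
      if (take < m && t <= a1[ord[take]]) break;  // further axes not causal
    }
    return t;
  }

  void relaxNeighbours(int idx) {
    int i, j, k;
    coords(idx, i, j, k);
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int d = 0; d < 6; ++d) {
      const int ci = i + di[d], cj = j + dj[d], ck = k + dk[d];
      if (ci < 0 || ci >= nx_ || cj < 0 || cj >= ny_ || ck < 0 || ck >= nz_)
        continue;
      const int nidx = ci + nx_ * (cj + static_cast<long>(ny_) * ck);
      if (state_[nidx] == 2) continue;
      const double t = solve(ci, cj, ck);
      if (t < time_[nidx]) {
        time_[nidx] = t;
        state_[nidx] = 1;
        heap_.push({t, order_++, nidx});
      }
    }
  }

  const double *f_;
  const double *spacing_;
  int order_scheme_;
  int nx_, ny_, nz_;
  long n_;
  std::vector<double> time_;
  std::vector<unsigned char> state_;
  std::priority_queue<HeapEntry, std::vector<HeapEntry>, HeapCmp> heap_;
  unsigned long order_;
};

int checkedIndex(const IntegerVector &seed, const IntegerVector &dim) {
  if (seed.size() != 3) stop("seed must have three voxel indices");
  for (int d = 0; d < 3; ++d)
    if (seed[d] < 0 || seed[d] >= dim[d]) stop("seed voxel outside grid");
  return seed[0] + dim[0] * (seed[1] + static_cast<long>(dim[1]) * seed[2]);
}

}  // namespace

// Full single-source solve: arrival time at every voxel.
// [[Rcpp::export]]
NumericVector fm_arrival_cpp(NumericVector speed, IntegerVector dim,
                             NumericVector spacing, IntegerVector seed,
                             double source_ball = 6.0, int order = 2) {
  if (dim.size() != 3 || spacing.size() != 3) stop("dim/spacing must be 3-vectors");
  Marcher m(REAL(speed), INTEGER(dim), REAL(spacing), order);
  const int s0 = checkedIndex(seed, dim);
  m.seed(s0);
  if (source_ball > 0) m.seedBall(s0, source_ball);
  while (m.step() >= 0) {
  }
  NumericVector out(speed.size());
  const std::vector<double> &t = m.times();
  std::copy(t.begin(), t.end(), out.begin());
  return out;
}

// Bidirectional solve: alternate front expansions until one voxel has been
// accepted by both fronts, then report both arrival maps, acceptance masks
// and the meeting voxel minimising T1 + T2 over the doubly-accepted set.
// [[Rcpp::export]]
List fm_bidirectional_cpp(NumericVector speed, IntegerVector dim,
                          NumericVector spacing, IntegerVector seed1,
                          IntegerVector seed2, double source_ball = 6.0,
                          int order = 2) {
  if (dim.size() != 3 || spacing.size() != 3) stop("dim/spacing must be 3-vectors");
  Marcher m1(REAL(speed), INTEGER(dim), REAL(spacing), order);
  Marcher m2(REAL(speed), INTEGER(dim), REAL(spacing), order);
  const int s1 = checkedIndex(seed1, dim);
  const int s2 = checkedIndex(seed2, dim);
  if (s1 == s2) stop("start and end seeds map to the same voxel");
  m1.seed(s1);
  m2.seed(s2);
  if (source_ball > 0) { m1.seedBall(s1, source_ball); m2.seedBall(s2, source_ball); }
  // alternate front expansions; once the fronts first meet, continue until
  // no remaining tentative pair can beat the best meeting sum (standard
  // bidirectional termination), so the meeting voxel is the true argmin of
  // T1 + T2 over the doubly-accepted set.
  bool met = false;
  double best_meet = std::numeric_limits<double>::infinity();
  double slack = 0.0;
  const double minsp = std::min(spacing[0], std::min(spacing[1], spacing[2]));
  while (true) {
    const bool take1 = m1.peek() <= m2.peek();
    const int idx = take1 ? m1.step() : m2.step();
    if (idx < 0) {
      if ((take1 ? m2.step() : m1.step()) < 0) {
        if (!met) stop("fronts never met: no finite path between the seeds");
        break;
      }
      continue;
    }
    const std::vector<unsigned char> &other =
        take1 ? m2.states() : m1.states();
    if (other[idx] == 2) {
      if (!met) {
        // grow a small doubly-accepted lens (a few voxels of travel at the
        // local speed) so the meeting region supports sub-voxel refinement
        slack = 4.0 * minsp / REAL(speed)[idx];
        met = true;
      }
      const double s = m1.times()[idx] + m2.times()[idx];
      if (s < best_meet) best_meet = s;
    }
    if (met && m1.peek() + m2.peek() >= best_meet + slack) break;
  }
  const std::vector<double> &t1 = m1.times();
  const std::vector<double> &t2 = m2.times();
  const std::vector<unsigned char> &st1 = m1.states();
  const std::vector<unsigned char> &st2 = m2.states();
  long best = -1;
  double bestsum = std::numeric_limits<double>::infinity();
  for (long i = 0; i < static_cast<long>(t1.size()); ++i) {
    if (st1[i] == 2 && st2[i] == 2) {
      const double s = t1[i] + t2[i];
      if (s < bestsum) {
        bestsum = s;
        best = i;
      }
    }
  }
  NumericVector o1(t1.size()), o2(t2.size());
  LogicalVector a1(t1.size()), a2(t2.size());
  for (long i = 0; i < static_cast<long>(t1.size()); ++i) {
    o1[i] = t1[i];
    o2[i] = t2[i];
    a1[i] = st1[i] == 2;
    a2[i] = st2[i] == 2;
  }
  return List::create(Named("time_start") = o1, Named("time_end") = o2,
                      Named("accepted_start") = a1, Named("accepted_end") = a2,
                      Named("meet_index") = static_cast<double>(best + 1));
}
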