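// MRF relaxation engines: Metropolis annealing, ICM, modified Metropolis
// dynamics (MMD) and annealed Gibbs sampling, over a Potts prior with
// Gaussian singleton energies. Labels are 0-based here; the R wrappers
// translate. All randomness comes from R's RNG so runs are reproducible
// from set.seed().
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int OFF8[8][2] = {{-1,-1},{-1,0},{-1,1},{0,-1},{0,1},{1,-1},{1,0},{1,1}};
static const int OFF4[4][2] = {{-1,0},{0,-1},{0,1},{1,0}};

struct Grid {
  int h, w, k, nn;
  const int (*off)[2];
  double beta;
  std::vector<double> sing; // site-major: s * k + c
  std::vector<int> lab;

  inline int idx(int i, int j) const { return i + j * h; }

  // Potts part of the local energy of label c at (i, j)
  inline double pair_energy(int i, int j, int c) const {
    double e = 0.0;
    for (int t = 0; t < nn; ++t) {
      int ni = i + off[t][0], nj = j + off[t][1];
      if (ni < 0 || nj < 0 || ni >= h || nj >= w) continue;
      e += (lab[idx(ni, nj)] == c) ? -beta : beta;
    }
    return e;
  }

  inline double local_energy(int i, int j, int c) const {
    return sing[(size_t)idx(i, j) * k + c] + pair_energy(i, j, c);
  }

  double total_energy() const {
    double u = 0.0;
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        int s = idx(i, j);
        u += sing[(size_t)s * k + lab[s]];
        // count each unordered pair once: offsets strictly "forward"
        for (int t = 0; t < nn; ++t) {
          int di = off[t][0], dj = off[t][1];
          if (di < 0 || (di == 0 && dj < 0)) continue;
          if (di == 0 && dj == 0) continue;
          int ni = i + di, nj = j + dj;
          if (ni < 0 || nj < 0 || ni >= h || nj >= w) continue;
          u += (lab[s] == lab[idx(ni, nj)]) ? -beta : beta;
        }
      }
    return u;
  }
};

static void shuffle_sites(std::vector<int>& perm) {
  for (int i = (int)perm.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }
}

// method: 0 = icm, 1 = metropolis, 2 = gibbs, 3 = mmd
// [[Rcpp::export]]
List cpp_relax(NumericMatrix f, IntegerMatrix init, NumericVector mu,
               NumericVector sigma2, double beta, int nbhd, int method,
               double t0, double cooling, double tol, int max_sweeps,
               double alpha) {
  const int h = f.nrow(), w = f.ncol(), k = mu.size();
  const size_t n = (size_t)h * w;
  Grid g;
  g.h = h; g.w = w; g.k = k; g.beta = beta;
  g.nn = (nbhd == 4) ? 4 : 8;
  g.off = (nbhd == 4) ? OFF4 : OFF8;

  g.sing.resize(n * k);
  std::vector<double> cst(k), inv2(k);
  for (int c = 0; c < k; ++c) {
    cst[c] = 0.5 * std::log(2.0 * M_PI * sigma2[c]);
    inv2[c] = 0.5 / sigma2[c];
  }
  for (size_t s = 0; s < n; ++s) {
    double fs = f[s];
    for (int c = 0; c < k; ++c) {
      double d = fs - mu[c];
      g.sing[s * k + c] = cst[c] + d * d * inv2[c];
    }
  }
  g.lab.assign(init.begin(), init.end());

  double U = g.total_energy();
  double bestU = U;
  std::vector<int> best = g.lab;

  std::vector<double> tr_energy, tr_changed, tr_temp;
  std::vector<int> perm(n);
  for (size_t s = 0; s < n; ++s) perm[s] = (int)s;

  double T = t0;
  bool converged = false;
  int sweep = 0;

  for (sweep = 1; sweep <= max_sweeps; ++sweep) {
    long changed = 0;
    if (method == 0) { // ICM: raster order, deterministic argmin
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i) {
          int s = g.idx(i, j);
          int cur = g.lab[s], arg = 0;
          double ebest = R_PosInf;
          for (int c = 0; c < k; ++c) {
            double e = g.local_energy(i, j, c);
            if (e < ebest) { ebest = e; arg = c; }
          }
          if (arg != cur) {
            U += ebest - g.local_energy(i, j, cur);
            g.lab[s] = arg;
            ++changed;
          }
        }
    } else {
      shuffle_sites(perm);
      for (size_t p = 0; p < n; ++p) {
        int s = perm[p];
        int i = s % h, j = s / h;
        int cur = g.lab[s];
        if (method == 2) { // Gibbs: sample the local conditional
          double emin = R_PosInf;
          std::vector<double> e(k);
          for (int c = 0; c < k; ++c) {
            e[c] = g.local_energy(i, j, c);
            if (e[c] < emin) emin = e[c];
          }
          double tot = 0.0;
          for (int c = 0; c < k; ++c) { e[c] = std::exp(-(e[c] - emin) / T); tot += e[c]; }
          double u = unif_rand() * tot, acc = 0.0;
          int pick = k - 1;
          for (int c = 0; c < k; ++c) { acc += e[c]; if (u <= acc) { pick = c; break; } }
          if (pick != cur) {
            U += g.local_energy(i, j, pick) - g.local_energy(i, j, cur);
            g.lab[s] = pick;
            ++changed;
          }
        } else { // Metropolis / MMD: random different-label proposal
          int prop = (int)(unif_rand() * (k - 1));
          if (prop >= cur) ++prop;
          if (prop >= k) prop = k - 1;
          double dU = g.local_energy(i, j, prop) - g.local_energy(i, j, cur);
          bool accept;
          if (dU <= 0.0) accept = true;
          else if (method == 3) accept = std::exp(-dU / T) >= alpha;
          else accept = unif_rand() < std::exp(-dU / T);
          if (accept) {
            g.lab[s] = prop;
            U += dU;
            ++changed;
          }
        }
      }
    }

    tr_energy.push_back(U);
    tr_changed.push_back((double)changed / (double)n);
    tr_temp.push_back(method == 0 ? NA_REAL : T);
    if (U < bestU) { bestU = U; best = g.lab; }

    if (method == 0) {
      if (changed == 0) { converged = true; break; }
    } else {
      T *= cooling;
      if ((double)changed / (double)n < tol) { converged = true; break; }
    }
  }

  // deterministic ICM returns its fixed point; stochastic relaxers return the
  // best labelling seen (energy never above the initial state's)
  const std::vector<int>& outlab = (method == 0) ? g.lab : best;
  IntegerMatrix lab_out(h, w);
  std::copy(outlab.begin(), outlab.end(), lab_out.begin());
  double finalU = (method == 0) ? U : bestU;

  return List::create(
    _["labels"] = lab_out,
    _["energy"] = NumericVector(tr_energy.begin(), tr_energy.end()),
    _["changed"] = NumericVector(tr_changed.begin(), tr_changed.end()),
    _["temperature"] = NumericVector(tr_temp.begin(), tr_temp.end()),
    _["final_energy"] = finalU,
    _["converged"] = converged);
}
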