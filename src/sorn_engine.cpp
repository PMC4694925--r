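// Core discrete-time SORN dynamics.  The exported phase runner iterates the
// binary threshold update together with the active plasticity rules; the
// equivalent single-step operations are also implemented in pure R at the
// package level and are cross-checked bit-exactly against this loop in the
// test suite.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// One synaptic-normalization sweep: every entry is pulled 10% of the way
// towards W_ij / (0.5 * rowsum_i + 0.5 * colsum_j).  Entries whose combined
// in/out sum is zero are necessarily zero themselves and are left unchanged.
static void snSweep(arma::mat& W) {
  const arma::uword n = W.n_rows;
  // fused single pass: row/column sums plus the nonzero index list (adding
  // skipped zeros would not change the sums bit-wise, so the summation
  // order matches plain rowSums/colSums)
  arma::colvec rs(n, arma::fill::zeros);
  arma::rowvec cs(n, arma::fill::zeros);
  static std::vector<arma::uword> nz;
  nz.clear();
  const double* ptr = W.memptr();
  for (arma::uword j = 0; j < n; ++j) {
    const arma::uword off = j * n;
    double colsum = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      const double w = ptr[off + i];
      if (w > 0.0) {
        rs(i) += w;
        colsum += w;
        nz.push_back(off + i);
      }
    }
    cs(j) = colsum;
  }
  // only nonzero entries change, and their denominator is strictly
  // positive; the arithmetic matches the pure-R reference
  // (0.9*w + (0.1*w)/d) exactly
  double* wp = W.memptr();
  for (size_t k = 0; k < nz.size(); ++k) {
    const arma::uword idx = nz[k];
    const double w = wp[idx];
    wp[idx] = 0.9 * w +
      (0.1 * w) / (0.5 * rs(idx % n) + 0.5 * cs(idx / n));
  }
}

// [[Rcpp::export(name = ".cppSnSweeps")]]
arma::mat cppSnSweeps(arma::mat W, int nSweeps) {
  for (int k = 0; k < nSweeps; ++k) snSweep(W);
  return W;
}

// Iterate synaptic normalization until all row and column sums of the
// nonzero structure are within tol of 1 (or maxIter is reached).
// [[Rcpp::export(name = ".cppSnNormalize")]]
List cppSnNormalize(arma::mat W, double tol, int maxIter) {
  int it = 0;
  double dev = R_PosInf;
  for (it = 0; it < maxIter; ++it) {
    snSweep(W);
    const arma::colvec rs = arma::sum(W, 1);
    const arma::rowvec cs = arma::sum(W, 0);
    double devR = 0.0, devC = 0.0;
    for (arma::uword i = 0; i < W.n_rows; ++i) {
      if (rs(i) > 0 && std::abs(rs(i) - 1.0) > devR) devR = std::abs(rs(i) - 1.0);
      if (cs(i) > 0 && std::abs(cs(i) - 1.0) > devC) devC = std::abs(cs(i) - 1.0);
    }
    dev = std::max(devR, devC);
    if (dev < tol) { ++it; break; }
  }
  return List::create(_["W"] = W, _["iterations"] = it, _["deviation"] = dev);
}

// Full phase runner.  Drive is passed in CSR-like form: for step t the
// excitatory units driveIdx[drivePtr[t] .. drivePtr[t+1]-1] (0-based) each
// receive an external input of wIn.  Recording convention: row t of the spike
// raster holds x(t+1), the excitatory state produced by the input of step t.
// [[Rcpp::export(name = ".cppRunPhase")]]
List cppRunPhase(arma::mat Wee,
                 arma::imat mask,
                 const arma::mat& Wei,
                 const arma::mat& Wie,
                 arma::vec Te,
                 const arma::vec& Ti,
                 const arma::vec& h,
                 arma::vec x,
                 arma::vec y,
                 const IntegerVector& drivePtr,
                 const IntegerVector& driveIdx,
                 double wIn,
                 bool stdp, bool sn, bool ip,
                 bool prune, double structRate, double structInit,
                 double etaStdp, double etaIp,
                 double noiseSd,
                 bool shuffleEnd,
                 bool recordInh,
                 int snapshotEvery) {
  const int T = drivePtr.size() - 1;
  const arma::uword nE = Wee.n_rows;
  const arma::uword nI = Wie.n_rows;

  RawMatrix spikes(T, (int)nE);
  RawMatrix inhSpikes(recordInh ? T : 0, recordInh ? (int)nI : 0);

  std::vector<int> snapStep;
  std::vector<double> snapFrac, snapTotW;
  long noiseFlips = 0, totalSpikes = 0;

  std::vector<arma::uword> oldAct, newAct, inhAct;
  oldAct.reserve(nE); newAct.reserve(nE); inhAct.reserve(nI);
  oldAct.clear();
  for (arma::uword i = 0; i < nE; ++i) if (x(i) > 0.5) oldAct.push_back(i);
  inhAct.clear();
  for (arma::uword i = 0; i < nI; ++i) if (y(i) > 0.5) inhAct.push_back(i);

  arma::vec a(nE), ai(nI);
  for (int t = 0; t < T; ++t) {
    // excitatory pre-threshold activation
    a.zeros();
    for (arma::uword k = 0; k < oldAct.size(); ++k) a += Wee.col(oldAct[k]);
    for (arma::uword k = 0; k < inhAct.size(); ++k) a -= Wei.col(inhAct[k]);
    for (int k = drivePtr[t]; k < drivePtr[t + 1]; ++k) a(driveIdx[k]) += wIn;
    a -= Te;

    newAct.clear();
    if (noiseSd > 0) {
      for (arma::uword i = 0; i < nE; ++i) {
        const bool clean = a(i) > 0.0;
        const bool noisy = a(i) + noiseSd * R::norm_rand() > 0.0;
        if (noisy != clean) ++noiseFlips;
        if (noisy) newAct.push_back(i);
      }
    } else {
      for (arma::uword i = 0; i < nE; ++i) if (a(i) > 0.0) newAct.push_back(i);
    }

    // inhibitory update uses the fresh excitatory state
    ai.zeros();
    for (arma::uword k = 0; k < newAct.size(); ++k) ai += Wie.col(newAct[k]);
    inhAct.clear();
    for (arma::uword i = 0; i < nI; ++i) if (ai(i) - Ti(i) > 0.0) inhAct.push_back(i);

    if (stdp) {
      std::vector<char> isOld(nE, 0), isNew(nE, 0);
      for (arma::uword k = 0; k < oldAct.size(); ++k) isOld[oldAct[k]] = 1;
      for (arma::uword k = 0; k < newAct.size(); ++k) isNew[newAct[k]] = 1;
      // potentiation: postsynaptic spike follows presynaptic spike
      for (arma::uword p = 0; p < newAct.size(); ++p) {
        const arma::uword i = newAct[p];
        for (arma::uword q = 0; q < oldAct.size(); ++q) {
          const arma::uword j = oldAct[q];
          if (i != j && mask(i, j)) Wee(i, j) += etaStdp;
        }
      }
      // depression: reversed order, clipped at zero; a pair whose net update
      // is zero (both units active in both steps) is never pruned
      for (arma::uword p = 0; p < oldAct.size(); ++p) {
        const arma::uword i = oldAct[p];
        for (arma::uword q = 0; q < newAct.size(); ++q) {
          const arma::uword j = newAct[q];
          if (i != j && mask(i, j)) {
            Wee(i, j) -= etaStdp;
            if (Wee(i, j) <= 0.0) {
              Wee(i, j) = 0.0;
              if (prune && !(isNew[i] && isOld[j])) mask(i, j) = 0;
            }
          }
        }
      }
      // structural plasticity: occasionally grow a fresh weak synapse
      if (structRate > 0 && R::unif_rand() < structRate) {
        const arma::uword i = (arma::uword)(R::unif_rand() * nE);
        const arma::uword j = (arma::uword)(R::unif_rand() * nE);
        if (i < nE && j < nE && i != j && !mask(i, j)) {
          mask(i, j) = 1;
          Wee(i, j) = structInit;
        }
      }
    }

    if (sn) snSweep(Wee);

    if (ip) {
      Te -= etaIp * h;
      for (arma::uword k = 0; k < newAct.size(); ++k) Te(newAct[k]) += etaIp;
    }

    for (arma::uword k = 0; k < newAct.size(); ++k) spikes(t, (int)newAct[k]) = 1;
    totalSpikes += (long)newAct.size();
    if (recordInh)
      for (arma::uword k = 0; k < inhAct.size(); ++k) inhSpikes(t, (int)inhAct[k]) = 1;

    if (snapshotEvery > 0 && ((t + 1) % snapshotEvery == 0)) {
      snapStep.push_back(t + 1);
      // fraction of strictly positive off-diagonal weights (zero-weight
      // synapses of an unpruned mask do not count as connections)
      long nPos = 0;
      for (arma::uword j = 0; j < nE; ++j)
        for (arma::uword i = 0; i < nE; ++i)
          if (i != j && Wee(i, j) > 0.0) ++nPos;
      snapFrac.push_back((double)nPos / (double)(nE * (nE - 1)));
      snapTotW.push_back(arma::accu(Wee));
    }

    oldAct.swap(newAct);
  }

  // reconstruct final binary states
  x.zeros();
  for (arma::uword k = 0; k < oldAct.size(); ++k) x(oldAct[k]) = 1.0;
  y.zeros();
  for (arma::uword k = 0; k < inhAct.size(); ++k) y(inhAct[k]) = 1.0;

  if (shuffleEnd) {
    // Fisher-Yates permutation of the excitatory state vector
    for (arma::uword i = nE - 1; i > 0; --i) {
      arma::uword j = (arma::uword)(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      const double tmp = x(i); x(i) = x(j); x(j) = tmp;
    }
  }

  return List::create(
      _["spikes"] = spikes,
      _["inhSpikes"] = inhSpikes,
      _["Wee"] = Wee,
      _["mask"] = mask,
      _["Te"] = Te,
      _["x"] = x,
      _["y"] = y,
      _["noiseFlips"] = (double)noiseFlips,
      _["totalSpikes"] = (double)totalSpikes,
      _["snapshotStep"] = wrap(snapStep),
      _["snapshotConnFrac"] = wrap(snapFrac),
      _["snapshotTotalWeight"] = wrap(snapTotW));
}
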