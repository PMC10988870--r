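#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// Discrete-generation Wright-Fisher engine for one randomly mating diploid
// population of N individuals (2N haplotypes), tracking segregating sites
// only. Per generation: multinomial resampling of parents (fitness-weighted
// at the focal sweep site when selection is active), Poisson(recPerBp * L)
// crossovers per transmitted gamete, Poisson(muTotal) new infinite-sites
// mutations per haplotype, then removal of lost sites and of fixed sites
// (fixed positions are recorded so a merged two-population sample can
// restore them as all-derived columns).
//
// All randomness comes from R's RNG, so set.seed() in R makes runs
// reproducible. sweepState: 0 = no sweep site, 1 = segregating,
// 2 = fixed, 3 = lost.

struct Pop {
  int nHap;
  std::vector<uint8_t> alleles;  // row-major, nHap x nSites
  std::vector<int> pos;          // sorted, 1-based bp
  std::unordered_set<int> occupied;
  std::vector<int> fixedPos;
};

static inline int ridx(int hap, int site, int nSites) {
  return hap * nSites + site;
}

static int draw_parent_neutral(int N) {
  int p = (int)(unif_rand() * N);
  return p >= N ? N - 1 : p;
}

static int draw_parent_weighted(const std::vector<double>& cumw) {
  double u = unif_rand() * cumw.back();
  int p = (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
  return p >= (int)cumw.size() ? (int)cumw.size() - 1 : p;
}

// transmit one gamete from parent individual `par` into child row `child`
static void transmit(const std::vector<uint8_t>& cur, std::vector<uint8_t>& nxt,
                     const std::vector<int>& pos, int nSites, int par,
                     int child, double recMean, double L) {
  int h0 = 2 * par + (unif_rand() < 0.5 ? 0 : 1);
  int k = (int)R::rpois(recMean);
  if (k == 0 || nSites == 0) {
    std::copy(cur.begin() + (size_t)h0 * nSites,
              cur.begin() + (size_t)(h0 + 1) * nSites,
              nxt.begin() + (size_t)child * nSites);
    return;
  }
  std::vector<double> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = unif_rand() * L;
  std::sort(bp.begin(), bp.end());
  int from = 0;
  int hapCur = h0;
  for (int i = 0; i < k; ++i) {
    // sites with pos <= bp come from the current parental haplotype
    int to = (int)(std::upper_bound(pos.begin(), pos.end(), (int)bp[i]) -
                   pos.begin());
    if (to > from)
      std::copy(cur.begin() + (size_t)hapCur * nSites + from,
                cur.begin() + (size_t)hapCur * nSites + to,
                nxt.begin() + (size_t)child * nSites + from);
    from = to;
    hapCur = (hapCur % 2 == 0) ? hapCur + 1 : hapCur - 1;
  }
  if (nSites > from)
    std::copy(cur.begin() + (size_t)hapCur * nSites + from,
              cur.begin() + (size_t)hapCur * nSites + (size_t)nSites,
              nxt.begin() + (size_t)child * nSites + from);
}

// [[Rcpp::export(name = ".wf_evolve_cpp")]]
List wf_evolve_cpp(IntegerMatrix hapIn, IntegerVector posIn, int nGen,
                   double muTotal, double recPerBp, double L,
                   int sweepPos, double s, double hDom) {
  Pop pop;
  pop.nHap = hapIn.nrow();
  const int N = pop.nHap / 2;
  int nSites = hapIn.ncol();
  pop.pos.assign(posIn.begin(), posIn.end());
  pop.alleles.resize((size_t)pop.nHap * nSites);
  for (int i = 0; i < pop.nHap; ++i)
    for (int j = 0; j < nSites; ++j)
      pop.alleles[ridx(i, j, nSites)] = (uint8_t)hapIn(i, j);
  for (int j = 0; j < nSites; ++j) pop.occupied.insert(pop.pos[j]);

  int sweepState = sweepPos > 0 ? 1 : 0;
  const double recMean = recPerBp * L;

  for (int gen = 0; gen < nGen; ++gen) {
    // fitness weights from the sweep site in the parental generation
    std::vector<double> cumw;
    bool weighted = false;
    if (sweepState == 1) {
      int sc = (int)(std::lower_bound(pop.pos.begin(), pop.pos.end(),
                                      sweepPos) - pop.pos.begin());
      if (sc < nSites && pop.pos[sc] == sweepPos) {
        cumw.resize(N);
        double acc = 0.0;
        for (int i = 0; i < N; ++i) {
          int gcount = pop.alleles[ridx(2 * i, sc, nSites)] +
                       pop.alleles[ridx(2 * i + 1, sc, nSites)];
          double w = gcount == 0 ? 1.0 : (gcount == 1 ? 1.0 + hDom * s
                                                      : 1.0 + s);
          acc += w;
          cumw[i] = acc;
        }
        weighted = true;
      }
    }

    // transmission
    std::vector<uint8_t> nxt((size_t)pop.nHap * nSites);
    for (int child = 0; child < pop.nHap; ++child) {
      int par = weighted ? draw_parent_weighted(cumw)
                         : draw_parent_neutral(N);
      transmit(pop.alleles, nxt, pop.pos, nSites, par, child, recMean, L);
    }

    // new mutations (infinite sites; collisions redrawn)
    int nMut = (int)R::rpois(muTotal * pop.nHap);
    std::vector<int> mutPos;
    std::vector<int> mutHap;
    for (int m = 0; m < nMut; ++m) {
      int p = 0;
      bool found = false;
      for (int tries = 0; tries < 100; ++tries) {
        p = 1 + (int)(unif_rand() * L);
        if (p > (int)L) p = (int)L;
        if (!pop.occupied.count(p)) { found = true; break; }
      }
      if (!found) continue;
      pop.occupied.insert(p);
      mutPos.push_back(p);
      mutHap.push_back((int)(unif_rand() * pop.nHap));
    }

    // column census over old + new sites
    int nNew = (int)mutPos.size();
    int nTot = nSites + nNew;
    std::vector<int> cnt(nTot, 0);
    for (int i = 0; i < pop.nHap; ++i) {
      const uint8_t* row = &nxt[(size_t)i * nSites];
      for (int j = 0; j < nSites; ++j) cnt[j] += row[j];
    }
    for (int m = 0; m < nNew; ++m) cnt[nSites + m] = 1;

    // keep segregating sites; record fixed positions; drop lost
    std::vector<int> keep;
    keep.reserve(nTot);
    std::vector<int> allPos(nTot);
    for (int j = 0; j < nSites; ++j) allPos[j] = pop.pos[j];
    for (int m = 0; m < nNew; ++m) allPos[nSites + m] = mutPos[m];
    for (int j = 0; j < nTot; ++j) {
      if (cnt[j] == 0) {
        pop.occupied.erase(allPos[j]);
        if (allPos[j] == sweepPos && sweepState == 1) sweepState = 3;
      } else if (cnt[j] == pop.nHap) {
        // keep the position marked occupied so no new mutation can reuse it
        pop.fixedPos.push_back(allPos[j]);
        if (allPos[j] == sweepPos && sweepState == 1) sweepState = 2;
      } else {
        keep.push_back(j);
      }
    }
    // sort kept sites by position
    std::sort(keep.begin(), keep.end(),
              [&](int a, int b) { return allPos[a] < allPos[b]; });

    // row-wise gather rebuild (cache-friendly): every cell is written, so
    // no zero-initialization pass is needed
    int nKeep = (int)keep.size();
    std::vector<uint8_t> rebuilt;
    rebuilt.resize((size_t)pop.nHap * nKeep);
    std::vector<int> newPos(nKeep);
    for (int jj = 0; jj < nKeep; ++jj) newPos[jj] = allPos[keep[jj]];
    for (int i = 0; i < pop.nHap; ++i) {
      const uint8_t* src = &nxt[(size_t)i * nSites];
      uint8_t* dst = &rebuilt[(size_t)i * nKeep];
      for (int jj = 0; jj < nKeep; ++jj) {
        int j = keep[jj];
        dst[jj] = j < nSites ? src[j] : 0;
      }
    }
    for (int jj = 0; jj < nKeep; ++jj) {
      int j = keep[jj];
      if (j >= nSites)
        rebuilt[ridx(mutHap[j - nSites], jj, nKeep)] = 1;
    }
    pop.alleles.swap(rebuilt);
    pop.pos.swap(newPos);
    nSites = nKeep;
  }

  IntegerMatrix hapOut(pop.nHap, nSites);
  for (int i = 0; i < pop.nHap; ++i)
    for (int j = 0; j < nSites; ++j)
      hapOut(i, j) = pop.alleles[ridx(i, j, nSites)];
  double sweepFreq = NA_REAL;
  if (sweepState == 1) {
    int sc = (int)(std::lower_bound(pop.pos.begin(), pop.pos.end(),
                                    sweepPos) - pop.pos.begin());
    if (sc < nSites && pop.pos[sc] == sweepPos) {
      int c = 0;
      for (int i = 0; i < pop.nHap; ++i) c += hapOut(i, sc);
      sweepFreq = (double)c / pop.nHap;
    }
  } else if (sweepState == 2) {
    sweepFreq = 1.0;
  } else if (sweepState == 3) {
    sweepFreq = 0.0;
  }
  return List::create(
    _["hap"] = hapOut,
    _["pos"] = IntegerVector(pop.pos.begin(), pop.pos.end()),
    _["fixedPos"] = IntegerVector(pop.fixedPos.begin(), pop.fixedPos.end()),
    _["sweepState"] = sweepState,
    _["sweepFreq"] = sweepFreq);
}
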