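#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// EHH machinery shared by ehh(), ihh() and the XP-EHH scan.
//
// Scope is all haplotypes of one population (the XP-EHH convention): the
// curve starts at 1 for the zero-length extension and the core site's own
// allele is not part of the homozygosity strings. At extension to site j,
// EHH = sum_k C(m_k, 2) / C(N, 2) over the counts m_k of distinct haplotype
// strings spanning the sites strictly beyond the core through j.
//
// The walk refines haplotype groups only at sites polymorphic within the
// population; at monomorphic sites the curve is flat, so the walker skips
// them but emits the plateau-end vertex before each refining site, making
// curves and trapezoid integrals identical to a site-by-site walk.
// Haplotypes in singleton groups can never rejoin a group and contribute
// nothing, so only "active" haplotypes are refined.
//
// Stopping rules (selscan-compatible): EHH below the cutoff (status 0);
// chromosome edge reached first (status 1, edge-truncated); an inter-site
// gap above maxGap on the full site grid (status 2); extension capped at
// maxExtend bp from the core (status 3, score still defined).

struct EhhSide {
  std::vector<double> offsets;  // physical distance from core (bp)
  std::vector<double> values;   // EHH at each offset (offset 0, value 1 implied)
  int status;
};

struct PopIndex {
  std::vector<int> polyIdx;   // full-grid indices of polymorphic sites
  std::vector<int> polyRank;  // full index -> rank in polyIdx (or -1)
  std::vector<int> blockId;   // gap blocks on the full grid
};

static PopIndex build_index(const IntegerMatrix& hap, const NumericVector& pos,
                            double maxGap) {
  const int nHap = hap.nrow();
  const int nSites = hap.ncol();
  PopIndex px;
  px.polyRank.assign(nSites, -1);
  px.blockId.assign(nSites, 0);
  for (int j = 0; j < nSites; ++j) {
    int c = 0;
    for (int k = 0; k < nHap; ++k) c += hap(k, j);
    if (c > 0 && c < nHap) {
      px.polyRank[j] = (int)px.polyIdx.size();
      px.polyIdx.push_back(j);
    }
  }
  int blk = 0;
  for (int j = 1; j < nSites; ++j) {
    if (pos[j] - pos[j - 1] > maxGap) ++blk;
    px.blockId[j] = blk;
  }
  return px;
}

static EhhSide ehh_walk(const IntegerMatrix& hap, const NumericVector& pos,
                        const PopIndex& px, int core, int step,
                        double cutoff, double maxExtend) {
  const int nHap = hap.nrow();
  const int nSites = hap.ncol();
  EhhSide out;
  const double denom = (double)nHap * (nHap - 1);
  const double corePos = pos[core];

  std::vector<int> grp(nHap, 0);
  std::vector<int> active(nHap);
  for (int k = 0; k < nHap; ++k) active[k] = k;
  std::vector<int> remapVal(2 * nHap + 2, 0);
  std::vector<int> remapStamp(2 * nHap + 2, -1);
  std::vector<int> cnt(nHap + 1, 0);
  int stamp = 0;
  double e = 1.0;

  // rank of the first polymorphic site strictly beyond the core
  int rank;
  if (step > 0) {
    rank = (px.polyRank[core] >= 0) ? px.polyRank[core] + 1
      : (int)(std::lower_bound(px.polyIdx.begin(), px.polyIdx.end(), core) -
              px.polyIdx.begin());
  } else {
    rank = ((px.polyRank[core] >= 0) ? px.polyRank[core]
      : (int)(std::lower_bound(px.polyIdx.begin(), px.polyIdx.end(), core) -
              px.polyIdx.begin())) - 1;
  }

  int lastFull = core;  // last full-grid site incorporated into the curve
  while (true) {
    int j = -1;
    if (rank >= 0 && rank < (int)px.polyIdx.size()) j = px.polyIdx[rank];
    bool havePoly = j >= 0 && ((step > 0) ? j > core : j < core);
    bool polyInRange = havePoly && std::abs(pos[j] - corePos) <= maxExtend;

    if (!polyInRange) {
      // no further refinement possible within range: find how far the
      // plateau extends on the full grid
      int edge = (step > 0) ? nSites - 1 : 0;
      int lim = lastFull;
      while (lim != edge &&
             std::abs(pos[lim + step] - corePos) <= maxExtend &&
             px.blockId[lim + step] == px.blockId[core])
        lim += step;
      if (lim != lastFull) {
        out.offsets.push_back(std::abs(pos[lim] - corePos));
        out.values.push_back(e);
      }
      if (lim == edge)
        out.status = 1;  // plateau reached the chromosome end
      else if (std::abs(pos[lim + step] - corePos) <= maxExtend)
        out.status = 2;  // stopped by an oversized gap
      else
        out.status = 3;  // max-extend truncation; score stays defined
      return out;
    }

    if (px.blockId[j] != px.blockId[core]) {
      out.status = 2;
      return out;
    }

    // plateau-end vertex: the full-grid neighbour of j on the core side
    int jprev = j - step;
    if (jprev != lastFull && px.blockId[jprev] == px.blockId[core]) {
      out.offsets.push_back(std::abs(pos[jprev] - corePos));
      out.values.push_back(e);
    }

    // refine active groups by the allele at j (single pass: remap,
    // relabel and count together)
    ++stamp;
    int nNew = 0;
    for (int k : active) {
      int key = 2 * grp[k] + hap(k, j);
      if (remapStamp[key] != stamp) {
        remapStamp[key] = stamp;
        remapVal[key] = nNew;
        cnt[nNew] = 0;
        ++nNew;
      }
      int id = remapVal[key];
      grp[k] = id;
      cnt[id]++;
    }
    double num = 0.0;
    for (int g = 0; g < nNew; ++g)
      num += (double)cnt[g] * (cnt[g] - 1);
    e = num / denom;
    out.offsets.push_back(std::abs(pos[j] - corePos));
    out.values.push_back(e);
    if (e < cutoff) {
      out.status = 0;
      return out;
    }
    size_t w = 0;
    for (size_t a = 0; a < active.size(); ++a)
      if (cnt[grp[active[a]]] >= 2) active[w++] = active[a];
    active.resize(w);
    lastFull = j;
    rank += step;
  }
}

// trapezoid over segments whose far endpoint is still >= cutoff
static double ihh_side_integral(const EhhSide& side, double cutoff) {
  double total = 0.0, prevOff = 0.0, prevVal = 1.0;
  for (size_t k = 0; k < side.values.size(); ++k) {
    if (side.values[k] < cutoff) break;
    total += (side.offsets[k] - prevOff) * (side.values[k] + prevVal) / 2.0;
    prevOff = side.offsets[k];
    prevVal = side.values[k];
  }
  return total;
}

// [[Rcpp::export(name = ".ehh_curve_cpp")]]
List ehh_curve_cpp(IntegerMatrix hap, NumericVector pos, int core0,
                   int step, double cutoff, double maxGap, double maxExtend) {
  if (hap.nrow() < 2) stop("EHH requires at least 2 haplotypes");
  PopIndex px = build_index(hap, pos, maxGap);
  EhhSide side = ehh_walk(hap, pos, px, core0, step, cutoff, maxExtend);
  return List::create(
    _["offsets"] = NumericVector(side.offsets.begin(), side.offsets.end()),
    _["values"] = NumericVector(side.values.begin(), side.values.end()),
    _["status"] = side.status);
}

// [[Rcpp::export(name = ".ihh_cpp")]]
List ihh_cpp(IntegerMatrix hap, NumericVector pos, int core0, double cutoff,
             double maxGap, double maxExtend) {
  if (hap.nrow() < 2) stop("iHH requires at least 2 haplotypes");
  PopIndex px = build_index(hap, pos, maxGap);
  EhhSide up = ehh_walk(hap, pos, px, core0, -1, cutoff, maxExtend);
  EhhSide dn = ehh_walk(hap, pos, px, core0, +1, cutoff, maxExtend);
  // status precedence: gap (2) > edge (1) > cutoff/max-extend (0/3)
  int status = 0;
  for (int s : {up.status, dn.status}) {
    if (s == 2) status = 2;
    else if (s == 1 && status != 2) status = 1;
  }
  double val = ihh_side_integral(up, cutoff) + ihh_side_integral(dn, cutoff);
  return List::create(_["ihh"] = val, _["status"] = status,
                      _["statusUp"] = up.status, _["statusDown"] = dn.status);
}

// [[Rcpp::export(name = ".xpehh_scan_cpp")]]
List xpehh_scan_cpp(IntegerMatrix hapSel, IntegerMatrix hapRef,
                    NumericVector pos, IntegerVector cores0, double cutoff,
                    double maxGap, double maxExtend) {
  const int n = cores0.size();
  PopIndex pxS = build_index(hapSel, pos, maxGap);
  PopIndex pxR = build_index(hapRef, pos, maxGap);
  NumericVector ihhSel(n), ihhRef(n);
  IntegerVector stSel(n), stRef(n);
  auto combine = [](int a, int b) {
    if (a == 2 || b == 2) return 2;
    if (a == 1 || b == 1) return 1;
    return 0;
  };
  for (int idx = 0; idx < n; ++idx) {
    int core = cores0[idx];
    EhhSide upS = ehh_walk(hapSel, pos, pxS, core, -1, cutoff, maxExtend);
    EhhSide dnS = ehh_walk(hapSel, pos, pxS, core, +1, cutoff, maxExtend);
    EhhSide upR = ehh_walk(hapRef, pos, pxR, core, -1, cutoff, maxExtend);
    EhhSide dnR = ehh_walk(hapRef, pos, pxR, core, +1, cutoff, maxExtend);
    ihhSel[idx] = ihh_side_integral(upS, cutoff) + ihh_side_integral(dnS, cutoff);
    ihhRef[idx] = ihh_side_integral(upR, cutoff) + ihh_side_integral(dnR, cutoff);
    stSel[idx] = combine(upS.status, dnS.status);
    stRef[idx] = combine(upR.status, dnR.status);
  }
  return List::create(_["ihhSel"] = ihhSel, _["ihhRef"] = ihhRef,
                      _["statusSel"] = stSel, _["statusRef"] = stRef);
}
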