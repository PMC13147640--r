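#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact-mode ROH scan for one individual on one chromosome.
//
// calls: genotype codes 0/1/2 (NA = missing), pos: internal 0-based SNP
// positions (strictly increasing). An index interval [i..j] qualifies when
//   het <= max_het, missing <= max_missing,
//   every adjacent gap pos[k+1]-pos[k] < max_gap,
//   j-i+1 >= min_snps, pos[j]-pos[i]+1 >= min_len,
//   (pos[j]-pos[i]+1)/1000 / (j-i+1) <= max_density (kb per SNP).
// Returned are the maximal qualifying intervals: those where extending one
// SNP left or right leaves no qualifying interval. Overlap resolution is
// done by the R caller.
//
// The het/missing/gap constraints are hereditary, so for each start i the
// set of ends satisfying them is a prefix [i .. r(i)] with r nondecreasing
// (two-pointer). The kb-per-SNP density margin 1000*D*n - len changes by
// 1000*D - gap per added SNP, so it is nondecreasing whenever all gaps in
// the window are <= 1000*D; in that common case the only right-maximal end
// for start i is r(i). Windows containing a larger gap fall back to a scan.
// [[Rcpp::export]]
IntegerMatrix cpp_detect_exact(IntegerVector calls, NumericVector pos,
                               int max_het, int max_missing, double max_gap,
                               int min_snps, double min_len,
                               double max_density) {
  const int m = calls.size();
  std::vector<int> cand_i, cand_j;
  if (m == 0) return IntegerMatrix(0, 2);

  std::vector<int> chet(m + 1, 0), cmis(m + 1, 0);
  for (int k = 0; k < m; ++k) {
    chet[k + 1] = chet[k] + (calls[k] == 1 ? 1 : 0);
    cmis[k + 1] = cmis[k] + (calls[k] == NA_INTEGER ? 1 : 0);
  }
  const double dlim = 1000.0 * max_density;  // bp per SNP limit

  // nextBig[k]: smallest t >= k with gap(t -> t+1) > dlim, else m-1
  std::vector<int> nextBig(m, m - 1);
  for (int k = m - 2; k >= 0; --k)
    nextBig[k] = (pos[k + 1] - pos[k] > dlim) ? k : nextBig[k + 1];

  // r(i) via two pointers over the hereditary constraints
  std::vector<int> r(m, 0);
  int j = 0;
  for (int i = 0; i < m; ++i) {
    if (j < i) j = i;
    while (j + 1 < m) {
      if (pos[j + 1] - pos[j] >= max_gap) break;
      int het = chet[j + 2] - chet[i], mis = cmis[j + 2] - cmis[i];
      if (het > max_het || mis > max_missing) break;
      ++j;
    }
    r[i] = j;
  }

  auto lenOf = [&](int i, int jj) { return pos[jj] - pos[i] + 1.0; };
  auto densOK = [&](int i, int jj) {
    return lenOf(i, jj) <= dlim * (jj - i + 1);
  };
  auto qualifies = [&](int i, int jj) {
    return jj <= r[i] && jj - i + 1 >= min_snps &&
           lenOf(i, jj) >= min_len && densOK(i, jj);
  };

  for (int i = 0; i < m; ++i) {
    int jlo = i + min_snps - 1;
    if (jlo > r[i]) continue;
    if (nextBig[i] >= r[i]) {
      // density margin nondecreasing: only r(i) can be right-maximal
      int jj = r[i];
      if (qualifies(i, jj) && (i == 0 || !qualifies(i - 1, jj))) {
        cand_i.push_back(i); cand_j.push_back(jj);
      }
    } else {
      for (int jj = jlo; jj <= r[i]; ++jj) {
        if (!qualifies(i, jj)) continue;
        bool right_ext = qualifies(i, jj + 1);  // jj+1 > r[i] handled inside
        if (jj + 1 >= m) right_ext = false;
        if (right_ext) continue;
        if (i == 0 || !qualifies(i - 1, jj)) {
          cand_i.push_back(i); cand_j.push_back(jj);
        }
      }
    }
  }

  IntegerMatrix out(cand_i.size(), 2);
  for (size_t k = 0; k < cand_i.size(); ++k) {
    out(k, 0) = cand_i[k];
    out(k, 1) = cand_j[k];
  }
  return out;
}

// shared helper: add interval [st, en) to a diff array over SNP positions
static inline void add_interval(const NumericVector& pos, double st, double en,
                                std::vector<int>& diff) {
  int lo = std::lower_bound(pos.begin(), pos.end(), st) - pos.begin();
  int hi = std::lower_bound(pos.begin(), pos.end(), en) - pos.begin();
  if (lo < hi) { diff[lo] += 1; diff[hi] -= 1; }
}

// Per-SNP count of individuals whose ROH covers the SNP (an individual
// counts at most once per SNP even with self-overlapping segments).
// seg_chrom/seg_ind are 0-based indices; pos_list has one positions vector
// per chromosome. Returns a list of per-chromosome integer count vectors.
// [[Rcpp::export]]
List cpp_coverage_counts(IntegerVector seg_ind, IntegerVector seg_chrom,
                         NumericVector seg_start, NumericVector seg_end,
                         List pos_list, int n_ind) {
  const int n_chrom = pos_list.size();
  List out(n_chrom);
  for (int c = 0; c < n_chrom; ++c) {
    NumericVector pos = pos_list[c];
    const int ns = pos.size();
    std::vector<int> diff(ns + 1, 0);
    // group this chromosome's segments by individual, merge unions
    for (int ind = 0; ind < n_ind; ++ind) {
      std::vector<std::pair<double, double> > iv;
      for (int s = 0; s < seg_ind.size(); ++s)
        if (seg_chrom[s] == c && seg_ind[s] == ind)
          iv.push_back(std::make_pair(seg_start[s], seg_end[s]));
      if (iv.empty()) continue;
      std::sort(iv.begin(), iv.end());
      double st = iv[0].first, en = iv[0].second;
      for (size_t k = 1; k < iv.size(); ++k) {
        if (iv[k].first <= en) en = std::max(en, iv[k].second);
        else { add_interval(pos, st, en, diff); st = iv[k].first; en = iv[k].second; }
      }
      add_interval(pos, st, en, diff);
    }
    IntegerVector counts(ns);
    int run = 0;
    for (int k = 0; k < ns; ++k) { run += diff[k]; counts[k] = run; }
    out[c] = counts;
  }
  return out;
}

// Max-statistic permutation null for ROH hotspot calling.
//
// Each permutation redistributes every segment independently to a uniform
// start on [0, chrom_len - length] (same individual, same chromosome,
// length preserved), recomputes the per-SNP coverage frequency with
// per-individual deduplication, and records the genome-wide maximum
// frequency. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_permute_null(IntegerVector seg_ind, IntegerVector seg_chrom,
                               NumericVector seg_len, NumericVector chrom_len,
                               List pos_list, int n_ind, int n_perm) {
  const int n_chrom = pos_list.size();
  const int n_seg = seg_ind.size();

  // index segments by (chromosome, individual) once
  std::vector<std::vector<std::vector<int> > > by(n_chrom,
      std::vector<std::vector<int> >(n_ind));
  for (int s = 0; s < n_seg; ++s) {
    if (seg_len[s] > chrom_len[seg_chrom[s]])
      stop("segment longer than its chromosome");
    by[seg_chrom[s]][seg_ind[s]].push_back(s);
  }

  std::vector<std::vector<int> > diff(n_chrom);
  for (int c = 0; c < n_chrom; ++c)
    diff[c].assign(((NumericVector)pos_list[c]).size() + 1, 0);

  NumericVector maxima(n_perm);
  std::vector<std::pair<double, double> > iv;
  for (int p = 0; p < n_perm; ++p) {
    int best = 0;
    for (int c = 0; c < n_chrom; ++c) {
      NumericVector pos = pos_list[c];
      const int ns = pos.size();
      if (ns == 0) continue;
      std::fill(diff[c].begin(), diff[c].end(), 0);
      const double L = chrom_len[c];
      for (int ind = 0; ind < n_ind; ++ind) {
        const std::vector<int>& segs = by[c][ind];
        if (segs.empty()) continue;
        iv.clear();
        for (size_t k = 0; k < segs.size(); ++k) {
          double len = seg_len[segs[k]];
          double st = std::floor(unif_rand() * (L - len + 1.0));
          if (st > L - len) st = L - len;  // guard the u == 1 edge
          iv.push_back(std::make_pair(st, st + len));
        }
        std::sort(iv.begin(), iv.end());
        double st = iv[0].first, en = iv[0].second;
        for (size_t k = 1; k < iv.size(); ++k) {
          if (iv[k].first <= en) en = std::max(en, iv[k].second);
          else { add_interval(pos, st, en, diff[c]); st = iv[k].first; en = iv[k].second; }
        }
        add_interval(pos, st, en, diff[c]);
      }
      int run = 0;
      for (int k = 0; k < ns; ++k) {
        run += diff[c][k];
        if (run > best) best = run;
      }
    }
    maxima[p] = (double)best / (double)n_ind;
  }
  return maxima;
}
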