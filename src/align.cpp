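// Seed-and-extend pairwise genome alignment with colinear chaining.
//
// One call aligns one target chromosome against one query sequence on one
// strand: exact k-mer seeds (N-free, occurrence-capped, soft-masked on the
// target), per-diagonal seed merging, ungapped x-drop extension, then
// sparse chaining of the extended segments with affine gap costs.  Chain
// blocks are trimmed so they are non-overlapping on both genomes, and the
// chain score equals the sum of block scores minus gap penalties.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1;
  case 'G': return 2; case 'T': return 3;
  default: return -1;  // N or other: never a match
  }
}

struct Seg {            // ungapped extended segment
  int ts, te, qs, qe;   // 0-based inclusive
  int score;
};

struct Chain {
  std::vector<int> segs;
  long long score;
};

// [[Rcpp::export(name = ".align_strand_cpp")]]
List align_strand_cpp(std::string target, std::string query,
                      int k, int match, int mismatch,
                      int gap_open, int gap_extend, int xdrop,
                      int min_chain_score, int max_occ,
                      IntegerVector mask_start, IntegerVector mask_end) {
  const int tn = (int) target.size(), qn = (int) query.size();
  List empty = List::create(Named("ts") = IntegerVector(0));
  if (tn < k || qn < k) return empty;

  // target mask (0-based inclusive intervals): seeds are not taken from
  // masked positions, but extension may run through them
  std::vector<char> masked(tn, 0);
  for (int i = 0; i < mask_start.size(); ++i) {
    int a = std::max(0, mask_start[i]), b = std::min(tn - 1, mask_end[i]);
    for (int p = a; p <= b; ++p) masked[p] = 1;
  }

  // pre-encode both sequences (A/C/G/T -> 0..3, other -> -1)
  std::vector<int8_t> tc_(tn), qc_(qn);
  for (int i = 0; i < tn; ++i) tc_[i] = (int8_t) code(target[(size_t) i]);
  for (int j = 0; j < qn; ++j) qc_[j] = (int8_t) code(query[(size_t) j]);

  // --- index target k-mers (direct-addressed, counting sort) ---------------
  if (k > 13) stop("seed length k > 13 is not supported");
  const uint32_t kmask = (1u << (2 * k)) - 1u;
  const size_t nslot = (size_t) kmask + 1;
  std::vector<int32_t> cnt(nslot + 1, 0);
  {
    uint32_t h = 0; int run = 0;
    for (int i = 0; i < tn; ++i) {
      int c = tc_[i];
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t) c) & kmask;
      if (++run >= k) {
        int pos = i - k + 1;
        if (!masked[pos]) ++cnt[h];
      }
    }
  }
  // occurrence ceiling, then prefix sums
  size_t total = 0;
  for (size_t s = 0; s < nslot; ++s) {
    if (cnt[s] > max_occ) cnt[s] = 0;
    total += (size_t) cnt[s];
  }
  std::vector<int32_t> off(nslot + 1, 0);
  for (size_t s = 0; s < nslot; ++s) off[s + 1] = off[s] + cnt[s];
  std::vector<int32_t> posv(total);
  {
    std::vector<int32_t> fill(off.begin(), off.end() - 1);
    uint32_t h = 0; int run = 0;
    for (int i = 0; i < tn; ++i) {
      int c = tc_[i];
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t) c) & kmask;
      if (++run >= k) {
        int pos = i - k + 1;
        if (!masked[pos] && cnt[h] > 0) posv[fill[h]++] = pos;
      }
    }
  }

  // --- collect seeds, bucketed by diagonal ---------------------------------
  // seed = (diag = tpos - qpos, qpos)
  std::vector<std::pair<int, int>> seeds;
  {
    uint32_t h = 0; int run = 0;
    for (int j = 0; j < qn; ++j) {
      int c = qc_[j];
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t) c) & kmask;
      if (++run >= k) {
        int qpos = j - k + 1;
        for (int32_t s = off[h]; s < off[h + 1]; ++s) {
          seeds.emplace_back(posv[s] - qpos, qpos);
        }
      }
    }
  }
  if (seeds.empty()) return empty;
  std::sort(seeds.begin(), seeds.end());

  // --- merge same-diagonal runs, x-drop extend -----------------------------
  std::vector<Seg> segs;
  size_t i0 = 0;
  while (i0 < seeds.size()) {
    int diag = seeds[i0].first;
    size_t i1 = i0;
    int ext_upto = -1;  // query position already covered by an extension
    while (i1 < seeds.size() && seeds[i1].first == diag) {
      // merge contiguous/overlapping seeds on this diagonal
      int qs = seeds[i1].second, qe = qs + k - 1;
      size_t i2 = i1 + 1;
      while (i2 < seeds.size() && seeds[i2].first == diag &&
             seeds[i2].second <= qe + 1) {
        qe = std::max(qe, seeds[i2].second + k - 1);
        ++i2;
      }
      if (qe > ext_upto) {
        // x-drop extension of [qs,qe] along this diagonal
        int ts = qs + diag;
        int sc = 0;
        for (int p = qs; p <= qe; ++p) {
          int ct = tc_[p + diag], cq = qc_[p];
          sc += (ct >= 0 && ct == cq) ? match : -mismatch;
        }
        // right
        int best = sc, bq = qe, cur = sc;
        int p = qe + 1;
        while (p < qn && p + diag < tn) {
          int ct = tc_[p + diag], cq = qc_[p];
          cur += (ct >= 0 && ct == cq) ? match : -mismatch;
          if (cur > best) { best = cur; bq = p; }
          if (best - cur > xdrop) break;
          ++p;
        }
        int qe2 = bq; cur = best; sc = best;
        // left
        int bq2 = qs;
        p = qs - 1;
        while (p >= 0 && p + diag >= 0) {
          int ct = tc_[p + diag], cq = qc_[p];
          cur += (ct >= 0 && ct == cq) ? match : -mismatch;
          if (cur > sc) { sc = cur; bq2 = p; }
          if (sc - cur > xdrop) break;
          --p;
        }
        Seg s;
        s.qs = bq2; s.qe = qe2; s.ts = bq2 + diag; s.te = qe2 + diag;
        s.score = sc;
        // chance seed matches extend to ~k + a few; only segments clearly
        // above that can participate in chaining
        if (s.score >= 2 * k * match) segs.push_back(s);
        ext_upto = qe2;
      }
      i1 = i2;
    }
    i0 = i1;
  }
  if (segs.empty()) return empty;

  // --- chaining ------------------------------------------------------------
  std::sort(segs.begin(), segs.end(),
            [](const Seg &a, const Seg &b) {
              return a.ts != b.ts ? a.ts < b.ts : a.qs < b.qs;
            });
  const int n = (int) segs.size();
  const int lookback = 512;
  const int max_dist = 30000;
  std::vector<long long> dp(n);
  std::vector<int> pred(n, -1);
  for (int i = 0; i < n; ++i) {
    dp[i] = segs[i].score;
    for (int j = i - 1; j >= 0 && j >= i - lookback; --j) {
      if (segs[j].te >= segs[i].te || segs[j].qe >= segs[i].qe) continue;
      if (segs[j].ts >= segs[i].ts || segs[j].qs >= segs[i].qs) continue;
      long long dt = (long long) segs[i].ts - segs[j].te - 1;
      long long dq = (long long) segs[i].qs - segs[j].qe - 1;
      if (dt > max_dist || dq > max_dist) continue;
      long long ov = std::max(0LL, std::max(-dt, -dq));
      long long gap = std::llabs(dt - dq);
      long long cost = (gap > 0 ? gap_open + gap_extend * gap : 0) +
        ov * match;
      long long cand = dp[j] + segs[i].score - cost;
      if (cand > dp[i]) { dp[i] = cand; pred[i] = j; }
    }
  }

  // --- extract chains greedily by score ------------------------------------
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return dp[a] > dp[b]; });
  std::vector<char> used(n, 0);
  std::vector<Chain> chains;
  for (int oi : order) {
    if (used[oi] || dp[oi] < min_chain_score) continue;
    // walk back; stop if we hit a used segment
    std::vector<int> path;
    int cur = oi;
    while (cur >= 0 && !used[cur]) { path.push_back(cur); cur = pred[cur]; }
    std::reverse(path.begin(), path.end());
    // recompute score for the (possibly truncated) path
    long long sc = 0;
    for (size_t pi = 0; pi < path.size(); ++pi) {
      sc += segs[path[pi]].score;
      if (pi > 0) {
        const Seg &a = segs[path[pi - 1]], &b = segs[path[pi]];
        long long dt = (long long) b.ts - a.te - 1;
        long long dq = (long long) b.qs - a.qe - 1;
        long long ov = std::max(0LL, std::max(-dt, -dq));
        long long gap = std::llabs(dt - dq);
        sc -= (gap > 0 ? gap_open + gap_extend * gap : 0) + ov * match;
      }
    }
    if (sc < min_chain_score) continue;
    for (int s : path) used[s] = 1;
    Chain c; c.segs = path; c.score = sc;
    chains.push_back(c);
  }

  // --- emit, trimming block overlaps ---------------------------------------
  int nc = (int) chains.size();
  IntegerVector c_ts(nc), c_te(nc), c_qs(nc), c_qe(nc);
  NumericVector c_score(nc);
  List c_blocks(nc);
  for (int ci = 0; ci < nc; ++ci) {
    const Chain &c = chains[ci];
    int nb = (int) c.segs.size();
    std::vector<int> bts(nb), bte(nb), bqs(nb), bqe(nb);
    int prev_te = -1, prev_qe = -1;
    int m = 0;
    for (int bi = 0; bi < nb; ++bi) {
      Seg s = segs[c.segs[bi]];
      int trim = std::max(std::max(prev_te - s.ts + 1, prev_qe - s.qs + 1), 0);
      s.ts += trim; s.qs += trim;
      if (s.ts > s.te || s.qs > s.qe) continue;
      bts[m] = s.ts; bte[m] = s.te; bqs[m] = s.qs; bqe[m] = s.qe;
      prev_te = s.te; prev_qe = s.qe;
      ++m;
    }
    IntegerMatrix bl(m, 4);
    for (int bi = 0; bi < m; ++bi) {
      bl(bi, 0) = bts[bi]; bl(bi, 1) = bte[bi];
      bl(bi, 2) = bqs[bi]; bl(bi, 3) = bqe[bi];
    }
    c_blocks[ci] = bl;
    c_ts[ci] = bts[0]; c_te[ci] = prev_te;
    c_qs[ci] = bqs[0]; c_qe[ci] = prev_qe;
    c_score[ci] = (double) c.score;
  }
  return List::create(Named("ts") = c_ts, Named("te") = c_te,
                      Named("qs") = c_qs, Named("qe") = c_qe,
                      Named("score") = c_score, Named("blocks") = c_blocks);
}
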