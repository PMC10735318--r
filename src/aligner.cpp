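// Local alignment engine: exact affine-gap Waterman-Eggert for small
// sequence pairs, and a seed-and-extend path (exact-match seeds, X-drop
// ungapped extension, windowed gapped refinement) for genome-scale targets.
// Coordinates are 0-based half-open here; the R wrappers convert.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <climits>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

const int NEG = -1000000000;

std::vector<uint8_t> encode(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
    case 'A': case 'a': v[i] = 0; break;
    case 'C': case 'c': v[i] = 1; break;
    case 'G': case 'g': v[i] = 2; break;
    case 'T': case 't': v[i] = 3; break;
    default: v[i] = 4;  // N or anything else: scored as worst mismatch
    }
  }
  return v;
}

struct Sub {
  int s[5][5];
  explicit Sub(const IntegerMatrix &m) {
    for (int i = 0; i < 5; ++i)
      for (int j = 0; j < 5; ++j) s[i][j] = m(i, j);
  }
};

struct Hit {
  int score, qs, qe, ts, te;  // 0-based half-open
  std::vector<std::array<int, 4>> blocks;  // gap-free blocks, ascending query
};

// Full Waterman-Eggert style search: repeatedly find the best local
// alignment, report it, forbid its aligned pairs, and re-run until the
// score drops below min_score.  Exact for affine gaps.
void waterman_eggert_core(const std::vector<uint8_t> &Q,
                          const std::vector<uint8_t> &T, const Sub &S,
                          int go, int ge, bool gapped, int min_score,
                          int max_hits, std::vector<Hit> &out) {
  const int n = (int)Q.size(), m = (int)T.size();
  if (n == 0 || m == 0) return;
  const size_t cells = (size_t)(n + 1) * (size_t)(m + 1);
  std::vector<int> H(cells);
  std::vector<uint8_t> trH(cells), trE(cells), trF(cells);
  std::vector<uint8_t> forbidden((size_t)n * (size_t)m, 0);
  std::vector<int> Fcol(m + 1);

  for (int round = 0; round < max_hits; ++round) {
    std::fill(H.begin(), H.end(), 0);
    std::fill(Fcol.begin(), Fcol.end(), NEG);
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
      const uint8_t qi = Q[i - 1];
      int eloc = NEG;
      const size_t row = (size_t)i * (m + 1), prow = (size_t)(i - 1) * (m + 1);
      for (int j = 1; j <= m; ++j) {
        int fv = NEG, ev = NEG;
        if (gapped) {
          const int up = H[prow + j];
          const int fExt = Fcol[j] + ge, fOpen = up + go + ge;
          fv = std::max(fExt, fOpen);
          trF[row + j] = fExt >= fOpen ? 1 : 0;
          Fcol[j] = fv;
          const int hprev = H[row + j - 1];
          const int eExt = eloc + ge, eOpen = hprev + go + ge;
          ev = std::max(eExt, eOpen);
          trE[row + j] = eExt >= eOpen ? 1 : 0;
          eloc = ev;
        }
        int diag = NEG;
        if (!forbidden[(size_t)(i - 1) * m + (j - 1)])
          diag = H[prow + j - 1] + S.s[qi][T[j - 1]];
        int h = 0; uint8_t tr = 0;
        if (diag > h) { h = diag; tr = 1; }
        if (gapped) {
          if (ev > h) { h = ev; tr = 2; }
          if (fv > h) { h = fv; tr = 3; }
        }
        H[row + j] = h;
        trH[row + j] = tr;
        if (h > best || (h == best && 0)) { /* ties: first (smaller i,j) kept */ }
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (best < min_score) break;

    // traceback from (bi, bj), state H
    std::vector<std::array<int, 2>> pairs;  // aligned (qi, tj), 0-based
    int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
    while (i > 0 && j > 0) {
      const size_t idx = (size_t)i * (m + 1) + j;
      if (state == 0) {
        const uint8_t tr = trH[idx];
        if (tr == 0) break;
        if (tr == 1) {
          pairs.push_back({i - 1, j - 1});
          forbidden[(size_t)(i - 1) * m + (j - 1)] = 1;
          --i; --j;
        } else if (tr == 2) state = 1;
        else state = 2;
      } else if (state == 1) {  // E: gap consuming target, move left
        if (trE[idx] == 0) state = 0;
        --j;
      } else {  // F: gap consuming query, move up
        if (trF[idx] == 0) state = 0;
        --i;
      }
    }
    if (pairs.empty()) break;  // safety; should not happen
    std::reverse(pairs.begin(), pairs.end());

    Hit h;
    h.score = best;
    h.qs = pairs.front()[0]; h.qe = pairs.back()[0] + 1;
    h.ts = pairs.front()[1]; h.te = pairs.back()[1] + 1;
    int bqs = pairs[0][0], bts = pairs[0][1];
    int pq = bqs, pt = bts;
    for (size_t k = 1; k < pairs.size(); ++k) {
      if (pairs[k][0] == pq + 1 && pairs[k][1] == pt + 1) {
        pq = pairs[k][0]; pt = pairs[k][1];
      } else {
        h.blocks.push_back({bqs, pq + 1, bts, pt + 1});
        bqs = pq = pairs[k][0];
        bts = pt = pairs[k][1];
      }
    }
    h.blocks.push_back({bqs, pq + 1, bts, pt + 1});
    out.push_back(std::move(h));
  }
}

// overlap on both sides (hits assumed same strand frame)
bool overlaps_both(const Hit &a, const Hit &b) {
  return a.qs < b.qe && b.qs < a.qe && a.ts < b.te && b.ts < a.te;
}

// keep higher score; ties broken by smaller target start
void dedupe_hits(std::vector<Hit> &hits) {
  std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.ts != b.ts) return a.ts < b.ts;
    return a.qs < b.qs;
  });
  std::vector<Hit> kept;
  for (auto &h : hits) {
    bool dup = false;
    for (auto &k : kept)
      if (overlaps_both(h, k)) { dup = true; break; }
    if (!dup) kept.push_back(std::move(h));
  }
  hits.swap(kept);
}

List hits_to_list(const std::vector<Hit> &hits, const std::vector<int> &qidx) {
  const int nh = (int)hits.size();
  IntegerVector qi(nh), sc(nh), qs(nh), qe(nh), ts(nh), te(nh);
  List blocks(nh);
  for (int k = 0; k < nh; ++k) {
    qi[k] = qidx[k];
    sc[k] = hits[k].score;
    qs[k] = hits[k].qs; qe[k] = hits[k].qe;
    ts[k] = hits[k].ts; te[k] = hits[k].te;
    const int nb = (int)hits[k].blocks.size();
    IntegerMatrix bm(nb, 4);
    for (int b = 0; b < nb; ++b)
      for (int c = 0; c < 4; ++c) bm(b, c) = hits[k].blocks[b][c];
    blocks[k] = bm;
  }
  return List::create(_["query"] = qi, _["score"] = sc, _["qs"] = qs,
                      _["qe"] = qe, _["ts"] = ts, _["te"] = te,
                      _["blocks"] = blocks);
}

}  // namespace

// [[Rcpp::export]]
int cpp_best_local_score(std::string q, std::string t, IntegerMatrix submat,
                         int gap_open, int gap_extend, bool gapped) {
  const std::vector<uint8_t> Q = encode(q), T = encode(t);
  const Sub S(submat);
  const int n = (int)Q.size(), m = (int)T.size();
  std::vector<int> H(m + 1, 0), F(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int diag = 0, hprev = 0, eloc = NEG;
    const uint8_t qi = Q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int up = H[j];
      int h = diag + S.s[qi][T[j - 1]];
      if (gapped) {
        F[j] = std::max(F[j] + gap_extend, up + gap_open + gap_extend);
        eloc = std::max(eloc + gap_extend, hprev + gap_open + gap_extend);
        h = std::max(h, std::max(eloc, F[j]));
      }
      if (h < 0) h = 0;
      if (h > best) best = h;
      diag = up; hprev = h; H[j] = h;
    }
  }
  return best;
}

// Score-only affine-gap local DP that reports the maximum of every
// positive-scoring excursion ("island") at or above floor_score.  Each
// cell carries the anchor (origin) of its excursion; per-anchor maxima
// are the island scores used for Gumbel lambda estimation.
// [[Rcpp::export]]
IntegerVector cpp_island_scores(std::string q, std::string t,
                                IntegerMatrix submat, int gap_open,
                                int gap_extend, bool gapped,
                                int floor_score) {
  const std::vector<uint8_t> Q = encode(q), T = encode(t);
  const Sub S(submat);
  const int n = (int)Q.size(), m = (int)T.size();
  std::vector<int> H(m + 1, 0), F(m + 1, NEG);
  std::vector<int> aH(m + 1, -1), aF(m + 1, -1);
  std::vector<int> amax;  // per-anchor island maximum
  for (int i = 1; i <= n; ++i) {
    const uint8_t qi = Q[i - 1];
    int diag = 0, adiag = -1;   // H[i-1][j-1] and its anchor
    int hprev = 0, aprev = -1;  // H[i][j-1] and its anchor
    int eloc = NEG, aE = -1;
    for (int j = 1; j <= m; ++j) {
      const int up = H[j], aup = aH[j];
      int h = diag + S.s[qi][T[j - 1]];
      int ah = adiag;
      if (gapped) {
        const int fExt = F[j] + gap_extend;
        const int fOpen = up + gap_open + gap_extend;
        if (fExt >= fOpen) F[j] = fExt;
        else { F[j] = fOpen; aF[j] = aup; }
        const int eExt = eloc + gap_extend;
        const int eOpen = hprev + gap_open + gap_extend;
        if (eExt >= eOpen) eloc = eExt;
        else { eloc = eOpen; aE = aprev; }
        if (eloc > h) { h = eloc; ah = aE; }
        if (F[j] > h) { h = F[j]; ah = aF[j]; }
      }
      if (h <= 0) { h = 0; ah = -1; }
      else if (ah < 0) { ah = (int)amax.size(); amax.push_back(0); }
      if (ah >= 0 && h > amax[ah]) amax[ah] = h;
      diag = up; adiag = aup;
      hprev = h; aprev = ah;
      H[j] = h; aH[j] = ah;
    }
  }
  std::vector<int> out;
  for (int v : amax) if (v >= floor_score) out.push_back(v);
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_waterman_eggert(std::string q, std::string t, IntegerMatrix submat,
                         int gap_open, int gap_extend, int min_score,
                         int max_hits, bool gapped) {
  const std::vector<uint8_t> Q = encode(q), T = encode(t);
  if ((double)(Q.size() + 1) * (double)(T.size() + 1) > 3.2e7)
    stop("sequence pair too large for exact mode");
  const Sub S(submat);
  std::vector<Hit> hits;
  waterman_eggert_core(Q, T, S, gap_open, gap_extend, gapped, min_score,
                       max_hits, hits);
  dedupe_hits(hits);
  std::vector<int> qidx(hits.size(), 0);
  return hits_to_list(hits, qidx);
}

// [[Rcpp::export]]
List cpp_seed_align(List queries, std::string target, IntegerMatrix submat,
                    int gap_open, int gap_extend, int min_score, int seed_len,
                    int x_drop, bool gapped, int max_hits_per_window,
                    int trigger) {
  if (seed_len < 4 || seed_len > 13) stop("seed_len must be in [4, 13]");
  // ungapped candidate floor: gapped alignments above min_score whose
  // individual gap-free segments all fall below min_score are recovered
  // by window refinement as long as one segment reaches the trigger
  if (trigger <= 0 || trigger > min_score) trigger = min_score;
  if (!gapped) trigger = min_score;
  const Sub S(submat);
  const std::vector<uint8_t> T = encode(target);
  const int m = (int)T.size();
  const int K = seed_len;
  const uint32_t nk = 1u << (2 * K);
  const uint32_t mask = nk - 1;

  // counting-sort index of target k-mer positions (k-mers with N skipped)
  std::vector<int> cnt(nk + 1, 0);
  {
    uint32_t code = 0; int run = 0;
    for (int j = 0; j < m; ++j) {
      if (T[j] > 3) { run = 0; code = 0; continue; }
      code = ((code << 2) | T[j]) & mask;
      if (++run >= K) cnt[code + 1]++;
    }
  }
  for (uint32_t c = 0; c < nk; ++c) cnt[c + 1] += cnt[c];
  std::vector<int> pos(cnt[nk]);
  {
    std::vector<int> fill(cnt.begin(), cnt.end() - 1);
    uint32_t code = 0; int run = 0;
    for (int j = 0; j < m; ++j) {
      if (T[j] > 3) { run = 0; code = 0; continue; }
      code = ((code << 2) | T[j]) & mask;
      if (++run >= K) pos[fill[code]++] = j - K + 1;
    }
  }

  std::vector<Hit> all_hits;
  std::vector<int> all_qidx;

  for (int qi = 0; qi < queries.size(); ++qi) {
    const std::vector<uint8_t> Q = encode(as<std::string>(queries[qi]));
    const int n = (int)Q.size();
    std::vector<Hit> cands;
    // per-diagonal state, indexed by tpos - qpos + n; covered target end
    // and last seed tpos interleaved to share a cache line
    std::vector<std::array<int, 2>> dstate(n + m + 1, {0, INT_MIN});
    const int two_hit_window = 64;
    const int long_extra = 4;  // lone exact runs of K + long_extra fire too

    uint32_t code = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      if (Q[i] > 3) { run = 0; code = 0; continue; }
      code = ((code << 2) | Q[i]) & mask;
      if (++run < K) continue;
      const int qpos = i - K + 1;
      for (int p = cnt[code]; p < cnt[code + 1]; ++p) {
        const int tpos = pos[p];
        const int d0 = tpos - qpos + n;
        int &cov = dstate[d0][0];
        const int prev = dstate[d0][1];
        dstate[d0][1] = tpos;
        if (tpos + K <= cov) continue;
        // two-hit rule: extension needs a second non-overlapping seed on
        // the same diagonal within the pairing window; a single exact run
        // of K + long_extra also fires so lone long matches are not lost
        bool fire = prev != INT_MIN && tpos - prev >= K &&
                    tpos - prev <= two_hit_window;
        if (!fire && qpos >= long_extra && tpos >= long_extra) {
          fire = true;
          for (int d = 1; d <= long_extra; ++d)
            if (Q[qpos - d] > 3 || Q[qpos - d] != T[tpos - d]) {
              fire = false; break;
            }
        }
        if (!fire) continue;

        // ungapped X-drop extension around the exact-match seed
        int seedsc = 0;
        for (int k = 0; k < K; ++k) seedsc += S.s[Q[qpos + k]][T[tpos + k]];
        int bestl = 0, runsc = 0, ls = qpos, lt = tpos;
        for (int a = qpos - 1, b = tpos - 1; a >= 0 && b >= 0; --a, --b) {
          runsc += S.s[Q[a]][T[b]];
          if (runsc > bestl) { bestl = runsc; ls = a; lt = b; }
          if (runsc <= bestl - x_drop) break;
        }
        int bestr = 0, le = qpos + K, te = tpos + K;
        runsc = 0;
        for (int a = qpos + K, b = tpos + K; a < n && b < m; ++a, ++b) {
          runsc += S.s[Q[a]][T[b]];
          if (runsc > bestr) { bestr = runsc; le = a + 1; te = b + 1; }
          if (runsc <= bestr - x_drop) break;
        }
        const int total = seedsc + bestl + bestr;
        // a failed extension must only cover its own seed: marking the
        // full extent would hide a high-scoring island that this seed
        // merely bridged into at a net loss
        cov = std::max(cov, total >= trigger ? te : tpos + K);
        if (total >= trigger) {
          Hit h;
          h.score = total; h.qs = ls; h.qe = le; h.ts = lt; h.te = te;
          h.blocks.push_back({ls, le, lt, te});
          cands.push_back(std::move(h));
        }
      }
    }

    if (cands.empty()) continue;

    if (!gapped) {
      dedupe_hits(cands);
      for (auto &h : cands) { all_hits.push_back(std::move(h)); all_qidx.push_back(qi); }
      continue;
    }

    // merge nearby candidate segments into refinement windows, then run the
    // exact engine inside each window to pick up gapped structure
    std::sort(cands.begin(), cands.end(),
              [](const Hit &a, const Hit &b) { return a.qs < b.qs; });
    const int margin = std::max(x_drop, 30);
    std::vector<Hit> refined;
    size_t w = 0;
    while (w < cands.size()) {
      int qs = cands[w].qs, qe = cands[w].qe, ts = cands[w].ts, te = cands[w].te;
      size_t w2 = w + 1;
      while (w2 < cands.size() && cands[w2].qs <= qe + margin &&
             cands[w2].ts <= te + margin && cands[w2].te + margin >= ts) {
        qe = std::max(qe, cands[w2].qe);
        te = std::max(te, cands[w2].te);
        ts = std::min(ts, cands[w2].ts);
        ++w2;
      }
      const int wqs = std::max(0, qs - margin), wqe = std::min(n, qe + margin);
      const int wts = std::max(0, ts - margin), wte = std::min(m, te + margin);
      if ((double)(wqe - wqs + 1) * (double)(wte - wts + 1) > 4e6) {
        for (size_t k = w; k < w2; ++k)
          if (cands[k].score >= min_score) refined.push_back(cands[k]);
      } else {
        std::vector<uint8_t> wq(Q.begin() + wqs, Q.begin() + wqe);
        std::vector<uint8_t> wt(T.begin() + wts, T.begin() + wte);
        std::vector<Hit> wh;
        waterman_eggert_core(wq, wt, S, gap_open, gap_extend, true, min_score,
                             max_hits_per_window, wh);
        for (auto &h : wh) {
          h.qs += wqs; h.qe += wqs; h.ts += wts; h.te += wts;
          for (auto &b : h.blocks) { b[0] += wqs; b[1] += wqs; b[2] += wts; b[3] += wts; }
          refined.push_back(std::move(h));
        }
      }
      w = w2;
    }
    dedupe_hits(refined);
    for (auto &h : refined) { all_hits.push_back(std::move(h)); all_qidx.push_back(qi); }
  }

  return hits_to_list(all_hits, all_qidx);
}
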