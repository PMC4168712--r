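#include "core.h"
#include <algorithm>

using namespace Rcpp;

// Greedy maximal seed extraction, right to left.
// Each iteration probes the rightmost uncovered k-window left-to-right;
// on full match the seed is extended maximally leftward and every located
// occurrence (up to P; junction-rejected hits do not count) is emitted.
// On partial match the unmatched right tail is skipped entirely: any seed
// containing it would fail too.
void seed_read(const FMView& f, const std::vector<int>& q, int k, int P,
               std::vector<Seed>& out) {
  int R = (int)q.size();
  if (R == 0) return;
  int kk = std::min(k, R);
  int right = R - 1;
  while (right >= kk - 1) {
    int s = right - kk + 1;
    int matched = match_lr(f, q, s, kk);
    if (matched < kk) {
      right = right - kk + matched;
      continue;
    }
    MatchRL m = match_rl(f, q, right, LLONG_MAX / 2);
    int cnt = 0;
    for (long long row = m.b; row <= m.e && cnt < P; ++row) {
      int seqid, strand; long long gpos;
      if (!fm_locate(f, row, m.matched, seqid, gpos, strand)) continue;
      out.push_back(Seed{right - m.matched + 1, m.matched, gpos, strand, seqid});
      ++cnt;
    }
    right = right - m.matched + kk - 1;
  }
}

// [[Rcpp::export]]
DataFrame cpp_extract_seeds(List idx, std::string read, int k, int P) {
  FMView f = make_view(idx);
  std::vector<int> q = encode_query(read);
  std::vector<Seed> hits;
  seed_read(f, q, k, P, hits);
  int R = (int)q.size();
  int nh = (int)hits.size();
  IntegerVector rpos0(nh), len(nh), seqid(nh), rpos_aligned0(nh);
  NumericVector gpos0(nh), est0(nh);
  CharacterVector strand(nh);
  for (int i = 0; i < nh; ++i) {
    const Seed& s = hits[i];
    rpos0[i] = s.rpos;
    len[i] = s.len;
    gpos0[i] = (double)s.gpos;
    seqid[i] = s.seqid + 1;
    strand[i] = s.strand == 0 ? "+" : "-";
    int ra = s.strand == 0 ? s.rpos : R - s.rpos - s.len;
    rpos_aligned0[i] = ra;
    double est = (double)s.gpos - ra;
    est0[i] = est < 0 ? 0 : est;
  }
  return DataFrame::create(
    _["read_offset0"] = rpos0, _["length"] = len, _["gpos0"] = gpos0,
    _["strand"] = strand, _["seqid"] = seqid,
    _["read_offset_aligned0"] = rpos_aligned0, _["est_start0"] = est0,
    _["stringsAsFactors"] = false);
}

// ---- banded gap alignment in (i, offset) coordinates ---------------------
// Cell (i, off) = min edits aligning read[0, i) with ref[0, i + off),
// |off| <= d - 1. Unit costs; indicator cost on the diagonal move.
static const int DP_INF = INT_MAX / 4;

GapAln band_align(const uint8_t* ref, int rlen, const int* read, int mlen,
                  int d, int mode) {
  if (mode == GAP_FREE_REF_START) {
    // free start on the reference == free end with both sequences reversed
    std::vector<uint8_t> rr(ref, ref + rlen);
    std::vector<int> rq(read, read + mlen);
    std::reverse(rr.begin(), rr.end());
    std::reverse(rq.begin(), rq.end());
    GapAln a = band_align(rr.data(), rlen, rq.data(), mlen, d, GAP_FREE_REF_END);
    std::reverse(a.ops.begin(), a.ops.end());
    return a;
  }

  int W = 2 * d - 1; // offsets -(d-1) .. +(d-1)
  GapAln res{false, 0, 0, ""};
  if (mode == GAP_GLOBAL && std::abs(rlen - mlen) > d - 1) return res;

  std::vector<int> D((size_t)(mlen + 1) * W, DP_INF);
  auto at = [&](int i, int off) -> int& {
    return D[(size_t)i * W + (off + d - 1)];
  };
  for (int off = 0; off <= std::min(d - 1, rlen); ++off) at(0, off) = off;
  for (int i = 1; i <= mlen; ++i) {
    for (int off = -(d - 1); off <= d - 1; ++off) {
      int rp = i + off; // ref prefix consumed at this cell
      if (rp < 0 || rp > rlen) continue;
      int best = DP_INF;
      // diagonal: consume one read and one ref base
      if (rp >= 1 && at(i - 1, off) < DP_INF) {
        int cost = (ref[rp - 1] == (uint8_t)read[i - 1] &&
                    read[i - 1] >= 1 && read[i - 1] <= 4) ? 0 : 1;
        best = std::min(best, at(i - 1, off) + cost);
      }
      // insertion (read base only): offset decreases, from off + 1
      if (off + 1 <= d - 1 && at(i - 1, off + 1) < DP_INF)
        best = std::min(best, at(i - 1, off + 1) + 1);
      // deletion (ref base only): from off - 1, same row
      if (off - 1 >= -(d - 1) && rp >= 1 && at(i, off - 1) < DP_INF)
        best = std::min(best, at(i, off - 1) + 1);
      at(i, off) = best;
    }
  }

  int end_off;
  if (mode == GAP_GLOBAL) {
    end_off = rlen - mlen;
    if (at(mlen, end_off) >= DP_INF) return res;
  } else { // GAP_FREE_REF_END: trailing reference is unpenalized
    end_off = 0;
    int best = DP_INF;
    for (int off = -(d - 1); off <= d - 1; ++off) {
      int rp = mlen + off;
      if (rp < 0 || rp > rlen) continue;
      if (at(mlen, off) < best) { best = at(mlen, off); end_off = off; }
    }
    if (best >= DP_INF) return res;
  }

  // traceback (M preferred, then D, then I: deterministic)
  std::string ops;
  int i = mlen, off = end_off;
  while (i > 0 || off > 0) {
    int rp = i + off;
    int cur = at(i, off);
    if (i > 0 && rp >= 1 && at(i - 1, off) < DP_INF) {
      int cost = (ref[rp - 1] == (uint8_t)read[i - 1] &&
                  read[i - 1] >= 1 && read[i - 1] <= 4) ? 0 : 1;
      if (cur == at(i - 1, off) + cost) { ops.push_back('M'); --i; continue; }
    }
    if (off - 1 >= -(d - 1) && rp >= 1 && at(i, off - 1) < DP_INF &&
        cur == at(i, off - 1) + 1) { ops.push_back('D'); --off; continue; }
    if (i > 0 && off + 1 <= d - 1 && at(i - 1, off + 1) < DP_INF &&
        cur == at(i - 1, off + 1) + 1) { ops.push_back('I'); --i; ++off; continue; }
    Rcpp::stop("internal error: banded DP traceback failed");
  }
  std::reverse(ops.begin(), ops.end());
  res.ok = true;
  res.dist = at(mlen, end_off);
  res.ref_consumed = mlen + end_off;
  res.ops = ops;
  return res;
}

// [[Rcpp::export]]
List cpp_band_align(std::string ref_gap, std::string read_gap, int d,
                    int mode) {
  if (d < 1) stop("d must be >= 1");
  std::vector<uint8_t> r(ref_gap.size());
  for (size_t i = 0; i < ref_gap.size(); ++i) r[i] = (uint8_t)code_base(ref_gap[i]);
  std::vector<int> q = encode_query(read_gap);
  GapAln a = band_align(r.data(), (int)r.size(), q.data(), (int)q.size(),
                        d, mode);
  if (!a.ok)
    return List::create(_["feasible"] = false);
  return List::create(_["feasible"] = true, _["distance"] = a.dist,
                      _["ref_consumed"] = a.ref_consumed, _["ops"] = a.ops);
}

// ---- anchor chain --------------------------------------------------------
// Greedy by descending seed length (ties: leftmost read position, then
// leftmost genome position); a seed is accepted iff collinear with and
// disjoint from every accepted seed, and its diagonal offset differs by
// < d from its adjacent accepted neighbors in read order.
std::vector<int> anchor_chain(const std::vector<SeedInfo>& seeds, int d) {
  int n = (int)seeds.size();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (seeds[a].len != seeds[b].len) return seeds[a].len > seeds[b].len;
    if (seeds[a].rpos != seeds[b].rpos) return seeds[a].rpos < seeds[b].rpos;
    return seeds[a].gpos < seeds[b].gpos;
  });
  std::vector<int> acc; // kept sorted by rpos
  for (int id : order) {
    const SeedInfo& s = seeds[id];
    bool okall = true;
    for (int j : acc) {
      const SeedInfo& t = seeds[j];
      bool s_left_read = s.rpos + s.len <= t.rpos;
      bool s_right_read = t.rpos + t.len <= s.rpos;
      bool s_left_gen = s.gpos + s.len <= t.gpos;
      bool s_right_gen = t.gpos + t.len <= s.gpos;
      bool disjoint = (s_left_read || s_right_read) && (s_left_gen || s_right_gen);
      bool collinear = (s_left_read && s_left_gen) || (s_right_read && s_right_gen);
      if (!disjoint || !collinear) { okall = false; break; }
    }
    if (!okall) continue;
    // offset constraint vs adjacent accepted neighbors in read order
    long long off = s.gpos - s.rpos;
    auto it = std::lower_bound(acc.begin(), acc.end(), id, [&](int a, int b) {
      return seeds[a].rpos < seeds[b].rpos;
    });
    bool okoff = true;
    if (it != acc.begin()) {
      const SeedInfo& p = seeds[*(it - 1)];
      if (std::llabs(off - (p.gpos - p.rpos)) >= d) okoff = false;
    }
    if (okoff && it != acc.end()) {
      const SeedInfo& nx = seeds[*it];
      if (std::llabs(off - (nx.gpos - nx.rpos)) >= d) okoff = false;
    }
    if (!okoff) continue;
    acc.insert(it, id);
  }
  return acc;
}

// [[Rcpp::export]]
IntegerVector cpp_anchor_chain(IntegerVector rpos0, NumericVector gpos0,
                               IntegerVector len, int d) {
  int n = rpos0.size();
  std::vector<SeedInfo> seeds(n);
  for (int i = 0; i < n; ++i)
    seeds[i] = SeedInfo{len[i], rpos0[i], (long long)gpos0[i]};
  std::vector<int> ch = anchor_chain(seeds, d);
  IntegerVector out(ch.size());
  for (size_t i = 0; i < ch.size(); ++i) out[i] = ch[i] + 1;
  return out;
}

std::string cigar_string(const std::vector<CigOp>& cig) {
  std::string s;
  for (const CigOp& c : cig) {
    s += std::to_string(c.len);
    s.push_back(c.op);
  }
  return s;
}

static void push_op(std::vector<CigOp>& cig, char op, int len) {
  if (len <= 0) return;
  if (!cig.empty() && cig.back().op == op) cig.back().len += len;
  else cig.push_back(CigOp{op, len});
}

static void push_ops(std::vector<CigOp>& cig, const std::string& ops) {
  for (char o : ops) push_op(cig, o, 1);
}

// Align the (aligned-orientation) read against the candidate region of one
// tag record: anchors are fixed zero-cost M blocks, interior gaps aligned
// globally, flanks with the unused window end unpenalized. On an
// infeasible band the whole candidate is retried once with 2d.
static Candidate align_candidate_d(const FMView& f,
                                   const std::vector<int>& q,
                                   const TagSlot& slot, int e, int d) {
  Candidate res;
  res.ok = false;
  res.tag_score = slot.score;
  res.tag_id = slot.tag;
  res.strand = slot.strand;
  int R = (int)q.size();
  std::vector<int> ch = anchor_chain(slot.seeds, d);
  if (ch.empty()) return res;
  std::vector<SeedInfo> a;
  for (int i : ch) a.push_back(slot.seeds[i]);

  // locate sequence of the first anchor; all anchors must share it
  int seqid = -1;
  {
    int lo = 0, hi = f.nseq - 1;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if ((long long)f.starts[mid] <= a.front().gpos) { seqid = mid; lo = mid + 1; }
      else hi = mid - 1;
    }
  }
  long long S = f.starts[seqid];
  long long E = S + f.seqlen[seqid];
  for (const SeedInfo& s : a)
    if (s.gpos < S || s.gpos + s.len > E) return res;

  long long ws = a.front().gpos - a.front().rpos - e;
  if (ws < S) ws = S;
  long long last_gend = a.back().gpos + a.back().len;
  int last_rend = a.back().rpos + a.back().len;
  long long we = last_gend + (R - last_rend) + e;
  if (we > E) we = E;

  std::vector<CigOp> cig;
  int edit = 0;

  // left flank: read [0, r0) vs ref [ws, g0), reference start free
  {
    int mlen = a.front().rpos;
    long long g0 = a.front().gpos;
    int rlen = (int)(g0 - ws);
    GapAln g = band_align(f.text + ws, rlen, q.data(), mlen, d,
                          GAP_FREE_REF_START);
    if (!g.ok) return res;
    res.pos = g0 - g.ref_consumed;
    push_ops(cig, g.ops);
    edit += g.dist;
  }
  push_op(cig, 'M', a.front().len);

  for (size_t i = 1; i < a.size(); ++i) {
    const SeedInfo& p = a[i - 1];
    const SeedInfo& s = a[i];
    int rstart = p.rpos + p.len, rend = s.rpos;
    long long gstart = p.gpos + p.len, gend = s.gpos;
    GapAln g = band_align(f.text + gstart, (int)(gend - gstart),
                          q.data() + rstart, rend - rstart, d, GAP_GLOBAL);
    if (!g.ok) return res;
    push_ops(cig, g.ops);
    edit += g.dist;
    push_op(cig, 'M', s.len);
  }

  // right flank: read [last_rend, R) vs ref [last_gend, we), ref end free
  {
    int mlen = R - last_rend;
    int rlen = (int)(we - last_gend);
    GapAln g = band_align(f.text + last_gend, rlen, q.data() + last_rend,
                          mlen, d, GAP_FREE_REF_END);
    if (!g.ok) return res;
    push_ops(cig, g.ops);
    edit += g.dist;
  }

  res.ok = true;
  res.seqid = seqid;
  res.edit = edit;
  res.cigar = cig;
  return res;
}

Candidate align_candidate(const FMView& f, const std::vector<int>& q,
                          const TagSlot& slot, int e, int d) {
  Candidate c = align_candidate_d(f, q, slot, e, d);
  if (!c.ok) c = align_candidate_d(f, q, slot, e, 2 * d);
  return c;
}
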