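#include "core.h"
#include <algorithm>

using namespace Rcpp;

struct Params {
  std::vector<int> k_breaks; // ascending minimum read lengths
  std::vector<int> k_values;
  int c, P, t, e, d, capacity;
};

static Params params_from_list(const List& pl) {
  Params p;
  IntegerVector kb = pl["k_breaks"], kv = pl["k_values"];
  p.k_breaks.assign(kb.begin(), kb.end());
  p.k_values.assign(kv.begin(), kv.end());
  p.c = as<int>(pl["c"]);
  p.P = as<int>(pl["P"]);
  p.t = as<int>(pl["t"]);
  p.e = as<int>(pl["e"]);
  p.d = as<int>(pl["d"]);
  p.capacity = as<int>(pl["capacity"]);
  return p;
}

static int schedule_k(const Params& p, int R) {
  int k = p.k_values[0];
  for (size_t i = 0; i < p.k_breaks.size(); ++i)
    if (R >= p.k_breaks[i]) k = p.k_values[i];
  return k;
}

// candidate ranking: edit asc, tag score desc, coordinate asc, '+' first
static bool cand_before(const Candidate& a, const Candidate& b) {
  if (a.edit != b.edit) return a.edit < b.edit;
  if (a.tag_score != b.tag_score) return a.tag_score > b.tag_score;
  if (a.seqid != b.seqid) return a.seqid < b.seqid;
  if (a.pos != b.pos) return a.pos < b.pos;
  return a.strand < b.strand;
}

static int mapq_from(int R, int best_edit, bool has_runner, int runner_edit) {
  if (!has_runner) return 60;
  int sb = R - best_edit, sr = R - runner_edit;
  if (sb <= sr) return 0;
  int denom = sb > 1 ? sb : 1;
  int q = (int)(60.0 * (sb - sr) / denom);
  return q > 60 ? 60 : q;
}

// Phase 1 (seed + tag scoring) and phase 2 (candidate alignment) for one
// read; returns ranked feasible candidates (possibly empty).
static std::vector<Candidate> align_all(const FMView& f, TagTable& tt,
                                        const std::string& read,
                                        const Params& p) {
  std::vector<Candidate> out;
  int R = (int)read.size();
  if (R == 0) return out;
  std::vector<int> q = encode_query(read);
  std::vector<int> qrc(R);
  for (int i = 0; i < R; ++i) qrc[i] = comp_code(q[R - 1 - i]);

  tt.advance();
  int k = schedule_k(p, R);
  std::vector<Seed> hits;
  seed_read(f, q, k, p.P, hits);
  if (hits.empty()) return out;

  long long L = (long long)R * p.c;
  for (const Seed& s : hits) {
    int ra = s.strand == 0 ? s.rpos : R - s.rpos - s.len;
    long long est = s.gpos - ra;
    if (est < 0) est = 0;
    tt.grant(est / L, s.strand, s.len, ra, s.gpos);
  }

  for (const TagSlot* slot : tt.top()) {
    const std::vector<int>& qa = slot->strand == 0 ? q : qrc;
    Candidate c = align_candidate(f, qa, *slot, p.e, p.d);
    if (c.ok) out.push_back(c);
  }
  std::sort(out.begin(), out.end(), cand_before);
  return out;
}

struct SamOut {
  std::vector<int> flag, mapq, edit, seqid;
  std::vector<double> pos1;
  std::vector<std::string> cigar;
  void push(int fl, int sq, double p, int mq, const std::string& cg, int ed) {
    flag.push_back(fl); seqid.push_back(sq); pos1.push_back(p);
    mapq.push_back(mq); cigar.push_back(cg); edit.push_back(ed);
  }
  List as_list() const {
    return List::create(_["flag"] = flag, _["seqid"] = seqid,
                        _["pos"] = pos1, _["mapq"] = mapq,
                        _["cigar"] = cigar, _["edit"] = edit);
  }
};

static void emit_single(SamOut& o, const FMView& f,
                        const std::vector<Candidate>& cands, int R) {
  if (cands.empty()) {
    o.push(4, NA_INTEGER, NA_REAL, 0, "*", NA_INTEGER);
    return;
  }
  const Candidate& b = cands[0];
  bool has_runner = false;
  int runner_edit = 0;
  for (size_t i = 1; i < cands.size(); ++i) {
    if (cands[i].tag_id != b.tag_id || cands[i].strand != b.strand) {
      has_runner = true;
      runner_edit = cands[i].edit;
      break;
    }
  }
  int mq = mapq_from(R, b.edit, has_runner, runner_edit);
  int fl = b.strand == 1 ? 16 : 0;
  o.push(fl, b.seqid + 1, (double)(b.pos - f.starts[b.seqid]) + 1, mq,
         cigar_string(b.cigar), b.edit);
}

// [[Rcpp::export]]
List cpp_align_batch(List idx, CharacterVector reads, List params) {
  FMView f = make_view(idx);
  Params p = params_from_list(params);
  TagTable tt(p.capacity, p.t);
  SamOut o;
  for (int i = 0; i < reads.size(); ++i) {
    std::string rd = as<std::string>(reads[i]);
    std::vector<Candidate> cands = align_all(f, tt, rd, p);
    emit_single(o, f, cands, (int)rd.size());
  }
  return o.as_list();
}

static long long ref_span(const Candidate& c) {
  long long s = 0;
  for (const CigOp& op : c.cigar)
    if (op.op == 'M' || op.op == 'D') s += op.len;
  return s;
}

// [[Rcpp::export]]
List cpp_align_pairs(List idx, CharacterVector reads1, CharacterVector reads2,
                     List params, double min_insert, double max_insert) {
  if (reads1.size() != reads2.size()) stop("paired inputs differ in length");
  FMView f = make_view(idx);
  Params p = params_from_list(params);
  TagTable tt(p.capacity, p.t);
  SamOut o1, o2;
  std::vector<double> tlen1(reads1.size(), 0), tlen2(reads1.size(), 0);

  for (int i = 0; i < reads1.size(); ++i) {
    std::string r1 = as<std::string>(reads1[i]);
    std::string r2 = as<std::string>(reads2[i]);
    int R1 = (int)r1.size(), R2 = (int)r2.size();
    std::vector<Candidate> c1 = align_all(f, tt, r1, p);
    std::vector<Candidate> c2 = align_all(f, tt, r2, p);

    // enumerate FR cross pairs within the insert bounds
    int bi = -1, bj = -1;
    long long best_score = LLONG_MIN, best_left = LLONG_MAX;
    double best_dist = 0;
    for (size_t a = 0; a < c1.size(); ++a) {
      for (size_t b = 0; b < c2.size(); ++b) {
        const Candidate &x = c1[a], &y = c2[b];
        if (x.seqid != y.seqid || x.strand == y.strand) continue;
        const Candidate& fw = x.strand == 0 ? x : y;
        const Candidate& rv = x.strand == 0 ? y : x;
        if (fw.pos > rv.pos) continue; // FR: forward end upstream
        long long left = fw.pos;
        long long right = rv.pos + ref_span(rv);
        long long dist = right - left;
        if (dist < (long long)min_insert || dist > (long long)max_insert)
          continue;
        long long score = (long long)(R1 - x.edit) + (R2 - y.edit);
        if (score > best_score ||
            (score == best_score && left < best_left)) {
          best_score = score; best_left = left; best_dist = (double)dist;
          bi = (int)a; bj = (int)b;
        }
      }
    }

    auto emit_end = [&](SamOut& o, const std::vector<Candidate>& cs,
                        int pick, int R, int first, bool proper,
                        const Candidate* mate, bool mate_mapped) {
      int base = 1 | (first ? 64 : 128);
      if (cs.empty() || pick < 0) {
        int fl = base | 4 | (mate_mapped ? 0 : 8);
        if (mate_mapped && mate && mate->strand == 1) fl |= 32;
        o.push(fl, NA_INTEGER, NA_REAL, 0, "*", NA_INTEGER);
        return;
      }
      const Candidate& b = cs[pick];
      bool has_runner = false; int runner_edit = 0;
      for (size_t u = 0; u < cs.size(); ++u) {
        if ((int)u == pick) continue;
        if (cs[u].tag_id != b.tag_id || cs[u].strand != b.strand) {
          has_runner = true; runner_edit = cs[u].edit; break;
        }
      }
      int fl = base;
      if (proper) fl |= 2;
      if (b.strand == 1) fl |= 16;
      if (!mate_mapped) fl |= 8;
      else if (mate && mate->strand == 1) fl |= 32;
      o.push(fl, b.seqid + 1, (double)(b.pos - f.starts[b.seqid]) + 1,
             mapq_from(R, b.edit, has_runner, runner_edit),
             cigar_string(b.cigar), b.edit);
    };

    if (bi >= 0) {
      const Candidate &x = c1[bi], &y = c2[bj];
      emit_end(o1, c1, bi, R1, 1, true, &y, true);
      emit_end(o2, c2, bj, R2, 0, true, &x, true);
      double d1 = x.pos <= y.pos ? best_dist : -best_dist;
      if (x.pos == y.pos) d1 = best_dist; // leftmost-or-first gets +
      tlen1[i] = d1; tlen2[i] = -d1;
    } else {
      bool m1 = !c1.empty(), m2 = !c2.empty();
      emit_end(o1, c1, m1 ? 0 : -1, R1, 1, false,
               m2 ? &c2[0] : nullptr, m2);
      emit_end(o2, c2, m2 ? 0 : -1, R2, 0, false,
               m1 ? &c1[0] : nullptr, m1);
      tlen1[i] = 0; tlen2[i] = 0;
    }
  }
  return List::create(_["end1"] = o1.as_list(), _["end2"] = o2.as_list(),
                      _["tlen1"] = tlen1, _["tlen2"] = tlen2);
}

// Expose the mid-level per-candidate alignment for the module surface.
// seeds are aligned-orientation offsets (0-based) with global forward
// genome coordinates (0-based).
// [[Rcpp::export]]
List cpp_align_to_candidate(List idx, std::string read_aligned,
                            IntegerVector rpos0, NumericVector gpos0,
                            IntegerVector len, double tag_score,
                            double tag_id, int strand, int e, int d) {
  FMView f = make_view(idx);
  std::vector<int> q = encode_query(read_aligned);
  TagSlot slot;
  slot.tag = (long long)tag_id;
  slot.strand = strand;
  slot.serial = 1;
  slot.score = (long long)tag_score;
  for (int i = 0; i < rpos0.size(); ++i)
    slot.seeds.push_back(SeedInfo{len[i], rpos0[i], (long long)gpos0[i]});
  Candidate c = align_candidate(f, q, slot, e, d);
  if (!c.ok) return List::create(_["feasible"] = false);
  return List::create(
    _["feasible"] = true, _["seqid"] = c.seqid + 1,
    _["pos"] = (double)(c.pos - f.starts[c.seqid]) + 1,
    _["strand"] = c.strand == 0 ? "+" : "-",
    _["cigar"] = cigar_string(c.cigar), _["edit"] = c.edit,
    _["tag_score"] = (double)c.tag_score, _["tag_id"] = (double)c.tag_id);
}
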