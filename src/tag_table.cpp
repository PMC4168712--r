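#include "core.h"

using namespace Rcpp;

// Reset-free open-addressing table. Records carry the serial of the read
// that wrote them; a slot whose serial differs from the current one is
// treated as empty, so advancing the serial invalidates every record in
// O(1) without touching slot memory.

TagTable::TagTable(int capacity, int t) : cap_(capacity), t_(t), serial_(1) {
  if (capacity < 1 || (capacity & (capacity - 1)) != 0)
    Rcpp::stop("tag table capacity must be a power of two");
  if (t < 1) Rcpp::stop("t must be >= 1");
  slots_.resize(capacity);
  for (auto& s : slots_) s.serial = 0;
}

void TagTable::advance() {
  if (serial_ == LLONG_MAX) { // wraparound guard: full clear, then restart
    for (auto& s : slots_) s.serial = 0;
    serial_ = 1;
  } else {
    ++serial_;
  }
  top_.clear();
}

size_t TagTable::hash_slot(long long tag, int strand) const {
  unsigned long long h = (unsigned long long)(tag * 2 + strand);
  h *= 0x9E3779B97F4A7C15ULL;
  h ^= h >> 29;
  return (size_t)(h & (unsigned long long)(cap_ - 1));
}

// ranking: score desc, then lower tag id, then '+' before '-'
bool TagTable::ranks_before(int a, int b) const {
  const TagSlot& x = slots_[a];
  const TagSlot& y = slots_[b];
  if (x.score != y.score) return x.score > y.score;
  if (x.tag != y.tag) return x.tag < y.tag;
  return x.strand < y.strand;
}

void TagTable::update_top(int idx) {
  for (size_t i = 0; i < top_.size(); ++i) {
    if (top_[i] == idx) { // already listed: bubble up
      while (i > 0 && ranks_before(top_[i], top_[i - 1])) {
        std::swap(top_[i], top_[i - 1]);
        --i;
      }
      return;
    }
  }
  // candidate set = current list + this record; keep best t
  top_.push_back(idx);
  size_t i = top_.size() - 1;
  while (i > 0 && ranks_before(top_[i], top_[i - 1])) {
    std::swap(top_[i], top_[i - 1]);
    --i;
  }
  if ((int)top_.size() > t_) top_.pop_back();
}

void TagTable::grant(long long tag, int strand, int len, int rpos,
                     long long gpos) {
  size_t h = hash_slot(tag, strand);
  int found = -1;
  for (int probe = 0; probe < cap_; ++probe) {
    size_t j = (h + probe) & (size_t)(cap_ - 1);
    TagSlot& s = slots_[j];
    if (s.serial != serial_) { found = (int)j; break; } // dead or empty
    if (s.tag == tag && s.strand == strand) { found = (int)j; break; }
  }
  if (found < 0) {
    // pathological: table full of live records; evict the lowest-ranked
    // live record outside the top list
    int victim = -1;
    for (int j = 0; j < cap_; ++j) {
      bool in_top = false;
      for (int ti : top_) if (ti == j) { in_top = true; break; }
      if (in_top) continue;
      if (victim < 0 || ranks_before(victim, j)) victim = j;
    }
    if (victim < 0) Rcpp::stop("tag table full and no evictable slot");
    REprintf("tagalign: tag table full, evicting a live record\n");
    found = victim;
    slots_[found].serial = 0;
  }
  TagSlot& s = slots_[found];
  if (s.serial != serial_ || s.tag != tag || s.strand != strand) {
    s.tag = tag;
    s.strand = strand;
    s.serial = serial_;
    s.score = 0;
    s.seeds.clear();
  }
  s.score += len;
  s.seeds.push_back(SeedInfo{len, rpos, gpos});
  update_top(found);
}

std::vector<const TagSlot*> TagTable::top() const {
  std::vector<const TagSlot*> out;
  for (int i : top_) out.push_back(&slots_[i]);
  return out;
}

const TagSlot* TagTable::find(long long tag, int strand) const {
  size_t h = hash_slot(tag, strand);
  for (int probe = 0; probe < cap_; ++probe) {
    size_t j = (h + probe) & (size_t)(cap_ - 1);
    const TagSlot& s = slots_[j];
    if (s.serial != serial_) return nullptr;
    if (s.tag == tag && s.strand == strand) return &s;
  }
  return nullptr;
}

// ---- R handle for unit testing the table directly ------------------------

// [[Rcpp::export]]
SEXP cpp_tt_new(int capacity, int t) {
  XPtr<TagTable> p(new TagTable(capacity, t), true);
  return p;
}

// [[Rcpp::export]]
double cpp_tt_advance(SEXP xp) {
  XPtr<TagTable> p(xp);
  p->advance();
  return (double)p->serial();
}

// [[Rcpp::export]]
void cpp_tt_grant(SEXP xp, double tag, int strand, int len, int rpos0,
                  double gpos0) {
  XPtr<TagTable> p(xp);
  p->grant((long long)tag, strand, len, rpos0, (long long)gpos0);
}

// [[Rcpp::export]]
List cpp_tt_top(SEXP xp) {
  XPtr<TagTable> p(xp);
  std::vector<const TagSlot*> top = p->top();
  int n = (int)top.size();
  NumericVector tag(n), score(n);
  CharacterVector strand(n);
  IntegerVector nseeds(n);
  for (int i = 0; i < n; ++i) {
    tag[i] = (double)top[i]->tag;
    strand[i] = top[i]->strand == 0 ? "+" : "-";
    score[i] = (double)top[i]->score;
    nseeds[i] = (int)top[i]->seeds.size();
  }
  return DataFrame::create(_["tag_id"] = tag, _["strand"] = strand,
                           _["score"] = score, _["n_seeds"] = nseeds,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
SEXP cpp_tt_seeds(SEXP xp, double tag, int strand) {
  XPtr<TagTable> p(xp);
  const TagSlot* s = p->find((long long)tag, strand);
  if (!s) return R_NilValue;
  int n = (int)s->seeds.size();
  IntegerVector len(n), rpos0(n);
  NumericVector gpos0(n);
  for (int i = 0; i < n; ++i) {
    len[i] = s->seeds[i].len;
    rpos0[i] = s->seeds[i].rpos;
    gpos0[i] = (double)s->seeds[i].gpos;
  }
  return DataFrame::create(_["length"] = len, _["read_offset_aligned0"] = rpos0,
                           _["gpos0"] = gpos0);
}

// [[Rcpp::export]]
double cpp_tt_serial(SEXP xp) {
  XPtr<TagTable> p(xp);
  return (double)p->serial();
}
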