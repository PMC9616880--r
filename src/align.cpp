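// Core sequence primitives: unit-cost fitting (semi-global) alignment with
// deterministic traceback, batch read classification against an adaptor
// panel, and the context-dependent mutation channel used by the simulator.
//
// Alignment convention: the reference is aligned end-to-end ("global" on the
// reference); leading and trailing bases of the query are free. Costs are
// unit (match 0, mismatch/insertion/deletion 1). Traceback prefers
// match > mismatch > deletion > insertion, and the alignment end is the
// leftmost query position achieving the minimal cost. Insertions (extra query
// bases) are attributed to the reference position immediately 5' of the
// inserted base (pileup convention).

#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
using namespace Rcpp;

static inline int base_index(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

// Score-only fitting alignment. Returns minimal edit cost and the leftmost
// query end position (1-based, 0 when the reference aligns before query
// start) achieving it. `ws` is reusable scratch; when `abandon` is
// non-negative the search may return early with dist > abandon once no cell
// can reach a score <= abandon (row minima are non-decreasing).
static void fit_score_ws(const std::string& ref, const std::string& query,
                         int& dist, int& qend, std::vector<int>& ws,
                         int abandon = -1) {
  const int m = (int)ref.size(), n = (int)query.size();
  if ((int)ws.size() < 2 * (n + 1)) ws.resize(2 * (n + 1));
  int* prev = ws.data();
  int* cur = ws.data() + (n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = 0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    int rowmin = i;
    const char rc = ref[i - 1];
    for (int j = 1; j <= n; ++j) {
      int best = prev[j - 1] + (rc == query[j - 1] ? 0 : 1);
      const int up = prev[j] + 1;       // deletion (ref base absent)
      const int left = cur[j - 1] + 1;  // insertion (extra query base)
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
      if (best < rowmin) rowmin = best;
    }
    if (abandon >= 0 && rowmin > abandon) { dist = rowmin; qend = 0; return; }
    std::swap(prev, cur);
  }
  dist = prev[0]; qend = 0;
  for (int j = 1; j <= n; ++j) if (prev[j] < dist) { dist = prev[j]; qend = j; }
}

static void fit_score(const std::string& ref, const std::string& query,
                      int& dist, int& qend) {
  std::vector<int> ws;
  fit_score_ws(ref, query, dist, qend, ws);
}

// [[Rcpp::export]]
List cpp_fit_score(std::string ref, std::string query) {
  int d, qe; fit_score(ref, query, d, qe);
  return List::create(_["dist"] = d, _["qend"] = qe);
}

// one reference fitted into each of several queries
// [[Rcpp::export]]
IntegerVector cpp_fit_queries(std::string ref, CharacterVector queries) {
  IntegerVector out(queries.size());
  std::vector<int> ws;
  for (R_xlen_t i = 0; i < queries.size(); ++i) {
    int d, qe; fit_score_ws(ref, as<std::string>(queries[i]), d, qe, ws);
    out[i] = d;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_fit_scores(CharacterVector refs, std::string query) {
  IntegerVector out(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i) {
    int d, qe; fit_score(as<std::string>(refs[i]), query, d, qe);
    out[i] = d;
  }
  return out;
}

struct FitAln {
  int dist, qstart, qend;         // query span, 0-based half-open
  int n_match, n_mismatch, n_insertion, n_deletion;
  std::vector<int> op_ref, op_read, op_code; // codes: 1 M, 2 X, 3 I, 4 D
};

static void fit_align(const std::string& ref, const std::string& query,
                      FitAln& a, bool with_ops) {
  const int m = (int)ref.size(), n = (int)query.size();
  std::vector<int> dp((size_t)(m + 1) * (n + 1));
  for (int j = 0; j <= n; ++j) dp[j] = 0;
  for (int i = 1; i <= m; ++i) {
    dp[(size_t)i * (n + 1)] = i;
    const char rc = ref[i - 1];
    for (int j = 1; j <= n; ++j) {
      int best = dp[(size_t)(i - 1) * (n + 1) + j - 1] + (rc == query[j - 1] ? 0 : 1);
      int up = dp[(size_t)(i - 1) * (n + 1) + j] + 1;
      int left = dp[(size_t)i * (n + 1) + j - 1] + 1;
      if (up < best) best = up;
      if (left < best) best = left;
      dp[(size_t)i * (n + 1) + j] = best;
    }
  }
  int qend = 0, dist = dp[(size_t)m * (n + 1)];
  for (int j = 1; j <= n; ++j)
    if (dp[(size_t)m * (n + 1) + j] < dist) { dist = dp[(size_t)m * (n + 1) + j]; qend = j; }
  a.dist = dist; a.qend = qend;
  a.n_match = a.n_mismatch = a.n_insertion = a.n_deletion = 0;
  a.op_ref.clear(); a.op_read.clear(); a.op_code.clear();
  int i = m, j = qend;
  // traceback; ops recorded in reverse, preference match > mismatch > del > ins
  while (i > 0) {
    const size_t at = (size_t)i * (n + 1) + j;
    const int cur = dp[at];
    if (j > 0 && ref[i - 1] == query[j - 1] &&
        dp[(size_t)(i - 1) * (n + 1) + j - 1] == cur) {
      --i; --j; ++a.n_match;
      if (with_ops) { a.op_ref.push_back(i); a.op_read.push_back(j); a.op_code.push_back(1); }
    } else if (j > 0 && dp[(size_t)(i - 1) * (n + 1) + j - 1] + 1 == cur &&
               ref[i - 1] != query[j - 1]) {
      --i; --j; ++a.n_mismatch;
      if (with_ops) { a.op_ref.push_back(i); a.op_read.push_back(j); a.op_code.push_back(2); }
    } else if (dp[(size_t)(i - 1) * (n + 1) + j] + 1 == cur) {
      --i; ++a.n_deletion;
      if (with_ops) { a.op_ref.push_back(i); a.op_read.push_back(-1); a.op_code.push_back(4); }
    } else {
      --j; ++a.n_insertion;
      if (with_ops) {
        // attribute to preceding reference position (i-1); i >= 1 here
        a.op_ref.push_back(i - 1); a.op_read.push_back(j); a.op_code.push_back(3);
      }
    }
  }
  a.qstart = j;
  if (with_ops) {
    std::reverse(a.op_ref.begin(), a.op_ref.end());
    std::reverse(a.op_read.begin(), a.op_read.end());
    std::reverse(a.op_code.begin(), a.op_code.end());
  }
}

// [[Rcpp::export]]
List cpp_fit_align(std::string ref, std::string query, bool with_ops = true) {
  FitAln a; fit_align(ref, query, a, with_ops);
  List out = List::create(
    _["dist"] = a.dist, _["qstart"] = a.qstart, _["qend"] = a.qend,
    _["n_match"] = a.n_match, _["n_mismatch"] = a.n_mismatch,
    _["n_insertion"] = a.n_insertion, _["n_deletion"] = a.n_deletion);
  if (with_ops) {
    const int k = (int)a.op_ref.size();
    IntegerMatrix ops(k, 3);
    for (int t = 0; t < k; ++t) {
      ops(t, 0) = a.op_ref[t]; ops(t, 1) = a.op_read[t]; ops(t, 2) = a.op_code[t];
    }
    colnames(ops) = CharacterVector::create("ref_pos", "read_pos", "op");
    out["ops"] = ops;
  }
  return out;
}

// Batch classification of reads against a panel. Two-stage decision: locate
// the shared 5' constant region on each searched strand, then score every
// variable region inside the localised window; minimal variable-region edit
// distance wins, with an exact tie between distinct adaptors reported as
// unclassified. The winning adaptor is then fully aligned to the read for
// event-profile accumulation.
// [[Rcpp::export]]
List cpp_classify_reads(CharacterVector reads, std::string constant5,
                        CharacterVector variables, CharacterVector fulls,
                        int clip = 500, double min_identity = 0.7,
                        bool both_orientations = true, int window_slack = 16) {
  const int nr = (int)reads.size(), na = (int)variables.size();
  std::vector<std::string> vars(na), fl(na);
  for (int a = 0; a < na; ++a) {
    vars[a] = as<std::string>(variables[a]);
    fl[a] = as<std::string>(fulls[a]);
  }
  const int var_len = (int)vars[0].size();
  const int full_len = (int)fl[0].size();

  IntegerVector captor(nr), edit_dist(nr), vmm(nr), vins(nr), vdel(nr);
  IntegerVector qstart(nr), qend(nr);
  CharacterVector orient(nr);
  NumericVector identity(nr), per_read_err(nr);

  // per-adaptor event counts: full_len x 4 (match, mismatch, insertion, deletion)
  std::vector<IntegerMatrix> events;
  for (int a = 0; a < na; ++a) events.push_back(IntegerMatrix(full_len, 4));

  std::vector<int> scratch;
  const int c5_len = (int)constant5.size();
  for (int r = 0; r < nr; ++r) {
    std::string seq = as<std::string>(reads[r]);
    if ((int)seq.size() > clip) seq = seq.substr(0, clip);
    std::string rc = both_orientations ? revcomp(seq) : std::string();

    // locate the shared 5' constant on each searched strand; a strand whose
    // constant fits far worse than the other's cannot carry the winning
    // variable region and is skipped (margin covers chance c5 resemblance)
    const int ns = both_orientations ? 2 : 1;
    int d5[2] = {0, 0}, qe5[2] = {0, 0};
    for (int s = 0; s < ns; ++s) {
      fit_score_ws(constant5, (s == 0) ? seq : rc, d5[s], qe5[s], scratch);
    }
    const int d5min = (ns == 2) ? std::min(d5[0], d5[1]) : d5[0];
    const int prune_margin = c5_len / 4;

    int best_score = INT_MAX, best_a = -1, best_strand = 0, n_best_distinct = 0;
    std::string win[2];
    for (int s = 0; s < ns; ++s) {
      const std::string& strand = (s == 0) ? seq : rc;
      int ws = qe5[s];
      int wl = var_len + window_slack;
      if (ws > (int)strand.size()) ws = (int)strand.size();
      if (ws + wl > (int)strand.size()) wl = (int)strand.size() - ws;
      win[s] = strand.substr(ws, wl);
      if (ns == 2 && d5[s] > d5min + prune_margin) continue;
      for (int a = 0; a < na; ++a) {
        int d, qe;
        fit_score_ws(vars[a], win[s], d, qe, scratch,
                     best_score == INT_MAX ? -1 : best_score);
        if (d < best_score) {
          best_score = d; best_a = a; best_strand = s; n_best_distinct = 1;
        } else if (d == best_score && a != best_a) {
          ++n_best_distinct;
        }
      }
    }

    // ranking used the variable region only (constants are shared); the
    // classified/unclassified gate uses the full-adaptor identity, since a
    // genuine adaptor read also carries the constant segments
    bool ok = (best_a >= 0 && n_best_distinct == 1);
    double ident = NA_REAL;
    FitAln fa;
    if (ok) {
      const std::string& strand = (best_strand == 0) ? seq : rc;
      fit_align(fl[best_a], strand, fa, true);
      const int ftot = fa.n_match + fa.n_mismatch + fa.n_insertion + fa.n_deletion;
      ident = ftot > 0 ? (double)fa.n_match / ftot : 0.0;
      FitAln va; fit_align(vars[best_a], win[best_strand], va, false);
      vmm[r] = va.n_mismatch; vins[r] = va.n_insertion; vdel[r] = va.n_deletion;
      per_read_err[r] = (double)(va.n_mismatch + va.n_insertion + va.n_deletion) / var_len;
      if (ident < min_identity) ok = false;
    }
    if (!ok) {
      captor[r] = NA_INTEGER; orient[r] = NA_STRING; identity[r] = ident;
      edit_dist[r] = NA_INTEGER; qstart[r] = NA_INTEGER; qend[r] = NA_INTEGER;
      if (best_a < 0 || n_best_distinct != 1) {
        vmm[r] = NA_INTEGER; vins[r] = NA_INTEGER; vdel[r] = NA_INTEGER;
        per_read_err[r] = NA_REAL;
      }
      continue;
    }
    identity[r] = ident;
    captor[r] = best_a + 1;
    orient[r] = (best_strand == 0) ? "+" : "-";
    edit_dist[r] = fa.dist; qstart[r] = fa.qstart; qend[r] = fa.qend;
    IntegerMatrix& ev = events[best_a];
    for (size_t t = 0; t < fa.op_ref.size(); ++t)
      ev(fa.op_ref[t], fa.op_code[t] - 1) += 1;
  }

  List evl(na);
  for (int a = 0; a < na; ++a) evl[a] = events[a];
  return List::create(
    _["captor"] = captor, _["orientation"] = orient, _["identity"] = identity,
    _["edit_distance"] = edit_dist, _["var_mismatch"] = vmm,
    _["var_insertion"] = vins, _["var_deletion"] = vdel,
    _["per_read_error"] = per_read_err,
    _["adaptor_qstart"] = qstart, _["adaptor_qend"] = qend,
    _["events"] = evl);
}

// Align each read end-to-end-on-reference against a designated reference and
// accumulate per-position event counts (used when the read-to-reference
// assignment is already known, e.g. ground-truth profiling or gene-control
// reads aligned to their reference index).
// [[Rcpp::export]]
List cpp_profile_reads(CharacterVector reads, IntegerVector ref_index,
                       CharacterVector refs) {
  const int nr = (int)reads.size(), nrefs = (int)refs.size();
  if (ref_index.size() != nr) stop("ref_index length must match reads");
  std::vector<std::string> rf(nrefs);
  for (int i = 0; i < nrefs; ++i) rf[i] = as<std::string>(refs[i]);
  std::vector<IntegerMatrix> events;
  for (int i = 0; i < nrefs; ++i)
    events.push_back(IntegerMatrix((int)rf[i].size(), 4));
  IntegerVector dist(nr);
  for (int r = 0; r < nr; ++r) {
    const int a = ref_index[r] - 1;
    if (a < 0 || a >= nrefs) stop("ref_index out of range");
    FitAln fa; fit_align(rf[a], as<std::string>(reads[r]), fa, true);
    dist[r] = fa.dist;
    IntegerMatrix& ev = events[a];
    for (size_t t = 0; t < fa.op_ref.size(); ++t)
      ev(fa.op_ref[t], fa.op_code[t] - 1) += 1;
  }
  List evl(nrefs);
  for (int i = 0; i < nrefs; ++i) evl[i] = events[i];
  return List::create(_["events"] = evl, _["edit_distance"] = dist);
}

// Context-dependent error channel. For each emitted base the 6-mer window of
// the template ending at that base selects the per-class rates (the first
// five positions use an implicit left A-padding via the rolling index). At
// most one event per template position: mismatch substitutes a different
// base, insertion emits the base followed by one uniform random base,
// deletion skips the base. Rates are scaled by `multiplier` and the total is
// capped at 0.95 by proportional rescaling. Uses R's RNG.
// [[Rcpp::export]]
List cpp_mutate_many(CharacterVector templates, NumericVector p_mismatch,
                     NumericVector p_insertion, NumericVector p_deletion,
                     NumericVector multiplier) {
  const int n = (int)templates.size();
  if (p_mismatch.size() != 4096 || p_insertion.size() != 4096 || p_deletion.size() != 4096)
    stop("rate vectors must have length 4096");
  CharacterVector out(n);
  IntegerVector n_sub(n), n_ins(n), n_del(n);
  const char* bases = "ACGT";
  for (int r = 0; r < n; ++r) {
    const std::string tpl = as<std::string>(templates[r]);
    const double mult = multiplier[r % multiplier.size()];
    std::string em; em.reserve(tpl.size() + 16);
    int ns = 0, ni = 0, nd = 0, ctx = 0;
    for (size_t i = 0; i < tpl.size(); ++i) {
      const int b = base_index(tpl[i]);
      if (b < 0) stop("non-ACGT base in template");
      ctx = ((ctx << 2) | b) & 0xFFF;
      double pm = p_mismatch[ctx] * mult, pi = p_insertion[ctx] * mult,
             pd = p_deletion[ctx] * mult;
      const double tot = pm + pi + pd;
      if (tot > 0.95) { const double f = 0.95 / tot; pm *= f; pi *= f; pd *= f; }
      const double u = unif_rand();
      if (u < pm) {
        int nb = (int)(unif_rand() * 3.0); if (nb >= 3) nb = 2;
        if (nb >= b) ++nb;
        em.push_back(bases[nb]); ++ns;
      } else if (u < pm + pi) {
        em.push_back(tpl[i]);
        int ib = (int)(unif_rand() * 4.0); if (ib >= 4) ib = 3;
        em.push_back(bases[ib]); ++ni;
      } else if (u < pm + pi + pd) {
        ++nd;
      } else {
        em.push_back(tpl[i]);
      }
    }
    out[r] = em; n_sub[r] = ns; n_ins[r] = ni; n_del[r] = nd;
  }
  return List::create(_["sequence"] = out, _["n_sub"] = n_sub,
                      _["n_ins"] = n_ins, _["n_del"] = n_del);
}
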