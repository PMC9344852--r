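// Core data structures for barcode error correction: 2-bit sequence codes,
// combination-ID encoding of k-mer subsets, the k-mer index (hash table from
// combination ID to the set of sequences containing that combination), exact
// epsilon-neighborhood queries via the pigeonhole guarantee, and the
// count-ordered clustering / timepoint-classification passes.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

// ---------------------------------------------------------------------------
// Scheme: partition bounds and the lexicographically ordered (p-eps)-subsets
// ---------------------------------------------------------------------------

struct Scheme {
  int l = 0, k = 0, eps = 0, p = 0;
  std::vector<int> start;                 // 0-based partition starts
  std::vector<int> len;                   // partition lengths (last may be r)
  std::vector<std::vector<int>> subsets;  // 0-based partition indices
  long long shift = 0;                    // 4^max_nt, separates subset blocks

  void init(int l_, int k_, int eps_, IntegerVector starts, IntegerVector lens,
            IntegerMatrix subs, int max_nt) {
    l = l_; k = k_; eps = eps_;
    p = starts.size();
    start.assign(starts.begin(), starts.end());
    len.assign(lens.begin(), lens.end());
    subsets.resize(subs.ncol());
    for (int j = 0; j < subs.ncol(); ++j) {
      subsets[j].resize(subs.nrow());
      for (int i = 0; i < subs.nrow(); ++i) subsets[j][i] = subs(i, j);
    }
    shift = 1;
    for (int i = 0; i < max_nt; ++i) shift *= 4;
  }

  // combination IDs of an encoded sequence, one per subset
  void ids(const uint8_t* code, std::vector<long long>& out) const {
    out.clear();
    out.reserve(subsets.size());
    for (size_t j = 0; j < subsets.size(); ++j) {
      long long v = 0;
      for (int part : subsets[j]) {
        const int s = start[part], e = start[part] + len[part];
        for (int pos = s; pos < e; ++pos) v = v * 4 + code[pos];
      }
      out.push_back((long long)j * shift + v);
    }
  }
};

static void encode_seq(const char* s, int l, uint8_t* out) {
  for (int i = 0; i < l; ++i) {
    int c = base_code(s[i]);
    if (c < 0) stop("sequence contains a non-ACGT character: '%s'", s);
    out[i] = (uint8_t)c;
  }
}

static inline int hamming_codes(const uint8_t* a, const uint8_t* b, int l,
                                int cap) {
  int d = 0;
  for (int i = 0; i < l; ++i) {
    if (a[i] != b[i] && ++d > cap && cap >= 0) return cap + 1;
  }
  return d;
}

// ---------------------------------------------------------------------------
// Index
// ---------------------------------------------------------------------------

struct ShepIndex {
  Scheme sch;
  std::vector<std::string> seqs;
  std::vector<uint8_t> enc;  // n x l, row-major
  std::unordered_map<long long, std::vector<int>> table;
  std::vector<int> visit;  // scratch stamps for bucket-union dedup
  int gen = 0;

  int n() const { return (int)seqs.size(); }
  const uint8_t* code(int i) const { return enc.data() + (size_t)i * sch.l; }

  void add(const std::string& s) {
    const int i = n();
    seqs.push_back(s);
    enc.resize((size_t)(i + 1) * sch.l);
    encode_seq(s.c_str(), sch.l, enc.data() + (size_t)i * sch.l);
    std::vector<long long> idv;
    sch.ids(code(i), idv);
    for (long long id : idv) table[id].push_back(i);
    visit.push_back(0);
  }

  // 0-based indices of all sequences sharing >= 1 combination ID with `code`,
  // excluding those whose sequence equals `q` exactly
  void kmer_neighborhood(const uint8_t* qc, const std::string& q,
                         std::vector<int>& out) {
    out.clear();
    ++gen;
    std::vector<long long> idv;
    sch.ids(qc, idv);
    for (long long id : idv) {
      auto it = table.find(id);
      if (it == table.end()) continue;
      for (int j : it->second) {
        if (visit[j] == gen) continue;
        visit[j] = gen;
        if (seqs[j] == q) continue;
        out.push_back(j);
      }
    }
  }
};

static Scheme scheme_from_r(List scheme) {
  Scheme s;
  s.init(as<int>(scheme["l"]), as<int>(scheme["k"]), as<int>(scheme["epsilon"]),
         as<IntegerVector>(scheme["starts0"]), as<IntegerVector>(scheme["lens"]),
         as<IntegerMatrix>(scheme["subsets0"]), as<int>(scheme["max_nt"]));
  return s;
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b, int cap) {
  if (a.size() != b.size())
    stop("sequences differ in length (%d vs %d)", (int)a.size(), (int)b.size());
  const int l = (int)a.size();
  std::vector<uint8_t> ca(l), cb(l);
  encode_seq(a.c_str(), l, ca.data());
  encode_seq(b.c_str(), l, cb.data());
  return hamming_codes(ca.data(), cb.data(), l, cap);
}

// [[Rcpp::export]]
CharacterVector cpp_combination_ids(std::string seq, List scheme) {
  Scheme s = scheme_from_r(scheme);
  if ((int)seq.size() != s.l)
    stop("sequence length %d does not match scheme length %d", (int)seq.size(),
         s.l);
  std::vector<uint8_t> code(s.l);
  encode_seq(seq.c_str(), s.l, code.data());
  std::vector<long long> idv;
  s.ids(code.data(), idv);
  CharacterVector out(idv.size());
  for (size_t i = 0; i < idv.size(); ++i) out[i] = std::to_string(idv[i]);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector seqs, List scheme) {
  XPtr<ShepIndex> xp(new ShepIndex(), true);
  xp->sch = scheme_from_r(scheme);
  xp->seqs.reserve(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() != xp->sch.l)
      stop("sequence %ld has length %d, expected %d", (long)(i + 1),
           (int)s.size(), xp->sch.l);
    xp->add(s);
  }
  return xp;
}

// [[Rcpp::export]]
IntegerVector cpp_index_insert(SEXP xps, CharacterVector seqs) {
  XPtr<ShepIndex> xp(xps);
  IntegerVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    xp->add(as<std::string>(seqs[i]));
    out[i] = xp->n();  // 1-based position
  }
  return out;
}

// [[Rcpp::export]]
int cpp_index_size(SEXP xps) {
  XPtr<ShepIndex> xp(xps);
  return xp->n();
}

// [[Rcpp::export]]
CharacterVector cpp_index_seqs(SEXP xps) {
  XPtr<ShepIndex> xp(xps);
  return wrap(xp->seqs);
}

// [[Rcpp::export]]
IntegerVector cpp_table_entries_per_seq(SEXP xps) {
  XPtr<ShepIndex> xp(xps);
  IntegerVector out(xp->n());
  for (auto& kv : xp->table)
    for (int j : kv.second) out[j]++;
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_kmer_neighborhood(SEXP xps, std::string q) {
  XPtr<ShepIndex> xp(xps);
  if ((int)q.size() != xp->sch.l)
    stop("query length %d does not match index length %d", (int)q.size(),
         xp->sch.l);
  std::vector<uint8_t> qc(xp->sch.l);
  encode_seq(q.c_str(), xp->sch.l, qc.data());
  std::vector<int> nb;
  xp->kmer_neighborhood(qc.data(), q, nb);
  IntegerVector out(nb.size());
  for (size_t i = 0; i < nb.size(); ++i) out[i] = nb[i] + 1;
  return out;
}

// [[Rcpp::export]]
List cpp_eps_neighborhood(SEXP xps, std::string q, NumericVector counts) {
  XPtr<ShepIndex> xp(xps);
  if ((int)q.size() != xp->sch.l)
    stop("query length %d does not match index length %d", (int)q.size(),
         xp->sch.l);
  const int eps = xp->sch.eps, l = xp->sch.l;
  const bool have_counts = counts.size() == xp->n();
  std::vector<uint8_t> qc(l);
  encode_seq(q.c_str(), l, qc.data());
  std::vector<int> nb;
  xp->kmer_neighborhood(qc.data(), q, nb);
  std::vector<std::pair<int, int>> hits;  // (idx, dist)
  for (int j : nb) {
    int d = hamming_codes(qc.data(), xp->code(j), l, eps);
    if (d <= eps) hits.push_back({j, d});
  }
  std::sort(hits.begin(), hits.end(), [&](const std::pair<int, int>& a,
                                          const std::pair<int, int>& b) {
    if (a.second != b.second) return a.second < b.second;
    if (have_counts && counts[a.first] != counts[b.first])
      return counts[a.first] > counts[b.first];
    return xp->seqs[a.first] < xp->seqs[b.first];
  });
  IntegerVector idx(hits.size()), dist(hits.size());
  for (size_t i = 0; i < hits.size(); ++i) {
    idx[i] = hits[i].first + 1;
    dist[i] = hits[i].second;
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// ---------------------------------------------------------------------------
// Bayesian test
// ---------------------------------------------------------------------------

// ln K for a candidate at distance d with count fc against a putative barcode
// with estimated true count nhat; lnfmax and l*ln4 are the prior terms.
static double log_bf_core(int d, double fc, double nhat, double rho, int l,
                          double lnfmax) {
  if (rho <= 0.0) return d >= 1 ? R_NegInf : R_PosInf;
  const double logp = d * std::log(rho / 3.0) + (l - d) * std::log1p(-rho);
  if (fc > nhat || nhat < 1) return R_NegInf;  // binomial mass is zero
  const double phat = std::exp(logp);
  const double lpmf = R::dbinom(fc, nhat, phat, 1);
  return lpmf + logp + l * std::log(4.0) + lnfmax;
}

static inline double nhat_from_total(double Fp, double rho, int l) {
  return std::round(Fp / std::pow(1.0 - rho, l));
}

// [[Rcpp::export]]
double cpp_log_bf(int d, double fc, double nhat, double rho, int l,
                  double fmax) {
  return log_bf_core(d, fc, nhat, rho, l, std::log(fmax));
}

// ---------------------------------------------------------------------------
// Single-timepoint clustering pass (count-descending order assumed)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_cluster(SEXP xps, NumericVector counts, double rho, double thresh,
                 double skip_frac, bool use_skip) {
  XPtr<ShepIndex> xp(xps);
  const int n = xp->n(), l = xp->sch.l, eps = xp->sch.eps;
  if (counts.size() != n) stop("counts length does not match index size");
  const double fmax = counts[0], lnfmax = std::log(fmax);
  IntegerVector assign(n), dist(n);
  LogicalVector is_center(n);
  NumericVector ctot(n);
  std::vector<int> nb;

  for (int i = 0; i < n; ++i) {
    bool make_center = false;
    int best = -1, bd = eps + 1;
    if (i == 0 || (use_skip && counts[i] > skip_frac * fmax)) {
      make_center = true;
    } else {
      xp->kmer_neighborhood(xp->code(i), xp->seqs[i], nb);
      for (int j : nb) {
        if (!is_center[j]) continue;
        int d = hamming_codes(xp->code(i), xp->code(j), l, eps);
        if (d > eps) continue;
        if (best < 0 || d < bd ||
            (d == bd && (counts[j] > counts[best] ||
                         (counts[j] == counts[best] &&
                          xp->seqs[j] < xp->seqs[best])))) {
          best = j;
          bd = d;
        }
      }
      if (best < 0) {
        make_center = true;
      } else {
        double nhat = nhat_from_total(ctot[best], rho, l);
        double lnK = log_bf_core(bd, counts[i], nhat, rho, l, lnfmax);
        if (lnK < thresh) {
          make_center = true;  // TRUE_BARCODE: new cluster
        } else {
          assign[i] = best + 1;
          dist[i] = bd;
          ctot[best] += counts[i];
        }
      }
    }
    if (make_center) {
      is_center[i] = true;
      assign[i] = i + 1;
      dist[i] = 0;
      ctot[i] = counts[i];
    }
  }
  return List::create(_["assign"] = assign, _["dist"] = dist,
                      _["is_center"] = is_center, _["cluster_total"] = ctot);
}

// ---------------------------------------------------------------------------
// Later-timepoint classification pass
// ---------------------------------------------------------------------------

// Centers live in the (growable) index `xps`. `ft` holds each center's count
// accumulated at this timepoint so far (seeded with exact-match reads by the
// caller). Sequences must arrive in descending count order and contain no
// exact center matches. A sequence within eps of its closest center is
// absorbed unless the Bayes test calls it a true barcode, in which case it is
// promoted to a new center and inserted into the index so that subsequent
// sequences can be assigned to it. Sequences with no center within eps are
// left unassigned (assign = 0) for separate clustering.
// [[Rcpp::export]]
List cpp_classify_timepoint(SEXP xps, NumericVector ft, CharacterVector seqs,
                            NumericVector counts, double rho, double thresh,
                            double fmax) {
  XPtr<ShepIndex> xp(xps);
  const int l = xp->sch.l, eps = xp->sch.eps;
  if (ft.size() != xp->n()) stop("ft length does not match center count");
  const double lnfmax = std::log(fmax);
  std::vector<double> Ft(ft.begin(), ft.end());
  const int m = seqs.size();
  IntegerVector assign(m), dist(m);
  LogicalVector promoted(m);
  std::vector<int> nb;
  std::vector<uint8_t> qc(l);

  for (int i = 0; i < m; ++i) {
    std::string q = as<std::string>(seqs[i]);
    if ((int)q.size() != l) stop("sequence length mismatch at %d", i + 1);
    encode_seq(q.c_str(), l, qc.data());
    xp->kmer_neighborhood(qc.data(), q, nb);
    int best = -1, bd = eps + 1;
    for (int j : nb) {
      int d = hamming_codes(qc.data(), xp->code(j), l, eps);
      if (d > eps) continue;
      if (best < 0 || d < bd ||
          (d == bd &&
           (Ft[j] > Ft[best] ||
            (Ft[j] == Ft[best] && xp->seqs[j] < xp->seqs[best])))) {
        best = j;
        bd = d;
      }
    }
    if (best < 0) {
      assign[i] = 0;  // unassigned: buffered for separate clustering
      dist[i] = NA_INTEGER;
      continue;
    }
    double nhat = nhat_from_total(Ft[best], rho, l);
    double lnK = log_bf_core(bd, counts[i], nhat, rho, l, lnfmax);
    if (lnK < thresh) {  // emerging (or previously merged) true barcode
      xp->add(q);
      Ft.push_back(counts[i]);
      assign[i] = xp->n();
      dist[i] = 0;
      promoted[i] = true;
    } else {
      assign[i] = best + 1;
      dist[i] = bd;
      Ft[best] += counts[i];
    }
  }
  return List::create(_["assign"] = assign, _["dist"] = dist,
                      _["promoted"] = promoted, _["ft"] = wrap(Ft));
}
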