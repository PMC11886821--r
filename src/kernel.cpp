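// Greedy / modified cosine kernel, templated on the working precision.
//
// The kernel has three stages per reference/query cell:
//   1. collect candidate peak pairs within the m/z tolerance, in (i, j)
//      enumeration order, capped at match_limit per pass (overflow flag);
//   2. sort the pairs by descending weight product, ties broken by
//      (ref_index, query_index) ascending — a fixed, hardware-independent
//      order so results are bit-reproducible;
//   3. greedily accept pairs whose peaks are both unused, accumulating the
//      products; the score is the accumulator divided by the product of the
//      two spectrum norms (carried in batch metadata, not recomputed here).
//
// The float instantiation reproduces single-precision arithmetic throughout,
// including the tolerance comparison, which is where single/double
// disagreements at the tolerance boundary originate.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

template <typename T>
struct CandPair {
  int i;
  int j;
  T p;
};

template <typename T>
struct PairCmp {
  bool operator()(const CandPair<T>& a, const CandPair<T>& b) const {
    if (a.p != b.p) return a.p > b.p;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  }
};

// Enumerate feasible pairs |ref_mz[i] - (query_mz[j] + shift)| <= tol in
// i-major order. At most `limit` pairs are appended; encountering one more
// feasible pair raises overflow and stops the pass. Pairs whose encoded key
// is in `skip` (already collected by an earlier pass) are ignored and do not
// consume the budget.
template <typename T>
bool collect_pass(const T* rmz, const T* rw, int rn,
                  const T* qmz, const T* qw, int qn,
                  T tol, T shift, int limit,
                  const std::unordered_set<int64_t>* skip,
                  std::vector<CandPair<T> >& out) {
  int added = 0;
  for (int i = 0; i < rn; ++i) {
    for (int j = 0; j < qn; ++j) {
      T d = rmz[i] - (qmz[j] + shift);
      if (d < T(0)) d = -d;
      if (d <= tol) {
        if (skip && skip->count(static_cast<int64_t>(i) * qn + j)) continue;
        if (added >= limit) return true;
        out.push_back(CandPair<T>{i, j, rw[i] * qw[j]});
        ++added;
      }
    }
  }
  return false;
}

template <typename T>
void greedy_reduce_core(std::vector<CandPair<T> >& pairs, int rn, int qn,
                        T& acc, int& matches) {
  std::sort(pairs.begin(), pairs.end(), PairCmp<T>());
  std::vector<char> rused(rn, 0), qused(qn, 0);
  acc = T(0);
  matches = 0;
  for (size_t k = 0; k < pairs.size(); ++k) {
    const CandPair<T>& pr = pairs[k];
    if (!rused[pr.i] && !qused[pr.j]) {
      rused[pr.i] = 1;
      qused[pr.j] = 1;
      acc += pr.p;
      ++matches;
    }
  }
}

template <typename T>
void score_pair_core(const T* rmz, const T* rw, int rn, T rnorm,
                     const T* qmz, const T* qw, int qn, T qnorm,
                     T tol, int limit, bool modified, T rprec, T qprec,
                     double& score, int& matches, bool& overflow) {
  score = 0.0;
  matches = 0;
  overflow = false;
  if (rn == 0 || qn == 0) return;
  // degenerate (zero-norm) spectra score 0 without error
  if (!(rnorm > T(0)) || !(qnorm > T(0))) return;

  std::vector<CandPair<T> > pairs;
  bool ovf = collect_pass<T>(rmz, rw, rn, qmz, qw, qn, tol, T(0), limit,
                             0, pairs);
  if (modified) {
    std::unordered_set<int64_t> seen;
    for (size_t k = 0; k < pairs.size(); ++k)
      seen.insert(static_cast<int64_t>(pairs[k].i) * qn + pairs[k].j);
    T shift = rprec - qprec;
    bool ovf2 = collect_pass<T>(rmz, rw, rn, qmz, qw, qn, tol, shift, limit,
                                &seen, pairs);
    ovf = ovf || ovf2;
  }
  overflow = ovf;

  T acc;
  greedy_reduce_core(pairs, rn, qn, acc, matches);
  if (matches == 0) return;
  T denom = rnorm * qnorm;
  score = static_cast<double>(acc / denom);
}

static std::vector<float> to_float(const NumericVector& x) {
  std::vector<float> out(x.size());
  for (R_xlen_t k = 0; k < x.size(); ++k) out[k] = static_cast<float>(x[k]);
  return out;
}

// [[Rcpp::export]]
List cpp_collect_pairs(NumericVector ref_mz, NumericVector ref_w,
                       NumericVector query_mz, NumericVector query_w,
                       double tolerance, int match_limit, double shift,
                       bool single) {
  std::vector<int> ri, qi;
  std::vector<double> pp;
  bool ovf;
  if (single) {
    std::vector<float> rmz = to_float(ref_mz), rw = to_float(ref_w);
    std::vector<float> qmz = to_float(query_mz), qw = to_float(query_w);
    std::vector<CandPair<float> > pairs;
    ovf = collect_pass<float>(rmz.data(), rw.data(), (int)rmz.size(),
                              qmz.data(), qw.data(), (int)qmz.size(),
                              (float)tolerance, (float)shift, match_limit,
                              0, pairs);
    for (size_t k = 0; k < pairs.size(); ++k) {
      ri.push_back(pairs[k].i + 1);
      qi.push_back(pairs[k].j + 1);
      pp.push_back((double)pairs[k].p);
    }
  } else {
    std::vector<CandPair<double> > pairs;
    ovf = collect_pass<double>(REAL(ref_mz), REAL(ref_w), (int)ref_mz.size(),
                               REAL(query_mz), REAL(query_w),
                               (int)query_mz.size(), tolerance, shift,
                               match_limit, 0, pairs);
    for (size_t k = 0; k < pairs.size(); ++k) {
      ri.push_back(pairs[k].i + 1);
      qi.push_back(pairs[k].j + 1);
      pp.push_back(pairs[k].p);
    }
  }
  return List::create(_["ref_index"] = wrap(ri), _["query_index"] = wrap(qi),
                      _["product"] = wrap(pp), _["overflow"] = ovf);
}

// [[Rcpp::export]]
List cpp_greedy_reduce(IntegerVector ref_index, IntegerVector query_index,
                       NumericVector product, int ref_len, int query_len,
                       bool single) {
  int matches = 0;
  double acc_d;
  if (single) {
    std::vector<CandPair<float> > pairs(ref_index.size());
    for (R_xlen_t k = 0; k < ref_index.size(); ++k)
      pairs[k] = CandPair<float>{ref_index[k] - 1, query_index[k] - 1,
                                 (float)product[k]};
    float acc;
    greedy_reduce_core(pairs, ref_len, query_len, acc, matches);
    acc_d = (double)acc;
  } else {
    std::vector<CandPair<double> > pairs(ref_index.size());
    for (R_xlen_t k = 0; k < ref_index.size(); ++k)
      pairs[k] = CandPair<double>{ref_index[k] - 1, query_index[k] - 1,
                                  product[k]};
    double acc;
    greedy_reduce_core(pairs, ref_len, query_len, acc, matches);
    acc_d = acc;
  }
  return List::create(_["score"] = acc_d, _["matches"] = matches);
}

// [[Rcpp::export]]
List cpp_score_pair(NumericVector ref_mz, NumericVector ref_w, double ref_norm,
                    NumericVector query_mz, NumericVector query_w,
                    double query_norm, double tolerance, int match_limit,
                    bool modified, double ref_prec, double query_prec,
                    bool single) {
  double score;
  int matches;
  bool overflow;
  if (single) {
    std::vector<float> rmz = to_float(ref_mz), rw = to_float(ref_w);
    std::vector<float> qmz = to_float(query_mz), qw = to_float(query_w);
    score_pair_core<float>(rmz.data(), rw.data(), (int)rmz.size(),
                           (float)ref_norm, qmz.data(), qw.data(),
                           (int)qmz.size(), (float)query_norm,
                           (float)tolerance, match_limit, modified,
                           (float)ref_prec, (float)query_prec,
                           score, matches, overflow);
  } else {
    score_pair_core<double>(REAL(ref_mz), REAL(ref_w), (int)ref_mz.size(),
                            ref_norm, REAL(query_mz), REAL(query_w),
                            (int)query_mz.size(), query_norm, tolerance,
                            match_limit, modified, ref_prec, query_prec,
                            score, matches, overflow);
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["overflow"] = overflow);
}

// Score a full B_ref x B_query block. Peak matrices are pad_width x B
// (one column per spectrum slot, zero-padded past each true length).
// Every cell is independent of every other — the loop order below is an
// implementation detail, not part of the contract.
// [[Rcpp::export]]
List cpp_score_block(NumericMatrix ref_mz, NumericMatrix ref_w,
                     IntegerVector ref_len, NumericVector ref_norm,
                     NumericVector ref_prec,
                     NumericMatrix query_mz, NumericMatrix query_w,
                     IntegerVector query_len, NumericVector query_norm,
                     NumericVector query_prec,
                     double tolerance, int match_limit, bool modified,
                     bool single) {
  const int br = ref_len.size(), bq = query_len.size();
  const int mr = ref_mz.nrow(), mq = query_mz.nrow();
  NumericMatrix score(br, bq);
  IntegerMatrix matches(br, bq);
  LogicalMatrix overflow(br, bq);

  if (single) {
    std::vector<float> rmz(mr * br), rw(mr * br), qmz(mq * bq), qw(mq * bq);
    for (int k = 0; k < mr * br; ++k) {
      rmz[k] = (float)ref_mz[k];
      rw[k] = (float)ref_w[k];
    }
    for (int k = 0; k < mq * bq; ++k) {
      qmz[k] = (float)query_mz[k];
      qw[k] = (float)query_w[k];
    }
    for (int i = 0; i < br; ++i) {
      if (ref_len[i] == 0) continue;
      for (int j = 0; j < bq; ++j) {
        if (query_len[j] == 0) continue;
        double s;
        int m;
        bool o;
        score_pair_core<float>(
            rmz.data() + (size_t)i * mr, rw.data() + (size_t)i * mr,
            ref_len[i], (float)ref_norm[i], qmz.data() + (size_t)j * mq,
            qw.data() + (size_t)j * mq, query_len[j], (float)query_norm[j],
            (float)tolerance, match_limit, modified,
            modified ? (float)ref_prec[i] : 0.0f,
            modified ? (float)query_prec[j] : 0.0f, s, m, o);
        score(i, j) = s;
        matches(i, j) = m;
        overflow(i, j) = o;
      }
    }
  } else {
    const double* rmz = REAL(ref_mz);
    const double* rw = REAL(ref_w);
    const double* qmz = REAL(query_mz);
    const double* qw = REAL(query_w);
    for (int i = 0; i < br; ++i) {
      if (ref_len[i] == 0) continue;
      for (int j = 0; j < bq; ++j) {
        if (query_len[j] == 0) continue;
        double s;
        int m;
        bool o;
        score_pair_core<double>(
            rmz + (size_t)i * mr, rw + (size_t)i * mr, ref_len[i],
            ref_norm[i], qmz + (size_t)j * mq, qw + (size_t)j * mq,
            query_len[j], query_norm[j], tolerance, match_limit, modified,
            modified ? ref_prec[i] : 0.0, modified ? query_prec[j] : 0.0,
            s, m, o);
        score(i, j) = s;
        matches(i, j) = m;
        overflow(i, j) = o;
      }
    }
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["overflow"] = overflow);
}
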