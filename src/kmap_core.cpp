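#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// 2-bit encoding, big-endian (first base most significant) so that the
// numeric order of codes equals the lexicographic order of the strings.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t rc_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (code & 3ULL));
    code >>= 2;
  }
  return rc;
}

static inline int ham_code(uint64_t a, uint64_t b, int k) {
  uint64_t x = a ^ b;
  int d = 0;
  for (int i = 0; i < k; ++i) {
    if (x & 3ULL) ++d;
    x >>= 2;
  }
  return d;
}

static std::string decode_one(uint64_t code, int k) {
  std::string s((size_t) k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t) i] = BASES[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_encode(CharacterVector x, int k) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP el = STRING_ELT(x, i);
    if (el == NA_STRING || LENGTH(el) != k) { out[i] = NA_REAL; continue; }
    const char* s = CHAR(el);
    uint64_t code = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base_code(s[j]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | (uint64_t) b;
    }
    out[i] = ok ? (double) code : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode(NumericVector codes, int k) {
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = decode_one((uint64_t) codes[i], k);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_revcomp_codes(NumericVector codes, int k) {
  R_xlen_t n = codes.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (double) rc_code((uint64_t) codes[i], k);
  return out;
}

// Count all valid k-windows.  Windows containing a non-ACGT character are
// skipped but still advance by one position.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k, bool rc) {
  std::unordered_map<uint64_t, double> tab;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  double total = 0.0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    SEXP el = STRING_ELT(seqs, s);
    if (el == NA_STRING) continue;
    const char* str = CHAR(el);
    int n = LENGTH(el);
    uint64_t code = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = base_code(str[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t) b) & mask;
      if (++valid >= k) {
        uint64_t key = code;
        if (rc) {
          uint64_t r = rc_code(code, k);
          if (r < key) key = r;
        }
        tab[key] += 1.0;
        total += 1.0;
      }
    }
  }
  std::vector<std::pair<uint64_t, double> > v(tab.begin(), tab.end());
  std::sort(v.begin(), v.end());
  R_xlen_t m = (R_xlen_t) v.size();
  NumericVector counts(m), codes(m);
  CharacterVector names(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    codes[i] = (double) v[(size_t) i].first;
    counts[i] = v[(size_t) i].second;
    names[i] = decode_one(v[(size_t) i].first, k);
  }
  counts.attr("names") = names;
  return List::create(_["counts"] = counts, _["codes"] = codes,
                      _["total_windows"] = total);
}

static void enum_ball_rec(uint64_t cur, int k, int pos, int rem,
                          std::vector<uint64_t>& out) {
  for (int p = pos; p < k; ++p) {
    int shift = 2 * (k - 1 - p);
    uint64_t base = (cur >> shift) & 3ULL;
    for (uint64_t b = 0; b < 4; ++b) {
      if (b == base) continue;
      uint64_t mut = (cur & ~(3ULL << shift)) | (b << shift);
      out.push_back(mut);
      if (rem > 1) enum_ball_rec(mut, k, p + 1, rem - 1, out);
    }
  }
}

static std::vector<uint64_t> enum_ball(uint64_t center, int k, int r) {
  std::vector<uint64_t> out;
  out.push_back(center);
  if (r > 0) enum_ball_rec(center, k, 0, r, out);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ball_members(double center, int k, int r) {
  std::vector<uint64_t> ball = enum_ball((uint64_t) center, k, r);
  NumericVector out((R_xlen_t) ball.size());
  for (size_t i = 0; i < ball.size(); ++i) out[(R_xlen_t) i] = (double) ball[i];
  return out;
}

// Observed count mass and theoretical size of the Hamming ball around each
// center.  With rc = true the count keys are canonical k-mers and the ball is
// the strand union B(c) U B(revcomp(c)); the returned size is the raw size of
// that union, matching what canonical counting aggregates.  A member m whose
// reverse complement also lies in B(c) shares its canonical key with it, so
// each such non-palindromic member contributes half its canonical count.
// Uses a dense table for k <= 12 and a hash table above.
NumericMatrix ball_stats_impl(NumericVector codes, NumericVector counts,
                              NumericVector centers, int k, int r, bool rc) {
  bool dense = (k <= 12);
  std::vector<float> dtab;
  std::unordered_map<uint64_t, double> htab;
  if (dense) {
    dtab.assign((size_t) 1 << (2 * k), 0.0f);
    for (R_xlen_t i = 0; i < codes.size(); ++i)
      dtab[(size_t) codes[i]] = (float) counts[i];
  } else {
    htab.reserve((size_t) codes.size() * 2);
    for (R_xlen_t i = 0; i < codes.size(); ++i)
      htab[(uint64_t) codes[i]] = counts[i];
  }
  R_xlen_t nc = centers.size();
  NumericMatrix out(nc, 2);
  std::vector<uint64_t> ball;
  for (R_xlen_t ci = 0; ci < nc; ++ci) {
    uint64_t c = (uint64_t) centers[ci];
    ball.clear();
    ball.push_back(c);
    if (r > 0) enum_ball_rec(c, k, 0, r, ball);
    double sum = 0.0, size = 0.0;
    if (!rc) {
      for (size_t i = 0; i < ball.size(); ++i) {
        uint64_t m = ball[i];
        if (dense) sum += (double) dtab[(size_t) m];
        else {
          std::unordered_map<uint64_t, double>::iterator it = htab.find(m);
          if (it != htab.end()) sum += it->second;
        }
      }
      size = (double) ball.size();
    } else {
      uint64_t rcc = rc_code(c, k);
      long inter = 0;
      for (size_t i = 0; i < ball.size(); ++i) {
        uint64_t m = ball[i];
        uint64_t rm = rc_code(m, k);
        uint64_t cm = m < rm ? m : rm;
        double v = 0.0;
        if (dense) v = (double) dtab[(size_t) cm];
        else {
          std::unordered_map<uint64_t, double>::iterator it = htab.find(cm);
          if (it != htab.end()) v = it->second;
        }
        bool in_both = ham_code(m, rcc, k) <= r;
        if (in_both) ++inter;
        sum += (in_both && m != rm) ? 0.5 * v : v;
      }
      size = 2.0 * (double) ball.size() - (double) inter;
    }
    out(ci, 0) = sum;
    out(ci, 1) = size;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ball_stats(NumericVector codes, NumericVector counts,
                             NumericVector centers, int k, int r, bool rc) {
  return ball_stats_impl(codes, counts, centers, k, r, rc);
}

static std::unordered_set<uint64_t> member_set(NumericVector members, int k,
                                               bool rc) {
  std::unordered_set<uint64_t> set;
  set.reserve((size_t) members.size() * (rc ? 4 : 2));
  for (R_xlen_t i = 0; i < members.size(); ++i) {
    uint64_t m = (uint64_t) members[i];
    set.insert(m);
    if (rc) set.insert(rc_code(m, k));
  }
  return set;
}

// Blank every window matching a member (union of matched positions, scanned
// against the original sequence) with the sentinel 'N'.
// [[Rcpp::export]]
CharacterVector cpp_mask_members(CharacterVector seqs, int k,
                                 NumericVector members, bool rc) {
  std::unordered_set<uint64_t> set = member_set(members, k, rc);
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  R_xlen_t ns = seqs.size();
  CharacterVector out(ns);
  std::vector<char> hit;
  for (R_xlen_t s = 0; s < ns; ++s) {
    SEXP el = STRING_ELT(seqs, s);
    if (el == NA_STRING) { out[s] = NA_STRING; continue; }
    const char* str = CHAR(el);
    int n = LENGTH(el);
    std::string res(str, (size_t) n);
    hit.assign((size_t) n, 0);
    uint64_t code = 0;
    int valid = 0;
    bool any = false;
    for (int i = 0; i < n; ++i) {
      int b = base_code(str[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t) b) & mask;
      if (++valid >= k && set.count(code)) {
        any = true;
        for (int j = i - k + 1; j <= i; ++j) hit[(size_t) j] = 1;
      }
    }
    if (any)
      for (int i = 0; i < n; ++i)
        if (hit[(size_t) i]) res[(size_t) i] = 'N';
    out[s] = res;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_member_hits(CharacterVector seqs, int k,
                              NumericVector members, bool rc) {
  std::unordered_set<uint64_t> set = member_set(members, k, rc);
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  R_xlen_t ns = seqs.size();
  LogicalVector out(ns);
  for (R_xlen_t s = 0; s < ns; ++s) {
    SEXP el = STRING_ELT(seqs, s);
    bool found = false;
    if (el != NA_STRING) {
      const char* str = CHAR(el);
      int n = LENGTH(el);
      uint64_t code = 0;
      int valid = 0;
      for (int i = 0; i < n && !found; ++i) {
        int b = base_code(str[i]);
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t) b) & mask;
        if (++valid >= k && set.count(code)) found = true;
      }
    }
    out[s] = found;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_hamming_matrix(CharacterVector items) {
  R_xlen_t n = items.size();
  IntegerMatrix out(n, n);
  std::vector<const char*> ptr((size_t) n);
  std::vector<int> len((size_t) n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP el = STRING_ELT(items, i);
    ptr[(size_t) i] = CHAR(el);
    len[(size_t) i] = LENGTH(el);
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const char* a = ptr[(size_t) i];
      const char* b = ptr[(size_t) j];
      int L = len[(size_t) i];
      int d = 0;
      for (int p = 0; p < L; ++p)
        if (a[p] != b[p]) ++d;
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// Mismatch-tolerant scan of a consensus over each read (both strands when
// rc = true).  Forward matches win when a window matches both orientations.
// [[Rcpp::export]]
DataFrame cpp_scan_consensus(CharacterVector seqs, std::string cons,
                             int max_mm, bool rc) {
  int L = (int) cons.size();
  std::string crc(cons.rbegin(), cons.rend());
  for (size_t i = 0; i < crc.size(); ++i) {
    int b = base_code(crc[i]);
    crc[i] = (b >= 0) ? BASES[3 - b] : crc[i];
  }
  std::vector<int> read, start, mm;
  std::vector<std::string> strand;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    SEXP el = STRING_ELT(seqs, s);
    if (el == NA_STRING) continue;
    const char* str = CHAR(el);
    int n = LENGTH(el);
    for (int i = 0; i + L <= n; ++i) {
      int df = 0, dr = 0;
      for (int p = 0; p < L; ++p) {
        if (str[i + p] != cons[(size_t) p]) ++df;
        if (str[i + p] != crc[(size_t) p]) ++dr;
      }
      if (df <= max_mm) {
        read.push_back((int) s + 1);
        start.push_back(i);
        mm.push_back(df);
        strand.push_back("+");
      } else if (rc && dr <= max_mm) {
        read.push_back((int) s + 1);
        start.push_back(i);
        mm.push_back(dr);
        strand.push_back("-");
      }
    }
  }
  return DataFrame::create(_["read"] = read, _["start"] = start,
                           _["mismatches"] = mm, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// Full-batch gradient descent on the cross-entropy loss between the
// high-dimensional similarities P and the low-dimensional Student-type
// similarities q = 1/(1+d^2).  Near-coincident points receive Gaussian
// diffusion noise before each gradient evaluation; per-point gradient norms
// are clipped at `clip` (0 disables clipping).  Uses R's RNG.
// [[Rcpp::export]]
List cpp_embed(NumericMatrix P, NumericMatrix W0, int iters, double lr,
               double thr, double sd, double clip) {
  int n = P.nrow();
  std::vector<double> wx((size_t) n), wy((size_t) n);
  std::vector<double> gx((size_t) n), gy((size_t) n);
  for (int i = 0; i < n; ++i) {
    wx[(size_t) i] = W0(i, 0);
    wy[(size_t) i] = W0(i, 1);
  }
  // entropy part of the loss is constant in W
  double H = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double p = P(i, j);
      double h = 0.0;
      if (p > 0.0) h += p * std::log(p);
      if (p < 1.0) h += (1.0 - p) * std::log(1.0 - p);
      H += 2.0 * h;
    }
  }
  NumericVector loss(iters);
  double thr2 = thr * thr;
  const double qlo = 1e-12, qhi = 1.0 - 1e-12;
  for (int it = 0; it < iters; ++it) {
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
    // diffusion escape for near-coincident pairs
    if (thr > 0.0) {
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j) {
          if (i == j) continue;
          double dx = wx[(size_t) i] - wx[(size_t) j];
          double dy = wy[(size_t) i] - wy[(size_t) j];
          if (dx * dx + dy * dy <= thr2) {
            wx[(size_t) j] += norm_rand() * sd;
            wy[(size_t) j] += norm_rand() * sd;
          }
        }
      }
    }
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    double cross = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = wx[(size_t) i] - wx[(size_t) j];
        double dy = wy[(size_t) i] - wy[(size_t) j];
        double d2 = dx * dx + dy * dy;
        double q = 1.0 / (1.0 + d2);
        double p = P(i, j);
        double qc = q < qlo ? qlo : (q > qhi ? qhi : q);
        double term = 0.0;
        if (p > 0.0) term += p * std::log(qc);
        if (p < 1.0) term += (1.0 - p) * std::log(1.0 - qc);
        cross += term;
        if (d2 > 0.0) {
          double coef = 4.0 * (p - q) / d2;
          gx[(size_t) i] += coef * dx;
          gy[(size_t) i] += coef * dy;
          gx[(size_t) j] -= coef * dx;
          gy[(size_t) j] -= coef * dy;
        }
      }
    }
    loss[it] = H - 2.0 * cross;
    for (int i = 0; i < n; ++i) {
      double nx = gx[(size_t) i], ny = gy[(size_t) i];
      if (clip > 0.0) {
        double nrm = std::sqrt(nx * nx + ny * ny);
        if (nrm > clip) {
          nx *= clip / nrm;
          ny *= clip / nrm;
        }
      }
      wx[(size_t) i] -= lr * nx;
      wy[(size_t) i] -= lr * ny;
    }
  }
  NumericMatrix W(n, 2);
  for (int i = 0; i < n; ++i) {
    W(i, 0) = wx[(size_t) i];
    W(i, 1) = wy[(size_t) i];
  }
  return List::create(_["W"] = W, _["loss"] = loss);
}
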