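// Smith-Waterman local alignment, affine gaps (a gap of length k costs
// gap_open + k * gap_extend).  Two paths: a plain scalar DP, and a striped
// SSE2 16-bit implementation (Farrar 2007) used for the all-vs-all proteome
// searches.  Scores are saturating 16-bit in the striped path; pairs whose
// score bound exceeds the 16-bit range fall back to the scalar path.
#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <algorithm>
#ifdef __SSE2__
#include <emmintrin.h>
#endif

using namespace Rcpp;

static void build_charmap(const std::string &alphabet, int *cmap, int fallback) {
  for (int i = 0; i < 256; ++i) cmap[i] = fallback;
  for (size_t i = 0; i < alphabet.size(); ++i)
    cmap[(unsigned char)alphabet[i]] = (int)i;
}

static std::vector<int> encode_seq(const char *s, const int *cmap) {
  size_t n = std::strlen(s);
  std::vector<int> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = cmap[(unsigned char)s[i]];
  return v;
}

// Plain O(mn) scalar DP, 32-bit scores.
static int sw_scalar(const std::vector<int> &a, const std::vector<int> &b,
                     const int *S, int K, int go, int ge) {
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return 0;
  const int goe = go + ge;
  std::vector<int> H(n + 1, 0), F(n + 1, 0);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int *Srow = S + a[i - 1] * K;
    int diag = 0, e = 0, hleft = 0;
    for (int j = 1; j <= n; ++j) {
      e = std::max(e - ge, hleft - goe);
      int f = std::max(F[j] - ge, H[j] - goe);
      int h = diag + Srow[b[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      F[j] = f;
      hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

#ifdef __SSE2__

// Striped query profile for the 16-bit Farrar kernel.
struct Profile16 {
  int seg_len;
  int qlen;
  std::vector<int16_t> data;  // K * seg_len * 8, 16-byte-aligned enough for loadu
};

static void build_profile16(const std::vector<int> &q, const int *S, int K,
                            Profile16 &P) {
  const int qlen = (int)q.size();
  const int seg = (qlen + 7) / 8;
  P.seg_len = seg;
  P.qlen = qlen;
  P.data.assign((size_t)K * seg * 8, 0);
  for (int a = 0; a < K; ++a) {
    int16_t *row = P.data.data() + (size_t)a * seg * 8;
    for (int i = 0; i < seg; ++i)
      for (int k = 0; k < 8; ++k) {
        int pos = k * seg + i;
        row[i * 8 + k] = (pos < qlen) ? (int16_t)S[a * K + q[pos]] : 0;
      }
  }
}

static inline int16_t hmax_epi16(__m128i v) {
  v = _mm_max_epi16(v, _mm_srli_si128(v, 8));
  v = _mm_max_epi16(v, _mm_srli_si128(v, 4));
  v = _mm_max_epi16(v, _mm_srli_si128(v, 2));
  return (int16_t)_mm_extract_epi16(v, 0);
}

static int sw_striped16(const Profile16 &P, const std::vector<int> &t,
                        int go, int ge) {
  const int seg = P.seg_len;
  const int tlen = (int)t.size();
  if (P.qlen == 0 || tlen == 0) return 0;
  const __m128i vZero = _mm_setzero_si128();
  const __m128i vGoe = _mm_set1_epi16((int16_t)(go + ge));
  const __m128i vGe = _mm_set1_epi16((int16_t)ge);
  std::vector<__m128i> pvH(seg, vZero), pvHLoad(seg, vZero), pvE(seg, vZero);
  __m128i vMax = vZero;
  for (int j = 0; j < tlen; ++j) {
    const __m128i *vP =
        (const __m128i *)(P.data.data() + (size_t)t[j] * seg * 8);
    __m128i vF = vZero;
    __m128i vH = _mm_slli_si128(pvH[seg - 1], 2);
    pvH.swap(pvHLoad);
    for (int i = 0; i < seg; ++i) {
      vH = _mm_adds_epi16(vH, _mm_loadu_si128(vP + i));
      vH = _mm_max_epi16(vH, pvE[i]);
      vH = _mm_max_epi16(vH, vF);
      vH = _mm_max_epi16(vH, vZero);
      pvH[i] = vH;
      vMax = _mm_max_epi16(vMax, vH);
      const __m128i vHg = _mm_subs_epu16(vH, vGoe);
      pvE[i] = _mm_max_epi16(_mm_subs_epu16(pvE[i], vGe), vHg);
      vF = _mm_max_epi16(_mm_subs_epu16(vF, vGe), vHg);
      vH = pvHLoad[i];
    }
    // lazy-F: propagate vertical gaps that wrap across stripe segments
    vF = _mm_slli_si128(vF, 2);
    int i = 0;
    __m128i vTemp = _mm_subs_epu16(pvH[0], vGoe);
    int guard = 0;
    while (_mm_movemask_epi8(_mm_cmpgt_epi16(vF, vTemp))) {
      pvH[i] = _mm_max_epi16(pvH[i], vF);
      vMax = _mm_max_epi16(vMax, pvH[i]);
      vF = _mm_subs_epu16(vF, vGe);
      if (++i >= seg) {
        i = 0;
        vF = _mm_slli_si128(vF, 2);
        // vF shrinks by ge every step and saturates at 0, so the loop
        // provably terminates; the guard is a pure safety net.
        if (++guard > 100000) break;
      }
      vTemp = _mm_subs_epu16(pvH[i], vGoe);
    }
  }
  return (int)hmax_epi16(vMax);
}
#endif  // __SSE2__

// Upper bound on the attainable score; used to decide 16-bit safety.
static int score_bound(int m, int n, int smax) {
  long b = (long)std::min(m, n) * (long)smax;
  return b > 1000000L ? 1000000 : (int)b;
}

// [[Rcpp::export]]
std::string cpp_sw_backend() {
#ifdef __SSE2__
  return "sse2-striped";
#else
  return "scalar";
#endif
}

// [[Rcpp::export]]
int cpp_sw_pair(std::string a, std::string b, IntegerMatrix smat,
                std::string alphabet, int gap_open, int gap_ext) {
  const int K = smat.nrow();
  int cmap[256];
  build_charmap(alphabet, cmap, K - 1);
  std::vector<int> Srm((size_t)K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) Srm[i * K + j] = smat(i, j);
  std::vector<int> ea = encode_seq(a.c_str(), cmap);
  std::vector<int> eb = encode_seq(b.c_str(), cmap);
  return sw_scalar(ea, eb, Srm.data(), K, gap_open, gap_ext);
}

// Scores of every query (rows) against every target (columns).
// [[Rcpp::export]]
IntegerMatrix cpp_sw_all(CharacterVector queries, CharacterVector targets,
                         IntegerMatrix smat, std::string alphabet,
                         int gap_open, int gap_ext) {
  const int K = smat.nrow();
  int cmap[256];
  build_charmap(alphabet, cmap, K - 1);
  std::vector<int> Srm((size_t)K * K);
  int smax = 0;
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) {
      Srm[i * K + j] = smat(i, j);
      if (smat(i, j) > smax) smax = smat(i, j);
    }
  const int nq = queries.size(), nt = targets.size();
  std::vector<std::vector<int> > et(nt);
  for (int j = 0; j < nt; ++j)
    et[j] = encode_seq(CHAR(STRING_ELT(targets, j)), cmap);
  IntegerMatrix out(nq, nt);
  for (int i = 0; i < nq; ++i) {
    std::vector<int> eq = encode_seq(CHAR(STRING_ELT(queries, i)), cmap);
#ifdef __SSE2__
    Profile16 P;
    build_profile16(eq, Srm.data(), K, P);
    for (int j = 0; j < nt; ++j) {
      if (score_bound((int)eq.size(), (int)et[j].size(), smax) < 30000)
        out(i, j) = sw_striped16(P, et[j], gap_open, gap_ext);
      else
        out(i, j) = sw_scalar(eq, et[j], Srm.data(), K, gap_open, gap_ext);
    }
#else
    for (int j = 0; j < nt; ++j)
      out(i, j) = sw_scalar(eq, et[j], Srm.data(), K, gap_open, gap_ext);
#endif
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Self-alignment score of each sequence against itself.
// [[Rcpp::export]]
IntegerVector cpp_sw_self(CharacterVector seqs, IntegerMatrix smat,
                          std::string alphabet, int gap_open, int gap_ext) {
  const int K = smat.nrow();
  int cmap[256];
  build_charmap(alphabet, cmap, K - 1);
  std::vector<int> Srm((size_t)K * K);
  int smax = 0;
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) {
      Srm[i * K + j] = smat(i, j);
      if (smat(i, j) > smax) smax = smat(i, j);
    }
  const int n = seqs.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> e = encode_seq(CHAR(STRING_ELT(seqs, i)), cmap);
#ifdef __SSE2__
    if (score_bound((int)e.size(), (int)e.size(), smax) < 30000) {
      Profile16 P;
      build_profile16(e, Srm.data(), K, P);
      out[i] = sw_striped16(P, e, gap_open, gap_ext);
    } else {
      out[i] = sw_scalar(e, e, Srm.data(), K, gap_open, gap_ext);
    }
#else
    out[i] = sw_scalar(e, e, Srm.data(), K, gap_open, gap_ext);
#endif
  }
  return out;
}
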