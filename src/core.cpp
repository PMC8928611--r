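// Core sequence kernels: semi-global affine alignment, paired-read merging,
// greedy centroid clustering with an 8-mer prescreen, chimera breakpoint
// scan, and the read simulator's inner loops. All randomness goes through
// R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <string>
using namespace Rcpp;

static const int NEG_INF = -1000000000;

// ---------------------------------------------------------------------------
// Semi-global (overlap) alignment, affine gaps.
// Scoring: match +1, mismatch -1; a gap run of length L costs open + L*ext
// (defaults open=2, ext=1). Terminal gaps are free. Tie-breaking in the
// traceback prefers diagonal moves (mismatch over gap), then gaps in the
// query (sequence a).
struct AlnResult {
  std::string aa, ab;
  int score;
  int n_mismatch, n_gap_runs, n_term_cols, cols;
};

static void count_aln(AlnResult &r) {
  const std::string &aa = r.aa, &ab = r.ab;
  int n = (int)aa.size();
  int lead = 0, trail = 0;
  while (lead < n && (aa[lead] == '-' || ab[lead] == '-')) lead++;
  while (trail < n - lead && (aa[n - 1 - trail] == '-' || ab[n - 1 - trail] == '-')) trail++;
  r.n_term_cols = lead + trail;
  r.cols = n - r.n_term_cols;
  int mism = 0, runs = 0;
  char prev = 'M';
  for (int i = lead; i < n - trail; i++) {
    if (aa[i] == '-' || ab[i] == '-') {
      char cur = (aa[i] == '-') ? 'A' : 'B';
      if (cur != prev) runs++;
      prev = cur;
    } else {
      if (aa[i] != ab[i]) mism++;
      prev = 'M';
    }
  }
  r.n_mismatch = mism;
  r.n_gap_runs = runs;
}

static AlnResult align_core(const std::string &a, const std::string &b,
                            int match, int mismatch, int gap_open, int gap_ext,
                            bool ends_free = false) {
  int la = (int)a.size(), lb = (int)b.size();
  int w = lb + 1;
  // H = best ending in match/mismatch; E = gap in a (consumes b);
  // F = gap in b (consumes a). Global: terminal gaps are charged in the
  // score (they are excluded later from the distance counts).
  // Rolling score rows; full matrix only for the packed traceback byte
  // (bits 0-1: H came from diag/E/F; bit 2: E extends; bit 3: F extends).
  // Buffers are reused across calls; the DP is the pipeline's hot path.
  static thread_local std::vector<int> Hrow, Frow;
  static thread_local std::vector<unsigned char> tb;
  size_t need = (size_t)(la + 1) * w;
  if (tb.size() < need) tb.resize(need);
  if ((int)Hrow.size() < w) { Hrow.resize(w); Frow.resize(w); }
  Hrow[0] = 0;
  tb[0] = 0;
  for (int j = 1; j <= lb; j++) {
    Hrow[j] = ends_free ? 0 : -(gap_open + j * gap_ext);
    Frow[j] = NEG_INF;
    tb[j] = ends_free ? 3 : (unsigned char)(1 | ((j == 1) ? 0 : 4));
  }
  // local-mode endpoint = global argmax (ties prefer corner-most cell)
  int bs = 0, bi = 0, bj = (ends_free ? 0 : lb);
  int final_score = (la == 0) ? Hrow[lb] : 0;
  for (int i = 1; i <= la; i++) {
    unsigned char *tbi = &tb[(size_t)i * w];
    const char ai = a[i - 1];
    int hdiag = Hrow[0];                    // H[i-1][0]
    Hrow[0] = ends_free ? 0 : -(gap_open + i * gap_ext);  // H[i][0]
    int Ej = NEG_INF;                       // E[i][0]
    tbi[0] = ends_free ? 3 : (unsigned char)(2 | ((i == 1) ? 0 : 8));
    for (int j = 1; j <= lb; j++) {
      // branchless selects; ties keep the first operand (diag > E > F,
      // gap-open > gap-extend)
      int eo = Hrow[j - 1] - gap_open - gap_ext;   // Hrow[j-1] = H[i][j-1]
      int ee = Ej - gap_ext;
      int e_ext = ee > eo;
      Ej = e_ext ? ee : eo;
      int fo = Hrow[j] - gap_open - gap_ext;       // Hrow[j] = H[i-1][j]
      int fe = Frow[j] - gap_ext;
      int f_ext = fe > fo;
      int Fj = f_ext ? fe : fo;
      Frow[j] = Fj;
      int diag = hdiag + ((ai == b[j - 1]) ? match : -mismatch);
      hdiag = Hrow[j];
      // prefer diagonal, then E (gap in query a), then F
      int use_e = Ej > diag;
      int best = use_e ? Ej : diag;
      int use_f = Fj > best;
      best = use_f ? Fj : best;
      int dir = use_f ? 2 : use_e;
      if (ends_free && best <= 0) { best = 0; dir = 3; }
      Hrow[j] = best;
      tbi[j] = (unsigned char)(dir | (e_ext << 2) | (f_ext << 3));
      if (ends_free && (best > bs ||
                        (best == bs && i + j > bi + bj) ||
                        (best == bs && i + j == bi + bj && i > bi))) {
        bs = best; bi = i; bj = j;
      }
    }
    if (i == la) final_score = Hrow[lb];
  }
  if (!ends_free) { bi = la; bj = lb; } else { final_score = bs; }
  std::string ra, rb;
  ra.reserve(la + lb); rb.reserve(la + lb);
  // trailing unaligned ends beyond the chosen endpoint
  for (int i = la; i > bi; i--) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = lb; j > bj; j--) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    unsigned char t = tb[(size_t)i * w + j];
    if (state == 'H') {
      unsigned char dir = t & 3;
      if (dir == 3) break;                 // local start
      if (dir == 0) {
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); i--; j--;
      } else if (dir == 1) state = 'E';
      else state = 'F';
    } else if (state == 'E') {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      if (!(t & 4)) state = 'H';
      j--;
    } else {
      ra.push_back(a[i - 1]); rb.push_back('-');
      if (!(t & 8)) state = 'H';
      i--;
    }
  }
  while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); i--; }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); j--; }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  AlnResult r; r.aa = ra; r.ab = rb; r.score = final_score;
  count_aln(r);
  return r;
}

// [[Rcpp::export]]
List cpp_align_pair(std::string a, std::string b, int match = 1,
                    int mismatch = 1, int gap_open = 2, int gap_ext = 1,
                    bool ends_free = false) {
  AlnResult r = align_core(a, b, match, mismatch, gap_open, gap_ext, ends_free);
  return List::create(
    _["aligned_a"] = r.aa, _["aligned_b"] = r.ab, _["score"] = r.score,
    _["n_mismatch"] = r.n_mismatch, _["n_internal_gap_runs"] = r.n_gap_runs,
    _["n_terminal_gap_cols"] = r.n_term_cols, _["aligned_cols"] = r.cols);
}

// ---------------------------------------------------------------------------
// Reverse complement
static char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
    case 'T': return 'A'; case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a'; default: return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int k = 0; k < n; k++) {
    std::string s = as<std::string>(x[k]);
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); i++) r[i] = comp(r[i]);
    out[k] = r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Paired-read merging: best ungapped overlap of fwd against revcomp(rev).
// Score = matches - mismatches in the overlap; admissible overlaps have
// length >= min_overlap and mismatch fraction <= max_mm_frac; ties go to the
// longest overlap. Consensus: agreement keeps max quality; disagreement
// takes the higher-quality base with quality |q1-q2|; equal-quality
// disagreement yields N at quality 0.
static bool merge_core(const std::string &f, const std::vector<int> &qf,
                       const std::string &rc, const std::vector<int> &qr,
                       int min_overlap, double max_mm_frac,
                       std::string &seq, std::vector<int> &qual, int &ov_out) {
  int lf = (int)f.size(), lr = (int)rc.size();
  int max_ov = std::min(lf, lr);
  int best_ov = -1, best_score = NEG_INF;
  int allowed_base;
  for (int ov = max_ov; ov >= min_overlap; ov--) {
    allowed_base = (int)std::floor(max_mm_frac * ov + 1e-9);
    int mm = 0, i0 = lf - ov;
    bool bail = false;
    for (int k = 0; k < ov; k++) {
      if (f[i0 + k] != rc[k]) {
        if (++mm > allowed_base) { bail = true; break; }
      }
    }
    if (bail) continue;
    int score = ov - 2 * mm;
    if (score > best_score) { best_score = score; best_ov = ov; }
    // ties keep the earlier (longer) overlap since we scan longest first
  }
  if (best_ov < 0) return false;
  int ov = best_ov, i0 = lf - ov;
  seq.assign(f, 0, i0);
  qual.assign(qf.begin(), qf.begin() + i0);
  for (int k = 0; k < ov; k++) {
    char bf = f[i0 + k], br = rc[k];
    int q1 = qf[i0 + k], q2 = qr[k];
    if (bf == br) { seq.push_back(bf); qual.push_back(std::max(q1, q2)); }
    else if (q1 > q2) { seq.push_back(bf); qual.push_back(q1 - q2); }
    else if (q2 > q1) { seq.push_back(br); qual.push_back(q2 - q1); }
    else { seq.push_back('N'); qual.push_back(0); }
  }
  seq.append(rc, ov, lr - ov);
  qual.insert(qual.end(), qr.begin() + ov, qr.end());
  ov_out = ov;
  return true;
}

// [[Rcpp::export]]
List cpp_merge_pair(std::string fwd, IntegerVector fq, std::string rev,
                    IntegerVector rq, int min_overlap, double max_mm_frac) {
  std::string rc(rev.rbegin(), rev.rend());
  for (size_t i = 0; i < rc.size(); i++) rc[i] = comp(rc[i]);
  std::vector<int> qr(rq.size());
  for (int i = 0; i < rq.size(); i++) qr[i] = rq[rq.size() - 1 - i];
  std::vector<int> qf = as<std::vector<int>>(fq);
  std::string seq; std::vector<int> qual; int ov = 0;
  bool ok = merge_core(fwd, qf, rc, qr, min_overlap, max_mm_frac, seq, qual, ov);
  if (!ok) return List::create(_["ok"] = false);
  return List::create(_["ok"] = true, _["seq"] = seq,
                      _["qual"] = wrap(qual), _["overlap_len"] = ov);
}

static std::vector<int> phred_decode(const std::string &s) {
  std::vector<int> q(s.size());
  for (size_t i = 0; i < s.size(); i++) q[i] = (int)s[i] - 33;
  return q;
}
static std::string phred_encode(const std::vector<int> &q) {
  std::string s(q.size(), '!');
  for (size_t i = 0; i < q.size(); i++) s[i] = (char)(q[i] + 33);
  return s;
}

// Batch merge over Phred+33 quality strings; returns merged seq/qual plus
// per-contig mean quality (for the QC stage) and overlap length.
// [[Rcpp::export]]
List cpp_merge_batch(CharacterVector fwd, CharacterVector fqual,
                     CharacterVector rev, CharacterVector rqual,
                     int min_overlap, double max_mm_frac) {
  int n = fwd.size();
  CharacterVector seq(n), qual(n);
  IntegerVector ov(n);
  LogicalVector ok(n);
  NumericVector meanq(n);
  for (int k = 0; k < n; k++) {
    std::string f = as<std::string>(fwd[k]);
    std::string r = as<std::string>(rev[k]);
    std::vector<int> qf = phred_decode(as<std::string>(fqual[k]));
    std::vector<int> qrr = phred_decode(as<std::string>(rqual[k]));
    std::string rc(r.rbegin(), r.rend());
    for (size_t i = 0; i < rc.size(); i++) rc[i] = comp(rc[i]);
    std::vector<int> qr(qrr.rbegin(), qrr.rend());
    std::string s; std::vector<int> q; int o = 0;
    bool good = merge_core(f, qf, rc, qr, min_overlap, max_mm_frac, s, q, o);
    ok[k] = good;
    if (good) {
      seq[k] = s; qual[k] = phred_encode(q); ov[k] = o;
      double m = 0; for (size_t i = 0; i < q.size(); i++) m += q[i];
      meanq[k] = m / q.size();
    } else { seq[k] = NA_STRING; qual[k] = NA_STRING; ov[k] = NA_INTEGER; meanq[k] = NA_REAL; }
  }
  return List::create(_["ok"] = ok, _["seq"] = seq, _["qual"] = qual,
                      _["overlap_len"] = ov, _["mean_q"] = meanq);
}

// ---------------------------------------------------------------------------
// Greedy abundance-sorted centroid clustering.
// Input sequences must already be ordered (decreasing count, ties
// lexicographic). Each sequence joins the first (founding-order) centroid
// within `cutoff` of it, else founds a new centroid. With prescreen=true an
// inverted 8-mer index skips centroids that cannot be within the cutoff
// (bound: shared distinct 8-mers >= V_query - 8*floor(cutoff*max(lq,lc)),
// conservative for substitution-dominated divergence), and equal-length
// pairs whose Hamming distance is already <= cutoff join without the DP.
static inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3; }
  return -1;
}

static int kmer_list(const std::string &s, std::vector<int> &out,
                     std::vector<unsigned char> &seen, std::vector<int> &touched) {
  out.clear(); touched.clear();
  int k = 0, valid = 0;
  const int mask = (1 << 16) - 1;
  for (size_t i = 0; i < s.size(); i++) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; continue; }
    k = ((k << 2) | c) & mask;
    if (++valid >= 8) {
      if (!seen[k]) { seen[k] = 1; out.push_back(k); touched.push_back(k); }
    }
  }
  for (int t : touched) seen[t] = 0;
  return (int)out.size();
}

// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double cutoff,
                                 bool prescreen = true) {
  int n = seqs.size();
  IntegerVector assign(n);
  std::vector<std::string> cent;                 // centroid sequences
  std::vector<std::vector<int>> cent_kmers;      // distinct 8-mers per centroid
  std::vector<std::vector<int>> index(1 << 16);  // kmer -> centroid list
  std::vector<int> shared;                       // scratch: shared counts
  std::vector<unsigned char> seen(1 << 16, 0);
  std::vector<int> kq, touched;
  for (int s = 0; s < n; s++) {
    std::string q = as<std::string>(seqs[s]);
    int lq = (int)q.size();
    int joined = -1;
    int nc = (int)cent.size();
    if (prescreen) {
      kmer_list(q, kq, seen, touched);
      int Vq = (int)kq.size();
      shared.assign(nc, 0);
      for (int km : kq) for (int c : index[km]) shared[c]++;
      for (int c = 0; c < nc && joined < 0; c++) {
        int lc = (int)cent[c].size();
        int D = (int)std::floor(cutoff * std::max(lq, lc) + 1e-9);
        if (shared[c] < Vq - 8 * D) continue;
        if (lc == lq) {
          int h = 0, lim = D;
          bool within = true;
          for (int i = 0; i < lq; i++) {
            if (q[i] != cent[c][i] && ++h > lim) { within = false; break; }
          }
          if (within) { joined = c; break; }
        }
        AlnResult r = align_core(q, cent[c], 1, 1, 2, 1);
        if (r.cols > 0 &&
            (double)(r.n_mismatch + r.n_gap_runs) / r.cols <= cutoff + 1e-12)
          joined = c;
      }
    } else {
      for (int c = 0; c < nc && joined < 0; c++) {
        AlnResult r = align_core(q, cent[c], 1, 1, 2, 1);
        if (r.cols > 0 &&
            (double)(r.n_mismatch + r.n_gap_runs) / r.cols <= cutoff + 1e-12)
          joined = c;
      }
    }
    if (joined < 0) {
      joined = nc;
      cent.push_back(q);
      if (prescreen) {
        cent_kmers.push_back(kq);
        for (int km : kq) index[km].push_back(joined);
      }
    }
    assign[s] = joined + 1;
  }
  return assign;
}

// ---------------------------------------------------------------------------
// Chimera breakpoint scan. diffmat is an L x ncand 0/1 matrix: diffmat[p,c]
// = 1 iff the query differs from candidate c at query position p (gaps
// projected onto query coordinates). Finds the ordered candidate pair (A,B)
// and breakpoint k (query[1..k] vs A, query[(k+1)..L] vs B) minimizing total
// model differences; candidates must be supplied in lexicographic id order
// so the (model, k, A, B) comparator realises the documented tie-breaking.
// [[Rcpp::export]]
List cpp_chimera_scan(IntegerMatrix diffmat) {
  int L = diffmat.nrow(), nc = diffmat.ncol();
  std::vector<int> tot(nc, 0);
  std::vector<std::vector<int>> pre(nc, std::vector<int>(L + 1, 0));
  for (int c = 0; c < nc; c++) {
    for (int p = 0; p < L; p++) pre[c][p + 1] = pre[c][p] + diffmat(p, c);
    tot[c] = pre[c][L];
  }
  int sbest = tot[0], sidx = 0;
  for (int c = 1; c < nc; c++) if (tot[c] < sbest) { sbest = tot[c]; sidx = c; }
  int mbest = NEG_INF * -1, mk = -1, ma = -1, mb = -1;
  mbest = 1 << 30;
  for (int a = 0; a < nc; a++) {
    for (int b = 0; b < nc; b++) {
      if (a == b) continue;
      const std::vector<int> &pa = pre[a], &pb = pre[b];
      int tb = tot[b];
      for (int k = 1; k < L; k++) {
        int m = pa[k] + tb - pb[k];
        if (m < mbest) { mbest = m; mk = k; ma = a; mb = b; }
      }
    }
  }
  int vl = 0, vr = 0;
  if (ma >= 0) {
    for (int p = 0; p < mk; p++)
      if (diffmat(p, ma) == 0 && diffmat(p, mb) == 1) vl++;
    for (int p = mk; p < L; p++)
      if (diffmat(p, mb) == 0 && diffmat(p, ma) == 1) vr++;
  }
  return List::create(_["single_best"] = sbest, _["single_idx"] = sidx + 1,
                      _["model_best"] = (ma >= 0) ? mbest : NA_INTEGER,
                      _["breakpoint"] = (ma >= 0) ? mk : NA_INTEGER,
                      _["a"] = (ma >= 0) ? ma + 1 : NA_INTEGER,
                      _["b"] = (mb >= 0) ? mb + 1 : NA_INTEGER,
                      _["votes_left"] = vl, _["votes_right"] = vr);
}

// ---------------------------------------------------------------------------
// Read simulator inner loop: per-base substitution errors plus a linearly
// decaying Phred profile (q_hi at the 5' end down to q_lo at the 3' end)
// with a per-read offset and per-base jitter. Uses R's RNG.
// [[Rcpp::export]]
List cpp_sim_reads(CharacterVector templates, int read_len, double err_rate,
                   double q_hi, double q_lo, double sd_read, double sd_base) {
  int n = templates.size();
  CharacterVector fseq(n), fqual(n), rseq(n), rqual(n);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int i = 0; i < n; i++) {
    std::string tpl = as<std::string>(templates[i]);
    int lt = (int)tpl.size();
    int lr = std::min(read_len, lt);
    std::string f = tpl.substr(0, lr);
    std::string r = tpl.substr(lt - lr, lr);
    std::reverse(r.begin(), r.end());
    for (int p = 0; p < lr; p++) r[p] = comp(r[p]);
    std::vector<int> qf(lr), qr(lr);
    double off_f = R::rnorm(0.0, sd_read), off_r = R::rnorm(0.0, sd_read);
    for (int p = 0; p < lr; p++) {
      if (err_rate > 0 && R::unif_rand() < err_rate) {
        int c = base_code(f[p]);
        int nb = (c + 1 + (int)(R::unif_rand() * 3)) & 3;
        f[p] = bases[nb];
      }
      if (err_rate > 0 && R::unif_rand() < err_rate) {
        int c = base_code(r[p]);
        if (c >= 0) { int nb = (c + 1 + (int)(R::unif_rand() * 3)) & 3; r[p] = bases[nb]; }
      }
      double frac = (lr > 1) ? (double)p / (lr - 1) : 0.0;
      double mu = q_hi - (q_hi - q_lo) * frac;
      int q1 = (int)std::lround(mu + off_f + R::rnorm(0.0, sd_base));
      int q2 = (int)std::lround(mu + off_r + R::rnorm(0.0, sd_base));
      qf[p] = std::min(41, std::max(2, q1));
      qr[p] = std::min(41, std::max(2, q2));
    }
    fseq[i] = f; rseq[i] = r;
    fqual[i] = phred_encode(qf); rqual[i] = phred_encode(qr);
  }
  return List::create(_["fwd_seq"] = fseq, _["fwd_qual"] = fqual,
                      _["rev_seq"] = rseq, _["rev_qual"] = rqual);
}

// Project the differences of query-vs-candidate alignments onto query
// coordinates, batched: returns an lq x ncand 0/1 matrix. A query position
// differs when it is a mismatch or sits opposite a subject gap; an
// insertion run in the query is charged to the following query position.
// [[Rcpp::export]]
IntegerMatrix cpp_diff_profiles(std::string query, CharacterVector cands) {
  int lq = (int)query.size(), nc = cands.size();
  IntegerMatrix out(lq, nc);
  for (int c = 0; c < nc; c++) {
    AlnResult r = align_core(query, as<std::string>(cands[c]), 1, 1, 2, 1);
    int qpos = 0;
    for (size_t col = 0; col < r.aa.size(); col++) {
      char qa = r.aa[col], sa = r.ab[col];
      if (qa != '-') {
        qpos++;
        if (sa == '-' || qa != sa) out(qpos - 1, c) = 1;
      } else {
        int at = std::min(qpos + 1, lq);
        out(at - 1, c) = 1;
      }
    }
  }
  return out;
}

// Distinct 8-mer presence per sequence against the 4^8 vocabulary; returns a
// list of sorted integer vectors (0-based kmer codes). Used by the
// naive-Bayes classifier.
// [[Rcpp::export]]
List cpp_kmer_sets(CharacterVector seqs, int word_len = 8) {
  int n = seqs.size();
  List out(n);
  int mask = (1 << (2 * word_len)) - 1;
  std::vector<unsigned char> seen(1 << (2 * word_len), 0);
  std::vector<int> touched;
  for (int i = 0; i < n; i++) {
    std::string s = as<std::string>(seqs[i]);
    touched.clear();
    int k = 0, valid = 0;
    std::vector<int> kms;
    for (size_t p = 0; p < s.size(); p++) {
      int c = base_code(s[p]);
      if (c < 0) { valid = 0; continue; }
      k = ((k << 2) | c) & mask;
      if (++valid >= word_len) {
        if (!seen[k]) { seen[k] = 1; kms.push_back(k); touched.push_back(k); }
      }
    }
    for (int t : touched) seen[t] = 0;
    std::sort(kms.begin(), kms.end());
    out[i] = wrap(kms);
  }
  return out;
}
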