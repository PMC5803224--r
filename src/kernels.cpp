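#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// Levenshtein distance with a cutoff: returns a value > maxd (namely maxd+1)
// as soon as the true distance is known to exceed maxd.  Banded DP, band
// half-width maxd, early exit when a full row exceeds the cutoff.
static int bounded_edit(const char* a, int la, const char* b, int lb, int maxd) {
    if (la > lb) { std::swap(a, b); std::swap(la, lb); }
    if (lb - la > maxd) return maxd + 1;
    const int INF = maxd + 1;
    std::vector<int> prev(lb + 1, INF), cur(lb + 1, INF);
    for (int j = 0; j <= std::min(lb, maxd); ++j) prev[j] = j;
    for (int i = 1; i <= la; ++i) {
        int jlo = std::max(0, i - maxd);
        int jhi = std::min(lb, i + maxd);
        std::fill(cur.begin() + jlo, cur.begin() + jhi + 1, INF);
        int rowmin = INF;
        for (int j = jlo; j <= jhi; ++j) {
            int best;
            if (j == 0) {
                best = i;
            } else {
                best = INF;
                int up = prev[j];                 // deletion from a
                if (up < INF && up + 1 < best) best = up + 1;
                int lf = cur[j - 1];              // insertion into a
                if (lf < INF && lf + 1 < best) best = lf + 1;
                int di = prev[j - 1];             // match / substitution
                if (di < INF) {
                    int c = di + (a[i - 1] != b[j - 1] ? 1 : 0);
                    if (c < best) best = c;
                }
            }
            if (best > INF) best = INF;
            cur[j] = best;
            if (best < rowmin) rowmin = best;
        }
        if (rowmin > maxd) return maxd + 1;
        std::swap(prev, cur);
    }
    return std::min(prev[lb], INF);
}

// [[Rcpp::export]]
int edit_distance_cpp(std::string a, std::string b) {
    int cap = (int)(a.size() + b.size());
    return bounded_edit(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(), cap);
}

// Edit distance of one query against a set; entries exceeding maxd are
// reported as maxd + 1.
// [[Rcpp::export]]
IntegerVector edit_distance_to_set_cpp(std::string q, CharacterVector refs,
                                       int maxd) {
    int n = refs.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string r = as<std::string>(refs[i]);
        out[i] = bounded_edit(q.c_str(), (int)q.size(),
                              r.c_str(), (int)r.size(), maxd);
    }
    return out;
}

// [[Rcpp::export]]
IntegerMatrix edit_distance_matrix_cpp(CharacterVector seqs, int maxd) {
    int n = seqs.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    IntegerMatrix D(n, n);
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
            int d = bounded_edit(s[i].c_str(), (int)s[i].size(),
                                 s[j].c_str(), (int)s[j].size(), maxd);
            D(i, j) = d; D(j, i) = d;
        }
    return D;
}

static inline int code_of(char c) {
    switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
    }
}

// 6-mer presence bitset (4096 bits) used to prescreen sequence pairs; short
// words would saturate on 300-bp amplicons and carry no signal.
#define KMER_W 6
#define KMER_WORDS 64
struct KmerSet { uint64_t w[KMER_WORDS]; };

static KmerSet kmer_presence(const std::vector<int>& s) {
    KmerSet ks;
    for (int k = 0; k < KMER_WORDS; ++k) ks.w[k] = 0;
    int L = (int)s.size();
    for (int i = 0; i + KMER_W <= L; ++i) {
        int idx = 0; bool ok = true;
        for (int k = 0; k < KMER_W; ++k) {
            if (s[i + k] < 0) { ok = false; break; }
            idx = (idx << 2) | s[i + k];
        }
        if (ok) ks.w[idx >> 6] |= (uint64_t)1 << (idx & 63);
    }
    return ks;
}

static int kmer_size(const KmerSet& a) {
    int n = 0;
    for (int k = 0; k < KMER_WORDS; ++k) {
#if defined(__GNUC__) || defined(__clang__)
        n += __builtin_popcountll(a.w[k]);
#else
        uint64_t v = a.w[k];
        while (v) { v &= v - 1; ++n; }
#endif
    }
    return n;
}

static int kmer_shared(const KmerSet& a, const KmerSet& b) {
    int n = 0;
    for (int k = 0; k < KMER_WORDS; ++k) {
#if defined(__GNUC__) || defined(__clang__)
        n += __builtin_popcountll(a.w[k] & b.w[k]);
#else
        uint64_t v = a.w[k] & b.w[k];
        while (v) { v &= v - 1; ++n; }
#endif
    }
    return n;
}

// Single-linkage components at edit distance <= d, grown breadth-first from
// the most abundant unassigned amplicon (input must be sorted by decreasing
// abundance).  Returns 1-based component labels numbered in seed order.
// A 6-mer presence prescreen skips pairs that cannot be within d edits: one
// edit alters at most 6 of a sequence's distinct 6-mers, so edit(a,b) <= d
// implies |K(a)| - |K(a) n K(b)| <= 6d.
// [[Rcpp::export]]
IntegerVector swarm_components_cpp(CharacterVector seqs, int d) {
    int n = seqs.size();
    std::vector<std::string> s(n);
    std::vector<KmerSet> km(n);
    std::vector<int> ksize(n);
    for (int i = 0; i < n; ++i) {
        s[i] = as<std::string>(seqs[i]);
        std::vector<int> enc(s[i].size());
        for (size_t t = 0; t < s[i].size(); ++t) enc[t] = code_of(s[i][t]);
        km[i] = kmer_presence(enc);
        ksize[i] = kmer_size(km[i]);
    }
    IntegerVector label(n, 0);
    int next = 0;
    std::vector<int> queue;
    for (int seed = 0; seed < n; ++seed) {
        if (label[seed] != 0) continue;
        ++next;
        label[seed] = next;
        queue.clear();
        queue.push_back(seed);
        size_t qi = 0;
        while (qi < queue.size()) {
            int x = queue[qi++];
            for (int y = 0; y < n; ++y) {
                if (label[y] != 0) continue;
                if (ksize[x] - kmer_shared(km[x], km[y]) > KMER_W * d) continue;
                int dist = bounded_edit(s[x].c_str(), (int)s[x].size(),
                                        s[y].c_str(), (int)s[y].size(), d);
                if (dist <= d) {
                    label[y] = next;
                    queue.push_back(y);
                }
            }
        }
    }
    return label;
}

// Global-global (Needleman-Wunsch/Gotoh) alignment with affine gaps; a gap
// of length k costs open + k * ext.  Returns percent identity computed over
// all alignment columns, end gaps included.  Tie-break: diagonal, then
// vertical, then horizontal.
// [[Rcpp::export]]
NumericVector nw_identity_cpp(CharacterVector a, CharacterVector b,
                              double match, double mismatch,
                              double gap_open, double gap_ext) {
    int npair = a.size();
    if (b.size() != npair) stop("a and b must have equal length");
    NumericVector out(npair);
    const double NEG = -1e30;
    for (int p = 0; p < npair; ++p) {
        std::string s1 = as<std::string>(a[p]);
        std::string s2 = as<std::string>(b[p]);
        int n = (int)s1.size(), m = (int)s2.size();
        if (n == 0 || m == 0) stop("empty sequence in global alignment");
        int W = m + 1;
        std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
            Y((n + 1) * W, NEG);
        // traceback: which matrix each cell came from (0=M,1=X,2=Y)
        std::vector<unsigned char> tbM((n + 1) * W), tbX((n + 1) * W),
            tbY((n + 1) * W);
        M[0] = 0;
        for (int i = 1; i <= n; ++i) {
            X[i * W] = -gap_open - gap_ext * i;
            tbX[i * W] = (i == 1) ? 0 : 1;
        }
        for (int j = 1; j <= m; ++j) {
            Y[j] = -gap_open - gap_ext * j;
            tbY[j] = (j == 1) ? 0 : 2;
        }
        for (int i = 1; i <= n; ++i) {
            for (int j = 1; j <= m; ++j) {
                int c = i * W + j;
                double sc = (s1[i - 1] == s2[j - 1]) ? match : mismatch;
                // M: diagonal step
                double bm = M[c - W - 1], best = bm; unsigned char tb = 0;
                if (X[c - W - 1] > best) { best = X[c - W - 1]; tb = 1; }
                if (Y[c - W - 1] > best) { best = Y[c - W - 1]; tb = 2; }
                M[c] = best + sc; tbM[c] = tb;
                // X: gap in s2 (vertical, consume s1[i])
                double xo = M[c - W] - gap_open - gap_ext;
                double xe = X[c - W] - gap_ext;
                if (xo >= xe) { X[c] = xo; tbX[c] = 0; }
                else { X[c] = xe; tbX[c] = 1; }
                double yo2 = Y[c - W] - gap_open - gap_ext;
                if (yo2 > X[c]) { X[c] = yo2; tbX[c] = 2; }
                // Y: gap in s1 (horizontal, consume s2[j])
                double yo = M[c - 1] - gap_open - gap_ext;
                double ye = Y[c - 1] - gap_ext;
                if (yo >= ye) { Y[c] = yo; tbY[c] = 0; }
                else { Y[c] = ye; tbY[c] = 1; }
                double xo2 = X[c - 1] - gap_open - gap_ext;
                if (xo2 > Y[c]) { Y[c] = xo2; tbY[c] = 2; }
            }
        }
        // traceback from the best final state
        int i = n, j = m;
        int state = 0;
        double fin = M[n * W + m];
        if (X[n * W + m] > fin) { fin = X[n * W + m]; state = 1; }
        if (Y[n * W + m] > fin) { fin = Y[n * W + m]; state = 2; }
        long cols = 0, matches = 0;
        while (i > 0 || j > 0) {
            int c = i * W + j;
            ++cols;
            if (state == 0) {
                if (s1[i - 1] == s2[j - 1]) ++matches;
                state = tbM[c]; --i; --j;
            } else if (state == 1) {
                state = tbX[c]; --i;
            } else {
                state = tbY[c]; --j;
            }
        }
        out[p] = 100.0 * matches / cols;
    }
    return out;
}

// Simplified UCHIME-style de-novo chimera scan on equal-length, abundance-
// sorted amplicons.  For each query the best two-parent single-breakpoint
// model over candidate parents (>= abskew x query abundance) is compared with
// the best single parent; a query is flagged when the chimeric model gains
// >= min_div identity percentage points and the chunk-free per-side vote
// score h = min(hL, hR), h_side = Y/(Y + xn*N + dn*A), reaches min_h.
// [[Rcpp::export]]
DataFrame chimera_scan_cpp(CharacterVector seqs, NumericVector abund,
                           double abskew, double min_div, double min_h,
                           double xn, double dn, int top_k,
                           int exhaustive_below) {
    int n = seqs.size();
    if (n == 0)
        return DataFrame::create(Named("query") = IntegerVector(0));
    int L = (int)std::string(seqs[0]).size();
    std::vector<std::vector<int> > enc(n, std::vector<int>(L));
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        if ((int)s.size() != L) stop("all amplicons must have equal length");
        for (int t = 0; t < L; ++t) enc[i][t] = code_of(s[t]);
    }
    std::vector<KmerSet> km(n);
    bool use_kmer = n >= exhaustive_below;
    if (use_kmer) for (int i = 0; i < n; ++i) km[i] = kmer_presence(enc[i]);

    IntegerVector out_q(n), out_pa(n), out_pb(n), out_bp(n);
    LogicalVector out_flag(n);
    NumericVector out_score(n), out_id_single(n), out_id_chim(n);

    std::vector<int> cand; cand.reserve(n);
    std::vector<std::pair<int,int> > scored;
    // prefix match sums, one row per candidate
    std::vector<std::vector<int> > S;

    for (int q = 0; q < n; ++q) {
        out_q[q] = q + 1;
        out_flag[q] = false; out_pa[q] = NA_INTEGER; out_pb[q] = NA_INTEGER;
        out_bp[q] = NA_INTEGER; out_score[q] = 0.0;
        out_id_single[q] = NA_REAL; out_id_chim[q] = NA_REAL;

        cand.clear();
        for (int j = 0; j < n; ++j)
            if (j != q && abund[j] >= abskew * abund[q] && abund[j] > abund[q])
                cand.push_back(j);
        if ((int)cand.size() < 2) continue;
        if (use_kmer && (int)cand.size() > top_k) {
            // chunked candidate search: rank parents per query chunk so the
            // minority-side parent of a chimera is not crowded out by the
            // majority parent's relatives
            const int n_chunks = 8;
            int per_chunk = std::max(1, top_k / n_chunks);
            std::vector<int> keep;
            std::vector<char> taken(n, 0);
            for (int ch = 0; ch < n_chunks; ++ch) {
                int lo = (int)((long)L * ch / n_chunks);
                int hi = (int)((long)L * (ch + 1) / n_chunks);
                std::vector<int> seg(enc[q].begin() + lo, enc[q].begin() + hi);
                KmerSet qk = kmer_presence(seg);
                scored.clear();
                for (size_t c = 0; c < cand.size(); ++c)
                    scored.push_back(std::make_pair(
                        -kmer_shared(qk, km[cand[c]]), cand[c]));
                std::stable_sort(scored.begin(), scored.end());
                int added = 0;
                for (size_t c = 0; c < scored.size() && added < per_chunk; ++c) {
                    int j = scored[c].second;
                    if (!taken[j]) { taken[j] = 1; keep.push_back(j); ++added; }
                }
            }
            std::sort(keep.begin(), keep.end());  // restore abundance order
            cand = keep;
        }
        int C = (int)cand.size();
        S.assign(C, std::vector<int>(L + 1, 0));
        for (int c = 0; c < C; ++c) {
            const std::vector<int>& p = enc[cand[c]];
            for (int t = 0; t < L; ++t)
                S[c][t + 1] = S[c][t] + (enc[q][t] == p[t] ? 1 : 0);
        }
        int best_single = -1, best_single_c = -1;
        for (int c = 0; c < C; ++c)
            if (S[c][L] > best_single) { best_single = S[c][L]; best_single_c = c; }
        (void)best_single_c;

        // best two-parent model over breakpoints
        int best_tot = -1, bA = -1, bB = -1, bT = -1;
        for (int t = 1; t < L; ++t) {
            int l1 = -1, l2 = -1, l1c = -1, l2c = -1;
            int r1 = -1, r2 = -1, r1c = -1, r2c = -1;
            for (int c = 0; c < C; ++c) {
                int lv = S[c][t];
                if (lv > l1) { l2 = l1; l2c = l1c; l1 = lv; l1c = c; }
                else if (lv > l2) { l2 = lv; l2c = c; }
                int rv = S[c][L] - S[c][t];
                if (rv > r1) { r2 = r1; r2c = r1c; r1 = rv; r1c = c; }
                else if (rv > r2) { r2 = rv; r2c = c; }
            }
            int tot, ca, cb;
            if (l1c != r1c) { tot = l1 + r1; ca = l1c; cb = r1c; }
            else if (l2c >= 0 && (r2c < 0 || l2 + r1 >= l1 + r2)) {
                tot = l2 + r1; ca = l2c; cb = r1c;
            } else if (r2c >= 0) {
                tot = l1 + r2; ca = l1c; cb = r2c;
            } else continue;
            if (tot > best_tot) { best_tot = tot; bA = ca; bB = cb; bT = t; }
        }
        if (best_tot < 0) continue;
        double id_single = 100.0 * best_single / L;
        double id_chim = 100.0 * best_tot / L;
        out_id_single[q] = id_single;
        out_id_chim[q] = id_chim;
        if (!(id_chim > id_single && id_chim - id_single >= min_div)) continue;

        // votes over columns where the two parents disagree
        const std::vector<int>& A = enc[cand[bA]];
        const std::vector<int>& B = enc[cand[bB]];
        const std::vector<int>& Q = enc[q];
        double YL = 0, NL = 0, AL = 0, YR = 0, NR = 0, AR = 0;
        for (int t = 0; t < L; ++t) {
            if (A[t] == B[t]) continue;
            bool left = t < bT;
            int model = left ? A[t] : B[t];
            int other = left ? B[t] : A[t];
            if (Q[t] == model) { if (left) ++YL; else ++YR; }
            else if (Q[t] == other) { if (left) ++NL; else ++NR; }
            else { if (left) ++AL; else ++AR; }
        }
        double hL = (YL + NL + AL > 0) ? YL / (YL + xn * NL + dn * AL) : 0.0;
        double hR = (YR + NR + AR > 0) ? YR / (YR + xn * NR + dn * AR) : 0.0;
        double h = std::min(hL, hR);
        out_score[q] = h;
        if (h < min_h) continue;

        // Rescue against indel-shifted relatives: a parent whose gapped
        // (edit-distance) identity comes within min_div of the chimeric
        // model is a better single-sequence explanation than a chimera.
        int cap = (int)std::ceil(L * (100.0 - id_chim + min_div) / 100.0);
        double best_gapped = id_single;
        const std::string qs = as<std::string>(seqs[q]);
        for (int c = 0; c < C; ++c) {
            std::string ps = as<std::string>(seqs[cand[c]]);
            int dqp = bounded_edit(qs.c_str(), (int)qs.size(),
                                   ps.c_str(), (int)ps.size(), cap);
            double idg = 100.0 * (L - dqp) / L;
            if (idg > best_gapped) best_gapped = idg;
        }
        if (id_chim - best_gapped < min_div) continue;

        out_flag[q] = true;
        out_pa[q] = cand[bA] + 1;
        out_pb[q] = cand[bB] + 1;
        out_bp[q] = bT;
    }
    return DataFrame::create(
        Named("query") = out_q,
        Named("is_chimera") = out_flag,
        Named("parent_a") = out_pa,
        Named("parent_b") = out_pb,
        Named("breakpoint") = out_bp,
        Named("score") = out_score,
        Named("id_single") = out_id_single,
        Named("id_chimera") = out_id_chim);
}
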