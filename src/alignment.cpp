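#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

#if defined(__GNUC__) || defined(__clang__)
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif

// Semi-global (overlap) alignment with unit scoring: match +1, mismatch -1,
// gap -1; terminal gaps free. Identity = matches / alignment columns, where
// columns spanned only by terminal gaps are excluded. Tie policy, fixed so
// results are deterministic: during fill diagonal > up > left; the endpoint
// is the maximal score over the last row and last column, ties resolved
// toward the bottom-right-most cell (largest i, then largest j).
// Instead of a traceback matrix, the per-cell (matches, columns) of the
// optimal path are propagated forward along the same locally chosen
// direction the traceback would follow, with rolling rows; this yields the
// identical result with O(min) memory and much better cache behaviour.
static void align_identity(const std::string &a, const std::string &b,
                           int &matches, int &cols) {
    const int n = a.size(), m = b.size();
    matches = 0; cols = 0;
    if (n == 0 || m == 0) return;
    if (a == b) { matches = n; cols = n; return; }

    // (matches, columns) of the traceback path are propagated forward
    // packed into one 64-bit word: matches in the high half, columns low.
    const unsigned long long ONE_COL = 1ULL, ONE_MATCH = 1ULL << 32;
    std::vector<int> ps(m + 1, 0), cs(m + 1, 0);
    std::vector<unsigned long long> pp(m + 1, 0), cp(m + 1, 0);
    // best endpoint over last row/column, bottom-right-most on ties
    int bscore = 0, bi = 0, bj = m;
    unsigned long long bp = 0;

    for (int i = 1; i <= n; ++i) {
        cs[0] = 0; cp[0] = 0;
        const char ai = a[i - 1];
        const int *RESTRICT psv = ps.data();
        int *RESTRICT csv = cs.data();
        const unsigned long long *RESTRICT ppv = pp.data();
        unsigned long long *RESTRICT cpv = cp.data();
        for (int j = 1; j <= m; ++j) {
            const bool eq = (ai == b[j - 1]);
            const int sd = psv[j - 1] + (eq ? 1 : -1);
            const int su = psv[j] - 1;
            const int sl = csv[j - 1] - 1;
            // preference on ties: diagonal > up > left
            int best = su > sd ? su : sd;
            best = sl > best ? sl : best;
            unsigned long long path =
                (best == sd)
                    ? ppv[j - 1] + ONE_COL + (eq ? ONE_MATCH : 0)
                    : ((best == su) ? ppv[j] + ONE_COL
                                    : cpv[j - 1] + ONE_COL);
            csv[j] = best; cpv[j] = path;
        }
        // last-column candidate (i, m): later i wins ties
        if (cs[m] >= bscore) {
            bscore = cs[m]; bi = i; bj = m; bp = cp[m];
        }
        std::swap(ps, cs); std::swap(pp, cp);
    }
    // last-row candidates (n, j): row n beats an earlier last-column tie;
    // larger j wins within the row
    for (int j = 0; j <= m; ++j) {
        int s = ps[j];
        if (s > bscore ||
            (s == bscore && (n > bi || (n == bi && j > bj)))) {
            bscore = s; bi = n; bj = j; bp = pp[j];
        }
    }
    matches = (int)(bp >> 32);
    cols = (int)(bp & 0xffffffffULL);
}

static double ident_frac(int matches, int cols) {
    return cols > 0 ? (double)matches / (double)cols : 0.0;
}

// Score-only pass (same recurrence, endpoint and tie policy as
// align_identity, but without path bookkeeping).  Returns the optimal
// score and endpoint (ie, je).  Used for an exact rejection bound: the
// identity-defining path has cols >= min(ie, je) and
// score = (2*identity - 1) * cols, so
//   identity >= t  (with 2t-1 > 0)  implies  score >= (2t-1) * min(ie, je).
static int align_score(const std::string &a, const std::string &b,
                       int &ie, int &je) {
    const int n = a.size(), m = b.size();
    ie = 0; je = m;
    if (n == 0 || m == 0) return 0;
    std::vector<int> ps(m + 1, 0), cs(m + 1, 0);
    int bscore = 0, bi = 0, bj = m;
    for (int i = 1; i <= n; ++i) {
        cs[0] = 0;
        const char ai = a[i - 1];
        const int *RESTRICT psv = ps.data();
        int *RESTRICT csv = cs.data();
        for (int j = 1; j <= m; ++j) {
            const int sd = psv[j - 1] + (ai == b[j - 1] ? 1 : -1);
            const int su = psv[j] - 1;
            const int sl = csv[j - 1] - 1;
            int best = su > sd ? su : sd;
            csv[j] = sl > best ? sl : best;
        }
        if (cs[m] >= bscore) { bscore = cs[m]; bi = i; bj = m; }
        std::swap(ps, cs);
    }
    for (int j = 0; j <= m; ++j) {
        int s = ps[j];
        if (s > bscore ||
            (s == bscore && (n > bi || (n == bi && j > bj)))) {
            bscore = s; bi = n; bj = j;
        }
    }
    ie = bi; je = bj;
    return bscore;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_identity_pairs(CharacterVector a, CharacterVector b) {
    const int n = a.size();
    NumericMatrix out(n, 3);
    colnames(out) = CharacterVector::create("identity", "matches", "columns");
    for (int k = 0; k < n; ++k) {
        std::string sa = as<std::string>(a[k]), sb = as<std::string>(b[k]);
        int m, c;
        align_identity(sa, sb, m, c);
        out(k, 0) = ident_frac(m, c);
        out(k, 1) = m;
        out(k, 2) = c;
    }
    return out;
}

// Greedy centroid clustering (UCLUST-style): sequences are scanned in the
// given order; each joins the first (or best, if best_hit) existing centroid
// with identity >= threshold, else founds a new centroid. Returns the 1-based
// index (into the input order) of each sequence's centroid.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold,
                                 bool best_hit) {
    const int n = seqs.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    std::vector<int> centroids;
    IntegerVector assign(n);
    const double eps = 1e-9;
    for (int i = 0; i < n; ++i) {
        int hit = -1;
        long long bm = -1, bc = 1; // best identity as exact rational bm/bc
        const double margin = 2.0 * threshold - 1.0;
        for (size_t k = 0; k < centroids.size(); ++k) {
            int c = centroids[k];
            int m, cl;
            if (margin > 0) {
                // cheap score-only pass; provably below threshold -> skip
                int ie, je;
                int sc = align_score(s[i], s[c], ie, je);
                int floor_cols = ie < je ? ie : je;
                if ((double)sc + eps < margin * (double)floor_cols) continue;
            }
            align_identity(s[i], s[c], m, cl);
            if (cl > 0 && (double)m + eps >= threshold * (double)cl) {
                if (!best_hit) { hit = c; break; }
                if (hit < 0 || (long long)m * bc > bm * (long long)cl) {
                    hit = c; bm = m; bc = cl;
                }
            }
        }
        if (hit < 0) { centroids.push_back(i); hit = i; }
        assign[i] = hit + 1;
    }
    return assign;
}

// Exhaustive best-hit scan of queries against references. Ties on identity
// (compared exactly as rationals) are broken by the longer aligned span
// (more alignment columns), then by the earlier reference (callers pass
// references sorted by accession so this is the lexicographic rule).
// exclude[i] (1-based, 0 = none) marks a reference skipped for query i
// (leave-one-out self-search mode).
// [[Rcpp::export]]
NumericMatrix cpp_best_hits(CharacterVector queries, CharacterVector refs,
                            IntegerVector exclude) {
    const int nq = queries.size(), nr = refs.size();
    std::vector<std::string> r(nr);
    for (int j = 0; j < nr; ++j) r[j] = as<std::string>(refs[j]);
    NumericMatrix out(nq, 3);
    colnames(out) = CharacterVector::create("ref_index", "identity", "columns");
    for (int i = 0; i < nq; ++i) {
        std::string q = as<std::string>(queries[i]);
        int skip = (i < exclude.size() && exclude[i] != NA_INTEGER)
            ? exclude[i] - 1 : -1;
        int bidx = -1; long long bm = -1, bc = 1; int bcols = -1;
        for (int j = 0; j < nr; ++j) {
            if (j == skip) continue;
            int m, c;
            if (bidx >= 0) {
                // upper-bound the identity from a score-only pass; skip
                // references that provably cannot beat the current best
                int ie, je;
                int sc = align_score(q, r[j], ie, je);
                int fc = ie < je ? ie : je;
                double upper = sc >= 0
                    ? ((double)sc / (double)(fc > 0 ? fc : 1) + 1.0) / 2.0
                    : 0.5;
                if (upper + 1e-9 < (double)bm / (double)bc) continue;
            }
            align_identity(q, r[j], m, c);
            if (c == 0) { m = 0; c = 1; }
            bool better = false;
            long long lhs = (long long)m * bc, rhs = bm * (long long)c;
            if (bidx < 0 || lhs > rhs) better = true;
            else if (lhs == rhs && c > bcols) better = true;
            if (better) { bidx = j; bm = m; bc = c; bcols = c; }
        }
        out(i, 0) = bidx + 1;
        out(i, 1) = (double)bm / (double)bc;
        out(i, 2) = bcols;
    }
    return out;
}

// Sliding-window Hamming scan: leftmost position (1-based) of minimal
// mismatch count of motif against each sequence; mismatches reported so the
// caller applies its max_mismatch cutoff. Position 0 when motif is longer
// than the sequence.
// [[Rcpp::export]]
IntegerMatrix cpp_anchor_scan(CharacterVector seqs, std::string motif) {
    const int n = seqs.size(), w = motif.size();
    IntegerMatrix out(n, 2);
    colnames(out) = CharacterVector::create("position", "mismatches");
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        const int L = (int)s.size() - w;
        int bpos = 0, bmis = w + 1;
        for (int p = 0; p <= L; ++p) {
            int mis = 0;
            for (int k = 0; k < w && mis < bmis; ++k)
                if (s[p + k] != motif[k]) ++mis;
            if (mis < bmis) { bmis = mis; bpos = p + 1; if (mis == 0) break; }
        }
        out(i, 0) = bpos;
        out(i, 1) = (bpos == 0) ? NA_INTEGER : bmis;
    }
    return out;
}
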