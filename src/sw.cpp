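#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

// Affine-gap Smith-Waterman over plain ACGT strings. Two entry points:
// a batch score-only kernel (linear memory, used to pick the best
// allele/strand for every read) and a single-pair traceback (full
// matrices, used only on the winning pair to recover intervals,
// identity and the read<->segment position map).

static inline int sub_score(char a, char b, int match, int mismatch) {
    // N (or any ambiguity code) never rewards a match
    if (a == 'N' || b == 'N') return mismatch;
    return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".sw_batch_score")]]
IntegerMatrix sw_batch_score(CharacterVector patterns, CharacterVector subjects,
                             int match, int mismatch, int gap_open, int gap_ext) {
    const int np = patterns.size(), ns = subjects.size();
    IntegerMatrix out(np, ns);
    std::vector<int> H, E; // per-column rolling rows
    for (int j = 0; j < ns; ++j) {
        const std::string s = as<std::string>(subjects[j]);
        const int m = (int)s.size();
        H.assign(m + 1, 0);
        E.assign(m + 1, 0);
        for (int i = 0; i < np; ++i) {
            const char *p = CHAR(STRING_ELT(patterns, i));
            const int n = (int)LENGTH(STRING_ELT(patterns, i));
            std::fill(H.begin(), H.end(), 0);
            std::fill(E.begin(), E.end(), 0);
            int best = 0;
            for (int r = 0; r < n; ++r) {
                int diag = 0;   // H[r][c-1] from previous row
                int F = 0;      // gap in subject (horizontal), reset per row
                const char pc = p[r];
                for (int c = 1; c <= m; ++c) {
                    const int up = H[c];
                    int e = std::max(up - gap_open - gap_ext, E[c] - gap_ext);
                    if (e < 0) e = 0;
                    int f = std::max(H[c - 1] - gap_open - gap_ext, F - gap_ext);
                    if (f < 0) f = 0;
                    int h = diag + sub_score(pc, s[c - 1], match, mismatch);
                    if (h < e) h = e;
                    if (h < f) h = f;
                    if (h < 0) h = 0;
                    diag = up;
                    H[c] = h;
                    E[c] = e;
                    F = f;
                    if (h > best) best = h;
                }
            }
            out(i, j) = best;
        }
    }
    return out;
}

// Traceback preference on ties: diagonal, then vertical (gap in
// subject row direction), then horizontal -- fixed so results are
// deterministic.
// [[Rcpp::export(name = ".sw_traceback")]]
List sw_traceback(std::string pattern, std::string subject,
                  int match, int mismatch, int gap_open, int gap_ext) {
    const int n = (int)pattern.size(), m = (int)subject.size();
    // full matrices, row-major (n+1) x (m+1)
    std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), 0),
        F((n + 1) * (m + 1), 0);
    auto idx = [m](int i, int j) { return i * (m + 1) + j; };
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            int e = std::max(H[idx(i - 1, j)] - gap_open - gap_ext,
                             E[idx(i - 1, j)] - gap_ext);
            if (e < 0) e = 0;
            int f = std::max(H[idx(i, j - 1)] - gap_open - gap_ext,
                             F[idx(i, j - 1)] - gap_ext);
            if (f < 0) f = 0;
            int h = H[idx(i - 1, j - 1)] +
                    sub_score(pattern[i - 1], subject[j - 1], match, mismatch);
            if (h < e) h = e;
            if (h < f) h = f;
            if (h < 0) h = 0;
            H[idx(i, j)] = h;
            E[idx(i, j)] = e;
            F[idx(i, j)] = f;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    std::vector<int> pmap, smap; // aligned columns, -1 = gap
    int n_match = 0, n_cols = 0;
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E (vertical), 2 = F (horizontal)
    while (i > 0 && j > 0) {
        if (state == 0) {
            const int h = H[idx(i, j)];
            if (h == 0) break;
            const int d = H[idx(i - 1, j - 1)] +
                sub_score(pattern[i - 1], subject[j - 1], match, mismatch);
            if (h == d) {
                pmap.push_back(i - 1);
                smap.push_back(j - 1);
                if (pattern[i - 1] == subject[j - 1]) ++n_match;
                ++n_cols;
                --i; --j;
            } else if (h == E[idx(i, j)]) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) { // gap in subject: consume pattern base
            pmap.push_back(i - 1);
            smap.push_back(-1);
            ++n_cols;
            const int e = E[idx(i, j)];
            state = (e == H[idx(i - 1, j)] - gap_open - gap_ext) ? 0 : 1;
            --i;
        } else { // gap in pattern: consume subject base
            pmap.push_back(-1);
            smap.push_back(j - 1);
            ++n_cols;
            const int f = F[idx(i, j)];
            state = (f == H[idx(i, j - 1)] - gap_open - gap_ext) ? 0 : 2;
            --j;
        }
    }
    std::reverse(pmap.begin(), pmap.end());
    std::reverse(smap.begin(), smap.end());
    return List::create(
        _["score"] = best,
        _["p_start"] = i, _["p_end"] = bi,   // 0-based half-open on pattern
        _["s_start"] = j, _["s_end"] = bj,   // 0-based half-open on subject
        _["n_match"] = n_match, _["n_cols"] = n_cols,
        _["identity"] = n_cols > 0 ? (double)n_match / n_cols : 0.0,
        _["p_map"] = IntegerVector(pmap.begin(), pmap.end()),
        _["s_map"] = IntegerVector(smap.begin(), smap.end()));
}

// Strand vote: counts k-mers of each read (forward vs reverse
// complement) present in the reference k-mer set, returning the count
// difference. Positive = forward orientation matches the references.
// Used as a pre-alignment heuristic; callers fall back to scoring both
// orientations when the vote is weak.
// [[Rcpp::export(name = ".strand_vote")]]
IntegerVector strand_vote(CharacterVector reads, CharacterVector refs,
                          int k) {
    std::unordered_set<uint64_t> kmers;
    auto code = [](char c) -> int {
        switch (c) { case 'A': return 0; case 'C': return 1;
                     case 'G': return 2; case 'T': return 3; }
        return -1;
    };
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int r = 0; r < refs.size(); ++r) {
        const char *s = CHAR(STRING_ELT(refs, r));
        const int n = (int)LENGTH(STRING_ELT(refs, r));
        uint64_t h = 0; int run = 0;
        for (int i = 0; i < n; ++i) {
            int c = code(s[i]);
            if (c < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)c) & mask;
            if (++run >= k) kmers.insert(h);
        }
    }
    IntegerVector out(reads.size());
    const int shift = 2 * (k - 1);
    for (int r = 0; r < reads.size(); ++r) {
        const char *s = CHAR(STRING_ELT(reads, r));
        const int n = (int)LENGTH(STRING_ELT(reads, r));
        uint64_t hf = 0, hr = 0; int run = 0, nf = 0, nr = 0;
        for (int i = 0; i < n; ++i) {
            int c = code(s[i]);
            if (c < 0) { run = 0; hf = hr = 0; continue; }
            hf = ((hf << 2) | (uint64_t)c) & mask;
            hr = (hr >> 2) | ((uint64_t)(3 - c) << shift);
            if (++run >= k) {
                if (kmers.count(hf)) ++nf;
                if (kmers.count(hr)) ++nr;
            }
        }
        out[r] = nf - nr;
    }
    return out;
}

// Hamming distance between equal-length strings (clonotype collapse).
// [[Rcpp::export(name = ".hamming")]]
int hamming(std::string a, std::string b) {
    if (a.size() != b.size()) return NA_INTEGER;
    int d = 0;
    for (size_t k = 0; k < a.size(); ++k)
        if (a[k] != b[k]) ++d;
    return d;
}
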