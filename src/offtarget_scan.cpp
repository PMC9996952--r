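#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive sense-strand Hamming scan of a pattern against a set of
// subject sequences. Every window of every subject at distance
// <= max_mm is reported; no heuristic can miss a hit. Subjects shorter
// than the pattern yield no windows (the caller logs a notice).
//
// Positions are returned 0-based. 'N' in a subject mismatches every
// pattern base (patterns may not contain N; enforced by the caller).

// [[Rcpp::export(name = ".scan_hamming_cpp")]]
List scan_hamming_cpp(CharacterVector subjects, std::string pattern,
                      int max_mm) {
    const int k = (int) pattern.size();
    std::vector<int> out_subj, out_start, out_mm;
    for (int s = 0; s < subjects.size(); ++s) {
        const char *subj = CHAR(STRING_ELT(subjects, s));
        const int L = (int) LENGTH(STRING_ELT(subjects, s));
        for (int i = 0; i + k <= L; ++i) {
            int mm = 0;
            const char *w = subj + i;
            for (int j = 0; j < k; ++j) {
                if (w[j] != pattern[j]) {
                    if (++mm > max_mm) break;
                }
            }
            if (mm <= max_mm) {
                out_subj.push_back(s + 1);
                out_start.push_back(i);
                out_mm.push_back(mm);
            }
        }
    }
    return List::create(_["subject"] = wrap(out_subj),
                        _["start"] = wrap(out_start),
                        _["mismatches"] = wrap(out_mm));
}
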