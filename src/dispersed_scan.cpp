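#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Maximal repeated-pair scan between two sequences (or a sequence against
// itself) under a Hamming-mismatch budget.  Each diagonal offset is scanned
// once.  With boundaries B = [-1, mismatch positions, len], the maximal
// windows holding at most e = max_mm mismatches are
//   (B[t] + 1 .. B[t+e+1] - 1)   for t = 0 .. max(0, k - e)
// (k = number of mismatches); each window is keyed by its right boundary
// and emitted as the scan streams past it, keeping only the last e + 2
// boundaries in a small ring buffer.

struct Hits {
    std::vector<int> sa, sb, wl, wm;
};

static void scan_diagonal(const char* a, const char* b, int ia0, int ib0,
                          int len, int min_len, int max_len, int max_mm,
                          Hits& h) {
    if (len < min_len) return;
    const char* pa = a + ia0;
    const char* pb = b + ib0;
    const int e = max_mm;
    int ring[16];                 // holds last boundaries; capacity > e + 2
    int rhead = 0, rsize = 1;
    ring[0] = -1;                 // B[0] sentinel
    int seen = 0;                 // mismatches encountered so far
    auto emit = [&](int q, int back, int inside) {
        // left boundary is `back` ring entries behind the head
        int left = ring[(rhead - back + 16) % 16];
        int lo = left + 1, hi = q - 1;
        int wlen = hi - lo + 1;
        if (wlen < min_len || wlen > max_len) return;
        h.sa.push_back(ia0 + lo);
        h.sb.push_back(ib0 + lo);
        h.wl.push_back(wlen);
        h.wm.push_back(inside);
    };
    for (int k = 0; k < len; ++k) {
        if (pa[k] != pb[k]) {
            // this is boundary index i = seen + 1; emit the window it
            // right-bounds when it has e mismatches strictly inside
            if (seen >= e) emit(k, e, e);
            ++seen;
            rhead = (rhead + 1) % 16;
            ring[rhead] = k;
            if (rsize < e + 2) ++rsize;
        }
    }
    int back = std::min(seen, e);
    emit(len, back, back);
}

// [[Rcpp::export(name = ".dispersed_scan_cpp")]]
DataFrame dispersed_scan_cpp(std::string a, std::string b, bool self,
                             int min_len, int max_len, int max_mm) {
    if (max_mm < 0 || max_mm > 12) stop("max_mm must be in [0, 12]");
    int na = (int)a.size(), nb = (int)b.size();
    Hits h;
    if (self) {
        // forward repeats within one sequence: diagonals d >= 1 only,
        // (x, x+d) ordering dedupes the symmetric pair
        for (int d = 1; d < na; ++d)
            scan_diagonal(a.c_str(), a.c_str(), 0, d, na - d,
                          min_len, max_len, max_mm, h);
    } else {
        for (int d = -(nb - 1); d < na; ++d) {
            int ia0 = d > 0 ? d : 0;
            int ib0 = d > 0 ? 0 : -d;
            int len = std::min(na - ia0, nb - ib0);
            scan_diagonal(a.c_str(), b.c_str(), ia0, ib0, len,
                          min_len, max_len, max_mm, h);
        }
    }
    return DataFrame::create(_["start_a"] = h.sa, _["start_b"] = h.sb,
                             _["length"] = h.wl, _["mismatches"] = h.wm);
}
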