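// Marker-seeded watershed by priority flooding.
//
// Grows seed labels over the mask in order of decreasing surface height
// (equivalently: watershed of the negated surface), 8-connected. Ties are
// broken by insertion order, so the result is deterministic.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

struct QEntry {
    double value;
    unsigned long order;
    int idx;
    int label;
};
struct QCompare {
    bool operator()(const QEntry& a, const QEntry& b) const {
        if (a.value != b.value) return a.value < b.value;  // max-heap
        return a.order > b.order;                          // FIFO on ties
    }
};

// [[Rcpp::export(name = ".seededWatershed")]]
IntegerMatrix seededWatershed(NumericMatrix surface, IntegerMatrix seeds,
                              LogicalMatrix mask) {
    int nr = surface.nrow(), nc = surface.ncol();
    IntegerMatrix labels(nr, nc);
    std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
    unsigned long counter = 0;
    const int dr[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    const int dc[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r)
            if (seeds(r, c) > 0 && mask(r, c))
                labels(r, c) = seeds(r, c);
    for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
            if (labels(r, c) == 0) continue;
            for (int k = 0; k < 8; ++k) {
                int rr = r + dr[k], cc = c + dc[k];
                if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
                if (!mask(rr, cc) || labels(rr, cc) != 0) continue;
                pq.push({surface(rr, cc), counter++, rr + cc * nr,
                         labels(r, c)});
            }
        }
    while (!pq.empty()) {
        QEntry e = pq.top();
        pq.pop();
        int r = e.idx % nr, c = e.idx / nr;
        if (labels(r, c) != 0) continue;
        labels(r, c) = e.label;
        for (int k = 0; k < 8; ++k) {
            int rr = r + dr[k], cc = c + dc[k];
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (!mask(rr, cc) || labels(rr, cc) != 0) continue;
            pq.push({surface(rr, cc), counter++, rr + cc * nr, e.label});
        }
    }
    return labels;
}
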