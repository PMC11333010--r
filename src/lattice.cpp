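#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <climits>
#include <cstdint>
using namespace Rcpp;

// Lattice conventions
// -------------------
// Conformations are self-avoiding walks (SAWs) on the square lattice, one
// point per residue, N-terminus first.  Step codes: 0 = +x, 1 = +y, 2 = -x,
// 3 = -y.  The canonical representative of each symmetry class (4 rotations
// x optional reflection) has its first step +x and its first off-axis step
// +y, which is equivalent to: first turn in the turn string is 'L'.
//
// A walk of L residues has L-1 steps and a turn string of L-2 characters
// over {S, L, R} (straight / left / right at each interior residue).  Two
// walks are congruent under rotation iff their turn strings are equal, and
// congruent under rotation+reflection iff equal up to a global L<->R swap.
// Motif templates are therefore matched as turn substrings modulo the swap;
// this is exactly the "all 8 point-group images, deduplicated" matching and
// counts each (window, geometric match) once.

static const int DX[4] = {1, 0, -1, 0};
static const int DY[4] = {0, 1, 0, -1};

namespace {

struct Enumerator {
    int L;
    std::vector<int> xs, ys;
    std::vector<char> turns;              // 'S','L','R'
    std::vector<std::vector<bool> > occ;  // (2L+1)^2 board
    int off;
    std::vector<int> out_steps;           // flattened, row-major per walk
    long n_walks = 0;

    explicit Enumerator(int L_) : L(L_) {
        off = L;
        occ.assign(2 * L + 1, std::vector<bool>(2 * L + 1, false));
        xs.assign(L, 0); ys.assign(L, 0);
        turns.assign(std::max(L - 2, 0), 'S');
    }

    void run() {
        xs[0] = 0; ys[0] = 0;
        occ[off][off] = true;
        if (L >= 2) {
            xs[1] = 1; ys[1] = 0;
            occ[off + 1][off] = true;
            rec(2, 0, false);
        } else {
            emit();
        }
    }

    void rec(int i, int dir, bool turned) {
        if (i == L) { emit(); return; }
        static const char TS[3] = {'S', 'L', 'R'};
        static const int DD[3] = {0, 1, 3};
        for (int t = 0; t < 3; ++t) {
            if (!turned && TS[t] == 'R') continue;  // first turn must be L
            int nd = (dir + DD[t]) & 3;
            int nx = xs[i - 1] + DX[nd], ny = ys[i - 1] + DY[nd];
            if (occ[nx + off][ny + off]) continue;
            xs[i] = nx; ys[i] = ny;
            occ[nx + off][ny + off] = true;
            if (i >= 2) turns[i - 2] = TS[t];
            rec(i + 1, nd, turned || TS[t] != 'S');
            occ[nx + off][ny + off] = false;
        }
    }

    void emit() {
        ++n_walks;
        for (int i = 1; i < L; ++i) {
            int sx = xs[i] - xs[i - 1], sy = ys[i] - ys[i - 1];
            int code = (sx == 1) ? 0 : (sy == 1) ? 1 : (sx == -1) ? 2 : 3;
            out_steps.push_back(code);
        }
    }
};

std::string swap_lr(const std::string& s) {
    std::string r = s;
    for (char& c : r) { if (c == 'L') c = 'R'; else if (c == 'R') c = 'L'; }
    return r;
}

// Turn string of one walk given its step codes.
std::string turn_string(const int* steps, int nsteps) {
    std::string t;
    t.reserve(std::max(nsteps - 1, 0));
    for (int i = 1; i < nsteps; ++i) {
        int d = (steps[i] - steps[i - 1]) & 3;
        t.push_back(d == 0 ? 'S' : d == 1 ? 'L' : 'R');  // d == 3 -> 'R'
    }
    return t;
}

// Count windows of `hay` equal to `pat` or its chirality swap.
int count_windows(const std::string& hay, const std::string& pat,
                  bool skip_cterm) {
    if (pat.empty() || hay.size() < pat.size()) return 0;
    std::string q = swap_lr(pat);
    int n = 0;
    size_t last = hay.size() - pat.size();
    for (size_t j = 0; j <= last; ++j) {
        if (skip_cterm && j == last) continue;
        if (hay.compare(j, pat.size(), pat) == 0 ||
            (q != pat && hay.compare(j, pat.size(), q) == 0)) ++n;
    }
    return n;
}

void walk_points(const int* steps, int nsteps, std::vector<int>& px,
                 std::vector<int>& py) {
    px.assign(nsteps + 1, 0); py.assign(nsteps + 1, 0);
    for (int i = 0; i < nsteps; ++i) {
        px[i + 1] = px[i] + DX[steps[i]];
        py[i + 1] = py[i] + DY[steps[i]];
    }
}

// Non-covalent lattice contacts of one walk, encoded as 16-bit pair masks
// (bit i set for residue i+1).  Only valid for L <= 16.
void walk_contacts(const int* steps, int L, std::vector<uint16_t>& out) {
    std::vector<int> px, py;
    walk_points(steps, L - 1, px, py);
    out.clear();
    for (int a = 0; a < L; ++a)
        for (int b = a + 3; b < L; b += 2)  // parity: |a-b| odd, >= 3
            if (std::abs(px[a] - px[b]) + std::abs(py[a] - py[b]) == 1)
                out.push_back(static_cast<uint16_t>((1u << a) | (1u << b)));
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_enumerate_saws")]]
IntegerMatrix cpp_enumerate_saws(int L) {
    if (L < 2) stop("chain length must be at least 2");
    Enumerator e(L);
    e.run();
    IntegerMatrix m(e.n_walks, L - 1);
    for (long i = 0; i < e.n_walks; ++i)
        for (int j = 0; j < L - 1; ++j)
            m(i, j) = e.out_steps[i * (L - 1) + j];
    return m;
}

// Per-walk annotation: contact count, penalty-motif count, FLS count, RCO.
// `penalty_turns` are the turn strings of the penalty templates (counted at
// every window); `fls_turns` is the FLS turn string, counted at every window
// except, when `fls_skip_cterm`, the one flush with the C-terminal chain end.
//' @noRd
// [[Rcpp::export(name = "cpp_annotate_saws")]]
DataFrame cpp_annotate_saws(IntegerMatrix steps, CharacterVector penalty_turns,
                            std::string fls_turns, bool fls_skip_cterm) {
    int n = steps.nrow(), nsteps = steps.ncol(), L = nsteps + 1;
    std::vector<std::string> pens;
    for (int i = 0; i < penalty_turns.size(); ++i)
        pens.push_back(as<std::string>(penalty_turns[i]));
    IntegerVector nc(n), np(n), nf(n);
    NumericVector rco(n);
    std::vector<int> row(nsteps);
    std::vector<int> px, py;
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < nsteps; ++j) row[j] = steps(i, j);
        std::string t = turn_string(row.data(), nsteps);
        int p = 0;
        for (const std::string& pat : pens) p += count_windows(t, pat, false);
        np[i] = p;
        nf[i] = count_windows(t, fls_turns, fls_skip_cterm);
        walk_points(row.data(), nsteps, px, py);
        int cts = 0; long sep = 0;
        for (int a = 0; a < L; ++a)
            for (int b = a + 3; b < L; b += 2)
                if (std::abs(px[a] - px[b]) + std::abs(py[a] - py[b]) == 1) {
                    ++cts; sep += b - a;
                }
        nc[i] = cts;
        rco[i] = cts ? static_cast<double>(sep) / (static_cast<double>(L) * cts)
                     : NA_REAL;
    }
    return DataFrame::create(_["n_c"] = nc, _["n_penalty"] = np,
                             _["n_fls"] = nf, _["rco"] = rco);
}

// Exhaustive designability scan over all 2^L HP sequences.
//
// Conformations are grouped by contact set; within a group only the smallest
// penalty count can minimise the energy for any sequence (penalties are
// sequence-independent and eps_penalty >= 0), so each group carries
// (p_min, multiplicity at p_min, walk id if that multiplicity is 1).  When
// eps_penalty == 0 the whole group is merged (the model reduces to the pure
// HP model and all members are degenerate).  A sequence is protein-like iff
// exactly one conformation attains its minimum energy; group multiplicities
// make that count exact.  Energies are compared in integer arithmetic after
// scaling eps by `scale` (caller guarantees integrality).
//' @noRd
// [[Rcpp::export(name = "cpp_designability_scan")]]
List cpp_designability_scan(IntegerMatrix steps, IntegerVector n_penalty,
                            int eps_hh_scaled, int eps_penalty_scaled,
                            double scale) {
    int n = steps.nrow(), nsteps = steps.ncol(), L = nsteps + 1;
    if (L > 16) stop("exhaustive sequence scan supports L <= 16");
    if (n_penalty.size() != n) stop("n_penalty length mismatch");
    if (eps_hh_scaled < 0 || eps_penalty_scaled < 0)
        stop("energy parameters must be non-negative");
    const int eh = eps_hh_scaled, ep = eps_penalty_scaled;

    // group conformations by contact set
    struct Cls {
        std::vector<uint16_t> contacts;
        int nc = 0, p_min = INT_MAX, w = 0, sid = -1;
        long tot = 0; int sid_any = -1;
    };
    std::unordered_map<std::string, int> cmap;
    std::vector<Cls> cls;
    cls.reserve(4096);
    std::vector<int> row(nsteps);
    std::vector<uint16_t> cts;
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < nsteps; ++j) row[j] = steps(i, j);
        walk_contacts(row.data(), L, cts);
        std::string key(reinterpret_cast<const char*>(cts.data()),
                        cts.size() * sizeof(uint16_t));
        auto it = cmap.find(key);
        int ci;
        if (it == cmap.end()) {
            ci = static_cast<int>(cls.size());
            cmap.emplace(std::move(key), ci);
            cls.push_back(Cls());
            cls[ci].contacts = cts;
            cls[ci].nc = static_cast<int>(cts.size());
        } else {
            ci = it->second;
        }
        Cls& c = cls[ci];
        int p = n_penalty[i];
        if (ep > 0) {
            if (p < c.p_min) { c.p_min = p; c.w = 1; c.sid = i; }
            else if (p == c.p_min) { ++c.w; c.sid = -1; }
        } else {
            ++c.tot;
            c.sid_any = (c.tot == 1) ? i : -1;
        }
    }
    if (ep == 0)
        for (Cls& c : cls) { c.p_min = 0; c.w = static_cast<int>(c.tot); c.sid = c.sid_any; }

    // flatten sorted by lower energy bound (all contacts HH) for pruning
    int K = static_cast<int>(cls.size());
    std::vector<int> order(K);
    for (int k = 0; k < K; ++k) order[k] = k;
    std::vector<int> bound(K);
    for (int k = 0; k < K; ++k) bound[k] = -eh * cls[k].nc + ep * cls[k].p_min;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return bound[a] < bound[b]; });
    std::vector<int> b2(K), pm(K), w2(K), sid2(K), coff(K + 1);
    std::vector<uint16_t> call;
    for (int k = 0; k < K; ++k) {
        int i = order[k];
        b2[k] = bound[i]; pm[k] = cls[i].p_min; w2[k] = cls[i].w; sid2[k] = cls[i].sid;
        coff[k] = static_cast<int>(call.size());
        call.insert(call.end(), cls[i].contacts.begin(), cls[i].contacts.end());
    }
    coff[K] = static_cast<int>(call.size());

    unsigned nseq = 1u << L;
    IntegerVector ns(n, 0);
    IntegerVector nmin(nseq);
    NumericVector emin(nseq);
    long plike = 0;
    for (unsigned m = 0; m < nseq; ++m) {
        int best = INT_MAX; long cnt = 0; int arg = -1;
        for (int k = 0; k < K; ++k) {
            if (b2[k] > best) break;  // sorted: no later class can tie or beat
            int nhh = 0;
            for (int t = coff[k]; t < coff[k + 1]; ++t) {
                uint16_t c = call[t];
                if ((m & c) == c) ++nhh;
            }
            int e = -eh * nhh + ep * pm[k];
            if (e < best) { best = e; cnt = w2[k]; arg = sid2[k]; }
            else if (e == best) { cnt += w2[k]; arg = -1; }
        }
        emin[m] = best / scale;
        nmin[m] = static_cast<int>(cnt);
        if (cnt == 1) { ++plike; ++ns[arg]; }
    }
    return List::create(_["n_s"] = ns,
                        _["protein_like_count"] = static_cast<double>(plike),
                        _["min_energy"] = emin,
                        _["n_min_conformations"] = nmin,
                        _["n_contact_classes"] = K);
}

// Index (1-based) of each walk's chain-reversed counterpart within the same
// canonical enumeration; walks are identified by turn string (reversal
// reverses the turn string and swaps chirality, then canonical chirality is
// restored so the first turn is 'L').
//' @noRd
// [[Rcpp::export(name = "cpp_reverse_index")]]
IntegerVector cpp_reverse_index(IntegerMatrix steps) {
    int n = steps.nrow(), nsteps = steps.ncol();
    std::unordered_map<std::string, int> wmap;
    wmap.reserve(n * 2);
    std::vector<std::string> ts(n);
    std::vector<int> row(nsteps);
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < nsteps; ++j) row[j] = steps(i, j);
        ts[i] = turn_string(row.data(), nsteps);
        wmap[ts[i]] = i;
    }
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string r(ts[i].rbegin(), ts[i].rend());
        r = swap_lr(r);
        // canonical chirality: first non-S turn must be 'L'
        for (char c : r) {
            if (c == 'L') break;
            if (c == 'R') { r = swap_lr(r); break; }
        }
        auto it = wmap.find(r);
        if (it == wmap.end()) stop("reversed walk not found in enumeration");
        out[i] = it->second + 1;
    }
    return out;
}
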