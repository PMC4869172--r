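#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode A/C/G/T, -1 for anything else
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
CharacterVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                                 int min_overlap) {
  int n = reads.size();
  int alen = (int) adapter.size();
  CharacterVector out(n);
  for (int r = 0; r < n; ++r) {
    if (CharacterVector::is_na(reads[r])) { out[r] = NA_STRING; continue; }
    std::string s = as<std::string>(reads[r]);
    int L = (int) s.size();
    int cut = L;  // position where the adapter match starts; L = no match
    // smallest i such that s[i..L-1] == adapter[0..L-i-1], overlap in
    // [min_overlap, alen]
    int i_min = std::max(0, L - alen);
    for (int i = i_min; i <= L - min_overlap; ++i) {
      int ov = L - i;
      bool hit = true;
      for (int k = 0; k < ov; ++k) {
        if (s[i + k] != adapter[k]) { hit = false; break; }
      }
      if (hit) { cut = i; break; }
    }
    out[r] = s.substr(0, cut);
  }
  return out;
}

static const int SEED_LEN = 7;

struct SeedHit { int region; int pos; };

// Assign reads to short reference regions by Hamming distance, allowing
// max_mismatch substitutions (no indels), an upstream overhang of up to
// max_up nt and a downstream overhang of up to max_down nt (overhanging
// bases fall outside the region and are not compared). Seed-and-extend:
// with <=1 mismatch and the window set below, at least one in-region
// 7-mer window of the read is mismatch-free (see package vignette).
// Returns one row per surviving candidate: per (read, region) the single
// best placement (fewest mismatches, then least overhang, then leftmost),
// filtered to the global minimum mismatch count for that read.
// [[Rcpp::export]]
List assign_reads_cpp(CharacterVector reads, CharacterVector regions,
                      int max_mismatch, int max_up, int max_down) {
  int n_regions = regions.size();
  std::vector<std::string> reg(n_regions);
  for (int i = 0; i < n_regions; ++i) reg[i] = as<std::string>(regions[i]);

  // 7-mer index over all region positions
  std::unordered_map<uint32_t, std::vector<SeedHit>> index;
  for (int ri = 0; ri < n_regions; ++ri) {
    const std::string& s = reg[ri];
    int L = (int) s.size();
    if (L < SEED_LEN) continue;
    uint32_t code = 0; int valid = 0;
    for (int p = 0; p < L; ++p) {
      int b = base_code(s[p]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t) b) & ((1u << (2 * SEED_LEN)) - 1u);
      if (++valid >= SEED_LEN)
        index[code].push_back(SeedHit{ri, p - SEED_LEN + 1});
    }
  }

  int n_reads = reads.size();
  std::vector<int> out_read, out_region, out_start, out_mm, out_up, out_down;

  std::vector<int> rcode;  // scratch: encoded read
  for (int qi = 0; qi < n_reads; ++qi) {
    std::string q = as<std::string>(reads[qi]);
    int L = (int) q.size();
    if (L < SEED_LEN) continue;
    rcode.assign(L, -1);
    for (int p = 0; p < L; ++p) rcode[p] = base_code(q[p]);

    // window starts guaranteeing seed coverage under <=1 mismatch
    std::vector<int> windows;
    if (L <= 20) {
      for (int w = 0; w <= L - SEED_LEN; ++w) windows.push_back(w);
    } else {
      int h = L / 2;
      int cand[6] = {0, 1, h, L - SEED_LEN, L - SEED_LEN - 1, L - SEED_LEN - 2};
      for (int k = 0; k < 6; ++k)
        if (cand[k] >= 0 && cand[k] <= L - SEED_LEN) windows.push_back(cand[k]);
    }

    std::unordered_set<int64_t> seen;
    // best placement per region for this read
    std::unordered_map<int, std::array<int, 4>> best;  // region -> mm, ov, start, (set)

    for (int w : windows) {
      uint32_t code = 0; bool ok = true;
      for (int k = 0; k < SEED_LEN; ++k) {
        int b = rcode[w + k];
        if (b < 0) { ok = false; break; }
        code = (code << 2) | (uint32_t) b;
      }
      if (!ok) continue;
      auto it = index.find(code);
      if (it == index.end()) continue;
      for (const SeedHit& h : it->second) {
        int start = h.pos - w;
        int rl = (int) reg[h.region].size();
        int up = start < 0 ? -start : 0;
        int down = start + L > rl ? start + L - rl : 0;
        if (up > max_up || down > max_down) continue;
        int64_t key = ((int64_t) h.region << 32) | (uint32_t) (start + 4);
        if (!seen.insert(key).second) continue;
        // verify over the in-region overlap
        const std::string& s = reg[h.region];
        int mm = 0;
        int i0 = up, i1 = L - down;
        for (int i = i0; i < i1; ++i) {
          int b = rcode[i];
          int c = base_code(s[start + i]);
          if (b < 0 || c < 0 || b != c) {
            if (++mm > max_mismatch) break;
          }
        }
        if (mm > max_mismatch) continue;
        int ov = up + down;
        auto bi = best.find(h.region);
        if (bi == best.end()) {
          best[h.region] = {mm, ov, start, 0};
        } else {
          std::array<int, 4>& b0 = bi->second;
          if (mm < b0[0] || (mm == b0[0] && (ov < b0[1] ||
              (ov == b0[1] && start < b0[2]))))
            b0 = {mm, ov, start, 0};
        }
      }
    }
    if (best.empty()) continue;
    int min_mm = max_mismatch + 1;
    for (auto& kv : best) min_mm = std::min(min_mm, kv.second[0]);
    for (auto& kv : best) {
      if (kv.second[0] != min_mm) continue;
      out_read.push_back(qi + 1);
      out_region.push_back(kv.first + 1);
      out_start.push_back(kv.second[2]);
      out_mm.push_back(kv.second[0]);
      out_up.push_back(kv.second[2] < 0 ? -kv.second[2] : 0);
      int rl = (int) reg[kv.first].size();
      int d = kv.second[2] + L - rl;
      out_down.push_back(d > 0 ? d : 0);
    }
  }
  return List::create(
    _["read_idx"] = wrap(out_read), _["region_idx"] = wrap(out_region),
    _["start"] = wrap(out_start), _["mismatches"] = wrap(out_mm),
    _["overhang5"] = wrap(out_up), _["overhang3"] = wrap(out_down));
}

// Weighted base-pair maximization (Nussinov-style) over nested structures.
// Pair scores are positive weights; returned value is minus the optimal
// total weight, a folding-energy proxy in arbitrary units (<= 0).
// [[Rcpp::export]]
double nussinov_energy_cpp(std::string seq, double gc, double au, double gu,
                           int min_loop) {
  int n = (int) seq.size();
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) b[i] = base_code(seq[i]);
  auto pair_w = [&](int i, int j) -> double {
    int x = b[i], y = b[j];
    if (x < 0 || y < 0) return -1.0;
    if ((x == 2 && y == 1) || (x == 1 && y == 2)) return gc;  // G:C
    if ((x == 0 && y == 3) || (x == 3 && y == 0)) return au;  // A:U
    if ((x == 2 && y == 3) || (x == 3 && y == 2)) return gu;  // G:U
    return -1.0;
  };
  if (n == 0) return 0.0;
  std::vector<double> E((size_t) n * n, 0.0);
  auto at = [&](int i, int j) -> double& { return E[(size_t) i * n + j]; };
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double v = at(i + 1, j);  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double w = pair_w(i, k);
        if (w < 0) continue;
        double inner = at(i + 1, k - 1);
        double outer = (k + 1 <= j) ? at(k + 1, j) : 0.0;
        v = std::max(v, w + inner + outer);
      }
      at(i, j) = v;
    }
  }
  return -at(0, n - 1);
}
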