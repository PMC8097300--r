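// TPBWT sweep: per-template positional prefix/divergence arrays with
// cyclic site masks, neighbour-imputation through missing data, fragment
// merging in shared current-match arrays, and the cohort-consistent phase
// switch correction (haplotype swap applied to all templates from the
// inferred switch site forward).
//
// Conventions: sites are 0-based; alleles are 0/1/2 (2 = missing);
// haplotypes 2i and 2i+1 belong to individual i. div[j][i] holds the
// global site index at which the match between ppa[j][i] and ppa[j][i-1]
// began; the first element of a class receives the next processed site K
// as a "no match yet" sentinel. A subsegment must span >= Lm sites to be
// emitted, and open matches separated by a gap of fewer than Lm sites are
// merged. Reported haplotype labels are the logical (post-correction)
// labels, which stitch segments across inferred switches.

#include <Rcpp.h>
#include <climits>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Match {
  int start;
  int end;
};

class Sweep {
 public:
  Sweep(const IntegerMatrix& alleles, const IntegerMatrix& masks, int Lm,
        double Lf, int Mt, bool phase_correction, bool include_self,
        int n_hap_x, const NumericVector& cm)
      : A(alleles),
        masks_(masks),
        Lm_(Lm),
        Lf_(Lf),
        Mt_(Mt),
        phase_corr_(phase_correction),
        include_self_(include_self),
        nx_(n_hap_x),
        cm_(cm),
        M_(alleles.nrow()),
        N_(alleles.ncol()),
        t_(masks.nrow()),
        period_(masks.ncol()) {
    hap_map_.resize(M_);
    for (int h = 0; h < M_; ++h) hap_map_[h] = h;
    proc_.resize(t_);
    for (int k = 0; k < N_; ++k)
      for (int j = 0; j < t_; ++j)
        if (masks_(j, k % period_) == 1) proc_[j].push_back(k);
    ppa_.assign(t_, std::vector<int>());
    div_.assign(t_, std::vector<int>());
    for (int j = 0; j < t_; ++j) {
      ppa_[j].resize(M_);
      for (int h = 0; h < M_; ++h) ppa_[j][h] = h;
      div_[j].assign(M_, 0);
    }
    missrun_.assign(t_, std::vector<int>(M_, 0));
    toggles_.assign(M_ / 2, std::vector<int>());
    ptr_.assign(t_, 0);
    max_open_ = 0;
  }

  DataFrame run() {
    for (int k = 0; k < N_; ++k) {
      for (int j = 0; j < t_; ++j) {
        if (masks_(j, k % period_) != 1) continue;
        int K = (ptr_[j] + 1 < (int)proc_[j].size()) ? proc_[j][ptr_[j] + 1]
                                                     : N_;
        ++ptr_[j];
        site_update(j, k, K);
      }
    }
    trailing();
    for (auto& kv : open_) {
      int a = (int)(kv.first >> 32);
      int b = (int)(kv.first & 0xffffffffu);
      report(a, b, kv.second);
    }
    DataFrame out = DataFrame::create(
        Named("hap_a") = out_a_, Named("hap_b") = out_b_,
        Named("start_site") = out_s_, Named("end_site") = out_e_);
    out.attr("max_open_matches") = (int)max_open_;
    return out;
  }

 private:
  const IntegerMatrix& A;
  const IntegerMatrix& masks_;
  int Lm_;
  double Lf_;
  int Mt_;
  bool phase_corr_;
  bool include_self_;
  int nx_;
  const NumericVector& cm_;
  int M_, N_, t_, period_;

  std::vector<int> hap_map_;                // logical -> physical row
  std::vector<std::vector<int>> proc_;      // processed sites per template
  std::vector<int> ptr_;                    // position within proc_
  std::vector<std::vector<int>> ppa_, div_;
  std::vector<std::vector<int>> missrun_;
  std::vector<std::vector<int>> toggles_;
  std::unordered_map<uint64_t, Match> open_;
  size_t max_open_;
  std::vector<int> out_a_, out_b_, out_s_, out_e_;
  // per-site scratch
  std::vector<int> p0_, p1_, d0_, d1_, m0_, m1_, res_;

  static uint64_t key_of(int a, int b) {
    return ((uint64_t)a << 32) | (uint32_t)b;
  }

  void report(int a, int b, const Match& m) {
    if (cm_[m.end] - cm_[m.start] < Lf_) return;
    out_a_.push_back(a);
    out_b_.push_back(b);
    out_s_.push_back(m.start);
    out_e_.push_back(m.end);
  }

  bool pair_allowed(int a, int b) {
    if (a == b) return false;
    if (!include_self_ && a / 2 == b / 2) return false;
    if (nx_ > 0 && ((a < nx_) == (b < nx_))) return false;
    return true;
  }

  void toggle(int ind, int site) {
    std::swap(hap_map_[2 * ind], hap_map_[2 * ind + 1]);
    toggles_[ind].push_back(site);
    for (int j = 0; j < t_; ++j) {
      missrun_[j][2 * ind] = 0;
      missrun_[j][2 * ind + 1] = 0;
    }
  }

  bool near_any_toggle(int ind, int site) const {
    for (int s : toggles_[ind])
      if (std::abs(site - s) <= Lm_) return true;
    return false;
  }

  // Fig-12 style classification of a new fragment against open matches on
  // complementary haplotypes of the same individual pair; toggles the
  // implicated individual(s) and merges the fragment into the stitched
  // match. Returns true if the fragment was consumed.
  bool try_phase_fix(int a, int b, int fs, int fe) {
    int ca = a ^ 1, cb = b ^ 1;
    struct Cand {
      int x, y;      // slot to look up (unordered)
      int tog_a;     // toggle individual of a?
      int tog_b;
    };
    const Cand cands[3] = {
        {ca, cb, 1, 1},  // complementary in both -> switch in both
        {a, cb, 0, 1},   // same hap in a's individual -> switch in b's
        {ca, b, 1, 0},   // same hap in b's individual -> switch in a's
    };
    int best = -1, best_dist = 0;
    Match* best_m = nullptr;
    for (int c = 0; c < 3; ++c) {
      int x = std::min(cands[c].x, cands[c].y);
      int y = std::max(cands[c].x, cands[c].y);
      auto it = open_.find(key_of(x, y));
      if (it == open_.end()) continue;
      Match& m = it->second;
      if (fs < m.end - Lm_ || fs > m.end + Lm_ || fe <= m.end) continue;
      int dist = fs > m.end ? fs - m.end : m.end - fs;
      if (best < 0 || dist < best_dist) {
        best = c;
        best_dist = dist;
        best_m = &m;
      }
    }
    if (best < 0) return false;
    if (cands[best].tog_a) toggle(a / 2, fs);
    if (cands[best].tog_b) toggle(b / 2, fs);
    if (fs < best_m->start) best_m->start = fs;
    if (fe > best_m->end) best_m->end = fe;
    return true;
  }

  // After an inferred switch, templates whose state still reflects the
  // pre-toggle labels re-emit the same physical match on the complementary
  // slot. A fragment contained in a complementary open match and starting
  // within Lm of the involved individual's last toggle is that duplicate:
  // absorb it instead of storing (or re-toggling) it.
  bool absorb_duplicate(int a, int b, int fs, int fe) {
    int ca = a ^ 1, cb = b ^ 1;
    struct Cand { int x, y, ia, ib; };
    const Cand cands[3] = {
        {ca, cb, 1, 1}, {a, cb, 0, 1}, {ca, b, 1, 0}};
    for (int c = 0; c < 3; ++c) {
      int x = std::min(cands[c].x, cands[c].y);
      int y = std::max(cands[c].x, cands[c].y);
      auto it = open_.find(key_of(x, y));
      if (it == open_.end()) continue;
      Match& m = it->second;
      if (fs < m.start || fs > m.end || fe > m.end + Lm_) continue;
      bool near_toggle = (cands[c].ia && near_any_toggle(a / 2, fs)) ||
                         (cands[c].ib && near_any_toggle(b / 2, fs));
      if (!near_toggle) continue;
      if (fe > m.end) m.end = fe;
      return true;
    }
    return false;
  }

  // A candidate matching subsegment of >= Lm sites between haplotypes a
  // and b over [fs, fe]: merge into / stitch onto / replace the pair's
  // open match.
  void submit(int a, int b, int fs, int fe) {
    if (a > b) std::swap(a, b);
    if (!pair_allowed(a, b)) return;
    uint64_t key = key_of(a, b);
    auto it = open_.find(key);
    if (it != open_.end()) {
      Match& m = it->second;
      if (fs <= m.end + Lm_) {  // overlap, or gap of < Lm sites
        if (fs < m.start) m.start = fs;
        if (fe > m.end) m.end = fe;
        return;
      }
    }
    if (phase_corr_ && absorb_duplicate(a, b, fs, fe)) return;
    if (phase_corr_ && try_phase_fix(a, b, fs, fe)) return;
    if (it != open_.end()) {
      report(a, b, it->second);
      it->second = {fs, fe};
    } else {
      open_.emplace(key, Match{fs, fe});
      if (open_.size() > max_open_) max_open_ = open_.size();
    }
  }

  // emit terminating cross-allele pairs of the current block
  void flush(int k, const std::vector<int>& P, const std::vector<int>& D) {
    if (!m0_.empty() && !m1_.empty()) {
      for (int x : m0_) {
        for (int y : m1_) {
          int lo = std::min(x, y), hi = std::max(x, y);
          int st = D[lo + 1];
          for (int l = lo + 2; l <= hi; ++l)
            if (D[l] > st) st = D[l];
          if (k - st >= Lm_) submit(P[x], P[y], st, k - 1);
        }
      }
    }
    m0_.clear();
    m1_.clear();
  }

  // matches of the haplotype at ppa position i die (missing-run overflow):
  // emit them against both neighbours' chains before isolating it
  void emit_dying(int k, int i, const std::vector<int>& P,
                  const std::vector<int>& D) {
    int h = P[i];
    int run = D[i];
    for (int x = i - 1; x >= 0; --x) {
      if (run > k - Lm_) break;
      submit(P[x], h, run, k - 1);
      if (x > 0 && D[x] > run) run = D[x];
    }
    if (i + 1 < M_) {
      run = D[i + 1];
      for (int y = i + 1; y < M_; ++y) {
        if (run > k - Lm_) break;
        submit(h, P[y], run, k - 1);
        if (y + 1 < M_ && D[y + 1] > run) run = D[y + 1];
      }
    }
  }

  // missing allele: extend the neighbour with the longer current match
  // (smaller divergence); tie -> predecessor. Local to the template.
  int impute(int k, int i, const std::vector<int>& P,
             const std::vector<int>& D) {
    bool has_pred = i > 0;
    bool has_succ = i + 1 < M_;
    int apred = has_pred ? res_[i - 1] : 2;
    int asucc = has_succ ? A(hap_map_[P[i + 1]], k) : 2;
    bool prefer_pred =
        has_pred && (!has_succ || D[i] <= D[i + 1]);
    if (prefer_pred) {
      if (apred != 2) return apred;
      if (asucc != 2) return asucc;
    } else {
      if (asucc != 2) return asucc;
      if (apred != 2) return apred;
    }
    return 0;
  }

  void site_update(int j, int k, int K) {
    std::vector<int>& P = ppa_[j];
    std::vector<int>& D = div_[j];
    p0_.clear(); p1_.clear(); d0_.clear(); d1_.clear();
    m0_.clear(); m1_.clear();
    res_.assign(M_, 0);
    int s0 = K, s1 = K;
    for (int i = 0; i < M_; ++i) {
      int d = D[i];
      if (d > k - Lm_) flush(k, P, D);
      if (d > s0) s0 = d;
      if (d > s1) s1 = d;
      int h = P[i];
      int a = A(hap_map_[h], k);
      bool kill = false;
      if (a == 2) {
        int& mr = missrun_[j][h];
        ++mr;
        a = impute(k, i, P, D);
        if (mr > Mt_) {
          emit_dying(k, i, P, D);
          kill = true;
        }
      } else {
        missrun_[j][h] = 0;
      }
      res_[i] = a;
      if (kill) { s0 = K; s1 = K; }
      if (a == 0) {
        p0_.push_back(h); d0_.push_back(s0); m0_.push_back(i);
        s0 = kill ? K : 0;
      } else {
        p1_.push_back(h); d1_.push_back(s1); m1_.push_back(i);
        s1 = kill ? K : 0;
      }
    }
    flush(k, P, D);
    P.clear();
    P.insert(P.end(), p0_.begin(), p0_.end());
    P.insert(P.end(), p1_.begin(), p1_.end());
    D.clear();
    D.insert(D.end(), d0_.begin(), d0_.end());
    D.insert(D.end(), d1_.begin(), d1_.end());
  }

  // after the last site, emit every still-open adjacency match reaching
  // the end of the haplotypes
  void trailing() {
    for (int j = 0; j < t_; ++j) {
      const std::vector<int>& P = ppa_[j];
      const std::vector<int>& D = div_[j];
      int blk = 0;
      for (int i = 1; i <= M_; ++i) {
        if (i == M_ || D[i] > N_ - Lm_) {
          for (int x = blk; x < i; ++x) {
            int st = 0;
            for (int y = x + 1; y < i; ++y) {
              if (D[y] > st) st = D[y];
              if (st > N_ - Lm_) break;
              submit(P[x], P[y], st, N_ - 1);
            }
          }
          blk = i;
        }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export]]
DataFrame tpbwt_sweep_cpp(IntegerMatrix alleles, NumericVector cm,
                          IntegerMatrix masks, int Lm, double Lf, int Mt,
                          bool phase_correction, bool include_self_pairs,
                          int n_hap_x) {
  if (alleles.ncol() != cm.size())
    stop("cm must have one entry per site");
  if (Lm < 1) stop("Lm must be >= 1");
  Sweep sw(alleles, masks, Lm, Lf, Mt, phase_correction, include_self_pairs,
           n_hap_x, cm);
  return sw.run();
}
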