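#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Local affine-gap alignment (Smith-Waterman with Gotoh gaps) returning the
// best-scoring alignment, then iteratively masking the aligned query region
// and re-running until the score drops below min_score. Gap cost for a run of
// length k is gap_open + k * gap_extend. Traceback state is packed into one
// byte per DP cell: bits 0-1 = H source (0 stop, 1 diagonal, 2 E, 3 F),
// bit 2 = E extended from E, bit 3 = F extended from F.

namespace {

struct Hit {
  int q_start, q_end, t_start, t_end; // 0-based half-open
  int score, n_match;
  std::string cigar;
};

void rle_append(std::string &cig, char op, int len) {
  if (len > 0) cig += std::to_string(len) + op;
}

bool sw_once(const std::string &q, const std::string &t,
             const std::vector<char> &mask,
             int match, int mismatch, int gap_open, int gap_extend,
             Hit &hit) {
  const int n = (int)q.size(), m = (int)t.size();
  const int NEG = -1000000000;
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<int> Fcur(m + 1, NEG);
  std::vector<uint8_t> tb((size_t)n * m, 0);

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      uint8_t cell = 0;
      // E: gap in query (consumes target -> deletion)
      int e_open = Hcur[j - 1] - gap_open - gap_extend;
      int e_ext  = Ecur[j - 1] - gap_extend;
      if (e_ext > e_open) { Ecur[j] = e_ext; cell |= 4; }
      else Ecur[j] = e_open;
      // F: gap in target (consumes query -> insertion)
      int f_open = Hprev[j] - gap_open - gap_extend;
      int f_ext  = Fcur[j] - gap_extend;  // Fcur[j] still holds row i-1 value
      if (f_ext > f_open) { Fcur[j] = f_ext; cell |= 8; }
      else Fcur[j] = f_open;

      int s = (mask[i - 1] ? NEG / 2
                           : (q[i - 1] == t[j - 1] ? match : mismatch));
      int diag = Hprev[j - 1] + s;
      int h = 0; uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; src = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; src = 3; }
      Hcur[j] = h;
      tb[(size_t)(i - 1) * m + (j - 1)] = cell | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  if (bi < 0) return false;

  // traceback from (bi, bj)
  int i = bi, j = bj, n_match = 0;
  std::vector<std::pair<char,int>> ops; // reversed run-length
  auto push = [&](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.push_back({op, 1});
  };
  while (i > 0 && j > 0) {
    uint8_t cell = tb[(size_t)(i - 1) * m + (j - 1)];
    uint8_t src = cell & 3;
    if (src == 0) break;
    if (src == 1) {
      char op = (q[i - 1] == t[j - 1] && !mask[i - 1]) ? '=' : 'X';
      if (op == '=') ++n_match;
      push(op); --i; --j;
    } else if (src == 2) { // E run: deletions, walk left while extend bit set
      while (true) {
        push('D');
        bool ext = (tb[(size_t)(i - 1) * m + (j - 1)] & 4) != 0;
        --j;
        if (!ext || j == 0) break;
      }
    } else { // F run: insertions
      while (true) {
        push('I');
        bool ext = (tb[(size_t)(i - 1) * m + (j - 1)] & 8) != 0;
        --i;
        if (!ext || i == 0) break;
      }
    }
  }
  hit.q_start = i; hit.q_end = bi;
  hit.t_start = j; hit.t_end = bj;
  hit.score = best; hit.n_match = n_match;
  std::string cig;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it)
    rle_append(cig, it->first, it->second);
  hit.cigar = cig;
  return best > 0;
}

} // namespace

// [[Rcpp::export]]
List sw_align_multi(std::string query, std::string target,
                    int match = 1, int mismatch = -4,
                    int gap_open = 4, int gap_extend = 2,
                    int min_score = 20, int max_alignments = 20) {
  const double cells = (double)query.size() * (double)target.size();
  if (cells > 6e8)
    stop("sequences too long for the built-in aligner (%.0f DP cells)", cells);
  if (query.empty() || target.empty()) return List::create();

  std::vector<char> mask(query.size(), 0);
  List out;
  for (int k = 0; k < max_alignments; ++k) {
    Hit hit;
    if (!sw_once(query, target, mask, match, -std::abs(mismatch),
                 gap_open, gap_extend, hit))
      break;
    if (hit.score < min_score) break;
    out.push_back(List::create(
        _["q_start"] = hit.q_start, _["q_end"] = hit.q_end,
        _["t_start"] = hit.t_start, _["t_end"] = hit.t_end,
        _["score"] = hit.score, _["n_match"] = hit.n_match,
        _["cigar"] = hit.cigar));
    for (int i = hit.q_start; i < hit.q_end; ++i) mask[i] = 1;
  }
  return out;
}
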