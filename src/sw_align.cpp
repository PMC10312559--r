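#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap (Gotoh) Smith-Waterman local alignment of one query against
// one subject. Scores follow the blastn nucleotide defaults: reward for a
// match, penalty for a mismatch, and gap cost open + k * extend for a gap
// of length k. Returns the single best-scoring local alignment with a full
// traceback so identity and alignment length are exact.
//
// Case-insensitive; any non-ACGT character (e.g. N) scores as a mismatch
// against everything, which is the conservative choice for identity
// filtering.

static inline char upc(char c) { return (c >= 'a' && c <= 'z') ? c - 32 : c; }

// [[Rcpp::export(name = ".sw_align_one")]]
List sw_align_one(std::string query, std::string subject,
                  double reward = 2.0, double penalty = -3.0,
                  double gap_open = 5.0, double gap_extend = 2.0) {
  const int m = query.size(), n = subject.size();
  if (m == 0 || n == 0) {
    return List::create(_["score"] = 0.0, _["matches"] = 0,
                        _["align_length"] = 0, _["qstart"] = 0,
                        _["qend"] = 0, _["sstart"] = 0, _["send"] = 0);
  }
  for (int i = 0; i < m; ++i) query[i] = upc(query[i]);
  for (int j = 0; j < n; ++j) subject[j] = upc(subject[j]);

  const double NEG = -1e18;
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG); // gap in subject (up)
  std::vector<double> Fcur(n + 1, NEG);                    // gap in query (left)
  // trace: 0 stop, 1 diag, 2 up (E), 3 left (F); plus gap-state traces
  std::vector<unsigned char> traceH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> traceE((size_t)(m + 1) * (n + 1), 0); // 1 = open
  std::vector<unsigned char> traceF((size_t)(m + 1) * (n + 1), 0); // 1 = open

  double best = 0.0;
  int bi = 0, bj = 0;
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };

  for (int i = 1; i <= m; ++i) {
    Fcur[0] = NEG;
    Hcur[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      // E: gap in subject (consume query base), coming from row above
      double e_open = Hprev[j] - gap_open - gap_extend;
      double e_ext = Eprev[j] - gap_extend;
      if (e_open >= e_ext) { Ecur[j] = e_open; traceE[at(i, j)] = 1; }
      else { Ecur[j] = e_ext; traceE[at(i, j)] = 0; }
      // F: gap in query (consume subject base), coming from the left
      double f_open = Hcur[j - 1] - gap_open - gap_extend;
      double f_ext = Fcur[j - 1] - gap_extend;
      if (f_open >= f_ext) { Fcur[j] = f_open; traceF[at(i, j)] = 1; }
      else { Fcur[j] = f_ext; traceF[at(i, j)] = 0; }

      bool is_match = query[i - 1] == subject[j - 1] &&
                      (query[i - 1] == 'A' || query[i - 1] == 'C' ||
                       query[i - 1] == 'G' || query[i - 1] == 'T');
      double diag = Hprev[j - 1] + (is_match ? reward : penalty);

      double h = 0.0;
      unsigned char tr = 0;
      if (diag > h) { h = diag; tr = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; tr = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; tr = 3; }
      Hcur[j] = h;
      traceH[at(i, j)] = tr;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  // Traceback from the best cell.
  int i = bi, j = bj;
  int matches = 0, alen = 0;
  int qend = bi, send = bj;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char tr = traceH[at(i, j)];
      if (tr == 0) break;
      if (tr == 1) {
        bool is_match = query[i - 1] == subject[j - 1] &&
                        (query[i - 1] == 'A' || query[i - 1] == 'C' ||
                         query[i - 1] == 'G' || query[i - 1] == 'T');
        if (is_match) ++matches;
        ++alen; --i; --j;
      } else if (tr == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // in E: consume query base
      unsigned char open = traceE[at(i, j)];
      ++alen; --i;
      if (open) state = 0;
    } else { // in F: consume subject base
      unsigned char open = traceF[at(i, j)];
      ++alen; --j;
      if (open) state = 0;
    }
  }
  int qstart = i + 1, sstart = j + 1;
  if (best <= 0.0) { qstart = qend = sstart = send = 0; alen = 0; matches = 0; }

  return List::create(_["score"] = best, _["matches"] = matches,
                      _["align_length"] = alen, _["qstart"] = qstart,
                      _["qend"] = qend, _["sstart"] = sstart,
                      _["send"] = send);
}

// All-pairs wrapper: aligns every query against every subject and returns a
// flat table. Used by the internal similarity-search backend.
// [[Rcpp::export(name = ".sw_align_pairs")]]
DataFrame sw_align_pairs(CharacterVector queries, CharacterVector subjects,
                         double reward = 2.0, double penalty = -3.0,
                         double gap_open = 5.0, double gap_extend = 2.0) {
  const int nq = queries.size(), ns = subjects.size();
  const int total = nq * ns;
  IntegerVector qi(total), si(total), matches(total), alen(total),
      qstart(total), qend(total), sstart(total), send(total);
  NumericVector score(total);
  int k = 0;
  for (int a = 0; a < nq; ++a) {
    std::string q = as<std::string>(queries[a]);
    for (int b = 0; b < ns; ++b, ++k) {
      std::string s = as<std::string>(subjects[b]);
      List r = sw_align_one(q, s, reward, penalty, gap_open, gap_extend);
      qi[k] = a + 1; si[k] = b + 1;
      score[k] = as<double>(r["score"]);
      matches[k] = as<int>(r["matches"]);
      alen[k] = as<int>(r["align_length"]);
      qstart[k] = as<int>(r["qstart"]); qend[k] = as<int>(r["qend"]);
      sstart[k] = as<int>(r["sstart"]); send[k] = as<int>(r["send"]);
    }
  }
  return DataFrame::create(
      _["query_index"] = qi, _["subject_index"] = si, _["score"] = score,
      _["matches"] = matches, _["align_length"] = alen, _["qstart"] = qstart,
      _["qend"] = qend, _["sstart"] = sstart, _["send"] = send,
      _["stringsAsFactors"] = false);
}
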