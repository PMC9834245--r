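#include <Rcpp.h>
using namespace Rcpp;

// Semi-global edit distance: the whole pattern is aligned against any
// substring of the text (free leading/trailing gaps in the text only).
// Standard two-row DP with start-of-match tracking; O(m*n) time, O(n) space.
static void infix_one(const std::string& p, const std::string& t,
                      int& best, int& bstart, int& bend) {
  const int m = (int)p.size(), n = (int)t.size();
  if (n == 0) { best = m; bstart = 1; bend = 0; return; }
  std::vector<int> prev(n + 1), curr(n + 1), sprev(n + 1), scurr(n + 1);
  for (int j = 0; j <= n; ++j) { prev[j] = 0; sprev[j] = j + 1; }
  for (int i = 1; i <= m; ++i) {
    curr[0] = i; scurr[0] = 1;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (p[i - 1] == t[j - 1] ? 0 : 1);
      int del = prev[j] + 1;      // gap in text (pattern base unmatched)
      int ins = curr[j - 1] + 1;  // gap in pattern (text base consumed)
      int d = sub, s = sprev[j - 1];
      if (del < d) { d = del; s = sprev[j]; }
      if (ins < d) { d = ins; s = scurr[j - 1]; }
      curr[j] = d; scurr[j] = s;
    }
    std::swap(prev, curr); std::swap(sprev, scurr);
  }
  best = prev[0]; bstart = 1; bend = 0;
  for (int j = 0; j <= n; ++j) {
    if (prev[j] < best) { best = prev[j]; bstart = sprev[j]; bend = j; }
  }
  if (bend == 0) { bstart = 1; }  // pattern fully deleted; degenerate anchor
}

//' @noRd
// [[Rcpp::export(name = ".infix_locate_cpp")]]
DataFrame infix_locate_cpp(std::string pattern, CharacterVector texts) {
  const int n = texts.size();
  IntegerVector dist(n), start(n), end(n);
  for (int k = 0; k < n; ++k) {
    if (CharacterVector::is_na(texts[k])) {
      dist[k] = NA_INTEGER; start[k] = NA_INTEGER; end[k] = NA_INTEGER;
      continue;
    }
    std::string t = as<std::string>(texts[k]);
    int d, s, e;
    infix_one(pattern, t, d, s, e);
    dist[k] = d; start[k] = s; end[k] = e;
  }
  return DataFrame::create(_["dist"] = dist, _["start"] = start, _["end"] = end);
}

// Best and second-best whitelist hit per observed window.
// semiglobal = true aligns each barcode as an infix of the window
// (anchor-derived windows carry flanking bases); false uses plain
// global Levenshtein distance.
//' @noRd
// [[Rcpp::export(name = ".best_barcode_cpp")]]
List best_barcode_cpp(CharacterVector barcodes, CharacterVector windows,
                      bool semiglobal) {
  const int nb = barcodes.size(), nw = windows.size();
  std::vector<std::string> bc(nb);
  for (int i = 0; i < nb; ++i) bc[i] = as<std::string>(barcodes[i]);
  IntegerVector best_idx(nw), best_dist(nw), second_dist(nw);
  std::vector<int> prev, curr;  // shared DP buffers
  for (int k = 0; k < nw; ++k) {
    if (CharacterVector::is_na(windows[k])) {
      best_idx[k] = NA_INTEGER; best_dist[k] = NA_INTEGER; second_dist[k] = NA_INTEGER;
      continue;
    }
    std::string w = as<std::string>(windows[k]);
    const int n = (int)w.size();
    if ((int)prev.size() < n + 1) { prev.resize(n + 1); curr.resize(n + 1); }
    int b1 = INT_MAX, b2 = INT_MAX, idx = 0;
    for (int i = 0; i < nb; ++i) {
      const std::string& p = bc[i];
      const int m = (int)p.size();
      // row 0: semiglobal starts free anywhere in the window, global at 0
      for (int j = 0; j <= n; ++j) prev[j] = semiglobal ? 0 : j;
      int d = INT_MAX;
      bool abandoned = false;
      for (int r = 1; r <= m; ++r) {
        curr[0] = r;
        int rowmin = r;
        const char pc = p[r - 1];
        for (int j = 1; j <= n; ++j) {
          int v = prev[j - 1] + (pc == w[j - 1] ? 0 : 1);
          int del = prev[j] + 1, ins = curr[j - 1] + 1;
          if (del < v) v = del;
          if (ins < v) v = ins;
          curr[j] = v;
          if (v < rowmin) rowmin = v;
        }
        // row minima are non-decreasing: this barcode cannot improve on
        // the current runner-up, so its exact distance is irrelevant
        if (b2 != INT_MAX && rowmin > b2) { abandoned = true; break; }
        std::swap(prev, curr);
      }
      if (abandoned) continue;
      if (semiglobal) {
        d = prev[0];
        for (int j = 1; j <= n; ++j) if (prev[j] < d) d = prev[j];
      } else {
        d = prev[n];
      }
      if (d < b1) { b2 = b1; b1 = d; idx = i + 1; }
      else if (d < b2) { b2 = d; }
    }
    best_idx[k] = idx; best_dist[k] = b1;
    second_dist[k] = (nb > 1) ? b2 : NA_INTEGER;
  }
  return List::create(_["best_idx"] = best_idx, _["best_dist"] = best_dist,
                      _["second_dist"] = second_dist);
}
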