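// Low-level 2-D binary image primitives used by the segmentation and
// candidate-detection stages. All functions operate on one slice (a logical
// matrix); slice iteration happens in R. Connectivity: 4 or 8.

#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

static inline bool inb(int r, int c, int nr, int nc) {
  return r >= 0 && r < nr && c >= 0 && c < nc;
}

// Label connected foreground components. Returns an integer matrix with
// 0 = background, 1..k = component id (scan-order of first pixel).
// [[Rcpp::export(name = ".cc_label_2d")]]
IntegerMatrix cc_label_2d(LogicalMatrix img, int connectivity) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  const int nn = connectivity == 4 ? 4 : 8;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!img(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < nn; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (inb(rr, cc, nr, nc) && img(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// Erosion/dilation by an arbitrary structuring element given as offset rows
// (k x 2 matrix of (dr, dc)). Pixels outside the image are treated as
// background (false) for both operations.
// [[Rcpp::export(name = ".morph_2d")]]
LogicalMatrix morph_2d(LogicalMatrix img, IntegerMatrix offsets, bool erode) {
  const int nr = img.nrow(), nc = img.ncol(), k = offsets.nrow();
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      bool v = erode;
      for (int i = 0; i < k; ++i) {
        int rr = r + offsets(i, 0), cc = c + offsets(i, 1);
        bool px = inb(rr, cc, nr, nc) ? (bool)img(rr, cc) : false;
        if (erode) {
          if (!px) { v = false; break; }
        } else {
          if (px) { v = true; break; }
        }
      }
      out(r, c) = v;
    }
  }
  return out;
}

// Fill holes: background regions not connected (4-conn) to the image border
// become foreground.
// [[Rcpp::export(name = ".fill_holes_2d")]]
LogicalMatrix fill_holes_2d(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix reach(nr, nc); // background reachable from border
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; c += (r == 0 || r == nr - 1) ? 1 : (nc > 1 ? nc - 1 : 1)) {
      if (!img(r, c) && !reach(r, c)) { reach(r, c) = true; q.push(std::make_pair(r, c)); }
    }
  }
  const int dr[4] = {-1, 0, 0, 1}, dc[4] = {0, -1, 1, 0};
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int k = 0; k < 4; ++k) {
      int rr = p.first + dr[k], cc = p.second + dc[k];
      if (inb(rr, cc, nr, nc) && !img(rr, cc) && !reach(rr, cc)) {
        reach(rr, cc) = true;
        q.push(std::make_pair(rr, cc));
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = img(r, c) || !reach(r, c);
  return out;
}

// CRC-32 (PNG/zlib polynomial) of a raw vector, for PNG chunk checksums.
// [[Rcpp::export(name = ".crc32_raw")]]
double crc32_raw(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int k = 0; k < 8; ++k) c = (c & 1) ? 0xedb88320u ^ (c >> 1) : c >> 1;
      table[n] = c;
    }
    init = true;
  }
  uint32_t crc = 0xffffffffu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xffu] ^ (crc >> 8);
  crc ^= 0xffffffffu;
  return (double)crc;
}

// Adler-32 of a raw vector (zlib stream trailer).
// [[Rcpp::export(name = ".adler32_raw")]]
double adler32_raw(RawVector data) {
  uint32_t a = 1, b = 0;
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    a = (a + data[i]) % 65521u;
    b = (b + a) % 65521u;
  }
  return (double)((b << 16) | a);
}
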