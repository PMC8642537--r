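#include <Rcpp.h>
using namespace Rcpp;

// 8-neighborhood offsets in circular order: E, NE, N, NW, W, SW, S, SE
static const int DR[8] = { 0, -1, -1, -1,  0,  1, 1, 1 };
static const int DC[8] = { 1,  1,  0, -1, -1, -1, 0, 1 };

static inline bool fg(const LogicalMatrix& m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return false;
  return m(r, c) == TRUE;
}

// Simple-point test for (8, 4) connectivity: deleting p must leave exactly
// one 8-connected foreground component among its 8 neighbors and exactly one
// 4-connected background component in the neighborhood that touches a
// 4-neighbor of p. Deleting only simple points preserves the Euler number
// and all connectivity, which is the contract of the thinning step.
static bool is_simple(const LogicalMatrix& m, int r, int c) {
  bool nb[8];
  for (int k = 0; k < 8; ++k) nb[k] = fg(m, r + DR[k], c + DC[k]);

  // foreground components among ring cells, 8-adjacency (Chebyshev <= 1)
  int comp_fg = 0;
  int label[8];
  for (int k = 0; k < 8; ++k) label[k] = -1;
  for (int k = 0; k < 8; ++k) {
    if (!nb[k] || label[k] >= 0) continue;
    ++comp_fg;
    // BFS over ring positions
    int stack[8], top = 0;
    stack[top++] = k; label[k] = comp_fg;
    while (top > 0) {
      int a = stack[--top];
      for (int b = 0; b < 8; ++b) {
        if (!nb[b] || label[b] >= 0) continue;
        int dr = DR[a] - DR[b], dc = DC[a] - DC[b];
        if (dr >= -1 && dr <= 1 && dc >= -1 && dc <= 1) {
          label[b] = comp_fg;
          stack[top++] = b;
        }
      }
    }
  }
  if (comp_fg != 1) return false;

  // background components among ring cells, 4-adjacency, counted only if
  // the component contains a 4-neighbor of p (positions 0,2,4,6)
  int blabel[8];
  for (int k = 0; k < 8; ++k) blabel[k] = -1;
  int comp_bg = 0;
  for (int k = 0; k < 8; ++k) {
    if (nb[k] || blabel[k] >= 0) continue;
    ++comp_bg;
    int stack[8], top = 0;
    stack[top++] = k; blabel[k] = comp_bg;
    while (top > 0) {
      int a = stack[--top];
      for (int b = 0; b < 8; ++b) {
        if (nb[b] || blabel[b] >= 0) continue;
        int dr = DR[a] - DR[b], dc = DC[a] - DC[b];
        if ((dr == 0 && (dc == 1 || dc == -1)) ||
            (dc == 0 && (dr == 1 || dr == -1))) {
          blabel[b] = comp_bg;
          stack[top++] = b;
        }
      }
    }
  }
  int touching = 0;
  bool seen[9] = { false, false, false, false, false, false, false, false, false };
  for (int k = 0; k < 8; k += 2) {  // 4-neighbors E, N, W, S
    if (!nb[k] && blabel[k] > 0 && !seen[blabel[k]]) {
      seen[blabel[k]] = true;
      ++touching;
    }
  }
  return touching == 1;
}

static inline int n_neighbors(const LogicalMatrix& m, int r, int c) {
  int n = 0;
  for (int k = 0; k < 8; ++k) if (fg(m, r + DR[k], c + DC[k])) ++n;
  return n;
}

// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  LogicalMatrix m = clone(mask);
  int nr = m.nrow(), nc = m.ncol();
  // directional subiterations: border direction N, S, E, W
  static const int bdr[4] = { -1, 1, 0, 0 };
  static const int bdc[4] = { 0, 0, 1, -1 };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (m(r, c) != TRUE) continue;
          if (fg(m, r + bdr[d], c + bdc[d])) continue;  // not a d-border pixel
          int nn = n_neighbors(m, r, c);
          if (nn < 2) continue;                          // keep endpoints
          if (!is_simple(m, r, c)) continue;
          m(r, c) = FALSE;                               // sequential deletion
          changed = true;
        }
      }
    }
  }
  // final cleanup of residual 2x2 blocks (rare staircase leftovers); only
  // simple non-endpoint pixels are removed, so topology is still preserved
  bool again = true;
  while (again) {
    again = false;
    for (int r = 0; r + 1 < nr && !again; ++r) {
      for (int c = 0; c + 1 < nc && !again; ++c) {
        if (m(r, c) == TRUE && m(r + 1, c) == TRUE &&
            m(r, c + 1) == TRUE && m(r + 1, c + 1) == TRUE) {
          for (int k = 0; k < 4 && !again; ++k) {
            int rr = r + (k / 2), cc = c + (k % 2);
            if (n_neighbors(m, rr, cc) >= 2 && is_simple(m, rr, cc)) {
              m(rr, cc) = FALSE;
              again = true;
            }
          }
        }
      }
    }
  }
  return m;
}

// Trace the skeleton into maximal paths between nodes (pixels with != 2
// 8-neighbors). Pure cycles are split into two halves. Returns a list of
// n x 2 integer matrices of 1-based (row, col) coordinates.
// [[Rcpp::export(name = ".trace_segments_cpp")]]
List trace_segments_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix deg(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (mask(r, c) == TRUE) deg(r, c) = n_neighbors(mask, r, c);

  // used[r][c] bitmask over the 8 directions
  std::vector<unsigned char> used((size_t)nr * nc, 0);
  std::vector< std::vector<int> > paths;  // flattened r1,c1,r2,c2,...

  auto dir_of = [&](int r1, int c1, int r2, int c2) {
    for (int k = 0; k < 8; ++k)
      if (r1 + DR[k] == r2 && c1 + DC[k] == c2) return k;
    return -1;
  };
  auto mark = [&](int r1, int c1, int r2, int c2) {
    int k = dir_of(r1, c1, r2, c2);
    used[(size_t)r1 * nc + c1] |= (1 << k);
    int kk = dir_of(r2, c2, r1, c1);
    used[(size_t)r2 * nc + c2] |= (1 << kk);
  };
  auto step_used = [&](int r1, int c1, int r2, int c2) {
    int k = dir_of(r1, c1, r2, c2);
    return (used[(size_t)r1 * nc + c1] >> k) & 1;
  };

  // walk from a node through degree-2 pixels until the next node
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) != TRUE || deg(r, c) == 2) continue;  // nodes only
      if (deg(r, c) == 0) {  // isolated pixel: degenerate 1-px segment
        std::vector<int> p; p.push_back(r + 1); p.push_back(c + 1);
        paths.push_back(p);
        continue;
      }
      for (int k = 0; k < 8; ++k) {
        int r2 = r + DR[k], c2 = c + DC[k];
        if (!fg(mask, r2, c2) || step_used(r, c, r2, c2)) continue;
        std::vector<int> p;
        p.push_back(r + 1); p.push_back(c + 1);
        int pr = r, pc = c, cr = r2, cc = c2;
        mark(pr, pc, cr, cc);
        while (true) {
          p.push_back(cr + 1); p.push_back(cc + 1);
          if (deg(cr, cc) != 2) break;  // reached a node
          int nrr = -1, ncc = -1;
          for (int j = 0; j < 8; ++j) {
            int ar = cr + DR[j], ac = cc + DC[j];
            if (fg(mask, ar, ac) && !(ar == pr && ac == pc)) {
              nrr = ar; ncc = ac;
            }
          }
          if (nrr < 0) break;  // safety: dangling degree-2 (shouldn't happen)
          mark(cr, cc, nrr, ncc);
          pr = cr; pc = cc; cr = nrr; cc = ncc;
        }
        paths.push_back(p);
      }
    }
  }

  // remaining unvisited degree-2 pixels are pure cycles: trace and halve
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) != TRUE || deg(r, c) != 2) continue;
      if (used[(size_t)r * nc + c] != 0) continue;
      std::vector<int> loop;
      loop.push_back(r); loop.push_back(c);
      int pr = r, pc = c, cr = -1, cc = -1;
      for (int k = 0; k < 8; ++k) {
        int r2 = r + DR[k], c2 = c + DC[k];
        if (fg(mask, r2, c2)) { cr = r2; cc = c2; break; }
      }
      if (cr < 0) continue;
      mark(pr, pc, cr, cc);
      while (!(cr == r && cc == c)) {
        loop.push_back(cr); loop.push_back(cc);
        int nrr = -1, ncc = -1;
        for (int j = 0; j < 8; ++j) {
          int ar = cr + DR[j], ac = cc + DC[j];
          if (fg(mask, ar, ac) && !(ar == pr && ac == pc)) { nrr = ar; ncc = ac; }
        }
        if (nrr < 0) break;
        mark(cr, cc, nrr, ncc);
        pr = cr; pc = cc; cr = nrr; cc = ncc;
      }
      int npix = (int)loop.size() / 2;
      int half = npix / 2;
      // half 1: pixels 0..half ; half 2: pixels half..n-1 plus closing pixel 0
      std::vector<int> p1, p2;
      for (int i = 0; i <= half && i < npix; ++i) {
        p1.push_back(loop[2 * i] + 1); p1.push_back(loop[2 * i + 1] + 1);
      }
      for (int i = half; i < npix; ++i) {
        p2.push_back(loop[2 * i] + 1); p2.push_back(loop[2 * i + 1] + 1);
      }
      p2.push_back(loop[0] + 1); p2.push_back(loop[1] + 1);
      paths.push_back(p1);
      paths.push_back(p2);
    }
  }

  List out(paths.size());
  for (size_t i = 0; i < paths.size(); ++i) {
    int n = (int)paths[i].size() / 2;
    IntegerMatrix m(n, 2);
    for (int j = 0; j < n; ++j) {
      m(j, 0) = paths[i][2 * j];
      m(j, 1) = paths[i][2 * j + 1];
    }
    out[i] = m;
  }
  return out;
}

// 8-connected component labelling of a logical mask (0 = background).
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) != TRUE || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r * nc + c);
      lab(r, c) = next;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        int vr = v / nc, vc = v % nc;
        for (int k = 0; k < 8; ++k) {
          int ar = vr + DR[k], ac = vc + DC[k];
          if (ar < 0 || ac < 0 || ar >= nr || ac >= nc) continue;
          if (mask(ar, ac) == TRUE && lab(ar, ac) == 0) {
            lab(ar, ac) = next;
            stack.push_back(ar * nc + ac);
          }
        }
      }
    }
  }
  return lab;
}
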