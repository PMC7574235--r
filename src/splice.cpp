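#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Splice-aware local alignment of a protein query against a genomic window
// (coding strand), maximizing substitution-matrix score with:
//   * affine codon gaps (gap of L codons costs open + L*ext),
//   * introns entered only at GT and left only at AG, length >= min_intron,
//     fixed penalty per intron, phase 0/1/2 (codon-splitting) allowed,
//   * frameshifts as 1- or 2-base genomic jumps with a heavy penalty,
//   * in-frame stop codons scored by the (pre-set) '*' row of the matrix.
//
// DP over (i = nucleotides consumed, j = query residues consumed) with a
// codon-boundary state B, gap states Ix (target codons vs '-') and Iy
// (query residues vs '-'), and running-maximum intron channels per query
// position: one channel for phase-0 introns and per-partial-codon channels
// (5 and 25) for phase-1/2 introns, which must remember the donor-side
// bases of the split codon.  Channels are delayed by min_intron columns so
// only long-enough introns can be closed.

static const double NEG = -1e18;

static inline int baseidx(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return 4; }
}

// [[Rcpp::export]]
List cpp_splice_align(std::string dna, std::string query,
                      NumericMatrix smat, std::string alphabet,
                      std::string codon_aa, // 64 chars, index b0*16+b1*4+b2
                      double gap_open, double gap_ext,
                      double intron_pen, int min_intron,
                      double fs_pen, double score_floor) {
  const int G = (int)dna.size(), Q = (int)query.size();
  const int A = smat.nrow();
  std::vector<double> mat((size_t)A * A);
  for (int i = 0; i < A; ++i)
    for (int j = 0; j < A; ++j) mat[(size_t)i * A + j] = smat(i, j);
  int ai[256]; for (int i = 0; i < 256; ++i) ai[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i) ai[(unsigned char)alphabet[i]] = (int)i;
  const int xi = ai[(unsigned char)'X'] >= 0 ? ai[(unsigned char)'X'] : 0;

  std::vector<int> qidx(Q);
  for (int j = 0; j < Q; ++j) {
    int v = ai[(unsigned char)query[j]]; qidx[j] = v >= 0 ? v : xi;
  }
  // codon -> aa (matrix row index); any non-ACGT base -> X
  //   aa char kept separately for reporting
  std::vector<int> bidx(G);
  for (int i = 0; i < G; ++i) bidx[i] = baseidx(dna[i]);
  auto codon_char = [&](int b0, int b1, int b2) -> char {
    if (b0 > 3 || b1 > 3 || b2 > 3) return 'X';
    return codon_aa[(size_t)(b0 * 16 + b1 * 4 + b2)];
  };
  auto sc3 = [&](int b0, int b1, int b2, int qj) -> double {
    char aa = codon_char(b0, b1, b2);
    int r = ai[(unsigned char)aa]; if (r < 0) r = xi;
    return mat[(size_t)r * A + qj];
  };
  auto isGT = [&](int d) { return d >= 0 && d + 1 < G && dna[d] == 'G' && dna[d + 1] == 'T'; };

  const int Qw = Q + 1;
  const int D = std::max(min_intron, 4) + 8;      // ring depth for B columns
  std::vector<double> Bbuf((size_t)D * Qw, NEG);
  std::vector<double> Ixbuf((size_t)4 * Qw, NEG);
  std::vector<double> Iy(Qw, NEG);
  auto Bc = [&](int col) { return &Bbuf[(size_t)(col % D) * Qw]; };
  auto Ixc = [&](int col) { return &Ixbuf[(size_t)(col % 4) * Qw]; };

  // traceback: one byte per (i,j) per state + donor positions for introns
  std::vector<unsigned char> tbB((size_t)(G + 1) * Qw, 0),
    tbIx((size_t)(G + 1) * Qw, 0), tbIy((size_t)(G + 1) * Qw, 0);
  std::vector<int> donorArr((size_t)(G + 1) * Qw, -1);

  // intron channels (running maxima over admissible donors) per query pos
  std::vector<double> ch0(Qw, NEG), ch1((size_t)5 * Qw, NEG), ch2((size_t)25 * Qw, NEG);
  std::vector<int> p0(Qw, -1), p1((size_t)5 * Qw, -1), p2((size_t)25 * Qw, -1);

  double best = 0; int bi = -1, bj = -1;

  for (int i = 0; i <= G; ++i) {
    double *B = Bc(i), *Bm3 = i >= 3 ? Bc(i - 3) : NULL,
      *Bm1 = i >= 1 ? Bc(i - 1) : NULL, *Bm2 = i >= 2 ? Bc(i - 2) : NULL;
    double *Ix = Ixc(i), *Ixm3 = i >= 3 ? Ixc(i - 3) : NULL;
    size_t row = (size_t)i * Qw;

    // channel insertions (donors whose shortest legal intron ends here)
    int d0 = i - min_intron;
    if (d0 >= 0 && isGT(d0)) {
      const double *Bd = Bc(d0);
      for (int j = 0; j <= Q; ++j) {
        double v = Bd[j] + intron_pen;
        if (v > ch0[j]) { ch0[j] = v; p0[j] = d0; }
      }
    }
    int d1 = i - 2 - min_intron;
    if (d1 >= 1 && isGT(d1)) {
      const double *Bd = Bc(d1 - 1); int b = bidx[d1 - 1];
      double *ch = &ch1[(size_t)b * Qw]; int *pp = &p1[(size_t)b * Qw];
      for (int j = 0; j <= Q; ++j) {
        double v = Bd[j] + intron_pen;
        if (v > ch[j]) { ch[j] = v; pp[j] = d1; }
      }
    }
    int d2 = i - 1 - min_intron;
    if (d2 >= 2 && isGT(d2)) {
      const double *Bd = Bc(d2 - 2); int bb = bidx[d2 - 2] * 5 + bidx[d2 - 1];
      double *ch = &ch2[(size_t)bb * Qw]; int *pp = &p2[(size_t)bb * Qw];
      for (int j = 0; j <= Q; ++j) {
        double v = Bd[j] + intron_pen;
        if (v > ch[j]) { ch[j] = v; pp[j] = d2; }
      }
    }

    bool ag0 = i >= 2 && dna[i - 2] == 'A' && dna[i - 1] == 'G';
    bool ag1 = i >= 4 && dna[i - 4] == 'A' && dna[i - 3] == 'G';
    bool ag2 = i >= 3 && dna[i - 3] == 'A' && dna[i - 2] == 'G';

    B[0] = 0; tbB[row] = 0; Ix[0] = NEG; Iy[0] = NEG;
    for (int j = 1; j <= Q; ++j) {
      // Ix: genomic codon aligned to a gap
      double ix = NEG; unsigned char tix = 0;
      if (Bm3) {
        double o = Bm3[j] + gap_open + gap_ext, e = Ixm3[j] + gap_ext;
        if (o >= e) { ix = o; tix = 1; } else { ix = e; tix = 0; }
      }
      Ix[j] = ix; tbIx[row + j] = tix;
      // Iy: query residue aligned to a gap
      double oy = B[j - 1] + gap_open + gap_ext, ey = Iy[j - 1] + gap_ext;
      double iy; unsigned char tiy;
      if (oy >= ey) { iy = oy; tiy = 1; } else { iy = ey; tiy = 0; }
      Iy[j] = iy; tbIy[row + j] = tiy;

      double h = 0; unsigned char t = 0; int dn = -1;
      if (Bm3) {
        double d = Bm3[j - 1] + sc3(bidx[i - 3], bidx[i - 2], bidx[i - 1], qidx[j - 1]);
        if (d > h) { h = d; t = 1; }
      }
      if (ix > h) { h = ix; t = 2; }
      if (iy > h) { h = iy; t = 3; }
      if (Bm1) { double v = Bm1[j] + fs_pen; if (v > h) { h = v; t = 4; } }
      if (Bm2) { double v = Bm2[j] + fs_pen; if (v > h) { h = v; t = 5; } }
      if (ag0 && ch0[j] > h) { h = ch0[j]; t = 6; dn = p0[j]; }
      if (ag1) {
        for (int b = 0; b < 5; ++b) {
          double base = ch1[(size_t)b * Qw + (j - 1)];
          if (base <= NEG / 2) continue;
          double v = base + sc3(b, bidx[i - 2], bidx[i - 1], qidx[j - 1]);
          if (v > h) { h = v; t = 7; dn = p1[(size_t)b * Qw + (j - 1)]; }
        }
      }
      if (ag2) {
        for (int bb = 0; bb < 25; ++bb) {
          double base = ch2[(size_t)bb * Qw + (j - 1)];
          if (base <= NEG / 2) continue;
          double v = base + sc3(bb / 5, bb % 5, bidx[i - 1], qidx[j - 1]);
          if (v > h) { h = v; t = 8; dn = p2[(size_t)bb * Qw + (j - 1)]; }
        }
      }
      B[j] = h; tbB[row + j] = t;
      if (t >= 6) donorArr[row + j] = dn;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (bi < 0 || best < score_floor || best <= 0)
    return List::create(_["found"] = false, _["score"] = best);

  // ---- traceback --------------------------------------------------------
  std::vector<int> ex_start, ex_end, in_start, in_end, fs_pos, fs_len;
  std::string cds, prot, aq, at;
  int i = bi, j = bj, cur_end = bi;
  auto prepend_cds = [&](int a, int b) { cds.insert(0, dna.substr(a, b - a)); };
  bool done = false;
  while (!done) {
    size_t c = (size_t)i * Qw + j;
    unsigned char t = (j > 0 && i >= 0) ? tbB[c] : 0;
    switch (t) {
    case 0:
      ex_start.push_back(i); ex_end.push_back(cur_end);
      done = true; break;
    case 1: {
      char aa = codon_char(bidx[i - 3], bidx[i - 2], bidx[i - 1]);
      prot.insert(0, 1, aa); aq.insert(0, 1, query[j - 1]); at.insert(0, 1, aa);
      prepend_cds(i - 3, i); i -= 3; j -= 1; break;
    }
    case 2: {
      while (true) {
        size_t cc = (size_t)i * Qw + j;
        char aa = codon_char(bidx[i - 3], bidx[i - 2], bidx[i - 1]);
        prot.insert(0, 1, aa); aq.insert(0, 1, '-'); at.insert(0, 1, aa);
        prepend_cds(i - 3, i);
        bool open = tbIx[cc] != 0; i -= 3; if (open) break;
      }
      break;
    }
    case 3: {
      while (true) {
        size_t cc = (size_t)i * Qw + j;
        aq.insert(0, 1, query[j - 1]); at.insert(0, 1, '-');
        bool open = tbIy[cc] != 0; j -= 1; if (open) break;
      }
      break;
    }
    case 4: fs_pos.push_back(i - 1); fs_len.push_back(1);
      prepend_cds(i - 1, i); i -= 1; break;
    case 5: fs_pos.push_back(i - 2); fs_len.push_back(2);
      prepend_cds(i - 2, i); i -= 2; break;
    case 6: {
      int d = donorArr[c];
      ex_start.push_back(i); ex_end.push_back(cur_end);
      in_start.push_back(d); in_end.push_back(i);
      cur_end = d; i = d; break;
    }
    case 7: {
      int d = donorArr[c];
      char aa = codon_char(bidx[d - 1], bidx[i - 2], bidx[i - 1]);
      prot.insert(0, 1, aa); aq.insert(0, 1, query[j - 1]); at.insert(0, 1, aa);
      prepend_cds(i - 2, i);
      ex_start.push_back(i - 2); ex_end.push_back(cur_end);
      in_start.push_back(d); in_end.push_back(i - 2);
      cur_end = d; prepend_cds(d - 1, d);
      i = d - 1; j -= 1; break;
    }
    case 8: {
      int d = donorArr[c];
      char aa = codon_char(bidx[d - 2], bidx[d - 1], bidx[i - 1]);
      prot.insert(0, 1, aa); aq.insert(0, 1, query[j - 1]); at.insert(0, 1, aa);
      prepend_cds(i - 1, i);
      ex_start.push_back(i - 1); ex_end.push_back(cur_end);
      in_start.push_back(d); in_end.push_back(i - 1);
      cur_end = d; prepend_cds(d - 2, d);
      i = d - 2; j -= 1; break;
    }
    }
  }
  std::reverse(ex_start.begin(), ex_start.end());
  std::reverse(ex_end.begin(), ex_end.end());
  std::reverse(in_start.begin(), in_start.end());
  std::reverse(in_end.begin(), in_end.end());
  std::reverse(fs_pos.begin(), fs_pos.end());
  std::reverse(fs_len.begin(), fs_len.end());

  IntegerMatrix exons(ex_start.size(), 2), introns(in_start.size(), 2),
    fshift(fs_pos.size(), 2);
  for (size_t k = 0; k < ex_start.size(); ++k) {
    exons(k, 0) = ex_start[k]; exons(k, 1) = ex_end[k];
  }
  for (size_t k = 0; k < in_start.size(); ++k) {
    introns(k, 0) = in_start[k]; introns(k, 1) = in_end[k];
  }
  for (size_t k = 0; k < fs_pos.size(); ++k) {
    fshift(k, 0) = fs_pos[k]; fshift(k, 1) = fs_len[k];
  }
  return List::create(
    _["found"] = true, _["score"] = best,
    _["q_start"] = j, _["q_end"] = bj,
    _["t_start"] = i, _["t_end"] = bi,
    _["exons"] = exons, _["introns"] = introns, _["frameshifts"] = fshift,
    _["cds"] = cds, _["protein"] = prot,
    _["aligned_query"] = aq, _["aligned_target"] = at);
}
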