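#include <Rcpp.h>
using namespace Rcpp;

// Draw fragments from new developing-MAC molecules of one replicon.
//
// Each fragment comes from an independent molecule: every IES locus is
// retained with its own probability r[j], the fragment start is uniform on
// the realized molecule, and the fragment sequence is assembled piecewise
// from the MAC backbone plus the retained IES sequences. Uses R's RNG, so
// results are reproducible under set.seed() in the caller.
//
// mac      : MAC replicon sequence
// ins_pos  : 0-based MAC insertion points, strictly increasing
// ies_seq  : germline IES sequences (same order as ins_pos)
// r        : per-IES retention probabilities
// n_frag   : number of fragments to draw
// frag_len : fragment (insert) length in bp
// [[Rcpp::export(name = ".cpp_new_mac_fragments")]]
List cpp_new_mac_fragments(std::string mac, IntegerVector ins_pos,
                           CharacterVector ies_seq, NumericVector r,
                           int n_frag, int frag_len) {
  const int n_ies = ins_pos.size();
  if (ies_seq.size() != n_ies || r.size() != n_ies)
    stop("ins_pos, ies_seq and r must have equal length");
  const long mac_len = (long) mac.size();
  if (frag_len > mac_len)
    stop("fragment length exceeds replicon length");

  std::vector<std::string> seqs(n_ies);
  std::vector<long> ies_len(n_ies);
  for (int j = 0; j < n_ies; ++j) {
    seqs[j] = as<std::string>(ies_seq[j]);
    ies_len[j] = (long) seqs[j].size();
  }

  CharacterVector fragments(n_frag);
  LogicalVector retained_any(n_frag);
  std::vector<int> keep(n_ies);
  std::vector<long> cum(n_ies + 1); // cumulative retained IES bp before IES j

  std::string frag;
  frag.reserve(frag_len);

  for (int f = 0; f < n_frag; ++f) {
    cum[0] = 0;
    for (int j = 0; j < n_ies; ++j) {
      keep[j] = (unif_rand() < r[j]) ? 1 : 0;
      cum[j + 1] = cum[j] + (keep[j] ? ies_len[j] : 0);
    }
    const long mol_len = mac_len + cum[n_ies];
    const long n_starts = mol_len - frag_len + 1;
    long start = (long) std::floor(unif_rand() * (double) n_starts);
    if (start >= n_starts) start = n_starts - 1; // guard unif_rand() == 1

    // molecule layout per IES j (retained): the IES occupies
    // [ins_pos[j] + cum[j], ins_pos[j] + cum[j+1]) in molecule coordinates;
    // MAC base at position p sits at molecule coordinate p + cum[j(p)],
    // where j(p) counts IESs with ins_pos <= p... (insertion point p means
    // the IES precedes MAC base p).
    frag.clear();
    bool hit_ies = false;
    long pos = start;          // current molecule coordinate
    long remaining = frag_len;

    // find first IES index whose molecule-end is beyond `pos`
    int j = 0;
    {
      int lo = 0, hi = n_ies;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        long mol_end = ins_pos[mid] + cum[mid + 1];
        if (mol_end <= pos) lo = mid + 1; else hi = mid;
      }
      j = lo;
    }

    while (remaining > 0) {
      if (j < n_ies && keep[j]) {
        long mol_ies_start = ins_pos[j] + cum[j];
        long mol_ies_end = mol_ies_start + ies_len[j];
        if (pos >= mol_ies_start && pos < mol_ies_end) {
          long take = std::min(remaining, mol_ies_end - pos);
          frag.append(seqs[j], (size_t)(pos - mol_ies_start), (size_t) take);
          pos += take;
          remaining -= take;
          hit_ies = true;
          ++j;
          continue;
        }
      }
      // MAC segment from pos up to the start of the next retained IES
      long seg_end_mol = mol_len;
      int jn = j;
      while (jn < n_ies && !keep[jn]) ++jn;
      if (jn < n_ies) seg_end_mol = ins_pos[jn] + cum[jn];
      j = jn;
      long mac_pos = pos - cum[j]; // cum[j] retained bp precede this segment
      long take = std::min(remaining, seg_end_mol - pos);
      if (take <= 0)
        stop("internal error: empty MAC segment during fragment assembly");
      frag.append(mac, (size_t) mac_pos, (size_t) take);
      pos += take;
      remaining -= take;
    }

    fragments[f] = frag;
    retained_any[f] = hit_ies;
  }

  return List::create(_["fragment"] = fragments,
                      _["retained_any"] = retained_any);
}
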