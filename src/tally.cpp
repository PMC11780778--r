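#include <Rcpp.h>
using namespace Rcpp;

// Column layout shared with the R side: A C G T N del skip.

static int base_slot(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'N': case 'n': return 4;
  default: return -1;
  }
}

// Walk one mpileup base column. quals is consulted only when min_bq > 0;
// one quality character corresponds to each counted symbol (calls, '*',
// 'N', '>' and '<'), never to markers or indel runs.
static void tally_one(const std::string& s, char ref, const std::string& qual,
                      int min_bq, int* out, const std::string& where) {
  const int ref_slot = base_slot(ref);
  if (ref_slot < 0)
    stop("invalid reference base '" + std::string(1, ref) + "' at " + where);
  const bool use_qual = min_bq > 0;
  size_t qi = 0;
  size_t i = 0;
  const size_t n = s.size();
  while (i < n) {
    const char c = s[i];
    const int slot = base_slot(c);
    if (c == '.' || c == ',') {
      if (!use_qual || (qi < qual.size() && qual[qi] - 33 >= min_bq))
        out[ref_slot]++;
      qi++; i++;
    } else if (slot >= 0) {
      if (!use_qual || (qi < qual.size() && qual[qi] - 33 >= min_bq))
        out[slot]++;
      qi++; i++;
    } else if (c == '*') {
      out[5]++; qi++; i++;
    } else if (c == '>' || c == '<') {
      out[6]++; qi++; i++;
    } else if (c == '^') {
      i += 2;  // '^' is followed by a mapping-quality character
    } else if (c == '$') {
      i++;
    } else if (c == '+' || c == '-') {
      i++;
      if (i >= n || s[i] < '0' || s[i] > '9')
        stop("malformed indel (no length after '" + std::string(1, c) +
             "') at " + where);
      long k = 0;
      while (i < n && s[i] >= '0' && s[i] <= '9') {
        k = k * 10 + (s[i] - '0');
        i++;
      }
      if (i + static_cast<size_t>(k) > n)
        stop("indel run overruns base column at " + where);
      i += k;  // inserted/deleted bases are not calls at this position
    } else {
      stop("unknown pileup character '" + std::string(1, c) + "' at " + where);
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_tally(CharacterVector bases, CharacterVector ref,
                        CharacterVector quals, int min_bq,
                        CharacterVector where) {
  const R_xlen_t n = bases.size();
  const bool has_qual = quals.size() == n;
  IntegerMatrix out(n, 7);
  for (R_xlen_t i = 0; i < n; i++) {
    const std::string b = as<std::string>(bases[i]);
    const std::string r = as<std::string>(ref[i]);
    const std::string q = has_qual ? as<std::string>(quals[i]) : std::string();
    const std::string w = as<std::string>(where[i]);
    int row[7] = {0, 0, 0, 0, 0, 0, 0};
    tally_one(b, r.empty() ? 'N' : r[0], q, min_bq, row, w);
    for (int j = 0; j < 7; j++) out(i, j) = row[j];
  }
  colnames(out) = CharacterVector::create("A", "C", "G", "T", "N", "del", "skip");
  return out;
}
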