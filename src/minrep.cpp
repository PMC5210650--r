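#include <Rcpp.h>
using namespace Rcpp;

// Minimal representation of (pos, ref, alt): trim the shared suffix, then
// the shared prefix, in both cases only while both alleles stay longer than
// one base. Hot path: runs once per alternate allele at ingest.
// [[Rcpp::export(name = ".minrep_cpp")]]
List minrep_cpp(int pos, std::string ref, std::string alt) {
  size_t nr = ref.size(), na = alt.size();
  while (nr > 1 && na > 1 && ref[nr - 1] == alt[na - 1]) { --nr; --na; }
  size_t i = 0;
  while (nr - i > 1 && na - i > 1 && ref[i] == alt[i]) { ++i; ++pos; }
  return List::create(_["pos"] = pos,
                      _["ref"] = ref.substr(i, nr - i),
                      _["alt"] = alt.substr(i, na - i));
}
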