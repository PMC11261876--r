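#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
using namespace Rcpp;

// 64-bit FNV-1a over a raw vector; returned as hex string (R has no uint64).
// [[Rcpp::export]]
std::string fnv1a64(RawVector bytes) {
  uint64_t h = 1469598103934665603ULL;
  const uint64_t prime = 1099511628211ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= prime;
  }
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
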