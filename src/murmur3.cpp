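// MurmurHash3 x86 32-bit (Austin Appleby's public-domain algorithm),
// used for feature hashing of token strings.
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline uint32_t rotl32(uint32_t x, int8_t r) {
  return (x << r) | (x >> (32 - r));
}

static uint32_t murmur3_32(const uint8_t *data, size_t len, uint32_t seed) {
  const size_t nblocks = len / 4;
  uint32_t h1 = seed;
  const uint32_t c1 = 0xcc9e2d51u;
  const uint32_t c2 = 0x1b873593u;

  for (size_t i = 0; i < nblocks; i++) {
    uint32_t k1;
    std::memcpy(&k1, data + i * 4, 4);  // little-endian block read
    k1 *= c1; k1 = rotl32(k1, 15); k1 *= c2;
    h1 ^= k1; h1 = rotl32(h1, 13); h1 = h1 * 5 + 0xe6546b64u;
  }

  const uint8_t *tail = data + nblocks * 4;
  uint32_t k1 = 0;
  switch (len & 3) {
  case 3: k1 ^= tail[2] << 16; /* fallthrough */
  case 2: k1 ^= tail[1] << 8;  /* fallthrough */
  case 1: k1 ^= tail[0];
    k1 *= c1; k1 = rotl32(k1, 15); k1 *= c2; h1 ^= k1;
  }

  h1 ^= (uint32_t)len;
  h1 ^= h1 >> 16; h1 *= 0x85ebca6bu;
  h1 ^= h1 >> 13; h1 *= 0xc2b2ae35u;
  h1 ^= h1 >> 16;
  return h1;
}

//' MurmurHash3 (x86, 32-bit) of UTF-8 strings
//'
//' Returns the unsigned 32-bit hash as a double (R has no native uint32).
//'
//' @param x Character vector.
//' @param seed Integer seed.
//' @return Numeric vector of hashes in \[0, 2^32).
//' @export
// [[Rcpp::export]]
NumericVector murmur3_hash(CharacterVector x, int seed = 0) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_REAL; continue; }
    const char *s = x[i];
    out[i] = (double)murmur3_32((const uint8_t *)s, std::strlen(s),
                                (uint32_t)seed);
  }
  return out;
}
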