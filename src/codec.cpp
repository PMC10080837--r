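// Low-level codecs for BLOW5 records.
//
// Signal layer: svb-zd = delta transform -> zig-zag map -> stream variable
// byte. Samples are widened to int32 before the delta so that deltas at the
// int16 extremes (magnitude up to 65535) cannot overflow.
//
// Record layer: zlib (RFC 1950) and zstd (RFC 8878) at the codecs' default
// levels; the level is not persisted, decompression is level-agnostic.
// zlib additionally supports incremental inflation so that only the leading
// read_id of a record need ever be decompressed (index construction).

#include <Rcpp.h>
#include <zlib.h>
#include <zstd.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const char *ERR_CORRUPT_SIGNAL = "corrupt-signal: ";
static const char *ERR_CORRUPT_BLOCK = "corrupt-block: ";

// ---- zig-zag -------------------------------------------------------------

static inline uint32_t zigzag32(int32_t d) {
  return ((uint32_t)d << 1) ^ (uint32_t)(d >> 31); // arithmetic shift
}

static inline int32_t unzigzag32(uint32_t z) {
  return (int32_t)((z >> 1) ^ (~(z & 1) + 1));
}

// [[Rcpp::export(name = ".zigzag32")]]
NumericVector zigzag32_r(NumericVector d) {
  R_xlen_t n = d.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = (double)zigzag32((int32_t)d[i]);
  return out;
}

// [[Rcpp::export(name = ".unzigzag32")]]
NumericVector unzigzag32_r(NumericVector z) {
  R_xlen_t n = z.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = (double)unzigzag32((uint32_t)z[i]);
  return out;
}

// ---- svb-zd --------------------------------------------------------------

// [[Rcpp::export(name = ".svbzd_encode")]]
RawVector svbzd_encode(IntegerVector sig) {
  R_xlen_t n = sig.size();
  if (n == 0) return RawVector(0);
  size_t ncontrol = (size_t)((n + 3) / 4);
  std::vector<unsigned char> ctrl(ncontrol, 0);
  std::vector<unsigned char> data;
  data.reserve((size_t)n);
  int32_t prev = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    int32_t s = sig[i];
    int32_t d = (i == 0) ? s : (s - prev);
    prev = s;
    uint32_t z = zigzag32(d);
    int len = (z < (1u << 8)) ? 1 : (z < (1u << 16)) ? 2 : (z < (1u << 24)) ? 3 : 4;
    ctrl[(size_t)(i >> 2)] |= (unsigned char)((len - 1) << (2 * (i & 3)));
    for (int b = 0; b < len; b++)
      data.push_back((unsigned char)((z >> (8 * b)) & 0xFFu));
  }
  RawVector out(ncontrol + data.size());
  std::copy(ctrl.begin(), ctrl.end(), out.begin());
  std::copy(data.begin(), data.end(), out.begin() + ncontrol);
  return out;
}

// [[Rcpp::export(name = ".svbzd_decode")]]
IntegerVector svbzd_decode(RawVector enc, int n) {
  if (n < 0) stop("%snegative sample count", ERR_CORRUPT_SIGNAL);
  IntegerVector out(n);
  if (n == 0) {
    if (enc.size() != 0)
      stop("%strailing bytes after empty signal", ERR_CORRUPT_SIGNAL);
    return out;
  }
  size_t ncontrol = (size_t)((n + 3) / 4);
  if ((size_t)enc.size() < ncontrol)
    stop("%struncated control block", ERR_CORRUPT_SIGNAL);
  size_t pos = ncontrol;
  int32_t prev = 0;
  for (int i = 0; i < n; i++) {
    int len = 1 + ((enc[(size_t)(i >> 2)] >> (2 * (i & 3))) & 0x3);
    if (pos + (size_t)len > (size_t)enc.size())
      stop("%struncated data block at value %d", ERR_CORRUPT_SIGNAL, i + 1);
    uint32_t z = 0;
    for (int b = 0; b < len; b++)
      z |= ((uint32_t)(unsigned char)enc[pos + (size_t)b]) << (8 * b);
    pos += (size_t)len;
    int32_t d = unzigzag32(z);
    int32_t s = (i == 0) ? d : (prev + d);
    if (s < -32768 || s > 32767)
      stop("%sdecoded sample %d outside int16 range", ERR_CORRUPT_SIGNAL, i + 1);
    prev = s;
    out[i] = s;
  }
  if (pos != (size_t)enc.size())
    stop("%strailing bytes after signal", ERR_CORRUPT_SIGNAL);
  return out;
}

// ---- zlib ----------------------------------------------------------------

// [[Rcpp::export(name = ".zlib_compress")]]
RawVector zlib_compress(RawVector data) {
  uLong srcLen = (uLong)data.size();
  uLong bound = compressBound(srcLen);
  std::vector<unsigned char> buf(bound ? bound : 16);
  uLongf dstLen = (uLongf)buf.size();
  int rc = compress2(buf.data(), &dstLen,
                     (const Bytef *)(data.size() ? &data[0] : (Rbyte *)buf.data()),
                     srcLen, Z_DEFAULT_COMPRESSION);
  if (rc != Z_OK) stop("zlib compression failed (code %d)", rc);
  RawVector out((R_xlen_t)dstLen);
  std::copy(buf.begin(), buf.begin() + dstLen, out.begin());
  return out;
}

// [[Rcpp::export(name = ".zlib_decompress")]]
RawVector zlib_decompress(RawVector data) {
  z_stream strm;
  std::memset(&strm, 0, sizeof(strm));
  if (inflateInit(&strm) != Z_OK) stop("zlib init failed");
  strm.next_in = (Bytef *)(data.size() ? &data[0] : (Bytef *)&strm);
  strm.avail_in = (uInt)data.size();
  std::vector<unsigned char> out;
  std::vector<unsigned char> chunk(65536);
  int rc = Z_OK;
  while (rc != Z_STREAM_END) {
    strm.next_out = chunk.data();
    strm.avail_out = (uInt)chunk.size();
    rc = inflate(&strm, Z_NO_FLUSH);
    if (rc != Z_OK && rc != Z_STREAM_END) {
      inflateEnd(&strm);
      stop("%sinvalid zlib stream (code %d)", ERR_CORRUPT_BLOCK, rc);
    }
    out.insert(out.end(), chunk.data(), chunk.data() + (chunk.size() - strm.avail_out));
    if (rc == Z_OK && strm.avail_out != 0 && strm.avail_in == 0) {
      inflateEnd(&strm);
      stop("%struncated zlib stream", ERR_CORRUPT_BLOCK);
    }
  }
  inflateEnd(&strm);
  RawVector res((R_xlen_t)out.size());
  std::copy(out.begin(), out.end(), res.begin());
  return res;
}

// Incrementally inflate just enough of a compressed record payload to expose
// its leading fields: a uint16 read_id length followed by the read_id bytes
// and, optionally, `extra` further bytes. Returns the decompressed prefix and
// the total number of bytes actually produced by the inflater (for
// instrumentation: with a large record only one output buffer is filled).
// [[Rcpp::export(name = ".zlib_inflate_prefix")]]
List zlib_inflate_prefix(RawVector data, int extra) {
  const size_t CHUNK = 4096;
  z_stream strm;
  std::memset(&strm, 0, sizeof(strm));
  if (inflateInit(&strm) != Z_OK) stop("zlib init failed");
  strm.next_in = (Bytef *)(data.size() ? &data[0] : (Bytef *)&strm);
  strm.avail_in = (uInt)data.size();
  std::vector<unsigned char> out;
  std::vector<unsigned char> chunk(CHUNK);
  size_t need = 2; // until the id length is known
  bool have_len = false;
  int rc = Z_OK;
  while (out.size() < need) {
    strm.next_out = chunk.data();
    strm.avail_out = (uInt)chunk.size();
    rc = inflate(&strm, Z_NO_FLUSH);
    if (rc != Z_OK && rc != Z_STREAM_END) {
      inflateEnd(&strm);
      stop("%sinvalid zlib stream (code %d)", ERR_CORRUPT_BLOCK, rc);
    }
    size_t got = chunk.size() - strm.avail_out;
    out.insert(out.end(), chunk.data(), chunk.data() + got);
    if (!have_len && out.size() >= 2) {
      size_t idlen = (size_t)out[0] | ((size_t)out[1] << 8);
      need = 2 + idlen + (size_t)(extra > 0 ? extra : 0);
      have_len = true;
    }
    if (out.size() >= need) break;
    if (rc == Z_STREAM_END || (strm.avail_in == 0 && got == 0)) {
      inflateEnd(&strm);
      stop("%sstream ended before read_id was complete", ERR_CORRUPT_BLOCK);
    }
  }
  size_t produced = out.size();
  inflateEnd(&strm);
  RawVector prefix((R_xlen_t)need);
  std::copy(out.begin(), out.begin() + need, prefix.begin());
  return List::create(_["prefix"] = prefix,
                      _["bytes_produced"] = (double)produced);
}

// ---- zstd ----------------------------------------------------------------

// [[Rcpp::export(name = ".zstd_compress")]]
RawVector zstd_compress(RawVector data) {
  size_t bound = ZSTD_compressBound((size_t)data.size());
  std::vector<unsigned char> buf(bound ? bound : 16);
  size_t n = ZSTD_compress(buf.data(), buf.size(),
                           data.size() ? (const void *)&data[0] : (const void *)buf.data(),
                           (size_t)data.size(), ZSTD_CLEVEL_DEFAULT);
  if (ZSTD_isError(n)) stop("zstd compression failed: %s", ZSTD_getErrorName(n));
  RawVector out((R_xlen_t)n);
  std::copy(buf.begin(), buf.begin() + n, out.begin());
  return out;
}

// [[Rcpp::export(name = ".zstd_decompress")]]
RawVector zstd_decompress(RawVector data) {
  unsigned long long sz = ZSTD_getFrameContentSize(
      data.size() ? (const void *)&data[0] : (const void *)&data, (size_t)data.size());
  if (sz == ZSTD_CONTENTSIZE_ERROR)
    stop("%snot a zstd frame", ERR_CORRUPT_BLOCK);
  if (sz == ZSTD_CONTENTSIZE_UNKNOWN)
    stop("%szstd frame without content size", ERR_CORRUPT_BLOCK);
  RawVector out((R_xlen_t)sz);
  size_t n = ZSTD_decompress(sz ? (void *)&out[0] : (void *)&sz, (size_t)sz,
                             data.size() ? (const void *)&data[0] : (const void *)&sz,
                             (size_t)data.size());
  if (ZSTD_isError(n))
    stop("%szstd decompression failed: %s", ERR_CORRUPT_BLOCK, ZSTD_getErrorName(n));
  if (n != (size_t)sz)
    stop("%szstd frame shorter than declared", ERR_CORRUPT_BLOCK);
  return out;
}
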