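# Record payload codec.
#
# Payload layout (all little-endian), fixed so the read_id comes first and
# can be recovered from a partially decompressed stream:
#
#   uint16  read_id byte length
#   bytes   read_id
#   uint32  read_group
#   f64     digitisation, offset, range, sampling_rate
#   uint64  len_raw_signal
#   signal  svb-zd: uint64 encoded byte length + encoded bytes
#           none:   raw little-endian int16 samples
#   aux     values in schema order; strings/arrays carry a uint64 length
#           prefix (elements for arrays); missing values use the reserved
#           sentinel of their type (see format.md).
#
# Missing-value sentinels: signed integers = type minimum, unsigned integers
# = type maximum, float/double = NaN, char = 0x00, string/int16_array =
# all-ones uint64 length prefix. These sentinel values are therefore not
# representable as data.

U64_MISSING <- rep(as.raw(0xFF), 8L)

#' Encode a raw signal with a signal-layer method
#'
#' With `"svb-zd"` the samples are widened to 32 bits, delta-transformed
#' (first delta is the first sample itself), zig-zag mapped to unsigned, and
#' packed with stream variable byte: one 2-bit length code per value (four
#' per control byte, low bits first) followed by the 1--4 data bytes of each
#' value, little-endian. With `"none"` samples are stored as little-endian
#' 16-bit integers.
#'
#' @param signal integer vector of int16 samples.
#' @param method `"svb-zd"` or `"none"`.
#' @return raw vector of encoded bytes.
#' @export
signal_encode <- function(signal, method = "svb-zd") {
  switch(method,
    "none" = wb_i16(signal),
    "svb-zd" = .svbzd_encode(as.integer(signal)),
    slow5_error("slow5_unsupported", "unsupported signal encoding: %s", method)
  )
}

#' Decode an encoded raw signal
#'
#' Exact inverse of [signal_encode()]. The sample count must be supplied (it
#' is stored in the record as `len_raw_signal`).
#'
#' @param encoded raw vector produced by [signal_encode()].
#' @param n number of samples to recover.
#' @param method `"svb-zd"` or `"none"`.
#' @return integer vector of int16 samples.
#' @export
signal_decode <- function(encoded, n, method = "svb-zd") {
  switch(method,
    "none" = {
      if (length(encoded) != 2L * n) {
        slow5_error("slow5_corrupt", "corrupt signal: %d bytes for %d raw samples",
                    length(encoded), n)
      }
      if (n == 0) integer() else
        readBin(encoded, "integer", n = n, size = 2L, signed = TRUE, endian = "little")
    },
    "svb-zd" = tryCatch(.svbzd_decode(encoded, as.integer(n)),
                        error = function(e) slow5_error("slow5_corrupt", "%s", conditionMessage(e))),
    slow5_error("slow5_unsupported", "unsupported signal encoding: %s", method)
  )
}

#' Zig-zag map signed integers to unsigned (and back)
#'
#' `zigzag_encode` maps a signed 32-bit integer d to `(d << 1) XOR (d >> 31)`
#' (arithmetic shift) so that small magnitudes of either sign get small
#' codes; `zigzag_decode` is its inverse.
#'
#' @param x numeric vector of signed (encode) or unsigned (decode) values.
#' @return numeric vector.
#' @export
zigzag_encode <- function(x) .zigzag32(as.numeric(x))

#' @rdname zigzag_encode
#' @export
zigzag_decode <- function(x) .unzigzag32(as.numeric(x))

aux_pack_one <- function(value, type) {
  # NULL or a scalar NA marks a missing value (NaN counts as missing for
  # float/double: NaN is the reserved sentinel of those types).
  missing <- is.null(value) || (length(value) == 1 && is.na(value))
  switch(type,
    int8   = wb_u8(if (missing) 0x80 else { v <- as.integer(value); if (v < 0) v + 256L else v }),
    int16  = if (missing) wb_i16(-32768L) else wb_i16(as.integer(value)),
    int32  = if (missing) as.raw(c(0, 0, 0, 0x80)) else
               writeBin(as.integer(value), raw(), size = 4L, endian = "little"),
    int64  = if (missing) c(raw(7L), as.raw(0x80)) else wb_i64(as.numeric(value)),
    uint8  = wb_u8(if (missing) 255L else as.integer(value)),
    uint16 = wb_u16(if (missing) 65535L else as.integer(value)),
    uint32 = wb_u32(if (missing) 2^32 - 1 else as.numeric(value)),
    uint64 = if (missing) U64_MISSING else wb_u64(as.numeric(value)),
    float  = wb_f32(if (missing) NaN else as.numeric(value)),
    double = wb_f64(if (missing) NaN else as.numeric(value)),
    char   = if (missing) raw(1L) else charToRaw(substr(as.character(value), 1L, 1L)),
    string = if (missing) U64_MISSING else {
      b <- charToRaw(as.character(value)); c(wb_u64(length(b)), b)
    },
    int16_array = if (missing) U64_MISSING else {
      v <- as.integer(value); c(wb_u64(length(v)), wb_i16(v))
    },
    slow5_error("slow5_parse_error", "unknown auxiliary type tag: %s", type)
  )
}

aux_unpack_one <- function(cur, type) {
  switch(type,
    int8   = { v <- rd_i8(cur);  if (v == -128L) NA_integer_ else v },
    int16  = { v <- rd_i16(cur); if (v == -32768L) NA_integer_ else v },
    int32  = { b <- cur_take(cur, 4L)
               if (identical(b, as.raw(c(0, 0, 0, 0x80)))) NA_integer_ else
                 readBin(b, "integer", size = 4L, endian = "little") },
    int64  = { v <- rd_i64(cur); if (v == -2^63) NA_real_ else v },
    uint8  = { v <- rd_u8(cur);  if (v == 255L) NA_integer_ else v },
    uint16 = { v <- rd_u16(cur); if (v == 65535L) NA_integer_ else v },
    uint32 = { v <- rd_u32(cur); if (v == 2^32 - 1) NA_real_ else v },
    uint64 = { b <- cur_take(cur, 8L)
               if (identical(b, U64_MISSING)) NA_real_ else
                 sum(as.numeric(as.integer(b)) * 256^(0:7)) },
    float  = { v <- rd_f32(cur); if (is.nan(v)) NA_real_ else v },
    double = { v <- rd_f64(cur); if (is.nan(v)) NA_real_ else v },
    char   = { b <- cur_take(cur, 1L); if (b == as.raw(0)) NA_character_ else rawToChar(b) },
    string = { lb <- cur_take(cur, 8L)
               if (identical(lb, U64_MISSING)) NA_character_ else {
                 n <- sum(as.numeric(as.integer(lb)) * 256^(0:7))
                 rawToChar(cur_take(cur, n))
               } },
    int16_array = { lb <- cur_take(cur, 8L)
               if (identical(lb, U64_MISSING)) NA_integer_ else {
                 n <- sum(as.numeric(as.integer(lb)) * 256^(0:7))
                 rd_i16vec(cur, n)
               } },
    slow5_error("slow5_parse_error", "unknown auxiliary type tag: %s", type)
  )
}

#' Serialise a record to its uncompressed payload bytes
#'
#' @param record a validated [signal_record()].
#' @param header the owning [slow5_header()] (supplies the aux schema).
#' @param signal_method signal-layer method (defaults to the header's
#'   compression spec).
#' @return raw vector payload.
#' @export
pack_record <- function(record, header, signal_method = header$compression$signal) {
  idb <- charToRaw(record$read_id)
  if (length(idb) > 65535L) {
    slow5_error("slow5_field_overflow", "read_id longer than 65535 bytes")
  }
  parts <- vector("list", 10L + nrow(header$aux_schema))
  parts[[1L]] <- wb_u16(length(idb))
  parts[[2L]] <- idb
  parts[[3L]] <- wb_u32(record$read_group)
  parts[[4L]] <- wb_f64(record$digitisation)
  parts[[5L]] <- wb_f64(record$offset)
  parts[[6L]] <- wb_f64(record$range)
  parts[[7L]] <- wb_f64(record$sampling_rate)
  parts[[8L]] <- wb_u64(record$len_raw_signal)
  if (identical(signal_method, "svb-zd")) {
    enc <- signal_encode(record$raw_signal, "svb-zd")
    parts[[9L]] <- wb_u64(length(enc))
    parts[[10L]] <- enc
  } else {
    parts[[9L]] <- raw(0L)
    parts[[10L]] <- signal_encode(record$raw_signal, "none")
  }
  schema <- header$aux_schema
  for (k in seq_len(nrow(schema))) {
    parts[[10L + k]] <- aux_pack_one(record$aux[[schema$name[k]]], schema$type[k])
  }
  unlist(parts, use.names = FALSE)
}

#' Parse a payload back into a record
#'
#' Exact inverse of [pack_record()]; any unconsumed trailing bytes are a
#' corrupt-record error.
#'
#' @param payload raw vector produced by [pack_record()].
#' @inheritParams pack_record
#' @return a [signal_record()].
#' @export
unpack_record <- function(payload, header, signal_method = header$compression$signal) {
  cur <- raw_cursor(payload)
  idlen <- rd_u16(cur)
  read_id <- rawToChar(cur_take(cur, idlen))
  read_group <- rd_u32(cur)
  digitisation <- rd_f64(cur)
  offset <- rd_f64(cur)
  range <- rd_f64(cur)
  sampling_rate <- rd_f64(cur)
  n <- rd_u64(cur)
  if (identical(signal_method, "svb-zd")) {
    nb <- rd_u64(cur)
    sig <- signal_decode(cur_take(cur, nb), n, "svb-zd")
  } else {
    sig <- rd_i16vec(cur, n)
  }
  schema <- header$aux_schema
  aux <- stats::setNames(vector("list", nrow(schema)), schema$name)
  for (k in seq_len(nrow(schema))) {
    aux[[k]] <- aux_unpack_one(cur, schema$type[k])
  }
  if (cur_remaining(cur) != 0L) {
    slow5_error("slow5_corrupt", "corrupt record: %d trailing bytes", cur_remaining(cur))
  }
  signal_record(read_id, sig, read_group = read_group,
                digitisation = digitisation, offset = offset, range = range,
                sampling_rate = sampling_rate, aux = aux)
}

#' Record-layer block compression
#'
#' `"none"` is the identity; `"zlib"` emits an RFC 1950 zlib stream; `"zstd"`
#' emits an RFC 8878 Zstandard frame. Both use their codec's default level;
#' the level is not recorded because decompression does not need it.
#'
#' @param data raw vector.
#' @param method `"none"`, `"zlib"` or `"zstd"`.
#' @return raw vector.
#' @export
compress_block <- function(data, method = "zlib") {
  switch(method,
    none = data,
    zlib = .zlib_compress(data),
    zstd = .zstd_compress(data),
    slow5_error("slow5_unsupported", "unsupported record compression: %s", method)
  )
}

#' @rdname compress_block
#' @export
decompress_block <- function(data, method = "zlib") {
  switch(method,
    none = data,
    zlib = tryCatch(.zlib_decompress(data),
                    error = function(e) slow5_error("slow5_corrupt", "%s", conditionMessage(e))),
    zstd = tryCatch(.zstd_decompress(data),
                    error = function(e) slow5_error("slow5_corrupt", "%s", conditionMessage(e))),
    slow5_error("slow5_unsupported", "unsupported record compression: %s", method)
  )
}

#' Extract the read_id from a compressed record payload
#'
#' For zlib (and trivially for uncompressed payloads) the stream is inflated
#' incrementally and only as many bytes as the read_id needs are produced --
#' the partial-decompression strategy that makes index construction cheap.
#' zstd does not support partial decompression, so the payload is fully
#' decompressed first.
#'
#' @param compressed raw vector: the record's compressed payload.
#' @param method record-layer method the payload was compressed with.
#' @param extra also expose this many payload bytes after the read_id
#'   (internal use: the read_group field follows immediately).
#' @return the read_id string. For zlib input, attribute `bytes_produced`
#'   reports how many decompressed bytes the inflater actually generated.
#' @export
peek_read_id <- function(compressed, method = "zlib", extra = 0L) {
  prefix_info <- switch(method,
    none = {
      cur <- raw_cursor(compressed)
      idlen <- rd_u16(cur)
      list(prefix = compressed[seq_len(min(length(compressed), 2L + idlen + extra))],
           bytes_produced = 2 + idlen + extra)
    },
    zlib = tryCatch(.zlib_inflate_prefix(compressed, as.integer(extra)),
                    error = function(e) slow5_error("slow5_corrupt", "%s", conditionMessage(e))),
    zstd = {
      full <- decompress_block(compressed, "zstd")
      list(prefix = full, bytes_produced = length(full))
    },
    slow5_error("slow5_unsupported", "unsupported record compression: %s", method)
  )
  cur <- raw_cursor(prefix_info$prefix)
  idlen <- rd_u16(cur)
  id <- rawToChar(cur_take(cur, idlen))
  out <- id
  if (extra > 0L) attr(out, "extra") <- cur_take(cur, min(extra, cur_remaining(cur)))
  attr(out, "bytes_produced") <- prefix_info$bytes_produced
  out
}
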