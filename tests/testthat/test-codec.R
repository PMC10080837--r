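test_that("svb-zd encodes the documented byte stream", {
  # [5,5,5]: deltas [5,0,0] -> zig-zag [10,0,0] -> one control byte of zeros,
  # then the three 1-byte values
  expect_identical(signal_encode(c(5L, 5L, 5L), "svb-zd"),
                   as.raw(c(0x00, 0x0A, 0x00, 0x00)))
  # [-1]: delta -1 -> zig-zag 1
  expect_identical(signal_encode(-1L, "svb-zd"), as.raw(c(0x00, 0x01)))
  expect_identical(signal_encode(integer(), "svb-zd"), raw(0))
})

test_that("svb-zd decode is an exact inverse, including at int16 extremes", {
  x <- c(-32768L, 32767L, 0L)
  expect_identical(signal_decode(signal_encode(x, "svb-zd"), 3, "svb-zd"), x)
  expect_identical(signal_decode(raw(0), 0, "svb-zd"), integer())
  set.seed(7)
  for (i in 1:200) {
    n <- sample(0:300, 1)
    x <- as.integer(sample(-32768:32767, n, replace = TRUE))
    expect_identical(signal_decode(signal_encode(x, "svb-zd"), n, "svb-zd"), x)
  }
})

test_that("svb-zd rejects truncated or oversized input", {
  expect_error(signal_decode(as.raw(0x00), 4, "svb-zd"), class = "slow5_corrupt")
  enc <- signal_encode(c(1L, 2L, 3L), "svb-zd")
  expect_error(signal_decode(c(enc, as.raw(0)), 3, "svb-zd"), class = "slow5_corrupt")
  expect_error(signal_encode(1L, "lz4"), class = "slow5_unsupported")
})

test_that("svb-zd size is exactly ceil(n/4)+n bytes when every delta fits one byte", {
  for (n in c(1L, 4L, 5L, 100L, 1001L)) {
    x <- as.integer(cumsum(sample(-50:50, n, replace = TRUE)))
    expect_identical(length(signal_encode(x, "svb-zd")), as.integer(ceiling(n / 4) + n))
  }
})

test_that("zig-zag is a bijection with small codes for small magnitudes", {
  d <- -1000:1000
  z <- zigzag_encode(d)
  expect_false(any(duplicated(z)))
  expect_identical(zigzag_decode(z), as.numeric(d))
  expect_identical(zigzag_encode(c(0, -1, 1, -2, 2)), c(0, 1, 2, 3, 4))
})

test_that("record payload layout starts with the length-prefixed read_id", {
  hdr <- slow5_header()
  payload <- pack_record(signal_record("r1", integer()), hdr, "none")
  expect_identical(payload[1:4], c(as.raw(2), as.raw(0), charToRaw("r1")))

  # two records differing only in read_group differ only in the 4 bytes
  # right after the read_id
  a <- signal_record("abc", c(9L, -9L))
  b <- a; b$read_group <- 3L
  hdr2 <- slow5_header(group_attributes = rep(list(c(run = "x")), 4))
  pa <- pack_record(a, hdr2, "none")
  pb <- pack_record(b, hdr2, "none")
  diff <- which(pa != pb)
  expect_true(all(diff %in% (2 + 3 + 1):(2 + 3 + 4)))
})

test_that("pack/unpack round-trips randomized records with a full aux palette", {
  schema <- aux_schema(
    c("i8", "i16", "i32", "i64", "u8", "u16", "u32", "u64", "f", "d", "c", "s", "arr"),
    c("int8", "int16", "int32", "int64", "uint8", "uint16", "uint32", "uint64",
      "float", "double", "char", "string", "int16_array"))
  hdr <- slow5_header(aux = schema)
  set.seed(11)
  for (i in 1:50) {
    aux <- list(
      i8 = sample(-127:127, 1), i16 = sample(-32767:32767, 1),
      i32 = sample(-1e6:1e6, 1), i64 = sample(-1e6:1e6, 1) * 2^20,
      u8 = sample(0:254, 1), u16 = sample(0:65534, 1),
      u32 = floor(runif(1, 0, 2^32 - 2)), u64 = floor(runif(1, 0, 2^50)),
      f = 0.25 * sample(-100:100, 1), d = rnorm(1),
      c = sample(letters, 1), s = paste(sample(letters, 8), collapse = ""),
      arr = as.integer(sample(-32768:32767, sample(0:5, 1) + 1, replace = TRUE)))
    # occasionally blank out each field
    for (k in names(aux)) if (runif(1) < 0.2) aux[[k]] <- NA
    rec <- signal_record(paste0("read-", i),
                         as.integer(sample(-32768:32767, sample(0:40, 1), replace = TRUE)),
                         offset = rnorm(1), aux = aux)
    for (sm in c("none", "svb-zd")) {
      back <- unpack_record(pack_record(rec, hdr, sm), hdr, sm)
      expect_true(slow5r:::records_equal(rec, back),
                  label = sprintf("round trip (iter %d, %s)", i, sm))
    }
  }
})

test_that("unpack rejects truncated payloads and trailing bytes", {
  hdr <- slow5_header()
  payload <- pack_record(signal_record("r1", c(1L, 2L, 3L)), hdr, "svb-zd")
  expect_error(unpack_record(payload[1:(length(payload) - 2)], hdr, "svb-zd"),
               class = "slow5_corrupt")
  expect_error(unpack_record(c(payload, raw(3)), hdr, "svb-zd"),
               class = "slow5_corrupt")
})

test_that("block compression round-trips and rejects garbage", {
  set.seed(3)
  b <- as.raw(sample(0:255, 5000, replace = TRUE))
  expect_identical(compress_block(b, "none"), b)
  for (m in c("zlib", "zstd")) {
    expect_identical(decompress_block(compress_block(b, m), m), b)
    expect_identical(decompress_block(compress_block(raw(0), m), m), raw(0))
  }
  expect_error(decompress_block(b, "zlib"), class = "slow5_corrupt")
  expect_error(decompress_block(b, "zstd"), class = "slow5_corrupt")
  expect_error(compress_block(b, "lzma"), class = "slow5_unsupported")
})

test_that("peek_read_id equals the fully parsed read_id for every method", {
  dat <- small_dataset()
  for (m in c("none", "zlib", "zstd")) {
    for (rec in dat$records[1:10]) {
      payload <- pack_record(rec, dat$header, "svb-zd")
      comp <- compress_block(payload, m)
      expect_identical(as.character(peek_read_id(comp, m)), rec$read_id)
    }
  }
})

test_that("peek_read_id under zlib inflates only a prefix of a large record", {
  hdr <- slow5_header()
  big <- signal_record("big-one", as.integer(cumsum(sample(-3:3, 5e5, replace = TRUE))))
  comp <- compress_block(pack_record(big, hdr, "none"), "zlib")
  got <- peek_read_id(comp, "zlib")
  expect_identical(as.character(got), "big-one")
  # payload is ~1 MB; the inflater must stop within its first output buffer
  expect_lte(attr(got, "bytes_produced"), 4096)
})

test_that("full compression matrix round-trips boundary records", {
  hdr <- slow5_header(aux = synthetic_aux_schema_for_tests())
  recs <- edge_records(hdr)
  for (spec in all_compression_specs()) {
    for (rec in recs) {
      payload <- pack_record(rec, hdr, spec$signal)
      back <- unpack_record(decompress_block(compress_block(payload, spec$record),
                                             spec$record), hdr, spec$signal)
      expect_true(slow5r:::records_equal(rec, back),
                  label = sprintf("%s under [%s,%s]", rec$read_id,
                                  spec$record, spec$signal))
    }
  }
})
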