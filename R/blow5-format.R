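# Binary BLOW5 container.
#
# Layout (normative for this package, documented in inst/format.md):
#
#   bytes 0-7    magic "BLOW5\n" 0x01 0x00
#   byte  8      record-layer method (0 none, 1 zlib, 2 zstd)
#   byte  9      signal-layer method (0 none, 1 svb-zd)
#   bytes 10-13  uint32 header block length
#   ...          header block: SLOW5 ASCII header text, uncompressed
#   ...          record frames: uint32 frame length + compressed payload
#   last 8       EOF marker "EOF5WOLB"
#
# All integers little-endian.

BLOW5_MAGIC <- as.raw(c(0x42, 0x4C, 0x4F, 0x57, 0x35, 0x0A, 0x01, 0x00))
BLOW5_EOF <- charToRaw("EOF5WOLB")

RECORD_METHOD_CODES <- c(none = 0L, zlib = 1L, zstd = 2L)
SIGNAL_METHOD_CODES <- c(none = 0L, "svb-zd" = 1L)

DEFAULT_BATCH_SIZE <- 4096L

#' Write records to a BLOW5 binary file
#'
#' Each record is serialised with [pack_record()] (signal layer per `spec`),
#' block-compressed (record layer per `spec`) and stored as a length-prefixed
#' frame. The default compression is zlib on the record and svb-zd on the
#' signal.
#'
#' @param header a [slow5_header()].
#' @param records list of [signal_record()]s.
#' @param path output file path.
#' @param spec a [compression_spec()].
#' @return invisibly, the number of records written.
#' @export
write_blow5 <- function(header, records, path, spec = compression_spec()) {
  header$compression <- spec
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(BLOW5_MAGIC, con)
  writeBin(as.raw(c(RECORD_METHOD_CODES[spec$record], SIGNAL_METHOD_CODES[spec$signal])), con)
  hdr_text <- charToRaw(paste0(paste(slow5_header_lines(header), collapse = "\n"), "\n"))
  writeBin(wb_u32(length(hdr_text)), con)
  writeBin(hdr_text, con)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    chk <- validate_record(rec, header)
    if (!chk$ok) {
      slow5_error("slow5_validation", "record %d (%s): %s", i, rec$read_id,
                  chk$violations[1])
    }
    payload <- pack_record(rec, header, spec$signal)
    comp <- compress_block(payload, spec$record)
    writeBin(wb_u32(length(comp)), con)
    writeBin(comp, con)
  }
  writeBin(BLOW5_EOF, con)
  invisible(length(records))
}

#' Open a BLOW5 file for streaming access
#'
#' Reads and parses the header; records are decompressed and parsed lazily
#' via [blow5_next_record()] or fetched as raw frames via [next_batch()].
#'
#' @param path path to a `.blow5` file.
#' @return a handle of class `blow5_file` with elements `header` (including
#'   the file's [compression_spec()]) and `path`. Close with [blow5_close()].
#' @export
open_blow5 <- function(path) {
  size <- file.info(path)$size
  if (is.na(size)) slow5_error("slow5_io", "cannot read '%s'", path)
  con <- file(path, "rb")
  ok <- FALSE
  on.exit(if (!ok) close(con))
  magic <- readBin(con, "raw", 8L)
  if (length(magic) < 8L || !identical(magic, BLOW5_MAGIC)) {
    slow5_error("slow5_not_blow5", "'%s' is not a BLOW5 file (bad magic)", path)
  }
  methods <- as.integer(readBin(con, "raw", 2L))
  rec_m <- names(RECORD_METHOD_CODES)[match(methods[1], RECORD_METHOD_CODES)]
  sig_m <- names(SIGNAL_METHOD_CODES)[match(methods[2], SIGNAL_METHOD_CODES)]
  if (is.na(rec_m) || is.na(sig_m)) {
    slow5_error("slow5_not_blow5", "'%s': unknown compression method byte", path)
  }
  cur <- raw_cursor(readBin(con, "raw", 4L))
  hdr_len <- rd_u32(cur)
  hdr_bytes <- readBin(con, "raw", hdr_len)
  if (length(hdr_bytes) < hdr_len) {
    slow5_error("slow5_truncated", "'%s': truncated header block", path)
  }
  hdr_lines <- strsplit(rawToChar(hdr_bytes), "\n", fixed = TRUE)[[1]]
  header <- slow5_parse_header(hdr_lines, compression_spec(rec_m, sig_m))$header
  data_start <- 8 + 2 + 4 + hdr_len
  eof_ok <- FALSE
  if (size >= data_start + 8) {
    seek(con, size - 8)
    eof_ok <- identical(readBin(con, "raw", 8L), BLOW5_EOF)
  }
  seek(con, data_start)
  h <- new.env(parent = emptyenv())
  h$con <- con
  h$path <- path
  h$header <- header
  h$spec <- header$compression
  h$data_start <- data_start
  h$size <- size
  h$frames_end <- if (eof_ok) size - 8 else size
  h$eof_ok <- eof_ok
  h$pos <- data_start
  h$open <- TRUE
  class(h) <- "blow5_file"
  ok <- TRUE
  h
}

#' @export
print.blow5_file <- function(x, ...) {
  cat(sprintf("<blow5_file %s> %s, %d read group(s)\n", x$path,
              paste0("[", x$spec$record, ", ", x$spec$signal, "]"),
              x$header$num_read_groups))
  invisible(x)
}

#' @rdname open_blow5
#' @param h a `blow5_file` handle.
#' @export
blow5_close <- function(h) {
  if (isTRUE(h$open)) {
    close(h$con)
    h$open <- FALSE
  }
  invisible(NULL)
}

# Read the next raw frame (list(offset=, frame=)) or NULL at end of records.
blow5_next_frame <- function(h) {
  if (h$pos >= h$frames_end) {
    if (!h$eof_ok) {
      slow5_error("slow5_truncated", "'%s': missing EOF marker", h$path)
    }
    return(NULL)
  }
  if (h$pos + 4 > h$frames_end) {
    slow5_error("slow5_truncated", "'%s': truncated frame length at offset %.0f",
                h$path, h$pos)
  }
  len_raw <- readBin(h$con, "raw", 4L)
  len <- rd_u32(raw_cursor(len_raw))
  if (h$pos + 4 + len > h$frames_end) {
    slow5_error("slow5_truncated", "'%s': frame at offset %.0f overruns file",
                h$path, h$pos)
  }
  payload <- readBin(h$con, "raw", len)
  offset <- h$pos
  h$pos <- h$pos + 4 + len
  list(offset = offset, frame = c(len_raw, payload))
}

#' Read the next record from an open BLOW5 handle
#'
#' @param h a `blow5_file` handle from [open_blow5()].
#' @return a [signal_record()], or `NULL` when the record stream is
#'   exhausted.
#' @export
blow5_next_record <- function(h) {
  fr <- blow5_next_frame(h)
  if (is.null(fr)) return(NULL)
  payload <- decompress_block(fr$frame[-(1:4)], h$spec$record)
  unpack_record(payload, h$header, h$spec$signal)
}

#' Fetch a batch of raw record frames without decompressing
#'
#' Returns up to `batch_size` frames (each a length-prefixed compressed
#' record) together with their absolute byte offsets; an empty list exactly
#' at the end of the record stream. This is the unit a batch-parallel
#' consumer would farm out to workers; input order is the file order.
#'
#' @param h a `blow5_file` handle.
#' @param batch_size maximum number of frames to return.
#' @return list of `list(offset=, frame=)`.
#' @export
next_batch <- function(h, batch_size = DEFAULT_BATCH_SIZE) {
  stopifnot(batch_size >= 1)
  out <- vector("list", batch_size)
  n <- 0L
  while (n < batch_size) {
    fr <- blow5_next_frame(h)
    if (is.null(fr)) break
    n <- n + 1L
    out[[n]] <- fr
  }
  out[seq_len(n)]
}

#' Read a whole BLOW5 file into memory
#'
#' @param path path to a `.blow5` file.
#' @return list with elements `header` and `records`.
#' @export
read_blow5 <- function(path) {
  h <- open_blow5(path)
  on.exit(blow5_close(h))
  records <- list()
  i <- 0L
  repeat {
    rec <- blow5_next_record(h)
    if (is.null(rec)) break
    i <- i + 1L
    records[[i]] <- rec
  }
  list(header = h$header, records = records)
}

# Read any supported signal file (by extension) into memory.
read_signal_file <- function(path) {
  if (grepl("\\.blow5$", path)) read_blow5(path) else read_slow5(path)
}

# Write to either form based on the target/extension.
write_signal_file <- function(header, records, path, target = NULL,
                              spec = compression_spec()) {
  if (is.null(target)) {
    target <- if (grepl("\\.blow5$", path)) "blow5" else "slow5"
  }
  if (identical(target, "blow5")) {
    write_blow5(header, records, path, spec)
  } else {
    header$compression <- compression_spec("none", "none")
    write_slow5(header, records, path)
  }
}
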