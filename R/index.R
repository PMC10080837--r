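# Random-access index: read_id -> (byte offset, frame length) sidecar file.
#
# Index layout (little-endian):
#   bytes 0-7   magic "SLOW5IDX"
#   uint64      byte size of the indexed data file (staleness check)
#   uint64      entry count
#   entries     uint16 id length, id bytes, uint64 offset, uint64 length
#
# For BLOW5, offset addresses a frame's first length byte and length covers
# the length prefix plus the compressed payload, so a fetch is exactly one
# seek and one bounded read. For ASCII SLOW5, offsets address data-line
# starts and lengths include the trailing newline.

INDEX_MAGIC <- charToRaw("SLOW5IDX")

index_path_for <- function(path) paste0(path, ".idx")

#' Build the random-access index of a SLOW5/BLOW5 file
#'
#' Scans the file once, collecting each record's read_id and the byte extent
#' of its frame. For zlib-compressed (and uncompressed) BLOW5 records the
#' read_id is recovered by partial decompression ([peek_read_id()]); zstd
#' records must be fully decompressed first. Either route yields the same
#' index bytes -- partial decompression changes speed, not results.
#'
#' @param path data file (`.blow5` or `.slow5`).
#' @param force_full_decompression bypass partial decompression (testing /
#'   benchmarking hook).
#' @return the index file path (`path` + `.idx`), invisibly the entry count
#'   as attribute `n`.
#' @export
build_index <- function(path, force_full_decompression = FALSE) {
  qc <- quickcheck(path)
  if (!qc$ok) {
    slow5_error("slow5_corrupt", "cannot index '%s': %s", path, qc$defect)
  }
  if (grepl("\\.blow5$", path)) {
    h <- open_blow5(path)
    on.exit(blow5_close(h))
    ids <- character(); offs <- numeric(); lens <- numeric()
    repeat {
      batch <- next_batch(h, DEFAULT_BATCH_SIZE)
      if (!length(batch)) break
      for (fr in batch) {
        comp <- fr$frame[-(1:4)]
        id <- if (force_full_decompression || h$spec$record == "zstd") {
          unpack_record(decompress_block(comp, h$spec$record), h$header,
                        h$spec$signal)$read_id
        } else {
          as.character(peek_read_id(comp, h$spec$record))
        }
        ids <- c(ids, id); offs <- c(offs, fr$offset); lens <- c(lens, length(fr$frame))
      }
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    parsed <- slow5_parse_header(lines)
    nh <- parsed$n_lines
    sizes <- nchar(lines, type = "bytes") + 1L
    offs <- cumsum(c(0, sizes))[seq_along(lines)]
    body <- seq_len(length(lines) - nh) + nh
    ids <- vapply(body, function(i) split_tsv(lines[i])[1], character(1))
    lens <- sizes[body]
    offs <- offs[body]
  }
  dup <- duplicated(ids)
  if (any(dup)) {
    slow5_error("slow5_duplicate_id", "duplicate read_id '%s' in '%s'",
                ids[which(dup)[1]], path)
  }
  idx_path <- index_path_for(path)
  con <- file(idx_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(INDEX_MAGIC, con)
  writeBin(wb_u64(file.info(path)$size), con)
  writeBin(wb_u64(length(ids)), con)
  for (k in seq_along(ids)) {
    b <- charToRaw(ids[k])
    writeBin(c(wb_u16(length(b)), b, wb_u64(offs[k]), wb_u64(lens[k])), con)
  }
  out <- idx_path
  attr(out, "n") <- length(ids)
  invisible(out)
}

#' Load an index into memory
#'
#' @param idx_path index file path (default: data path + `.idx`).
#' @param data_path the indexed data file; its current byte size must match
#'   the size recorded in the index, otherwise the index is stale.
#' @return an object of class `slow5_index` supporting lookup via
#'   [index_lookup()].
#' @export
load_index <- function(data_path, idx_path = index_path_for(data_path)) {
  if (!file.exists(idx_path)) {
    slow5_error("slow5_io", "index file '%s' does not exist", idx_path)
  }
  bytes <- readBin(idx_path, "raw", file.info(idx_path)$size)
  cur <- raw_cursor(bytes)
  if (!identical(cur_take(cur, 8L), INDEX_MAGIC)) {
    slow5_error("slow5_corrupt_index", "'%s' is not an index file (bad magic)", idx_path)
  }
  src_size <- rd_u64(cur)
  now_size <- file.info(data_path)$size
  if (is.na(now_size) || now_size != src_size) {
    slow5_error("slow5_stale_index",
                "index '%s' records %.0f bytes but '%s' has %.0f; rebuild the index",
                idx_path, src_size, data_path, now_size)
  }
  n <- rd_u64(cur)
  ids <- character(n); offs <- numeric(n); lens <- numeric(n)
  for (k in seq_len(n)) {
    idlen <- rd_u16(cur)
    ids[k] <- rawToChar(cur_take(cur, idlen))
    offs[k] <- rd_u64(cur)
    lens[k] <- rd_u64(cur)
  }
  structure(list(ids = ids, offset = offs, length = lens, data_path = data_path),
            class = "slow5_index")
}

#' @export
print.slow5_index <- function(x, ...) {
  cat(sprintf("<slow5_index> %d read(s) of %s\n", length(x$ids), x$data_path))
  invisible(x)
}

#' Look up a read_id in a loaded index
#'
#' @param index a `slow5_index` from [load_index()].
#' @param read_id identifier to look up.
#' @return `list(offset=, length=)`, or `NULL` if absent (absence is not an
#'   error at this level).
#' @export
index_lookup <- function(index, read_id) {
  k <- match(read_id, index$ids)
  if (is.na(k)) return(NULL)
  list(offset = index$offset[k], length = index$length[k])
}

#' Fetch one record by read_id via the index
#'
#' Performs exactly one seek and one bounded read of the record's frame; no
#' linear scan.
#'
#' @param path the indexed data file.
#' @param index a fresh `slow5_index` for that file.
#' @param read_id identifier to fetch.
#' @param header optional pre-parsed header (avoids re-reading it when
#'   fetching many records).
#' @return a [signal_record()].
#' @export
fetch_by_read_id <- function(path, index, read_id, header = NULL) {
  entry <- index_lookup(index, read_id)
  if (is.null(entry)) {
    slow5_error("slow5_not_found", "read_id '%s' not found in '%s'", read_id, path)
  }
  if (grepl("\\.blow5$", path)) {
    if (is.null(header)) {
      h <- open_blow5(path)
      header <- h$header
      blow5_close(h)
    }
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, entry$offset)
    frame <- readBin(con, "raw", entry$length)
    cur <- raw_cursor(frame)
    len <- rd_u32(cur)
    payload <- decompress_block(cur_take(cur, len), header$compression$record)
    unpack_record(payload, header, header$compression$signal)
  } else {
    if (is.null(header)) {
      header <- slow5_parse_header(readLines(path, warn = FALSE))$header
    }
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, entry$offset)
    line <- sub("\n$", "", rawToChar(readBin(con, "raw", entry$length)))
    row_to_record(line, header, NA_integer_)
  }
}
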