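# Human-readable tab-separated SLOW5 form.
#
# Dialect: "@" introduces per-group metadata lines (one value column per
# read group), "#" introduces schema lines; fields are tab-separated, array
# elements comma-separated, and "." is the missing-value token. Header
# metadata attributes are emitted in lexicographic key order so that writing
# the same data twice yields byte-identical files; readers accept any order.
# Line endings are "\n"; "\r\n" is tolerated on read.
#
# ASCII-representability caveats (binary BLOW5 has none of these): an empty
# string, a "." string/char value and a zero-length auxiliary array are all
# written as the missing token.

MISSING_TOKEN <- "."

split_tsv <- function(line, pad_to = 0L) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (pad_to > length(f)) f <- c(f, rep("", pad_to - length(f)))
  f
}

fmt_aux_ascii <- function(value, type) {
  if (is.null(value) || (length(value) == 1 && is.na(value))) return(MISSING_TOKEN)
  out <- switch(type,
    int8 = , int16 = , int32 = , uint8 = , uint16 = sprintf("%d", as.integer(value)),
    uint32 = , int64 = , uint64 = sprintf("%.0f", as.numeric(value)),
    float = , double = fmt_double(as.numeric(value)),
    char = , string = as.character(value),
    int16_array = if (length(value) == 0) MISSING_TOKEN else
      paste(as.character(as.integer(value)), collapse = ","),
    slow5_error("slow5_parse_error", "unknown auxiliary type tag: %s", type)
  )
  if (!nzchar(out)) MISSING_TOKEN else out
}

parse_aux_ascii <- function(token, type, line_no) {
  if (identical(token, MISSING_TOKEN)) {
    return(switch(type,
      int8 = , int16 = , int32 = , uint8 = , uint16 = NA_integer_,
      uint32 = , int64 = , uint64 = , float = , double = NA_real_,
      char = , string = NA_character_,
      int16_array = NA_integer_))
  }
  bad <- function() slow5_error("slow5_parse_error",
    "line %d: cannot parse %s value '%s'", line_no, type, token)
  switch(type,
    int8 = , int16 = , int32 = , uint8 = , uint16 = {
      v <- suppressWarnings(as.integer(token)); if (is.na(v)) bad(); v
    },
    uint32 = , int64 = , uint64 = {
      v <- suppressWarnings(as.numeric(token)); if (is.na(v)) bad(); v
    },
    float = , double = {
      v <- suppressWarnings(as.numeric(token)); if (is.na(v) && token != "NA") bad(); v
    },
    char = , string = token,
    int16_array = {
      v <- suppressWarnings(as.integer(strsplit(token, ",", fixed = TRUE)[[1]]))
      if (anyNA(v)) bad(); v
    }
  )
}

# Header lines shared verbatim by the ASCII file and the BLOW5 header block.
slow5_header_lines <- function(header) {
  lines <- c(paste0("#slow5_version\t", header$version),
             paste0("#num_read_groups\t", header$num_read_groups))
  keys <- sort(unique(unlist(lapply(header$group_attributes, names))))
  for (k in keys) {
    vals <- vapply(header$group_attributes, function(g) {
      v <- unname(g[k]); if (is.na(v)) "" else v
    }, character(1))
    if (any(grepl("[\t\n\r]", vals))) {
      slow5_error("slow5_parse_error", "attribute '%s' contains tab or newline", k)
    }
    lines <- c(lines, paste0("@", k, "\t", paste(vals, collapse = "\t")))
  }
  schema <- header$aux_schema
  types <- c(PRIMARY_TYPES, schema$type)
  names_ <- c(PRIMARY_FIELDS, schema$name)
  c(lines,
    paste0("#", paste(types, collapse = "\t")),
    paste0("#", paste(names_, collapse = "\t")))
}

# Parse the header lines; returns list(header=, n_lines=) where n_lines is
# the number of lines consumed.
slow5_parse_header <- function(lines, compression = compression_spec("none", "none")) {
  lines <- sub("\r$", "", lines)
  if (!length(lines) || !startsWith(lines[1], "#slow5_version\t")) {
    slow5_error("slow5_parse_error", "line 1: missing version line")
  }
  version <- split_tsv(lines[1])[2]
  if (length(lines) < 2 || !startsWith(lines[2], "#num_read_groups\t")) {
    slow5_error("slow5_parse_error", "line 2: missing num_read_groups line")
  }
  n_groups <- suppressWarnings(as.integer(split_tsv(lines[2])[2]))
  if (is.na(n_groups) || n_groups < 1) {
    slow5_error("slow5_parse_error", "line 2: invalid read group count")
  }
  attrs <- list()
  i <- 3L
  while (i <= length(lines) && startsWith(lines[i], "@")) {
    f <- split_tsv(sub("^@", "", lines[i]), pad_to = n_groups + 1L)
    if (length(f) != n_groups + 1L) {
      slow5_error("slow5_parse_error",
                  "line %d: attribute line has %d value(s), expected %d",
                  i, length(f) - 1L, n_groups)
    }
    attrs[[f[1]]] <- f[-1]
    i <- i + 1L
  }
  if (i + 1L > length(lines) || !startsWith(lines[i], "#")) {
    slow5_error("slow5_parse_error", "line %d: missing column type line", i)
  }
  types <- split_tsv(sub("^#", "", lines[i]))
  names_ <- split_tsv(sub("^#", "", lines[i + 1L]))
  if (length(types) < 8L || !identical(types[1:8], PRIMARY_TYPES) ||
      !identical(names_[1:8], PRIMARY_FIELDS)) {
    slow5_error("slow5_parse_error",
                "line %d: first eight columns must be the primary fields", i)
  }
  if (length(types) != length(names_)) {
    slow5_error("slow5_parse_error", "line %d: %d types for %d column names",
                i, length(types), length(names_))
  }
  schema <- aux_schema(names_[-(1:8)], types[-(1:8)])
  group_attributes <- lapply(seq_len(n_groups), function(g) {
    stats::setNames(vapply(attrs, `[`, character(1), g), names(attrs))
  })
  if (!length(attrs)) {
    group_attributes <- replicate(n_groups, structure(character(), names = character()),
                                  simplify = FALSE)
  }
  list(header = slow5_header(group_attributes, schema, version = version,
                             compression = compression),
       n_lines = i + 1L)
}

record_to_row <- function(record, schema) {
  sig <- if (record$len_raw_signal == 0) MISSING_TOKEN else
    paste(as.character(record$raw_signal), collapse = ",")
  aux <- character(nrow(schema))
  for (k in seq_len(nrow(schema))) {
    aux[k] <- fmt_aux_ascii(record$aux[[schema$name[k]]], schema$type[k])
  }
  paste(c(record$read_id, as.character(record$read_group),
          fmt_double(c(record$digitisation, record$offset, record$range,
                       record$sampling_rate)),
          sprintf("%.0f", as.numeric(record$len_raw_signal)), sig, aux),
        collapse = "\t")
}

row_to_record <- function(line, header, line_no) {
  schema <- header$aux_schema
  ncol <- 8L + nrow(schema)
  f <- split_tsv(line)
  if (length(f) != ncol) {
    slow5_error("slow5_parse_error", "line %d: %d column(s), expected %d",
                line_no, length(f), ncol)
  }
  n <- suppressWarnings(as.numeric(f[7]))
  if (is.na(n) || n < 0) {
    slow5_error("slow5_parse_error", "line %d: invalid len_raw_signal '%s'",
                line_no, f[7])
  }
  if (n == 0) {
    sig <- integer()
  } else {
    sig <- suppressWarnings(as.integer(strsplit(f[8], ",", fixed = TRUE)[[1]]))
    if (anyNA(sig)) {
      slow5_error("slow5_parse_error", "line %d: non-integer signal token", line_no)
    }
    if (length(sig) != n) {
      slow5_error("slow5_parse_error",
                  "line %d: len_raw_signal=%d but %d signal sample(s)",
                  line_no, n, length(sig))
    }
  }
  nums <- suppressWarnings(as.numeric(f[3:6]))
  if (anyNA(nums)) {
    slow5_error("slow5_parse_error", "line %d: non-numeric calibration field", line_no)
  }
  aux <- stats::setNames(vector("list", nrow(schema)), schema$name)
  for (k in seq_len(nrow(schema))) {
    aux[[k]] <- parse_aux_ascii(f[8L + k], schema$type[k], line_no)
  }
  signal_record(f[1], sig, read_group = as.integer(f[2]),
                digitisation = nums[1], offset = nums[2], range = nums[3],
                sampling_rate = nums[4], aux = aux)
}

#' Write records to a SLOW5 ASCII file
#'
#' Emits the header (version, read-group count, per-group metadata, column
#' types, column names) followed by one tab-separated row per record, in
#' input order. Output is byte-stable: the same header and records always
#' produce the same file.
#'
#' @param header a [slow5_header()].
#' @param records list of [signal_record()]s.
#' @param path output file path (or a writable text connection).
#' @return invisibly, the number of records written.
#' @export
write_slow5 <- function(header, records, path) {
  con <- if (inherits(path, "connection")) path else {
    f <- file(path, "wb"); on.exit(close(f)); f
  }
  writeLines(slow5_header_lines(header), con, sep = "\n")
  schema <- header$aux_schema
  n <- length(records)
  chunk <- 512L
  for (start in seq_len(if (n) ceiling(n / chunk) else 0L)) {
    idx <- seq.int((start - 1L) * chunk + 1L, min(start * chunk, n))
    rows <- character(length(idx))
    for (j in seq_along(idx)) {
      rec <- records[[idx[j]]]
      chk <- validate_record(rec, header)
      if (!chk$ok) {
        slow5_error("slow5_validation", "record %d (%s): %s", idx[j],
                    rec$read_id, chk$violations[1])
      }
      rows[j] <- record_to_row(rec, schema)
    }
    writeLines(rows, con, sep = "\n")
  }
  invisible(n)
}

#' Read a SLOW5 ASCII file
#'
#' Exact inverse of [write_slow5()] (records field for field; header up to
#' attribute order). Parse failures name the offending line.
#'
#' @param path input file path (or a readable text connection).
#' @return list with elements `header` and `records`.
#' @export
read_slow5 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  parsed <- slow5_parse_header(lines)
  header <- parsed$header
  body <- seq_len(length(lines) - parsed$n_lines) + parsed$n_lines
  records <- vector("list", length(body))
  for (j in seq_along(body)) {
    records[[j]] <- row_to_record(lines[body[j]], header, body[j])
  }
  list(header = header, records = records)
}
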