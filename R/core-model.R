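#' @useDynLib slow5r, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom
#' @importFrom utils head tail
NULL

# Closed auxiliary type system. Unknown tags in a file are a parse error:
# a lossless round trip requires that every value can be re-serialised.
AUX_TYPES <- c("int8", "int16", "int32", "int64",
               "uint8", "uint16", "uint32", "uint64",
               "float", "double", "char", "string", "int16_array")

PRIMARY_FIELDS <- c("read_id", "read_group", "digitisation", "offset",
                    "range", "sampling_rate", "len_raw_signal", "raw_signal")

PRIMARY_TYPES <- c("string", "uint32", "double", "double",
                   "double", "double", "uint64", "int16_array")

#' Describe the auxiliary-field schema of a signal file
#'
#' Each record in a SLOW5/BLOW5 file carries the same ordered set of optional
#' auxiliary attributes (for example channel number or acquisition start
#' time). The schema fixes their names and on-disk types.
#'
#' @param names character vector of field names.
#' @param types character vector of type tags, one of `int8`, `int16`,
#'   `int32`, `int64`, `uint8`, `uint16`, `uint32`, `uint64`, `float`,
#'   `double`, `char`, `string`, `int16_array`.
#' @return a data frame with columns `name` and `type`.
#' @export
aux_schema <- function(names = character(), types = character()) {
  names <- as.character(names)
  types <- as.character(types)
  if (length(names) != length(types)) {
    slow5_error("slow5_parse_error", "aux schema: %d names but %d types",
                length(names), length(types))
  }
  bad <- setdiff(types, AUX_TYPES)
  if (length(bad)) {
    slow5_error("slow5_parse_error", "unknown auxiliary type tag(s): %s",
                paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names)) {
    slow5_error("slow5_parse_error", "duplicate auxiliary field name")
  }
  data.frame(name = names, type = types, stringsAsFactors = FALSE)
}

#' Compression specification for a BLOW5 file
#'
#' BLOW5 applies two independent compression layers: `record` compresses each
#' serialised record payload as a block (`none`, `zlib` or `zstd`), and
#' `signal` encodes the raw signal inside the payload (`none` or `svb-zd`,
#' delta + zig-zag + stream variable byte). The default, zlib on the record
#' and svb-zd on the signal, favours compatibility; zstd + svb-zd is more
#' compact.
#'
#' @param record record-layer method: `"none"`, `"zlib"` or `"zstd"`.
#' @param signal signal-layer method: `"none"` or `"svb-zd"`.
#' @return an object of class `slow5_compression`.
#' @export
compression_spec <- function(record = "zlib", signal = "svb-zd") {
  record <- match.arg(record, c("none", "zlib", "zstd"))
  signal <- match.arg(signal, c("none", "svb-zd"))
  structure(list(record = record, signal = signal), class = "slow5_compression")
}

#' @export
print.slow5_compression <- function(x, ...) {
  cat(sprintf("[%s, %s]\n", x$record, x$signal))
  invisible(x)
}

#' File header of a SLOW5/BLOW5 file
#'
#' Holds the format version, one metadata attribute map per read group
#' (acquisition metadata of one sequencing run: run id, flow cell, device,
#' ...), the auxiliary-field schema shared by every record, and -- for the
#' binary form -- the compression specification.
#'
#' @param group_attributes list with one named character vector per read
#'   group. All groups must expose the same attribute keys.
#' @param aux list of auxiliary values in schema order (or named; names are
#'   matched against the schema on validation).
#' @param version format version tag.
#' @param compression a [compression_spec()] (used by the binary writer).
#' @return an object of class `slow5_header`.
#' @export
slow5_header <- function(group_attributes = list(character()),
                         aux = aux_schema(),
                         version = "1.0",
                         compression = compression_spec()) {
  if (!is.list(group_attributes) || length(group_attributes) < 1) {
    slow5_error("slow5_parse_error", "at least one read group is required")
  }
  group_attributes <- lapply(group_attributes, function(g) {
    g <- if (length(g)) vapply(g, as.character, character(1)) else
      structure(character(), names = character())
    g
  })
  keys <- lapply(group_attributes, function(g) sort(names(g)))
  if (length(unique(keys)) > 1) {
    slow5_error("slow5_parse_error",
                "all read groups must share the same attribute key set")
  }
  structure(list(
    version = version,
    num_read_groups = length(group_attributes),
    group_attributes = group_attributes,
    aux_schema = aux,
    compression = compression
  ), class = "slow5_header")
}

#' @export
print.slow5_header <- function(x, ...) {
  cat(sprintf("SLOW5 header (version %s): %d read group(s), %d auxiliary field(s)\n",
              x$version, x$num_read_groups, nrow(x$aux_schema)))
  invisible(x)
}

#' One nanopore read: identifiers, calibration and raw signal
#'
#' The primary attributes mirror what acquisition software records per read:
#' a read identifier, the read-group index into the header's metadata tables,
#' the four calibration scalars (`digitisation`, `offset`, `range`,
#' `sampling_rate`) and the raw current signal as signed 16-bit ADC samples.
#' Auxiliary attributes are optional per-read values typed by the file's
#' [aux_schema()]; `NA` marks a missing value.
#'
#' @param read_id nonempty ASCII identifier (UUID-like); must not contain
#'   tabs or newlines.
#' @param raw_signal integer vector of samples in \[-32768, 32767\].
#' @param read_group nonnegative group index.
#' @param digitisation ADC counts over the full range (positive).
#' @param offset ADC count offset.
#' @param range picoamperes spanned by the full ADC range (positive).
#' @param sampling_rate sampling frequency in Hz (positive).
#' @param aux named list of auxiliary values (see [aux_schema()]).
#' @return an object of class `slow5_rec`.
#' @export
signal_record <- function(read_id, raw_signal = integer(), read_group = 0L,
                          digitisation = 8192, offset = 0, range = 1469.18,
                          sampling_rate = 4000, aux = list()) {
  structure(list(
    read_id = as.character(read_id),
    read_group = as.integer(read_group),
    digitisation = as.numeric(digitisation),
    offset = as.numeric(offset),
    range = as.numeric(range),
    sampling_rate = as.numeric(sampling_rate),
    len_raw_signal = length(raw_signal),
    raw_signal = as.integer(raw_signal),
    aux = aux
  ), class = "slow5_rec")
}

#' @export
print.slow5_rec <- function(x, ...) {
  cat(sprintf("<slow5_rec %s> group %d, %d samples @ %g Hz\n",
              x$read_id, x$read_group, x$len_raw_signal, x$sampling_rate))
  invisible(x)
}

#' Validate a record against a file header
#'
#' Checks every record invariant (signal length bookkeeping, int16 sample
#' range, identifier character set, group index bound, auxiliary keys against
#' the schema). Violations are reported, never raised, so writers can decide
#' how to fail.
#'
#' @param record a [signal_record()].
#' @param header a [slow5_header()].
#' @return list with elements `ok` (logical) and `violations` (character).
#' @export
validate_record <- function(record, header) {
  v <- character()
  if (!is.character(record$read_id) || length(record$read_id) != 1 ||
      is.na(record$read_id) || !nzchar(record$read_id)) {
    v <- c(v, "read_id must be a nonempty string")
  } else if (grepl("[\t\n\r]", record$read_id)) {
    v <- c(v, "read_id contains tab or newline characters")
  }
  if (record$len_raw_signal != length(record$raw_signal)) {
    v <- c(v, sprintf("signal length mismatch: len_raw_signal=%d but %d samples",
                      record$len_raw_signal, length(record$raw_signal)))
  }
  sig <- record$raw_signal
  if (length(sig) && (anyNA(sig) || min(sig) < -32768L || max(sig) > 32767L)) {
    v <- c(v, "raw_signal sample outside signed 16-bit range")
  }
  if (is.na(record$read_group) || record$read_group < 0L) {
    v <- c(v, "read_group must be a nonnegative integer")
  } else if (record$read_group >= header$num_read_groups) {
    v <- c(v, sprintf("read_group out of range: %d with %d group(s)",
                      record$read_group, header$num_read_groups))
  }
  if (!is.na(record$digitisation) && record$digitisation <= 0) {
    v <- c(v, "digitisation must be positive")
  }
  schema <- header$aux_schema
  aux_names <- names(record$aux)
  if (is.null(aux_names)) aux_names <- character()
  if (length(record$aux) != nrow(schema) ||
      (nrow(schema) > 0 && !identical(aux_names, schema$name))) {
    v <- c(v, sprintf("aux keys do not match schema: have [%s], schema [%s]",
                      paste(aux_names, collapse = ","),
                      paste(schema$name, collapse = ",")))
  }
  list(ok = length(v) == 0L, violations = v)
}

#' Convert raw ADC samples to picoamperes
#'
#' Applies the standard nanopore calibration
#' \deqn{pA_i = (raw_i + offset) \times range / digitisation}
#' using the record's own calibration scalars.
#'
#' @param record a [signal_record()].
#' @return numeric vector of picoampere values, one per sample.
#' @export
signal_to_pA <- function(record) {
  if (is.na(record$digitisation) || record$digitisation <= 0) {
    slow5_error("slow5_calibration_error",
                "degenerate calibration: digitisation = %s", record$digitisation)
  }
  (as.numeric(record$raw_signal) + record$offset) * record$range / record$digitisation
}

# Field-for-field record equality used across tests and the toolkit.
records_equal <- function(a, b) {
  if (!identical(a$read_id, b$read_id)) return(FALSE)
  if (a$read_group != b$read_group) return(FALSE)
  for (f in c("digitisation", "offset", "range", "sampling_rate")) {
    if (!identical(a[[f]], b[[f]])) return(FALSE)
  }
  if (a$len_raw_signal != b$len_raw_signal) return(FALSE)
  if (!identical(a$raw_signal, b$raw_signal)) return(FALSE)
  if (length(a$aux) != length(b$aux)) return(FALSE)
  if (!identical(names(a$aux), names(b$aux))) return(FALSE)
  for (k in seq_along(a$aux)) {
    x <- a$aux[[k]]; y <- b$aux[[k]]
    miss_x <- length(x) == 1 && is.na(x); miss_y <- length(y) == 1 && is.na(y)
    if (miss_x != miss_y) return(FALSE)
    if (!miss_x && !isTRUE(all.equal(x, y, tolerance = 0))) {
      if (!identical(as.vector(x), as.vector(y))) return(FALSE)
    }
  }
  TRUE
}

headers_equal <- function(a, b) {
  if (a$num_read_groups != b$num_read_groups) return(FALSE)
  if (!identical(a$aux_schema, b$aux_schema)) return(FALSE)
  for (g in seq_len(a$num_read_groups)) {
    ga <- a$group_attributes[[g]]; gb <- b$group_attributes[[g]]
    if (!identical(ga[order(names(ga))], gb[order(names(gb))])) return(FALSE)
  }
  TRUE
}
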