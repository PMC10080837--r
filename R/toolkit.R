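# Dataset-level operations. All commands preserve records exactly (never
# create or drop one) and their output order is a deterministic function of
# input order, so any rerun -- and any worker-count setting -- yields
# byte-identical output.

expand_inputs <- function(inputs, extensions) {
  out <- character()
  for (p in inputs) {
    if (dir.exists(p)) {
      fs <- list.files(p, pattern = paste0("\\.(", paste(extensions, collapse = "|"), ")$"),
                       full.names = TRUE, recursive = TRUE)
      out <- c(out, sort(fs))
    } else {
      out <- c(out, p)
    }
  }
  out
}

serialize_attr_map <- function(g) {
  ks <- sort(names(g))
  paste(ks, g[ks], sep = "\x1f", collapse = "\x1e")
}

#' Merge signal files, assigning read groups by acquisition metadata
#'
#' Combines records from every input into one output file. Source read
#' groups whose metadata attribute maps are identical (after completion to
#' the union key set, absent keys as `""`) are unified into one output
#' group; distinct maps get separate groups, numbered in first-encounter
#' order over the inputs in argument order (directories expand in
#' lexicographic filename order). Within each input, record order is
#' preserved; read_ids are never deduplicated.
#'
#' @param inputs character vector of `.slow5`/`.blow5` files or directories.
#' @param output output path (`.slow5` or `.blow5`).
#' @param spec a [compression_spec()] for BLOW5 output.
#' @param threads,batch_size accepted for interface compatibility; they
#'   never change the output.
#' @return list with `count` (records written) and `plan` (data frame
#'   mapping each input file and source group to its target group).
#' @export
slow5_merge <- function(inputs, output, spec = compression_spec(),
                        threads = 1L, batch_size = DEFAULT_BATCH_SIZE) {
  files <- expand_inputs(inputs, c("slow5", "blow5"))
  if (!length(files)) slow5_error("slow5_io", "no input files to merge")
  datasets <- lapply(files, read_signal_file)

  schema0 <- datasets[[1]]$header$aux_schema
  for (d in datasets) {
    if (!identical(d$header$aux_schema, schema0)) {
      slow5_error("slow5_schema_conflict",
                  "inputs have conflicting auxiliary schemas")
    }
  }
  all_keys <- sort(unique(unlist(lapply(datasets, function(d)
    lapply(d$header$group_attributes, names)))))
  complete_map <- function(g) {
    v <- stats::setNames(rep("", length(all_keys)), all_keys)
    v[names(g)] <- g
    v
  }

  target_maps <- list()
  keys_seen <- character()
  plan <- data.frame(input = character(), source_group = integer(),
                     target_group = integer(), stringsAsFactors = FALSE)
  for (fi in seq_along(datasets)) {
    hdr <- datasets[[fi]]$header
    for (g in seq_len(hdr$num_read_groups)) {
      cm <- complete_map(hdr$group_attributes[[g]])
      key <- serialize_attr_map(cm)
      t <- match(key, keys_seen)
      if (is.na(t)) {
        keys_seen <- c(keys_seen, key)
        target_maps <- c(target_maps, list(cm))
        t <- length(keys_seen)
      }
      plan <- rbind(plan, data.frame(input = files[fi], source_group = g - 1L,
                                     target_group = t - 1L, stringsAsFactors = FALSE))
    }
  }

  out_header <- slow5_header(target_maps, schema0, compression = spec)
  records <- list()
  n <- 0L
  for (fi in seq_along(datasets)) {
    hdr <- datasets[[fi]]$header
    remap <- plan$target_group[plan$input == files[fi]][
      order(plan$source_group[plan$input == files[fi]])]
    for (rec in datasets[[fi]]$records) {
      rec$read_group <- remap[rec$read_group + 1L]
      n <- n + 1L
      records[[n]] <- rec
    }
  }
  count <- write_signal_file(out_header, records, output, spec = spec)
  list(count = count, plan = plan)
}

#' Concatenate BLOW5 files without touching records
#'
#' A lightweight alternative to [slow5_merge()] for recombining the small
#' batches one acquisition run produces: inputs must share byte-identical
#' header blocks and compression spec, and their record-frame regions are
#' copied verbatim (no per-record decompression) under a single header and
#' EOF marker. Files with differing metadata are refused.
#'
#' @param inputs character vector of `.blow5` files or directories.
#' @param output output `.blow5` path.
#' @return number of records in the output.
#' @export
slow5_cat <- function(inputs, output) {
  files <- expand_inputs(inputs, "blow5")
  if (!length(files)) slow5_error("slow5_io", "no input files to concatenate")
  head_bytes <- NULL
  regions <- vector("list", length(files))
  for (fi in seq_along(files)) {
    h <- open_blow5(files[fi])
    if (!h$eof_ok) {
      blow5_close(h)
      slow5_error("slow5_truncated", "'%s': missing EOF marker", files[fi])
    }
    ds <- h$data_start
    fe <- h$frames_end
    blow5_close(h)
    con <- file(files[fi], "rb")
    hb <- readBin(con, "raw", ds)
    body <- readBin(con, "raw", fe - ds)
    close(con)
    if (is.null(head_bytes)) {
      head_bytes <- hb
    } else if (!identical(hb, head_bytes)) {
      slow5_error("slow5_metadata_mismatch",
                  "'%s' has a different header or compression spec than '%s'",
                  files[fi], files[1])
    }
    regions[[fi]] <- body
  }
  con <- file(output, "wb")
  writeBin(head_bytes, con)
  for (b in regions) writeBin(b, con)
  writeBin(BLOW5_EOF, con)
  close(con)
  slow5_stats(output)$count
}

split_chunk_sizes <- function(n, mode, parameter) {
  if (mode == "reads_per_file") {
    k <- ceiling(n / parameter)
    sizes <- rep(parameter, k)
    if (n %% parameter) sizes[k] <- n %% parameter
    sizes
  } else { # file_count: sizes differ by at most 1, larger chunks first
    if (parameter > n) {
      slow5_error("slow5_usage", "cannot split %d read(s) into %d files", n, parameter)
    }
    base <- n %/% parameter
    extra <- n %% parameter
    c(rep(base + 1L, extra), rep(base, parameter - extra))
  }
}

#' Split a signal file into several files
#'
#' Three modes: `by_group` writes one single-group file per read group
#' (records keep their order, group indices renumber to 0); `reads_per_file`
#' cuts contiguous chunks of a fixed size (last chunk may be smaller);
#' `file_count` cuts a fixed number of contiguous chunks whose sizes differ
#' by at most one, larger chunks first. The chunking modes require a
#' single-read-group input. Output names are the input stem plus a
#' zero-padded chunk ordinal.
#'
#' @param input a `.slow5`/`.blow5` file.
#' @param output_dir directory for the pieces (created if needed).
#' @param mode `"by_group"`, `"reads_per_file"` or `"file_count"`.
#' @param parameter reads per file / number of files (unused for
#'   `by_group`).
#' @param spec a [compression_spec()] for BLOW5 output.
#' @return data frame with columns `path` and `count`.
#' @export
slow5_split <- function(input, output_dir,
                        mode = c("by_group", "reads_per_file", "file_count"),
                        parameter = NULL, spec = compression_spec()) {
  mode <- match.arg(mode)
  dat <- read_signal_file(input)
  hdr <- dat$header
  ext <- if (grepl("\\.blow5$", input)) ".blow5" else ".slow5"
  stem <- sub("\\.(slow5|blow5)$", "", basename(input))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  # pieces of a BLOW5 file keep its compression spec
  if (ext == ".blow5") spec <- hdr$compression

  if (mode == "by_group") {
    groups <- seq_len(hdr$num_read_groups) - 1L
    width <- max(1L, nchar(as.character(max(groups))))
    out <- data.frame(path = character(), count = integer(), stringsAsFactors = FALSE)
    for (g in groups) {
      keep <- vapply(dat$records, function(r) r$read_group == g, logical(1))
      recs <- lapply(dat$records[keep], function(r) { r$read_group <- 0L; r })
      sub_hdr <- slow5_header(hdr$group_attributes[g + 1L], hdr$aux_schema,
                              version = hdr$version, compression = spec)
      path <- file.path(output_dir, sprintf("%s_%0*d%s", stem, width, g, ext))
      write_signal_file(sub_hdr, recs, path, spec = spec)
      out <- rbind(out, data.frame(path = path, count = length(recs),
                                   stringsAsFactors = FALSE))
    }
    return(out)
  }

  if (hdr$num_read_groups != 1L) {
    slow5_error("slow5_usage",
                "mode '%s' requires a single-read-group input (found %d groups)",
                mode, hdr$num_read_groups)
  }
  if (is.null(parameter) || parameter < 1) {
    slow5_error("slow5_usage", "mode '%s' needs a positive parameter", mode)
  }
  sizes <- split_chunk_sizes(length(dat$records), mode, as.integer(parameter))
  width <- max(1L, nchar(as.character(length(sizes) - 1L)))
  bounds <- cumsum(c(0L, sizes))
  out <- data.frame(path = character(), count = integer(), stringsAsFactors = FALSE)
  for (k in seq_along(sizes)) {
    recs <- dat$records[seq.int(bounds[k] + 1L, bounds[k + 1L])]
    path <- file.path(output_dir, sprintf("%s_%0*d%s", stem, width, k - 1L, ext))
    write_signal_file(hdr, recs, path, spec = spec)
    out <- rbind(out, data.frame(path = path, count = length(recs),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Retrieve records by read_id
#'
#' Uses the random-access index (built on demand if absent) to fetch each
#' requested record with a single seek, returning them in request order.
#' Duplicate requests yield duplicate records.
#'
#' @param input an indexed (or indexable) `.slow5`/`.blow5` file.
#' @param read_ids character vector of identifiers, in the desired output
#'   order.
#' @param output optional output path; if given, the selection is written
#'   there (format by extension) and the count returned invisibly.
#' @param skip_absent if `TRUE`, absent ids are skipped and counted instead
#'   of raising an error.
#' @param spec a [compression_spec()] for BLOW5 output.
#' @param threads accepted for interface compatibility; never changes output.
#' @return list of records (plus attribute `n_skipped` when `skip_absent`),
#'   or the written count if `output` is given.
#' @export
slow5_get <- function(input, read_ids, output = NULL, skip_absent = FALSE,
                      spec = compression_spec(), threads = 1L) {
  idx_path <- index_path_for(input)
  if (!file.exists(idx_path)) build_index(input)
  index <- tryCatch(load_index(input), slow5_stale_index = function(e) {
    build_index(input)
    load_index(input)
  })
  header <- if (grepl("\\.blow5$", input)) {
    h <- open_blow5(input); on.exit(blow5_close(h)); h$header
  } else {
    slow5_parse_header(readLines(input, warn = FALSE))$header
  }
  records <- list()
  n_skipped <- 0L
  for (id in read_ids) {
    if (is.null(index_lookup(index, id))) {
      if (skip_absent) {
        n_skipped <- n_skipped + 1L
        next
      }
      slow5_error("slow5_not_found", "read_id '%s' not found in '%s'", id, input)
    }
    records[[length(records) + 1L]] <- fetch_by_read_id(input, index, id, header)
  }
  if (!is.null(output)) {
    out_hdr <- header
    count <- write_signal_file(out_hdr, records, output, spec = spec)
    return(invisible(count))
  }
  if (skip_absent) attr(records, "n_skipped") <- n_skipped
  records
}

#' View or convert a signal file
#'
#' Converts between ASCII SLOW5 and binary BLOW5, or between BLOW5
#' compression specs, preserving header and records field for field. With
#' `output = NULL` the SLOW5 text is returned (the command-line `view`
#' prints it to standard output).
#'
#' @param input a `.slow5`/`.blow5` file.
#' @param output output path, or `NULL` to return SLOW5 text lines.
#' @param target `"slow5"` or `"blow5"`; default inferred from `output`'s
#'   extension (`"slow5"` when printing).
#' @param spec a [compression_spec()] for BLOW5 output (ignored for slow5).
#' @param threads,batch_size accepted for interface compatibility; they
#'   never change the output.
#' @return record count (invisible) when writing; character vector of SLOW5
#'   lines when `output = NULL`.
#' @export
slow5_view <- function(input, output = NULL, target = NULL,
                       spec = compression_spec(), threads = 1L,
                       batch_size = DEFAULT_BATCH_SIZE) {
  dat <- read_signal_file(input)
  if (is.null(output)) {
    con <- textConnection("out_lines", "w", local = TRUE)
    hdr <- dat$header
    hdr$compression <- compression_spec("none", "none")
    write_slow5(hdr, dat$records, con)
    close(con)
    return(out_lines)
  }
  if (is.null(target)) target <- if (grepl("\\.blow5$", output)) "blow5" else "slow5"
  count <- write_signal_file(dat$header, dat$records, output, target = target, spec = spec)
  invisible(count)
}

#' Summary statistics of a signal file
#'
#' One linear pass over the record frames: for BLOW5 only the payload prefix
#' up to the read_group field is decompressed (full decompression under
#' zstd), using a 128-KiB read buffer.
#'
#' @param input a `.slow5`/`.blow5` file.
#' @return list of class `slow5_stats`: `count`, `num_read_groups`,
#'   `compression`, `fields` (primary + auxiliary listing) and
#'   `group_counts`.
#' @export
slow5_stats <- function(input) {
  qc <- quickcheck(input)
  if (!qc$ok) {
    slow5_error("slow5_corrupt", "'%s' is malformed: %s", input, qc$defect)
  }
  if (grepl("\\.blow5$", input)) {
    h <- open_blow5(input)
    on.exit(blow5_close(h))
    header <- h$header
    spec <- h$spec
    group_counts <- integer(header$num_read_groups)
    # scan the frame region through a 128-KiB buffer
    buf <- raw(0)
    seek(h$con, h$data_start)
    remaining <- h$frames_end - h$data_start
    count <- 0L
    while (remaining > 0 || length(buf) > 0) {
      while (length(buf) < 4 && remaining > 0) {
        got <- readBin(h$con, "raw", min(131072, remaining))
        remaining <- remaining - length(got)
        buf <- c(buf, got)
      }
      if (length(buf) == 0) break
      len <- rd_u32(raw_cursor(buf[1:4]))
      while (length(buf) < 4 + len && remaining > 0) {
        got <- readBin(h$con, "raw", min(max(131072, 4 + len - length(buf)), remaining))
        remaining <- remaining - length(got)
        buf <- c(buf, got)
      }
      if (length(buf) < 4 + len) {
        slow5_error("slow5_truncated", "'%s': truncated record frame", input)
      }
      comp <- buf[seq.int(5, 4 + len)]
      buf <- buf[-seq_len(4 + len)]
      id <- peek_read_id(comp, spec$record, extra = 4L)
      grp <- rd_u32(raw_cursor(attr(id, "extra")))
      count <- count + 1L
      group_counts[grp + 1L] <- group_counts[grp + 1L] + 1L
    }
  } else {
    dat <- read_slow5(input)
    header <- dat$header
    spec <- compression_spec("none", "none")
    count <- length(dat$records)
    group_counts <- integer(header$num_read_groups)
    for (r in dat$records) {
      group_counts[r$read_group + 1L] <- group_counts[r$read_group + 1L] + 1L
    }
  }
  structure(list(
    count = count,
    num_read_groups = header$num_read_groups,
    compression = spec,
    fields = list(primary = PRIMARY_FIELDS, aux = header$aux_schema),
    group_counts = group_counts
  ), class = "slow5_stats")
}

#' @export
print.slow5_stats <- function(x, ...) {
  cat(sprintf("records: %d\nread groups: %d\ncompression: [%s, %s]\n",
              x$count, x$num_read_groups, x$compression$record, x$compression$signal))
  cat("per-group counts:", paste(x$group_counts, collapse = ", "), "\n")
  cat("primary fields:", paste(x$fields$primary, collapse = ", "), "\n")
  if (nrow(x$fields$aux)) {
    cat("auxiliary fields:",
        paste(sprintf("%s (%s)", x$fields$aux$name, x$fields$aux$type), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Fast structural integrity check
#'
#' Verifies the magic bytes, header parse, first record parse and EOF-marker
#' presence without reading the whole file. Failures are reported in the
#' return value, never raised.
#'
#' @param input a `.slow5`/`.blow5` file.
#' @return list with `ok` (logical) and `defect` (description of the first
#'   defect, or `NA`).
#' @export
quickcheck <- function(input) {
  fail <- function(msg) list(ok = FALSE, defect = msg)
  if (!file.exists(input)) return(fail("file does not exist"))
  if (grepl("\\.blow5$", input)) {
    h <- tryCatch(open_blow5(input), error = function(e) e)
    if (inherits(h, "error")) {
      msg <- conditionMessage(h)
      return(fail(if (grepl("magic", msg)) "bad magic (not a BLOW5 file)" else msg))
    }
    on.exit(blow5_close(h))
    if (!h$eof_ok) return(fail("missing EOF marker"))
    first <- tryCatch(blow5_next_record(h), error = function(e) e)
    if (inherits(first, "error")) {
      return(fail(paste0("record parse failure: ", conditionMessage(first))))
    }
    list(ok = TRUE, defect = NA_character_)
  } else {
    lines <- tryCatch(readLines(input, warn = FALSE), error = function(e) e)
    if (inherits(lines, "error")) return(fail(conditionMessage(lines)))
    parsed <- tryCatch(slow5_parse_header(lines), error = function(e) e)
    if (inherits(parsed, "error")) {
      return(fail(paste0("header parse failure: ", conditionMessage(parsed))))
    }
    if (length(lines) > parsed$n_lines) {
      first <- tryCatch(row_to_record(lines[parsed$n_lines + 1L], parsed$header,
                                      parsed$n_lines + 1L),
                        error = function(e) e)
      if (inherits(first, "error")) {
        return(fail(paste0("record parse failure: ", conditionMessage(first))))
      }
    }
    list(ok = TRUE, defect = NA_character_)
  }
}

#' Skim selected components of a signal file
#'
#' Prints only what is asked for: `header_only` emits the SLOW5 header
#' lines; `read_ids_only` emits one read_id per line in file order (via
#' partial decompression where the record layer allows it); a character
#' vector of column names emits those columns tab-separated.
#'
#' @param input a `.slow5`/`.blow5` file.
#' @param selection `"header_only"`, `"read_ids_only"`, or a character
#'   vector of column names (primary fields and/or auxiliary field names).
#' @return character vector of output lines.
#' @export
slow5_skim <- function(input, selection = "read_ids_only") {
  is_blow5 <- grepl("\\.blow5$", input)
  if (identical(selection, "header_only")) {
    header <- if (is_blow5) {
      h <- open_blow5(input); on.exit(blow5_close(h)); h$header
    } else {
      slow5_parse_header(readLines(input, warn = FALSE))$header
    }
    return(slow5_header_lines(header))
  }
  if (identical(selection, "read_ids_only")) {
    if (is_blow5) {
      h <- open_blow5(input)
      on.exit(blow5_close(h))
      ids <- character()
      repeat {
        batch <- next_batch(h)
        if (!length(batch)) break
        ids <- c(ids, vapply(batch, function(fr)
          as.character(peek_read_id(fr$frame[-(1:4)], h$spec$record)), character(1)))
      }
      return(ids)
    }
    dat <- read_slow5(input)
    return(vapply(dat$records, function(r) r$read_id, character(1)))
  }
  dat <- read_signal_file(input)
  valid <- c(PRIMARY_FIELDS, dat$header$aux_schema$name)
  bad <- setdiff(selection, valid)
  if (length(bad)) {
    slow5_error("slow5_usage", "unknown column(s) %s; valid columns: %s",
                paste(bad, collapse = ", "), paste(valid, collapse = ", "))
  }
  schema <- dat$header$aux_schema
  vapply(dat$records, function(r) {
    vals <- vapply(selection, function(col) {
      if (col == "raw_signal") {
        if (r$len_raw_signal == 0) MISSING_TOKEN else
          paste(as.character(r$raw_signal), collapse = ",")
      } else if (col == "len_raw_signal") {
        sprintf("%.0f", as.numeric(r$len_raw_signal))
      } else if (col %in% c("digitisation", "offset", "range", "sampling_rate")) {
        fmt_double(r[[col]])
      } else if (col %in% PRIMARY_FIELDS) {
        as.character(r[[col]])
      } else {
        fmt_aux_ascii(r$aux[[col]], schema$type[schema$name == col])
      }
    }, character(1))
    paste(vals, collapse = "\t")
  }, character(1))
}
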