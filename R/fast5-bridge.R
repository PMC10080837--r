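# FAST5 <-> SLOW5/BLOW5 conversion. HDF5 reading/writing is delegated to a
# bundled python helper (h5py); the SLOW5 ASCII form is the exchange format,
# so all format logic stays on the R side and the helper is pure HDF5
# plumbing. Conversion is lossless: every captured signal sample and
# attribute survives a round trip.

find_python <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  slow5_error("slow5_io", "no python interpreter found on PATH (needed for FAST5 I/O)")
}

fast5_helper <- function() {
  p <- system.file("python", "fast5_io.py", package = "slow5r")
  if (!nzchar(p)) slow5_error("slow5_io", "bundled FAST5 helper not found")
  p
}

run_fast5_helper <- function(args) {
  out <- suppressWarnings(system2(find_python(), c(shQuote(fast5_helper()),
                                                   vapply(args, shQuote, character(1))),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    slow5_error("slow5_malformed_fast5", "FAST5 helper failed: %s",
                paste(out, collapse = "; "))
  }
  out
}

#' Convert a multi-read FAST5 file to SLOW5/BLOW5
#'
#' One record per read: the four calibration attributes become primary
#' fields, `tracking_id`/`context_tags` run metadata becomes header group
#' attributes (one read group per file, keys prefixed with their source
#' group), and the remaining per-read attributes become auxiliary fields.
#' Records are ordered by read_id (HDF5 iteration order).
#'
#' @param input a multi-read `.fast5` file.
#' @param output output path; format from extension (`.slow5`/`.blow5`).
#' @param spec a [compression_spec()] for BLOW5 output.
#' @return invisibly, the number of records converted.
#' @export
fast5_to_slow5 <- function(input, output, spec = compression_spec()) {
  tmp <- tempfile(fileext = ".slow5")
  on.exit(unlink(tmp))
  run_fast5_helper(c("f2s", input, tmp))
  dat <- read_slow5(tmp)
  invisible(write_signal_file(dat$header, dat$records, output, spec = spec))
}

#' Convert SLOW5/BLOW5 back to multi-read FAST5
#'
#' Emits one FAST5 file per read group, re-batched at `reads_per_file` reads
#' per file (4000 is the MinKNOW default), restoring header attributes to
#' `tracking_id`/`context_tags` and auxiliary fields to their per-read
#' locations. Array-typed auxiliary fields, which have no native FAST5
#' location, are stored under a reserved `aux/` subgroup (with a warning),
#' never dropped.
#'
#' @param input a `.slow5`/`.blow5` file.
#' @param output_dir destination directory (created if needed).
#' @param reads_per_file batch size per output file.
#' @param stem output filename stem (default: input stem).
#' @return character vector of FAST5 paths written.
#' @export
slow5_to_fast5 <- function(input, output_dir, reads_per_file = 4000L, stem = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(stem)) stem <- sub("\\.(slow5|blow5)$", "", basename(input))
  src <- input
  if (grepl("\\.blow5$", input)) {
    src <- tempfile(fileext = ".slow5")
    on.exit(unlink(src))
    dat <- read_blow5(input)
    hdr <- dat$header
    hdr$compression <- compression_spec("none", "none")
    write_slow5(hdr, dat$records, src)
  }
  out <- run_fast5_helper(c("s2f", src, output_dir, stem,
                            as.character(reads_per_file)))
  paths <- out[file.exists(out)]
  if (!length(paths)) {
    slow5_error("slow5_io", "FAST5 conversion produced no files: %s",
                paste(out, collapse = "; "))
  }
  paths
}

partition_evenly <- function(n, workers) {
  workers <- max(1L, min(as.integer(workers), n))
  base <- n %/% workers
  extra <- n %% workers
  sizes <- c(rep(base + 1L, extra), rep(base, workers - extra))
  rep(seq_len(workers), times = sizes)
}

#' Convert every signal file under a directory tree
#'
#' Recursively finds files by extension (`.fast5` for `f2s`; `.slow5` and
#' `.blow5` for `s2f`), partitions the file list as evenly as possible
#' across `workers`, and converts one output file per input file, mirroring
#' relative paths. Worker count partitions the work but never changes any
#' output byte. A failing file is recorded in the manifest and the rest
#' proceed.
#'
#' @param input_dir directory to search.
#' @param output_dir mirrored output directory.
#' @param direction `"f2s"` or `"s2f"`.
#' @param workers number of work partitions.
#' @param spec a [compression_spec()] for BLOW5 output (f2s).
#' @param out_format `"blow5"` or `"slow5"` (f2s output form).
#' @return manifest data frame, sorted by input path, with columns `input`,
#'   `output`, `count`, `worker`, `ok`; attribute `n_failed` counts
#'   failures.
#' @export
convert_directory <- function(input_dir, output_dir, direction = c("f2s", "s2f"),
                              workers = 1L, spec = compression_spec(),
                              out_format = "blow5") {
  direction <- match.arg(direction)
  if (!dir.exists(input_dir)) slow5_error("slow5_io", "'%s' does not exist", input_dir)
  pattern <- if (direction == "f2s") "\\.fast5$" else "\\.(slow5|blow5)$"
  files <- sort(list.files(input_dir, pattern = pattern, recursive = TRUE))
  manifest <- data.frame(input = character(), output = character(),
                         count = integer(), worker = integer(), ok = logical(),
                         stringsAsFactors = FALSE)
  if (!length(files)) return(manifest)
  assignment <- partition_evenly(length(files), workers)
  for (k in seq_along(files)) {
    rel <- files[k]
    in_path <- file.path(input_dir, rel)
    res <- tryCatch({
      if (direction == "f2s") {
        out_rel <- sub("\\.fast5$", paste0(".", out_format), rel)
        out_path <- file.path(output_dir, out_rel)
        dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
        n <- fast5_to_slow5(in_path, out_path, spec = spec)
        list(output = out_path, count = n, ok = TRUE)
      } else {
        out_sub <- file.path(output_dir, dirname(rel))
        n <- slow5_stats(in_path)$count
        paths <- slow5_to_fast5(in_path, out_sub,
                                stem = sub("\\.(slow5|blow5)$", "", basename(rel)))
        list(output = paste(paths, collapse = ";"), count = n, ok = TRUE)
      }
    }, error = function(e) list(output = NA_character_, count = NA_integer_,
                                ok = FALSE, msg = conditionMessage(e)))
    if (!res$ok) message(sprintf("conversion of '%s' failed: %s", in_path, res$msg))
    manifest <- rbind(manifest, data.frame(input = in_path, output = res$output,
                                           count = res$count, worker = assignment[k],
                                           ok = res$ok, stringsAsFactors = FALSE))
  }
  manifest <- manifest[order(manifest$input), , drop = FALSE]
  rownames(manifest) <- NULL
  attr(manifest, "n_failed") <- sum(!manifest$ok)
  manifest
}

#' Watch a run directory and convert FAST5 files as they appear
#'
#' Polls `run_dir` (acquisition software closes one FAST5 file per batch of
#' reads); a file whose size is unchanged between two polls is considered
#' complete and queued FIFO. At most `max_workers` conversions run per poll
#' cycle; the rest stay queued. With `delete = TRUE` a source file is
#' removed only after its output passes [quickcheck()] and a record-count
#' match -- a corrupted input is never deleted.
#'
#' @param run_dir directory to watch for `.fast5` files.
#' @param output_dir destination for `.blow5` outputs.
#' @param max_workers maximum conversions per poll cycle.
#' @param poll_interval seconds between polls.
#' @param timeout overall watch duration cap in seconds.
#' @param idle_stop stop after this many consecutive polls with nothing new
#'   and nothing queued.
#' @param delete delete each source FAST5 after verified conversion.
#' @param spec a [compression_spec()] for the outputs.
#' @return conversion log data frame with columns `input`, `output`,
#'   `detected_order`, `status` (`converted`/`failed`), `count`,
#'   `verified`, `deleted`.
#' @export
watch_and_convert <- function(run_dir, output_dir, max_workers = 1L,
                              poll_interval = 5, timeout = 300,
                              idle_stop = 3L, delete = FALSE,
                              spec = compression_spec()) {
  if (!dir.exists(run_dir)) slow5_error("slow5_io", "'%s' does not exist", run_dir)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  sizes <- new.env(parent = emptyenv())
  queue <- character()
  done <- character()
  detected <- character()
  log <- data.frame(input = character(), output = character(),
                    detected_order = integer(), status = character(),
                    count = integer(), verified = logical(), deleted = logical(),
                    stringsAsFactors = FALSE)
  start <- Sys.time()
  idle <- 0L
  repeat {
    fs <- sort(list.files(run_dir, pattern = "\\.fast5$", full.names = TRUE))
    activity <- FALSE
    for (f in fs) {
      if (f %in% done || f %in% queue) next
      sz <- file.info(f)$size
      prev <- if (exists(f, envir = sizes)) get(f, envir = sizes) else NA
      assign(f, sz, envir = sizes)
      if (!is.na(prev) && prev == sz) {
        queue <- c(queue, f) # stable across two polls: complete
        if (!(f %in% detected)) detected <- c(detected, f)
        activity <- TRUE
      } else {
        activity <- TRUE # still growing (or just seen); keep polling
      }
    }
    n_run <- min(length(queue), max_workers)
    for (f in head(queue, n_run)) {
      out_path <- file.path(output_dir, sub("\\.fast5$", ".blow5", basename(f)))
      res <- tryCatch({
        n <- fast5_to_slow5(f, out_path, spec = spec)
        ok <- quickcheck(out_path)$ok && slow5_stats(out_path)$count == n
        del <- FALSE
        if (delete && ok) {
          unlink(f)
          del <- TRUE
        }
        data.frame(input = f, output = out_path,
                   detected_order = match(f, detected),
                   status = "converted", count = n, verified = ok, deleted = del,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        message(sprintf("conversion of '%s' failed: %s", f, conditionMessage(e)))
        data.frame(input = f, output = NA_character_,
                   detected_order = match(f, detected),
                   status = "failed", count = NA_integer_, verified = FALSE,
                   deleted = FALSE, stringsAsFactors = FALSE)
      })
      log <- rbind(log, res)
      done <- c(done, f)
    }
    queue <- setdiff(queue, done)
    if (n_run > 0) activity <- TRUE
    idle <- if (activity) 0L else idle + 1L
    elapsed <- as.numeric(difftime(Sys.time(), start, units = "secs"))
    if ((idle >= idle_stop && !length(queue)) || elapsed > timeout) break
    Sys.sleep(poll_interval)
  }
  log
}
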