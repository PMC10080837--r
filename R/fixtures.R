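# Seeded synthetic data: deterministic records and FAST5 files emulating
# what MinKNOW writes during a run (batches of reads per file, 16-bit
# signals, per-run metadata), so every toolkit operation is testable with
# no real sequencing data.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic-data generator
#'
#' The signal model is a random walk with occasional abrupt level shifts,
#' mimicking the segmented, slowly varying pore current that makes
#' delta-based signal compression worthwhile (pure white noise would not;
#' constant signals compress trivially). Calibration scalars are fixed
#' plausible device constants. The default of 4000 reads per FAST5 file is
#' the MinKNOW batching default.
#'
#' @param seed integer seed; identical configurations generate identical
#'   data, byte for byte.
#' @param n_reads number of reads.
#' @param reads_per_fast5 batch size when emitting FAST5 files.
#' @param n_read_groups number of read groups (distinct simulated runs).
#' @param signal_len length-2 vector: signal lengths are sampled uniformly
#'   from this range (desk-scale stand-in for real ONT read durations).
#' @param baseline,step_sd,shift_prob,shift_scale signal model: starting
#'   level (ADC counts), random-walk step standard deviation, per-sample
#'   probability of a level shift, and shift magnitude scale.
#' @param missing_aux_rate fraction of reads with a missing `median_before`
#'   (FAST5 inputs may lack fields per read).
#' @return object of class `slow5_synth_config`.
#' @export
synthetic_config <- function(seed = 1L, n_reads = 100L, reads_per_fast5 = 4000L,
                             n_read_groups = 1L, signal_len = c(1000L, 3000L),
                             baseline = 500, step_sd = 2, shift_prob = 0.002,
                             shift_scale = 120, missing_aux_rate = 0.05) {
  stopifnot(n_reads >= 0, reads_per_fast5 >= 1, n_read_groups >= 1,
            length(signal_len) == 2, signal_len[1] <= signal_len[2])
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 reads_per_fast5 = as.integer(reads_per_fast5),
                 n_read_groups = as.integer(n_read_groups),
                 signal_len = as.integer(signal_len), baseline = baseline,
                 step_sd = step_sd, shift_prob = shift_prob,
                 shift_scale = shift_scale, missing_aux_rate = missing_aux_rate),
            class = "slow5_synth_config")
}

rand_hex <- function(n) {
  paste(sample(c(0:9, letters[1:6]), n, replace = TRUE), collapse = "")
}

rand_uuid <- function() {
  paste(vapply(c(8L, 4L, 4L, 4L, 12L), rand_hex, character(1)), collapse = "-")
}

# The auxiliary fields this package maps between FAST5 per-read attributes
# and SLOW5 aux columns (a representative MinKNOW set).
synthetic_aux_schema <- function() {
  aux_schema(
    c("channel_number", "median_before", "read_number", "start_mux", "start_time"),
    c("string", "double", "int32", "uint8", "uint64")
  )
}

#' Generate a deterministic set of synthetic signal records
#'
#' @param config a [synthetic_config()].
#' @return list with `header` and `records` (see [slow5_header()],
#'   [signal_record()]).
#' @export
generate_records <- function(config) {
  stopifnot(inherits(config, "slow5_synth_config"))
  with_seed(config$seed, {
    groups <- lapply(seq_len(config$n_read_groups), function(g) {
      c("tracking_id.run_id" = rand_hex(16L),
        "tracking_id.flow_cell_id" = sprintf("FAK%05d", sample.int(99999L, 1L)),
        "tracking_id.device_id" = sprintf("MN%05d", sample.int(99999L, 1L)),
        "tracking_id.exp_start_time" = "2023-01-01T00:00:00Z",
        "context_tags.sample_frequency" = "4000",
        "context_tags.experiment_type" = "genomic_dna")
    })
    header <- slow5_header(groups, synthetic_aux_schema())
    records <- vector("list", config$n_reads)
    read_group_of <- if (config$n_read_groups > 1) {
      sample.int(config$n_read_groups, config$n_reads, replace = TRUE) - 1L
    } else {
      integer(config$n_reads)
    }
    for (i in seq_len(config$n_reads)) {
      n <- if (config$signal_len[1] == config$signal_len[2]) config$signal_len[1] else
        sample(seq.int(config$signal_len[1], config$signal_len[2]), 1L)
      steps <- rnorm(n, 0, config$step_sd)
      shifts <- rbinom(n, 1L, config$shift_prob) *
        sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.5, 1.5) * config$shift_scale
      sig <- as.integer(pmin(32767, pmax(-32768,
               round(config$baseline + cumsum(steps + shifts)))))
      aux <- list(
        channel_number = as.character(sample.int(512L, 1L)),
        median_before = if (runif(1) < config$missing_aux_rate) NA_real_ else
          round(rnorm(1, 250, 30), 3),
        read_number = i,
        start_mux = sample.int(4L, 1L),
        start_time = floor(runif(1, 0, 2^31))
      )
      records[[i]] <- signal_record(rand_uuid(), sig,
                                    read_group = read_group_of[i], aux = aux)
    }
    list(header = header, records = records)
  })
}

#' Generate a directory of synthetic multi-read FAST5 files
#'
#' Emits `ceil(n_reads / reads_per_fast5)` multi-read FAST5 files laid out
#' like MinKNOW output (one read group per run; reads batched per file),
#' deterministically from the seed. Requires a python interpreter with
#' `h5py` on the PATH.
#'
#' @param config a [synthetic_config()] (with `n_read_groups = 1`).
#' @param output_dir destination directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return character vector of FAST5 paths; the generated `header` and
#'   `records` are attached as attributes `header` and `records`.
#' @export
generate_fast5_dataset <- function(config, output_dir, overwrite = FALSE) {
  if (config$n_read_groups != 1L) {
    slow5_error("slow5_usage", "FAST5 generation emulates one run per dataset; use n_read_groups = 1")
  }
  if (dir.exists(output_dir) && length(list.files(output_dir)) && !overwrite) {
    slow5_error("slow5_io", "output directory '%s' is not empty (set overwrite = TRUE)",
                output_dir)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- generate_records(config)
  tmp <- tempfile(fileext = ".slow5")
  on.exit(unlink(tmp))
  write_slow5(dat$header, dat$records, tmp)
  paths <- slow5_to_fast5(tmp, output_dir, reads_per_file = config$reads_per_fast5,
                          stem = sprintf("synthetic_run_%d", config$seed))
  attr(paths, "header") <- dat$header
  attr(paths, "records") <- dat$records
  paths
}
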