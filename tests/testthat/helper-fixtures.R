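# Shared fixtures: everything is generated in code, nothing is stored.

expect_records_equal <- function(a, b) {
  expect_equal(length(a), length(b))
  ok <- mapply(slow5r:::records_equal, a, b)
  expect_true(all(ok), label = sprintf("records equal (first mismatch at %s)",
                                       if (all(ok)) "none" else which(!ok)[1]))
}

read_ids_of <- function(records) vapply(records, function(r) r$read_id, character(1))

all_compression_specs <- function() {
  out <- list()
  for (rm in c("none", "zlib", "zstd")) {
    for (sm in c("none", "svb-zd")) {
      out[[paste(rm, sm, sep = "+")]] <- compression_spec(rm, sm)
    }
  }
  out
}

# Hand-built boundary records: int16 extremes, empty signal, all-missing aux,
# long read_id. They satisfy every record invariant and exercise the edges the
# generator's signal model does not reach.
edge_records <- function(header) {
  aux_missing <- list(channel_number = NA_character_, median_before = NA_real_,
                      read_number = NA_integer_, start_mux = NA_integer_,
                      start_time = NA_real_)
  aux_full <- list(channel_number = "512", median_before = 123.456,
                   read_number = 42L, start_mux = 4L, start_time = 2^40)
  list(
    signal_record("edge-extremes", c(-32768L, 32767L, 0L, -32768L, 32767L),
                  aux = aux_full),
    signal_record("edge-empty-signal", integer(), aux = aux_full),
    signal_record("edge-missing-aux", c(1L, -1L, 100L), aux = aux_missing),
    signal_record(paste0("edge-long-", paste(rep("x", 200), collapse = "")),
                  c(5L, 5L, 5L), aux = aux_full)
  )
}

# One modest dataset reused across tests that only need "some records".
small_dataset <- local({
  dat <- NULL
  function() {
    if (is.null(dat)) {
      dat <<- generate_records(synthetic_config(seed = 101, n_reads = 40,
                                                signal_len = c(40, 120)))
    }
    dat
  }
})

synthetic_aux_schema_for_tests <- function() slow5r:::synthetic_aux_schema()

write_temp_blow5 <- function(dat, spec = compression_spec()) {
  path <- tempfile(fileext = ".blow5")
  write_blow5(dat$header, dat$records, path, spec)
  path
}
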