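# FAST5 conversion tests exercise the bundled h5py helper end to end; the
# generator's records are the ground truth throughout.

fast5_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = 71, n_reads = 25, reads_per_fast5 = 10,
                              signal_len = c(40, 100))
      dir <- tempfile("fast5fix")
      paths <- generate_fast5_dataset(cfg, dir)
      cache <<- list(cfg = cfg, dir = dir, paths = paths,
                     header = attr(paths, "header"),
                     records = attr(paths, "records"))
    }
    cache
  }
})

sort_by_id <- function(records) records[order(read_ids_of(records))]

test_that("f2s recovers generator ground truth exactly", {
  fx <- fast5_fixture()
  out <- tempfile(fileext = ".blow5")
  n <- fast5_to_slow5(fx$paths[1], out)
  expect_identical(n, 10L)
  got <- read_blow5(out)
  expect_records_equal(sort_by_id(fx$records[1:10]), got$records)
  expect_true(slow5r:::headers_equal(fx$header, got$header))
  # every signal sample byte-equal
  for (k in seq_along(got$records)) {
    expect_identical(got$records[[k]]$raw_signal,
                     sort_by_id(fx$records[1:10])[[k]]$raw_signal)
  }
})

test_that("the f2s/s2f composition is lossless and idempotent", {
  fx <- fast5_fixture()
  b1 <- tempfile(fileext = ".blow5")
  fast5_to_slow5(fx$paths[2], b1)
  round_dir <- tempfile()
  f5 <- slow5_to_fast5(b1, round_dir)
  expect_length(f5, 1)
  b2 <- tempfile(fileext = ".blow5")
  fast5_to_slow5(f5[1], b2)
  r1 <- read_blow5(b1); r2 <- read_blow5(b2)
  expect_records_equal(r1$records, r2$records)
  expect_true(slow5r:::headers_equal(r1$header, r2$header))
})

test_that("s2f re-batches reads per file and never mixes read groups", {
  # 25 single-group reads at 10 per file -> 3 files of 10/10/5
  fx <- fast5_fixture()
  merged <- tempfile(fileext = ".blow5")
  slow5_cat(lapply(fx$paths, function(p) {
    o <- tempfile(fileext = ".blow5"); fast5_to_slow5(p, o); o
  }), merged)
  out_dir <- tempfile()
  f5 <- slow5_to_fast5(merged, out_dir, reads_per_file = 10L)
  expect_length(f5, 3)
  counts <- vapply(f5, function(p) {
    o <- tempfile(fileext = ".blow5")
    fast5_to_slow5(p, o)
    slow5_stats(o)$count
  }, integer(1))
  expect_identical(unname(counts), c(10L, 10L, 5L))

  # two-group input: one output file per group, no mixing
  g1 <- generate_records(synthetic_config(seed = 72, n_reads = 4, signal_len = c(20, 30)))
  g2 <- generate_records(synthetic_config(seed = 73, n_reads = 3, signal_len = c(20, 30)))
  f1 <- tempfile(fileext = ".blow5"); f2 <- tempfile(fileext = ".blow5")
  write_blow5(g1$header, g1$records, f1)
  write_blow5(g2$header, g2$records, f2)
  m <- tempfile(fileext = ".blow5")
  slow5_merge(c(f1, f2), m)
  out2 <- tempfile()
  f5g <- slow5_to_fast5(m, out2)
  expect_length(f5g, 2)
  runs <- vapply(f5g, function(p) {
    o <- tempfile(fileext = ".blow5")
    fast5_to_slow5(p, o)
    read_blow5(o)$header$group_attributes[[1]][["tracking_id.run_id"]]
  }, character(1))
  expect_identical(sort(unname(runs)),
                   sort(c(g1$header$group_attributes[[1]][["tracking_id.run_id"]],
                          g2$header$group_attributes[[1]][["tracking_id.run_id"]])))
})

test_that("malformed FAST5 files are reported, not silently converted", {
  bad <- tempfile(fileext = ".fast5")
  writeBin(as.raw(1:64), bad)
  expect_error(fast5_to_slow5(bad, tempfile(fileext = ".blow5")),
               class = "slow5_malformed_fast5")
})

test_that("directory conversion mirrors paths, filters extensions and balances work", {
  fx <- fast5_fixture()
  tree <- tempfile()
  dir.create(file.path(tree, "sub"), recursive = TRUE)
  file.copy(fx$paths[1], file.path(tree, "a.fast5"))
  file.copy(fx$paths[2], file.path(tree, "b.fast5"))
  file.copy(fx$paths[3], file.path(tree, "sub", "c.fast5"))
  writeLines("not signal data", file.path(tree, "notes.txt"))
  out <- tempfile()
  m <- convert_directory(tree, out, "f2s", workers = 2)
  expect_identical(nrow(m), 3L)
  expect_identical(attr(m, "n_failed"), 0L)
  expect_true(all(file.exists(m$output)))
  expect_identical(basename(m$output), c("a.blow5", "b.blow5", "c.blow5"))
  expect_true(any(grepl("sub", m$output)))
  expect_identical(sum(m$count), 25L)
  # work is split as evenly as possible
  expect_identical(as.integer(table(m$worker)), c(2L, 1L))
  expect_identical(slow5r:::partition_evenly(10L, 4L), rep(1:4, c(3L, 3L, 2L, 2L)))

  # worker count never changes an output byte
  out1 <- tempfile(); out8 <- tempfile()
  m1 <- convert_directory(tree, out1, "f2s", workers = 1)
  m8 <- convert_directory(tree, out8, "f2s", workers = 8)
  expect_identical(m1$count, m8$count)
  expect_identical(basename(m1$output), basename(m8$output))
  for (k in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$output[k], "raw", file.size(m1$output[k])),
                     readBin(m8$output[k], "raw", file.size(m8$output[k])))
  }
})

test_that("a failing file is recorded in the manifest while others convert", {
  fx <- fast5_fixture()
  tree <- tempfile(); dir.create(tree)
  file.copy(fx$paths[1], file.path(tree, "good.fast5"))
  writeBin(as.raw(1:64), file.path(tree, "broken.fast5"))
  out <- tempfile()
  m <- suppressMessages(convert_directory(tree, out, "f2s"))
  expect_identical(attr(m, "n_failed"), 1L)
  expect_identical(m$ok, c(FALSE, TRUE)) # sorted by input path
  expect_true(file.exists(m$output[m$ok]))
})

test_that("the watcher converts files as they appear and verifies before deleting", {
  fx <- fast5_fixture()
  run <- tempfile(); dir.create(run)
  out <- tempfile()
  for (p in fx$paths) file.copy(p, run)
  log <- watch_and_convert(run, out, max_workers = 1, poll_interval = 0.05,
                           timeout = 60, idle_stop = 3)
  expect_identical(nrow(log), 3L)
  expect_true(all(log$status == "converted"))
  expect_true(all(log$verified))
  expect_identical(sort(log$detected_order), 1:3)
  expect_length(list.files(out, pattern = "\\.blow5$"), 3)
  # with max_workers 1 conversions are serialised but all complete
  expect_identical(sum(log$count), 25L)
})

test_that("the watcher never deletes a source that fails integrity checks", {
  run <- tempfile(); dir.create(run)
  out <- tempfile()
  bad <- file.path(run, "corrupt.fast5")
  writeBin(as.raw(1:128), bad)
  log <- suppressMessages(
    watch_and_convert(run, out, poll_interval = 0.05, timeout = 30,
                      idle_stop = 3, delete = TRUE))
  expect_identical(log$status, "failed")
  expect_false(log$deleted)
  expect_true(file.exists(bad))
})

test_that("the watcher deletes verified sources when asked", {
  fx <- fast5_fixture()
  run <- tempfile(); dir.create(run)
  out <- tempfile()
  file.copy(fx$paths[1], run)
  src <- list.files(run, full.names = TRUE)
  log <- watch_and_convert(run, out, poll_interval = 0.05, timeout = 30,
                           idle_stop = 3, delete = TRUE)
  expect_true(log$deleted)
  expect_false(file.exists(src))
  expect_true(quickcheck(log$output)$ok)
})
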