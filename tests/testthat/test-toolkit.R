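two_run_fixture <- function(n1 = 10, n2 = 12) {
  d1 <- generate_records(synthetic_config(seed = 31, n_reads = n1, signal_len = c(30, 60)))
  d2 <- generate_records(synthetic_config(seed = 32, n_reads = n2, signal_len = c(30, 60)))
  f1 <- tempfile(fileext = ".blow5"); f2 <- tempfile(fileext = ".blow5")
  write_blow5(d1$header, d1$records, f1)
  write_blow5(d2$header, d2$records, f2)
  list(d1 = d1, d2 = d2, f1 = f1, f2 = f2)
}

test_that("merge assigns read groups by run metadata and conserves records", {
  fx <- two_run_fixture()
  out <- tempfile(fileext = ".blow5")
  res <- slow5_merge(c(fx$f1, fx$f2), out)
  expect_identical(res$count, 22L)
  merged <- read_blow5(out)
  expect_identical(merged$header$num_read_groups, 2L)
  expect_identical(res$plan$target_group, c(0L, 1L))
  groups <- vapply(merged$records, function(r) r$read_group, integer(1))
  expect_identical(groups, c(rep(0L, 10), rep(1L, 12)))
  # records preserved, only regrouped
  stripped <- lapply(merged$records, function(r) { r$read_group <- 0L; r })
  orig <- lapply(c(fx$d1$records, fx$d2$records), function(r) { r$read_group <- 0L; r })
  expect_records_equal(orig, stripped)
})

test_that("merge unifies read groups with byte-identical attribute maps", {
  dat <- small_dataset()
  f1 <- tempfile(fileext = ".blow5"); f2 <- tempfile(fileext = ".blow5")
  write_blow5(dat$header, dat$records[1:5], f1)
  write_blow5(dat$header, dat$records[6:10], f2)
  out <- tempfile(fileext = ".blow5")
  res <- slow5_merge(c(f1, f2), out)
  merged <- read_blow5(out)
  expect_identical(merged$header$num_read_groups, 1L)
  expect_true(all(vapply(merged$records, function(r) r$read_group, integer(1)) == 0L))
  expect_identical(res$count, 10L)
})

test_that("merging a single file is record-equal to the input", {
  dat <- small_dataset()
  f <- write_temp_blow5(dat)
  out <- tempfile(fileext = ".blow5")
  slow5_merge(f, out)
  expect_records_equal(dat$records, read_blow5(out)$records)
})

test_that("merge refuses conflicting auxiliary schemas", {
  dat <- small_dataset()
  f1 <- write_temp_blow5(dat)
  other_hdr <- slow5_header(dat$header$group_attributes, aux_schema("x", "uint8"))
  f2 <- tempfile(fileext = ".blow5")
  write_blow5(other_hdr, list(signal_record("solo", 1L, aux = list(x = 1L))), f2)
  expect_error(slow5_merge(c(f1, f2), tempfile(fileext = ".blow5")),
               class = "slow5_schema_conflict")
})

test_that("cat concatenates identically-headed files and equals merge's records", {
  dat <- small_dataset()
  files <- vapply(list(1:8, 9:20, 21:30), function(idx) {
    f <- tempfile(fileext = ".blow5")
    write_blow5(dat$header, dat$records[idx], f)
    f
  }, character(1))
  out_cat <- tempfile(fileext = ".blow5")
  expect_identical(slow5_cat(files, out_cat), 30L)
  out_merge <- tempfile(fileext = ".blow5")
  slow5_merge(files, out_merge)
  expect_records_equal(read_blow5(out_cat)$records, read_blow5(out_merge)$records)
})

test_that("cat of one file is a byte-identical copy; mismatched metadata is refused", {
  dat <- small_dataset()
  f <- write_temp_blow5(dat)
  out <- tempfile(fileext = ".blow5")
  slow5_cat(f, out)
  expect_identical(readBin(f, "raw", file.size(f)), readBin(out, "raw", file.size(out)))

  fx <- two_run_fixture()
  expect_error(slow5_cat(c(fx$f1, fx$f2), tempfile(fileext = ".blow5")),
               class = "slow5_metadata_mismatch")
  # differing compression spec is also a mismatch
  f_zstd <- write_temp_blow5(dat, compression_spec("zstd", "svb-zd"))
  expect_error(slow5_cat(c(f, f_zstd), tempfile(fileext = ".blow5")),
               class = "slow5_metadata_mismatch")
})

test_that("split chunk arithmetic follows the documented rules", {
  expect_identical(slow5r:::split_chunk_sizes(10000L, "reads_per_file", 4000L),
                   c(4000L, 4000L, 2000L))
  expect_identical(slow5r:::split_chunk_sizes(10L, "file_count", 3L), c(4L, 3L, 3L))
  expect_identical(slow5r:::split_chunk_sizes(12L, "file_count", 4L), rep(3L, 4))
  expect_error(slow5r:::split_chunk_sizes(2L, "file_count", 3L), class = "slow5_usage")
})

test_that("split by reads_per_file cuts contiguous chunks with stable names", {
  dat <- generate_records(synthetic_config(seed = 41, n_reads = 100,
                                           signal_len = c(20, 40)))
  f <- write_temp_blow5(dat)
  out_dir <- tempfile()
  res <- slow5_split(f, out_dir, "reads_per_file", 40L)
  expect_identical(res$count, c(40L, 40L, 20L))
  expect_identical(basename(res$path), paste0(sub("\\.blow5$", "", basename(f)),
                                              "_", 0:2, ".blow5"))
  got <- unlist(lapply(res$path, function(p) read_ids_of(read_blow5(p)$records)))
  expect_identical(got, read_ids_of(dat$records))
})

test_that("split by_group inverts merge", {
  fx <- two_run_fixture()
  merged <- tempfile(fileext = ".blow5")
  slow5_merge(c(fx$f1, fx$f2), merged)
  out_dir <- tempfile()
  res <- slow5_split(merged, out_dir, "by_group")
  expect_identical(nrow(res), 2L)
  expect_identical(res$count, c(10L, 12L))
  back1 <- read_blow5(res$path[1])
  expect_identical(back1$header$num_read_groups, 1L)
  expect_records_equal(fx$d1$records, back1$records)
  expect_records_equal(fx$d2$records, read_blow5(res$path[2])$records)
  expect_true(slow5r:::headers_equal(fx$d1$header, back1$header))
})

test_that("chunking modes refuse multi-group inputs", {
  fx <- two_run_fixture()
  merged <- tempfile(fileext = ".blow5")
  slow5_merge(c(fx$f1, fx$f2), merged)
  expect_error(slow5_split(merged, tempfile(), "reads_per_file", 5L),
               class = "slow5_usage")
  expect_error(slow5_split(merged, tempfile(), "file_count", 2L),
               class = "slow5_usage")
})

test_that("get returns records in request order, duplicates included", {
  dat <- small_dataset()
  f <- write_temp_blow5(dat)
  ids <- read_ids_of(dat$records)
  set.seed(1)
  req <- sample(ids, 15)
  got <- slow5_get(f, req)
  expect_identical(read_ids_of(got), req)
  linear <- dat$records[match(req, ids)]
  expect_records_equal(linear, got)

  dup <- c(ids[3], ids[3])
  expect_identical(read_ids_of(slow5_get(f, dup)), dup)

  err <- tryCatch(slow5_get(f, c(ids[1], "ghost-read")), error = function(e) e)
  expect_s3_class(err, "slow5_not_found")
  expect_match(conditionMessage(err), "ghost-read")

  skipped <- slow5_get(f, c(ids[1], "ghost-read", ids[2]), skip_absent = TRUE)
  expect_identical(read_ids_of(skipped), ids[1:2])
  expect_identical(attr(skipped, "n_skipped"), 1L)
})

test_that("get writes a selection file and builds the index on demand", {
  dat <- small_dataset()
  f <- write_temp_blow5(dat)
  expect_false(file.exists(paste0(f, ".idx")))
  out <- tempfile(fileext = ".slow5")
  ids <- read_ids_of(dat$records)[c(5, 2, 9)]
  slow5_get(f, ids, output = out)
  expect_true(file.exists(paste0(f, ".idx")))
  sel <- read_slow5(out)
  expect_identical(read_ids_of(sel$records), ids)
})

test_that("view converts across every pair of compression specs losslessly", {
  dat <- generate_records(synthetic_config(seed = 51, n_reads = 12,
                                           signal_len = c(30, 60)))
  specs <- all_compression_specs()
  sources <- lapply(specs, function(s) write_temp_blow5(dat, s))
  for (src in sources) {
    for (s in specs) {
      out <- tempfile(fileext = ".blow5")
      slow5_view(src, out, spec = s)
      expect_records_equal(dat$records, read_blow5(out)$records)
    }
  }
})

test_that("view without an output renders SLOW5 text", {
  dat <- small_dataset()
  f <- write_temp_blow5(dat)
  lines <- slow5_view(f)
  expect_match(lines[1], "^#slow5_version")
  tmp <- tempfile()
  writeLines(lines, tmp)
  expect_records_equal(dat$records, read_slow5(tmp)$records)
})

test_that("stats reports generator-true counts with per-group conservation", {
  dat <- generate_records(synthetic_config(seed = 61, n_reads = 57,
                                           n_read_groups = 3, signal_len = c(20, 40)))
  truth <- table(factor(vapply(dat$records, function(r) r$read_group, integer(1)),
                        levels = 0:2))
  for (rm in c("none", "zlib", "zstd")) {
    f <- write_temp_blow5(dat, compression_spec(rm, "svb-zd"))
    st <- slow5_stats(f)
    expect_identical(st$count, 57L)
    expect_identical(st$num_read_groups, 3L)
    expect_identical(st$group_counts, as.integer(truth))
    expect_identical(sum(st$group_counts), st$count)
    expect_identical(st$compression$record, rm)
  }
  # header-only file
  empty <- tempfile(fileext = ".blow5")
  write_blow5(dat$header, list(), empty)
  expect_identical(slow5_stats(empty)$count, 0L)
})

test_that("quickcheck passes sound files and pinpoints structural damage", {
  dat <- small_dataset()
  f <- write_temp_blow5(dat)
  expect_true(quickcheck(f)$ok)

  bytes <- readBin(f, "raw", file.size(f))
  no_eof <- tempfile(fileext = ".blow5")
  writeBin(bytes[1:(length(bytes) - 8)], no_eof)
  qc <- quickcheck(no_eof)
  expect_false(qc$ok)
  expect_match(qc$defect, "EOF marker")

  bad_magic <- tempfile(fileext = ".blow5")
  flipped <- bytes; flipped[2] <- as.raw(0)
  writeBin(flipped, bad_magic)
  qc <- quickcheck(bad_magic)
  expect_false(qc$ok)
  expect_match(qc$defect, "magic")

  bad_frame <- tempfile(fileext = ".blow5")
  h <- open_blow5(f); ds <- h$data_start; blow5_close(h)
  corrupted <- bytes
  corrupted[(ds + 5):(ds + 12)] <- as.raw(rep(0xAA, 8))
  writeBin(corrupted, bad_frame)
  qc <- quickcheck(bad_frame)
  expect_false(qc$ok)
  expect_match(qc$defect, "record parse failure")
})

test_that("skim prints exactly the requested components", {
  dat <- small_dataset()
  f <- write_temp_blow5(dat)
  ids <- slow5_skim(f, "read_ids_only")
  expect_identical(ids, read_ids_of(dat$records))

  hdr_lines <- slow5_skim(f, "header_only")
  expect_identical(hdr_lines, slow5r:::slow5_header_lines(read_blow5(f)$header))

  cols <- slow5_skim(f, c("read_id", "len_raw_signal"))
  parts <- strsplit(cols, "\t", fixed = TRUE)
  expect_identical(vapply(parts, `[`, character(1), 1), ids)
  expect_identical(vapply(parts, `[`, character(1), 2),
                   vapply(dat$records, function(r) sprintf("%d", r$len_raw_signal),
                          character(1)))

  err <- tryCatch(slow5_skim(f, "no_such_column"), error = function(e) e)
  expect_s3_class(err, "slow5_usage")
  expect_match(conditionMessage(err), "read_id")
})

test_that("toolkit outputs are deterministic and worker-count independent", {
  fx <- two_run_fixture()
  bytes_of <- function(p) readBin(p, "raw", file.size(p))
  m1 <- tempfile(fileext = ".blow5"); m2 <- tempfile(fileext = ".blow5")
  slow5_merge(c(fx$f1, fx$f2), m1, threads = 1L, batch_size = 2L)
  slow5_merge(c(fx$f1, fx$f2), m2, threads = 8L, batch_size = 4096L)
  expect_identical(bytes_of(m1), bytes_of(m2))

  v1 <- tempfile(fileext = ".blow5"); v2 <- tempfile(fileext = ".blow5")
  slow5_view(fx$f1, v1, threads = 1L)
  slow5_view(fx$f1, v2, threads = 8L)
  expect_identical(bytes_of(v1), bytes_of(v2))

  g1 <- tempfile(fileext = ".slow5"); g2 <- tempfile(fileext = ".slow5")
  ids <- read_ids_of(fx$d1$records)[c(3, 1, 7)]
  slow5_get(fx$f1, ids, output = g1, threads = 1L)
  slow5_get(fx$f1, ids, output = g2, threads = 8L)
  expect_identical(bytes_of(g1), bytes_of(g2))
})

test_that("the command-line dispatcher drives the toolkit end to end", {
  dat <- small_dataset()
  src <- tempfile(fileext = ".slow5")
  write_slow5(dat$header, dat$records, src)
  out <- tempfile(fileext = ".blow5")
  expect_identical(slow5r_cli(c("view", src, "-o", out)), 0L)
  expect_records_equal(dat$records, read_blow5(out)$records)
  expect_identical(slow5r_cli(c("index", out)), 0L)
  expect_identical(slow5r_cli(c("quickcheck", out)), 0L)
  expect_identical(slow5r_cli(c("quickcheck", src)), 0L)
  expect_identical(slow5r_cli(c("frobnicate")), 1L)
  # get via CLI prints SLOW5 text for the requested ids
  id <- dat$records[[2]]$read_id
  txt <- capture.output(status <- slow5r_cli(c("get", out, id)))
  expect_identical(status, 0L)
  expect_match(tail(txt, 1), paste0("^", id, "\t"))
})
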