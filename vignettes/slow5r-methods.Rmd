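---
title: "Nanopore signal data management with slow5r: formats, codecs and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanopore signal data management with slow5r}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slow5r)
```

## The problem

Oxford Nanopore (ONT) devices measure ionic current through a protein pore
as a DNA or RNA strand translocates it, and store that raw signal — a time
series of signed 16-bit ADC samples per read — in HDF5-based FAST5
containers. FAST5 is awkward for high-throughput analysis: it is larger
than it needs to be, every access goes through the HDF5 library, and that
library serialises thread-based I/O. slow5r implements an alternative pair
of representations and the surrounding data-management toolkit:

* **SLOW5**, a tab-separated ASCII form with a metadata header, readable by
  eye and by any text tooling;
* **BLOW5**, a compact binary container with two independent compression
  layers and an accompanying byte-offset index for single-seek random
  access.

Every operation a user needs around these formats is provided as an R
function and a CLI subcommand: lossless FAST5 conversion in both
directions (`f2s`/`s2f`, including live conversion of a running
experiment's output directory), `merge`/`cat`/`split` for reorganising
datasets, `index`/`get` for random access, `view` for format and
compression conversion, and `stats`/`quickcheck`/`skim` for inspection.

## Data model

A record carries the primary attributes `read_id`, `read_group`,
`digitisation`, `offset`, `range`, `sampling_rate`, `len_raw_signal` and
`raw_signal`, plus optional typed auxiliary attributes (channel number,
acquisition start time, ...) governed by a per-file schema. The calibration
scalars convert ADC counts to picoamperes:

$$pA_i = (raw_i + \mathrm{offset}) \times \mathrm{range} / \mathrm{digitisation}$$

with `sampling_rate` (Hz) converting sample index to time. `signal_to_pA()`
applies this; a non-positive digitisation is a calibration error, not a
silent NaN.

A *read group* is the set of reads sharing one acquisition run's metadata;
the file header holds one attribute map per group and each record carries a
group index. The auxiliary type system is closed (13 tags, from `int8` to
`int16_array`): an unknown tag is a parse error, because a value that
cannot be re-serialised would break the lossless round-trip contract.
Every type has an explicit missing marker (`.` in ASCII; a reserved
sentinel per type in binary — see `inst/format.md`), since FAST5 inputs may
lack fields per read. Read-id uniqueness is deliberately *not* a record
invariant — a streaming writer cannot check it globally — and is enforced
only at index construction, where duplicates are an error.

## Compression

BLOW5 compresses on two independent layers, all six combinations legal:

* **record layer** (`none`, `zlib`, `zstd`): the serialised record payload
  is compressed as one block. zlib (RFC 1950) is the default for
  compatibility; zstd is faster and usually smaller. Codec default levels
  are used and the level is not persisted — decompression is
  level-agnostic.
* **signal layer** (`none`, `svb-zd`): the raw signal inside the payload is
  delta-transformed, zig-zag mapped and packed with stream variable byte
  (svb). Nanopore current is locally flat with occasional jumps, so
  successive deltas are small and most samples fit in one byte; svb stores
  each value in 1–4 bytes with 2-bit length codes packed four to a control
  byte.

Three svb-zd details are fixed here for determinism, since reasonable
implementations could differ:

* samples are widened to 32 bits *before* the delta, so a delta spanning
  the int16 extremes (magnitude up to 65535) cannot overflow;
* the first delta is the first sample itself (`d0 = s0`) — one uniform
  stream, no separate starting value;
* control-byte fields are packed low bits first (value *i* at bits
  `2*(i mod 4)`).

The decoder is strict: truncated control or data blocks, decoded samples
outside int16, and trailing bytes are all corrupt-signal errors. Encoded
size for a signal whose zig-zagged deltas all fit one byte is exactly
`ceil(n/4) + n` bytes, which the tests assert; byte-level interoperability
with externally produced files is not claimed (the package's own layout is
normative and documented in `inst/format.md`).

The record payload puts the length-prefixed `read_id` first. That ordering
is what makes index construction cheap: zlib supports incremental
inflation, so `peek_read_id()` produces only as many decompressed bytes as
the read_id needs (one 4-KiB inflater buffer in practice, regardless of
signal size). zstd has no partial decompression, so peeking falls back to
full decompression — same result, different cost, and the tests assert the
two index routes are byte-identical.

## Container and index

A BLOW5 file is: 8 magic bytes, two method bytes, a length-prefixed
*uncompressed* SLOW5-text header block, contiguous length-prefixed record
frames, and an 8-byte EOF marker whose absence distinguishes truncation
from normal end-of-stream. The header block is stored uncompressed for
simplicity — it is a few hundred bytes against megabytes of signal, and it
keeps `cat` and `quickcheck` trivial. Frames are the batch unit:
`next_batch()` (default 4096 frames, a compromise between call overhead and
memory that the container does not record) returns raw frames plus offsets
so a consumer can decompress them independently and still reproduce the
linear stream.

The `.idx` sidecar maps read_id to frame offset *and length* — offsets
alone would force a fetch to read the next length prefix speculatively;
with the length, `fetch_by_read_id()` is exactly one seek and one bounded
read. Staleness is detected by the recorded source-file byte size rather
than modification times, which are not trustworthy across file systems.
ASCII SLOW5 files are indexable too, with line-granular offsets.

## Toolkit semantics

All commands obey three contracts asserted throughout the tests: records
are conserved (never created, dropped or reordered except as documented),
output is a deterministic function of input (reruns are byte-identical),
and worker/batch parameters never change output bytes. Parallelism is thus
a *contract*, not a mechanism: the `threads`/`workers` arguments partition
work (and are honoured in the conversion manifest) but execution is
sequential — an implementation is free to add real concurrency so long as
output identity holds.

Design points that were genuinely open and are fixed here:

* **merge** unifies source read groups whose attribute maps are equal after
  completion to the union key set (absent keys become `""`), numbering new
  groups in first-encounter order; equality of completed maps is the
  deterministic, metadata-driven identity test. Merge never deduplicates
  read_ids — conservation is safer, and duplicates surface at index time.
* **cat** requires byte-identical header blocks and compression specs and
  concatenates frame regions verbatim; anything less similar is refused
  (`merge` is the right tool there). Mixed compression specs are refused
  for the same reason.
* **split** chunk modes (`reads_per_file`, `file_count`) require a
  single-group input; balanced chunks put the larger pieces first; output
  names are the input stem plus a zero-padded ordinal.
* **get** returns records in *request* order (duplicates included), and
  builds a missing index on demand rather than erroring.
* **stats** scans frames through a 128-KiB buffer and decompresses only the
  payload prefix up to `read_group` (fully only under zstd).
* **quickcheck** verifies magic, header parse, first-frame parse and EOF
  marker — structural soundness without reading every record.

## FAST5 bridge

HDF5 I/O is delegated to a bundled python helper (`inst/python/fast5_io.py`,
using h5py), with the SLOW5 ASCII form as the exchange format, so every
format decision lives in one place. The mapping for multi-read FAST5:
calibration attributes under `channel_id` become primary fields;
`tracking_id`/`context_tags` attributes become header group attributes with
their group name as a key prefix (which is what lets `s2f` restore them to
the right HDF5 location); remaining per-read attributes become auxiliary
fields, with types inferred from their HDF5 dtypes. `s2f` writes one file
per read group, re-batched at 4000 reads per file — the MinKNOW default.
Array-typed auxiliary fields have no native FAST5 home and go under a
reserved `aux/` subgroup with a warning, never dropped. Records convert in
lexicographic read_id order (HDF5 iteration order); comparisons that span
a conversion therefore sort by read_id first.

Only the multi-read FAST5 layout is supported; single-read (legacy) files
and VBZ-plugin-compressed signal datasets are documented extension points.

Live conversion (`watch_and_convert()`) polls the run directory rather
than using kernel notification — the contract is detection and FIFO
queueing, not the mechanism, and polling is portable. A file is considered
complete when its size is unchanged across two polls (the default interval
is 5 s; acquisition software closes each batch file when done). At most
`max_workers` conversions run per cycle. With deletion enabled, a source
file is removed only after its output passes `quickcheck()` *and* a
record-count match; a corrupted input is logged as failed and never
deleted.

## Synthetic data

The generator (`synthetic_config()`, `generate_records()`,
`generate_fast5_dataset()`) is the single source of ground truth in the
tests: toolkit checks compare against generator-known counts and values,
never against recorded snapshots. It emulates the *structure* of MinKNOW
output — batches of reads per FAST5 file (default 4000), one metadata map
per run, 16-bit signals, occasional missing auxiliary values (5% of
`median_before` by default) — with a random-walk signal model
(baseline 500 ADC, step s.d. 2) punctuated by rare level shifts
(probability 0.002/sample, magnitude ~120), clipped to int16. That shape
is what makes delta-based compression meaningful to test: pure white noise
would make svb-zd look pointless and constant signals compress trivially.
Default signal lengths are drawn uniformly from 1000–3000 samples, and the
FAST5/whole-file test fixtures use lengths of a few hundred samples: these
are desk-scale choices so the suite exercises thousands of reads in
minutes, not a claim about real read durations. What the generator does
*not* emulate: realistic pore physics, base-caller-compatible signal
statistics, event-level structure, or the long-tailed read-length
distributions of real runs — so passing tests demonstrate format and
toolkit correctness, not analysis-ready realism.

Problem sizes used by the end-to-end property checks: 1000 records for the
full compression matrix and random access, 10000 for split arithmetic,
9000 reads across three 4000-read FAST5 files for the conversion round
trip, 100 random truncations for integrity checking, and 100 reads of 5000
samples for the compression-direction check.

## Numerical and degenerate-input choices

* Floating-point fields cross the ASCII boundary via the shortest decimal
  string that parses back bit-exactly, so ASCII round trips are lossless
  and files are byte-stable (header attributes are emitted in sorted key
  order for the same reason).
* 64-bit integer auxiliary values are held as R doubles: exact below
  2^53, which covers every field the bridge maps; the reserved sentinels
  are handled as explicit byte patterns.
* Empty signals are legal everywhere (zero-length encoding, `.` in the
  ASCII signal column); empty *strings*, literal `"."` strings and empty
  arrays are representable only in the binary form — the ASCII writer
  renders them as missing, a documented dialect limit.
* A record failing validation aborts a write with a classed error;
  partial output is possible and documented, matching stream-writer
  reality.
* Truncation anywhere in a BLOW5 file is detected: mid-frame by length
  bookkeeping, at end-of-file by the missing EOF marker.

## A worked example

```{r example}
cfg <- synthetic_config(seed = 7, n_reads = 50, signal_len = c(500, 1500))
dat <- generate_records(cfg)

blow5 <- file.path(tempdir(), "example.blow5")
write_blow5(dat$header, dat$records, blow5)
slow5_stats(blow5)

build_index(blow5)
idx <- load_index(blow5)
rec <- fetch_by_read_id(blow5, idx, dat$records[[10]]$read_id)
head(signal_to_pA(rec))
```

## Known limitations

* No claim of byte compatibility with externally maintained SLOW5/BLOW5
  implementations; this package's layout is self-consistent and documented.
* The FAST5 bridge requires a python interpreter with h5py on the PATH and
  supports the multi-read layout only.
* `merge` completes attribute maps to the union key set before comparing;
  two groups that differ only by an absent-vs-empty attribute are
  therefore unified.
* Range queries and positional (n-th record) access are out of scope for
  the index; it answers read_id lookups only.
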