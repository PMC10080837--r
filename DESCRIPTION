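Package: slow5r
Title: Reading, Writing and Managing Nanopore Raw Signal Data in SLOW5/BLOW5 Format
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with raw nanopore current signal data in the
    tab-separated SLOW5 format and its compressed binary counterpart BLOW5.
    Provides lossless conversion between multi-read FAST5 (HDF5), SLOW5 and
    BLOW5; two-layer record compression (zlib or zstd on the record, delta
    zig-zag stream-variable-byte encoding on the signal); a read_id byte-offset
    index for single-seek random access; and dataset operations to merge,
    concatenate, split, query, summarise and integrity-check signal files,
    including real-time conversion of a live sequencing run directory. A seeded
    synthetic-data generator emulating MinKNOW output batches makes the whole
    toolkit testable without any real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
SystemRequirements: zlib, zstd; FAST5 conversion additionally requires a
    python3 interpreter with h5py and numpy on the PATH.
Config/testthat/edition: 3
RoxygenNote: 7.3.3
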