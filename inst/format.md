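# slow5r on-disk formats

This file is the normative byte-level description of the files this package
writes. All multi-byte integers are little-endian.

## SLOW5 (ASCII, `.slow5`)

Tab-separated text, `\n` line endings (`\r\n` tolerated on read):

```
#slow5_version<TAB><version>
#num_read_groups<TAB><G>
@<key><TAB><value for group 0><TAB>...<TAB><value for group G-1>   (0+ lines)
#<type tags for the 8 primary columns, then one per auxiliary column>
#read_id<TAB>read_group<TAB>digitisation<TAB>offset<TAB>range<TAB>sampling_rate<TAB>len_raw_signal<TAB>raw_signal<TAB><aux names...>
<one data row per record>
```

* Primary column type tags are fixed:
  `string uint32 double double double double uint64 int16_array`.
* Auxiliary type tags form a closed set:
  `int8 int16 int32 int64 uint8 uint16 uint32 uint64 float double char
  string int16_array`. An unknown tag is a parse error.
* `raw_signal` and `int16_array` values are comma-separated integers.
* `.` is the missing-value token. Consequently an empty string, a literal
  `"."` string/char value and a zero-length array are not representable in
  the ASCII form (the binary form has no such limits). A record with
  `len_raw_signal` 0 writes `.` in the `raw_signal` column.
* Floating-point values are written with the shortest decimal string that
  parses back to the identical double.
* Metadata (`@`) lines are emitted in lexicographic key order; readers
  accept any order. Writing the same data twice is byte-identical.

## BLOW5 (binary, `.blow5`)

```
offset 0   8 bytes   magic: 42 4C 4F 57 35 0A 01 00  ("BLOW5\n", 0x01, 0x00)
offset 8   1 byte    record-layer method: 0 none, 1 zlib, 2 zstd
offset 9   1 byte    signal-layer method: 0 none, 1 svb-zd
offset 10  4 bytes   uint32 header block length H
offset 14  H bytes   header block: the SLOW5 ASCII header lines, uncompressed,
                     with a trailing newline
...                  record frames, contiguous
last 8     8 bytes   EOF marker: "EOF5WOLB"
```

A record frame is a `uint32` payload byte length followed by the payload,
compressed with the record-layer method (`none` = stored as-is; `zlib` =
RFC 1950 stream; `zstd` = RFC 8878 frame; codec default levels, level not
recorded).

### Record payload (before record-layer compression)

```
uint16   read_id byte length L
L bytes  read_id (ASCII)
uint32   read_group
float64  digitisation
float64  offset
float64  range
float64  sampling_rate
uint64   len_raw_signal (sample count N)
signal   signal method none:   2*N bytes, int16 little-endian samples
         signal method svb-zd: uint64 encoded byte length, then the encoding
aux      one value per auxiliary schema column, in schema order
```

The read_id leads the payload so that it can be recovered by partially
inflating a zlib stream (index construction); zstd requires full
decompression.

### svb-zd signal encoding

1. widen each int16 sample to int32;
2. delta transform: `d[0] = s[0]`, `d[i] = s[i] - s[i-1]`;
3. zig-zag map to uint32: `z = (d << 1) XOR (d >> 31)` (arithmetic shift);
4. stream variable byte: `ceil(N/4)` control bytes, each holding four 2-bit
   fields — value `i`'s field occupies bits `2*(i mod 4)` .. `2*(i mod 4)+1`
   (low bits first) and stores its byte length minus 1; then every value's
   1–4 data bytes, little-endian, concatenated in order.

An empty signal encodes to zero bytes.

### Auxiliary value encoding and missing-value sentinels

| type        | encoding                          | missing sentinel          |
|-------------|-----------------------------------|---------------------------|
| int8/16/32/64  | two's complement, 1/2/4/8 bytes | type minimum              |
| uint8/16/32/64 | 1/2/4/8 bytes                   | type maximum              |
| float / double | IEEE-754, 4/8 bytes             | NaN                       |
| char        | 1 byte                            | 0x00                      |
| string      | uint64 length + bytes             | all-ones length prefix    |
| int16_array | uint64 element count + int16s     | all-ones length prefix    |

Sentinel values are reserved: they are not representable as data.

## Index sidecar (`.idx`)

```
8 bytes   magic "SLOW5IDX"
uint64    byte size of the indexed data file at build time (staleness check)
uint64    entry count
entries   uint16 read_id length, read_id bytes, uint64 offset, uint64 length
```

For BLOW5, `offset` addresses a frame's first length byte and `length`
covers the length prefix plus compressed payload; entry extents tile the
frame region exactly. For ASCII SLOW5, `offset` addresses a data line start
and `length` includes the trailing newline.
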