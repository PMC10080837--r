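#!/usr/bin/env python3
"""HDF5 plumbing for the slow5r package.

Converts between multi-read FAST5 (HDF5) files and the package's SLOW5
ASCII dialect, which serves as the exchange format with R. Layout written
and expected (one read group per file, as MinKNOW produces):

  /<file> attrs: file_version
  /read_<read_id>/ attrs: run_id
      Raw/Signal            int16 dataset
      Raw attrs             read_id + auxiliary per-read attributes
      channel_id attrs      digitisation, offset, range, sampling_rate,
                            channel_number
      tracking_id attrs     run metadata (slow5 header keys "tracking_id.*")
      context_tags attrs    acquisition tags (header keys "context_tags.*")
      aux/<name>            int16 datasets for array-typed auxiliary fields
                            (reserved location for fields with no native
                            FAST5 home)

Usage:
  fast5_io.py f2s <in.fast5> <out.slow5>
  fast5_io.py s2f <in.slow5> <out_dir> <stem> <reads_per_file>
"""

import sys

import h5py
import numpy as np

MISSING = "."
PRIMARY_TYPES = ["string", "uint32", "double", "double", "double", "double",
                 "uint64", "int16_array"]
PRIMARY_FIELDS = ["read_id", "read_group", "digitisation", "offset", "range",
                  "sampling_rate", "len_raw_signal", "raw_signal"]
CALIBRATION = ["digitisation", "offset", "range", "sampling_rate"]
# canonical auxiliary column order; unknown extras follow alphabetically
AUX_PRIORITY = ["channel_number", "median_before", "read_number", "start_mux",
                "start_time"]

NUMPY_TO_TAG = {
    "int8": "int8", "int16": "int16", "int32": "int32", "int64": "int64",
    "uint8": "uint8", "uint16": "uint16", "uint32": "uint32", "uint64": "uint64",
    "float32": "float", "float64": "double",
}
TAG_TO_NUMPY = {
    "int8": np.int8, "int16": np.int16, "int32": np.int32, "int64": np.int64,
    "uint8": np.uint8, "uint16": np.uint16, "uint32": np.uint32,
    "uint64": np.uint64, "float": np.float32, "double": np.float64,
}


def to_str(v):
    if isinstance(v, bytes):
        return v.decode("ascii")
    return str(v)


def tag_of(value):
    if isinstance(value, (bytes, str)):
        return "string"
    if isinstance(value, np.ndarray):
        return "int16_array"
    name = np.asarray(value).dtype.name
    if name in NUMPY_TO_TAG:
        return NUMPY_TO_TAG[name]
    raise SystemExit(f"unsupported FAST5 attribute dtype: {name}")


def fmt(value, tag):
    if value is None:
        return MISSING
    if tag in ("float", "double"):
        return repr(float(value))
    if tag == "string":
        s = to_str(value)
        return s if s else MISSING
    if tag == "int16_array":
        a = np.asarray(value, dtype=np.int16)
        return ",".join(str(int(x)) for x in a) if a.size else MISSING
    return str(int(value))


def parse(token, tag):
    if token == MISSING:
        return None
    if tag in ("float", "double"):
        return float(token)
    if tag == "string":
        return token
    if tag == "int16_array":
        return np.array([int(x) for x in token.split(",")], dtype=np.int16)
    return int(token)


def f2s(fast5_path, out_path):
    with h5py.File(fast5_path, "r") as f:
        read_names = sorted(k for k in f.keys() if k.startswith("read_"))
        if not read_names:
            raise SystemExit(f"malformed FAST5 '{fast5_path}': no read groups")
        header = {}
        reads = []
        aux_tags = {}
        for rn in read_names:
            g = f[rn]
            read_id = rn[len("read_"):]
            if "Raw" not in g or "Signal" not in g["Raw"]:
                raise SystemExit(
                    f"malformed FAST5 '{fast5_path}': read {read_id} has no Raw/Signal")
            if "channel_id" not in g:
                raise SystemExit(
                    f"malformed FAST5 '{fast5_path}': read {read_id} has no channel_id")
            ch = g["channel_id"].attrs
            for c in CALIBRATION:
                if c not in ch:
                    raise SystemExit(
                        f"malformed FAST5 '{fast5_path}': read {read_id} lacks {c}")
            if not header:
                for grp, prefix in (("tracking_id", "tracking_id."),
                                    ("context_tags", "context_tags.")):
                    if grp in g:
                        for k, v in g[grp].attrs.items():
                            header[prefix + k] = to_str(v)
            sig = np.asarray(g["Raw"]["Signal"][()], dtype=np.int16)
            aux = {}
            for k, v in g["Raw"].attrs.items():
                if k == "read_id":
                    continue
                aux[k] = v
            for k, v in ch.items():
                if k not in CALIBRATION:
                    aux[k] = v
            if "aux" in g:
                for k in g["aux"].keys():
                    aux[k] = np.asarray(g["aux"][k][()], dtype=np.int16)
            for k, v in aux.items():
                aux_tags.setdefault(k, tag_of(v))
            reads.append((read_id, float(ch["digitisation"]), float(ch["offset"]),
                          float(ch["range"]), float(ch["sampling_rate"]), sig, aux))

    aux_names = [k for k in AUX_PRIORITY if k in aux_tags]
    aux_names += sorted(k for k in aux_tags if k not in AUX_PRIORITY)
    with open(out_path, "w", newline="\n") as out:
        out.write("#slow5_version\t1.0\n#num_read_groups\t1\n")
        for k in sorted(header):
            out.write(f"@{k}\t{header[k]}\n")
        out.write("#" + "\t".join(PRIMARY_TYPES + [aux_tags[k] for k in aux_names]) + "\n")
        out.write("#" + "\t".join(PRIMARY_FIELDS + aux_names) + "\n")
        for read_id, dig, off, rng, rate, sig, aux in reads:
            row = [read_id, "0", repr(dig), repr(off), repr(rng), repr(rate),
                   str(sig.size),
                   ",".join(str(int(x)) for x in sig) if sig.size else MISSING]
            row += [fmt(aux.get(k), aux_tags[k]) for k in aux_names]
            out.write("\t".join(row) + "\n")
    print(len(reads))


def read_slow5_text(path):
    with open(path) as fh:
        lines = [ln.rstrip("\n").rstrip("\r") for ln in fh]
    if not lines or not lines[0].startswith("#slow5_version\t"):
        raise SystemExit(f"'{path}': missing version line")
    n_groups = int(lines[1].split("\t")[1])
    attrs = {}
    i = 2
    while i < len(lines) and lines[i].startswith("@"):
        parts = lines[i][1:].split("\t")
        while len(parts) < n_groups + 1:
            parts.append("")
        attrs[parts[0]] = parts[1:]
        i += 1
    types = lines[i][1:].split("\t")
    names = lines[i + 1][1:].split("\t")
    if names[:8] != PRIMARY_FIELDS:
        raise SystemExit(f"'{path}': unexpected primary columns")
    schema = list(zip(names[8:], types[8:]))
    reads = []
    for ln in lines[i + 2:]:
        fields = ln.split("\t")
        n = int(fields[6])
        sig = (np.array([int(x) for x in fields[7].split(",")], dtype=np.int16)
               if n else np.array([], dtype=np.int16))
        if sig.size != n:
            raise SystemExit(f"'{path}': signal length mismatch for {fields[0]}")
        aux = {name: parse(tok, tag)
               for (name, tag), tok in zip(schema, fields[8:])}
        reads.append({
            "read_id": fields[0], "read_group": int(fields[1]),
            "digitisation": float(fields[2]), "offset": float(fields[3]),
            "range": float(fields[4]), "sampling_rate": float(fields[5]),
            "signal": sig, "aux": aux,
        })
    return n_groups, attrs, schema, reads


def s2f(slow5_path, out_dir, stem, reads_per_file):
    import os
    n_groups, attrs, schema, reads = read_slow5_text(slow5_path)
    tags = dict(schema)
    written = []
    for grp in range(n_groups):
        tracking = {k[len("tracking_id."):]: v[grp] for k, v in attrs.items()
                    if k.startswith("tracking_id.")}
        context = {k[len("context_tags."):]: v[grp] for k, v in attrs.items()
                   if k.startswith("context_tags.")}
        # unprefixed header attributes have no better FAST5 home than tracking_id
        tracking.update({k: v[grp] for k, v in attrs.items() if "." not in k})
        mine = [r for r in reads if r["read_group"] == grp]
        batches = [mine[b:b + reads_per_file] for b in range(0, len(mine), reads_per_file)]
        width = max(1, len(str(max(len(batches) - 1, 0))))
        for bi, batch in enumerate(batches):
            gtag = f"_g{grp}" if n_groups > 1 else ""
            path = os.path.join(out_dir, f"{stem}{gtag}_{bi:0{width}d}.fast5")
            with h5py.File(path, "w") as f:
                f.attrs["file_version"] = np.bytes_(b"2.2")
                for r in batch:
                    g = f.create_group(f"read_{r['read_id']}")
                    g.attrs["run_id"] = np.bytes_(tracking.get("run_id", "").encode())
                    raw = g.create_group("Raw")
                    raw.create_dataset("Signal", data=r["signal"], dtype=np.int16,
                                       track_times=False)
                    raw.attrs["read_id"] = np.bytes_(r["read_id"].encode())
                    ch = g.create_group("channel_id")
                    ch.attrs["digitisation"] = np.float64(r["digitisation"])
                    ch.attrs["offset"] = np.float64(r["offset"])
                    ch.attrs["range"] = np.float64(r["range"])
                    ch.attrs["sampling_rate"] = np.float64(r["sampling_rate"])
                    tr = g.create_group("tracking_id")
                    for k, v in tracking.items():
                        tr.attrs[k] = np.bytes_(v.encode())
                    ct = g.create_group("context_tags")
                    for k, v in context.items():
                        ct.attrs[k] = np.bytes_(v.encode())
                    auxg = None
                    for name, value in r["aux"].items():
                        if value is None:
                            continue
                        tag = tags[name]
                        if name == "channel_number":
                            ch.attrs["channel_number"] = np.bytes_(str(value).encode())
                        elif tag == "int16_array":
                            if auxg is None:
                                auxg = g.create_group("aux")
                                print(f"note: array field '{name}' stored under "
                                      f"reserved aux/ group", file=sys.stderr)
                            auxg.create_dataset(name, data=value, dtype=np.int16,
                                                track_times=False)
                        elif tag in ("string", "char"):
                            raw.attrs[name] = np.bytes_(str(value).encode())
                        else:
                            raw.attrs[name] = TAG_TO_NUMPY[tag](value)
            written.append(path)
    for p in written:
        print(p)


def main(argv):
    if len(argv) < 2:
        raise SystemExit(__doc__)
    cmd = argv[1]
    if cmd == "f2s":
        f2s(argv[2], argv[3])
    elif cmd == "s2f":
        s2f(argv[2], argv[3], argv[4], int(argv[5]))
    else:
        raise SystemExit(f"unknown command '{cmd}'")


if __name__ == "__main__":
    main(sys.argv)
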