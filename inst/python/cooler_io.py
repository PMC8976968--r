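"""Minimal cooler (HDF5) container backend.

Invoked by the R package through system2(); not a public interface.
Supports single-resolution .cool files and multi-resolution .mcool
containers (read-only), and writes single-resolution .cool files.

Commands:
  info   <path> [resolution]
      -> JSON on stdout: binsize, chroms, nbins, has_weights, resolutions
  dump   <path> <resolution|-> <chrom1> <chrom2|-> <balanced:0|1> <out.bin>
      -> binary file: int64 nrow, int64 ncol, float64 row-major values
         (NaN marks missing entries of a balanced matrix)
  create <out.cool> <meta.json> <pixels.bin>
      meta.json: {"binsize": int, "chroms": [{"name","length"}...],
                  "weights": [float|null ...] (optional)}
      pixels.bin: int64 n, then n int64 bin1_id, n int64 bin2_id,
                  n float64 count (upper-triangle, any order)

All validation failures print 'ERROR: <msg>' on stderr and exit 1.
"""
import json
import sys

import h5py
import numpy as np


def die(msg):
    sys.stderr.write("ERROR: %s\n" % msg)
    sys.exit(1)


def open_group(f, resolution):
    """Return the cooler data group for a single- or multi-res container."""
    if "bins" in f and "pixels" in f:
        return f
    if "resolutions" in f:
        avail = sorted(f["resolutions"].keys(), key=int)
        if resolution is None:
            die("multi-resolution container; a resolution must be given "
                "(available: %s)" % ", ".join(avail))
        if str(resolution) not in f["resolutions"]:
            die("resolution %s not in container (available: %s)"
                % (resolution, ", ".join(avail)))
        return f["resolutions"][str(resolution)]
    die("not a cooler container (no bins/pixels group)")


def chrom_table(grp):
    names = [n.decode() if isinstance(n, bytes) else str(n)
             for n in grp["chroms/name"][:]]
    lengths = [int(x) for x in grp["chroms/length"][:]]
    offsets = grp["indexes/chrom_offset"][:].astype(np.int64)
    return names, lengths, offsets


def cmd_info(path, resolution=None):
    with h5py.File(path, "r") as f:
        resolutions = None
        if "resolutions" in f and "bins" not in f:
            resolutions = sorted(int(r) for r in f["resolutions"].keys())
            if resolution is None:
                # info without a resolution: report container-level facts only
                print(json.dumps({"multires": True, "resolutions": resolutions}))
                return
        grp = open_group(f, resolution)
        names, lengths, offsets = chrom_table(grp)
        binsize = int(grp.attrs.get("bin-size", 0))
        if binsize == 0:
            # fall back to the first bin span
            binsize = int(grp["bins/end"][0] - grp["bins/start"][0])
        out = {
            "multires": resolutions is not None,
            "resolutions": resolutions,
            "binsize": binsize,
            "chroms": [{"name": n, "length": l}
                       for n, l in zip(names, lengths)],
            "nbins": int(offsets[-1]),
            "has_weights": "weight" in grp["bins"],
        }
        print(json.dumps(out))


def bin_range(names, offsets, chrom):
    if chrom not in names:
        die("chromosome '%s' not found in container (available: %s)"
            % (chrom, ", ".join(names)))
    i = names.index(chrom)
    return int(offsets[i]), int(offsets[i + 1])


def cmd_dump(path, resolution, chrom1, chrom2, balanced, out):
    with h5py.File(path, "r") as f:
        grp = open_group(f, resolution)
        names, lengths, offsets = chrom_table(grp)
        lo1, hi1 = bin_range(names, offsets, chrom1)
        if chrom2 == "-" or chrom2 == chrom1:
            lo2, hi2 = lo1, hi1
        else:
            lo2, hi2 = bin_range(names, offsets, chrom2)
        n1, n2 = hi1 - lo1, hi2 - lo2
        mat = np.zeros((n1, n2), dtype=np.float64)

        b1off = grp["indexes/bin1_offset"][:].astype(np.int64)
        b1 = grp["pixels/bin1_id"]
        b2 = grp["pixels/bin2_id"]
        cnt = grp["pixels/count"]

        def fill(rlo, rhi, clo, chi, transpose):
            s, e = int(b1off[rlo]), int(b1off[rhi])
            if e <= s:
                return
            r1 = b1[s:e].astype(np.int64)
            r2 = b2[s:e].astype(np.int64)
            v = cnt[s:e].astype(np.float64)
            keep = (r2 >= clo) & (r2 < chi)
            r1, r2, v = r1[keep], r2[keep], v[keep]
            if transpose:
                mat[r2 - clo, r1 - rlo] = v
            else:
                mat[r1 - rlo, r2 - clo] = v

        # pixels hold the upper triangle in global bin coordinates
        fill(lo1, hi1, lo2, hi2, transpose=False)
        fill(lo2, hi2, lo1, hi1, transpose=True)

        if balanced:
            if "weight" not in grp["bins"]:
                die("balanced values requested but no 'weight' column stored")
            w = grp["bins/weight"][:].astype(np.float64)
            w1 = w[lo1:hi1]
            w2 = w[lo2:hi2]
            mat = mat * w1[:, None] * w2[None, :]
            mat[np.isnan(w1), :] = np.nan
            mat[:, np.isnan(w2)] = np.nan

        with open(out, "wb") as fo:
            np.array([n1, n2], dtype="<i8").tofile(fo)
            mat.astype("<f8").tofile(fo)


def cmd_create(path, meta_path, pixels_path):
    with open(meta_path) as fm:
        meta = json.load(fm)
    binsize = int(meta["binsize"])
    names = [c["name"] for c in meta["chroms"]]
    lengths = np.array([int(c["length"]) for c in meta["chroms"]],
                       dtype="<i8")
    nbins_per = np.ceil(lengths / binsize).astype(np.int64)
    nbins = int(nbins_per.sum())
    chrom_offset = np.concatenate([[0], np.cumsum(nbins_per)]).astype("<i8")

    with open(pixels_path, "rb") as fp:
        n = int(np.fromfile(fp, dtype="<i8", count=1)[0])
        p1 = np.fromfile(fp, dtype="<i8", count=n)
        p2 = np.fromfile(fp, dtype="<i8", count=n)
        pv = np.fromfile(fp, dtype="<f8", count=n)
    if np.any(p2 < p1):
        die("pixels must be upper-triangle (bin1_id <= bin2_id)")
    order = np.lexsort((p2, p1))
    p1, p2, pv = p1[order], p2[order], pv[order]

    bin_chrom = np.repeat(np.arange(len(names), dtype="<i4"), nbins_per)
    starts = np.concatenate(
        [np.arange(k, dtype="<i8") * binsize for k in nbins_per])
    ends = np.minimum(starts + binsize, np.repeat(lengths, nbins_per))

    bin1_offset = np.searchsorted(p1, np.arange(nbins + 1)).astype("<i8")

    with h5py.File(path, "w") as f:
        f.attrs["format"] = "HDF5::Cooler"
        f.attrs["format-version"] = 3
        f.attrs["bin-type"] = "fixed"
        f.attrs["bin-size"] = binsize
        f.attrs["nchroms"] = len(names)
        f.attrs["nbins"] = nbins
        f.attrs["nnz"] = n
        f.attrs["storage-mode"] = "symmetric-upper"
        f.attrs["generated-by"] = "cooler_io.py"
        g = f.create_group("chroms")
        g.create_dataset("name", data=np.array(names, dtype="S64"))
        g.create_dataset("length", data=lengths)
        g = f.create_group("bins")
        g.create_dataset("chrom", data=bin_chrom)
        g.create_dataset("start", data=starts.astype("<i8"))
        g.create_dataset("end", data=ends.astype("<i8"))
        if meta.get("weights") is not None:
            w = np.array([np.nan if x is None else float(x)
                          for x in meta["weights"]], dtype="<f8")
            if len(w) != nbins:
                die("weights length %d != nbins %d" % (len(w), nbins))
            g.create_dataset("weight", data=w)
        g = f.create_group("pixels")
        g.create_dataset("bin1_id", data=p1)
        g.create_dataset("bin2_id", data=p2)
        g.create_dataset("count", data=pv)
        g = f.create_group("indexes")
        g.create_dataset("chrom_offset", data=chrom_offset)
        g.create_dataset("bin1_offset", data=bin1_offset)


def main(argv):
    if len(argv) < 2:
        die("no command given")
    cmd = argv[1]
    try:
        if cmd == "info":
            cmd_info(argv[2], None if len(argv) < 4 else argv[3])
        elif cmd == "dump":
            if len(argv) != 8:
                die("dump needs: path resolution chrom1 chrom2 balanced out")
            res = None if argv[3] == "-" else argv[3]
            cmd_dump(argv[2], res, argv[4], argv[5],
                     argv[6] not in ("0", "false"), argv[7])
        elif cmd == "create":
            cmd_create(argv[2], argv[3], argv[4])
        else:
            die("unknown command '%s'" % cmd)
    except OSError as e:
        die(str(e))


if __name__ == "__main__":
    main(sys.argv)
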