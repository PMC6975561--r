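# Deposited peak / LDEC / TAD lists

`reproduce_deposited_stats()` expects this directory to contain five BED
files exported from the study's deposited supplementary table of processed
NGS calls (sheets: all ERa peaks, persistent peaks, transient peaks, LDEC,
TADs), converted to plain BED (chrom, 0-based start, end):

- `all_peaks.bed`        — every +E2 ERa ChIP-seq peak
- `persistent_peaks.bed` — peaks present both with and without ligand
- `transient_peaks.bed`  — peaks present only after ligand
- `ldec.bed`             — ERa-signal-ranked super-enhancer (LDEC) regions
- `tads.bed`             — HiC TAD intervals (smallest overlapping TADs)

These are real-data downloads and are not shipped with the package; the
acceptance test over them stays red until the files are placed here.
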