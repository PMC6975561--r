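# ldec — ligand-dependent ERα enhancer cluster analysis

Estrogen receptor alpha (ERα) binds a small set of genomic sites even
without hormone. On estradiol (E2) stimulation, thousands of additional
*transient* sites appear, concentrated within ~20 kb of the pre-existing
*persistent* sites, and these grouped sites act as a transient regulatory
unit — a **ligand-dependent ERα enhancer cluster (LDEC)** — that loops
together in 3D, coincides with nuclear ERα condensates, and drives the
sharp 40-minute pulse of E2 target-gene transcription. `ldec` implements
the computational side of that analysis for epigenomics researchers
working with two-condition ChIP-seq peak sets:

- **Site classification** — partition −E2/+E2 peak lists into persistent,
  transient and −E2-unique sites (`classify_sites()`), and bin persistent
  sites into signal quantiles with the bottom two quartiles merged
  (`assign_quantiles()`).
- **Cluster calling** — single-linkage chaining of consecutive peaks
  within a gap `g` (default 20 kb), keeping chains of ≥ 3 sites
  (`call_clusters()`); the clustered fraction is compared against 100
  random draws of matched size from ERE-motif or DNase-hypersensitivity
  background lists, with an add-one empirical p-value
  (`null_clustering()`); signal decay away from the seed is profiled in
  two-site ordinal bins (`decay_profile()`).
- **Super-enhancer (LDEC) calling** — peaks stitched within 15 kb and
  rank-ordered by summed signal; with both axes scaled to [0, 1] the
  cutoff is the tangent point of a slope-1 line on the rank–signal curve,
  and regions above it are super-enhancers (`stitch_and_rank()`). LDECs
  are related to density clusters (`cluster_overlap_stats()`), TADs
  (`tad_containment()`) and nascent transcription in fixed promoter
  windows (`quantify_window_counts()`, `compare_groups()`).
- **3D contacts** — 5C forward×reverse primer matrices normalized against
  chr16 gene-desert control primers (`normalize_5c()`), binned over
  regions (`bin_contacts()`); ChIA-PET replicates merged by both-end
  anchor overlap (`merge_chiapet_replicates()`) and summarised as
  per-site interaction degrees (`interaction_degree()`);
  externally-supplied 100 kb chromatin-entropy bins compared across
  LDEC/non-LDEC groups (`entropy_group_compare()`).
- **Imaging** — immunoFISH enrichment ratio (spot mean / nucleus mean,
  colocalized at ≥ 1.4; `fish_enrichment()`), a random-ROI null inside
  nuclei (`random_roi_null()`), and FRAP recovery normalization with a
  mobile-fraction plateau (`frap_normalize()`, `frap_fit()`).
- **Synthetic data** — `simulate_peakscape()`, `simulate_contacts()` and
  `simulate_imaging()` generate every pipeline input at the study's scale
  with ground-truth labels, so the whole analysis is testable offline
  (see `vignette` source under `vignettes/`).

## Worked example

```r
library(ldec)
ps <- simulate_peakscape(sim_config(), seed = 7)   # study-scale inputs
cl <- classify_sites(ps$minus, ps$plus)
print(cl)
#> Site classification (overlap >= 1 bp)
#>   -E2 peaks: 6659  (+E2 peaks: 21784)
#>   persistent: 3779   -E2-unique: 2880   transient: 18005
cc <- call_clusters(label_plus_peaks(ps$plus, cl))
print(cc)
#> cluster_set: 1528 clusters (max_gap 20000 bp, min_sites 3, center distance)
#>   6938 of 21784 peaks clustered (31.8%)
se <- stitch_and_rank(ps$plus)
tad_containment(super_enhancers(se), ps$tads)$fraction_within
#> [1] 0.65
```

6659 unliganded peaks split into 3779 persistent and 2880 −E2-unique
sites; about 30% of the 21,784 +E2 peaks chain into ~1500 clusters
(random ERE draws of the same size give only ~8%), and roughly
two-thirds of the called super-enhancers sit inside a single TAD —
the same structure the wet-lab study reports.

The numbered drivers under `analysis/` run the full workflow
(`01_simulate.R` … `05_imaging.R`), printing what each step found and
writing its tables under `results/`.

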