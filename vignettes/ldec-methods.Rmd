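---
title: "Methods: identifying ligand-dependent ERα enhancer clusters"
author: "ldec package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying ligand-dependent ERα enhancer clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `ldec`, in the spirit of the methods sections that
accompany differential-expression or ordination packages: what each
procedure assumes, which knobs matter, and what the synthetic-data tests
do and do not demonstrate about real data.

## The biological model

Unliganded ERα marks a minority of its eventual binding repertoire
(*persistent* sites, recognisable by FOXA1 co-binding and retained
through hormone deprivation). Estradiol triggers thousands of additional
*transient* bindings that concentrate within tens of kilobases of the
persistent seeds. The package treats this as a one-dimensional point
process along the genome: persistent seeds with strong signal, transient
satellites whose binding strength decays with ordinal distance from the
seed, plus an unstructured background. The grouped sites behave as one
regulatory unit — an LDEC — visible independently as a signal-ranked
super-enhancer, as elevated 3D contact among member sites, and as an
ERα-dense punctum over the locus in imaging.

## Coordinates and I/O

All intervals are held in `GRanges` (1-based, closed) — one convention
everywhere inside the package. BED-family files (0-based, half-open) are
converted at the boundary and written back bit-exactly; 1-based inputs
such as 5C primer manifests and gene-model TSVs pass through unchanged.
Malformed lines are rejected with their line number; records with
`end <= start` are refused rather than silently fixed. Unsorted inputs
are sorted on load (idempotently); duplicate identical intervals are
kept, since the upstream peak caller defines the unit of observation.

## Site classification

A −E2 peak overlapping any +E2 peak by at least `min_overlap_bp`
(default 1 bp) is persistent; the remainder of the −E2 set is
−E2-unique; +E2 peaks with no −E2 partner are transient. The 1 bp
default is the permissive reading of "called in both conditions";
because peak boundaries come from the same caller in both conditions,
results are insensitive to this choice over any reasonable value, and
the parameter is exposed for sensitivity analysis. Persistent sites are
reported with their −E2 coordinates (they pre-exist the ligand); a −E2
peak overlapping several +E2 peaks is persistent once, and all its +E2
partners are removed from the transient set so nothing is counted twice.

Signal quantiles over persistent sites use empirical 25/50/75 percentile
cuts with the bottom two quartiles merged (Q1 = bottom half, Q2 =
50–75%, Q3 = top quarter), reflecting the low information content of the
weakest sites. Ties are resolved by a stable sort on (signal, chrom,
start) with boundary sites going to the lower quantile, making the
assignment deterministic; an all-identical signal vector is refused as
degenerate rather than assigned arbitrarily.

## Cluster calling and the randomized null

Clusters are single-linkage chains: walking each chromosome in order, a
peak joins the open chain when its distance to the previous peak is at
most `max_gap` (default 20 kb, with 5 and 10 kb used as robustness
checks); chains with at least `min_sites` (default 3) members are
emitted. Distance is center-to-center by default — peaks are ~200 bp
wide so the alternative edge-to-edge anchoring (`distance_mode =
"edge"`) differs only at the margin, but the choice must be fixed and
both are testable. Chaining is order-invariant and monotone: enlarging
`max_gap` never removes a peak from a cluster, and raising `min_sites`
never adds a cluster.

The null model draws `n_draw` sites uniformly *without replacement*
from a background list (genome-wide ERE motif matches, or DHS) and
re-runs the identical cluster caller, 100 times by default. The
empirical p-value uses the add-one correction `(1 + #{null ≥ observed})
/ (n_iter + 1)`, so 100 iterations can at best report p ≈ 0.0099, never
zero. The seed is a mandatory argument and is recorded in the result;
identical seeds reproduce the null draw exactly. The summary reports the
*mean* cluster count over iterations (the per-draw counts are also
returned, since a single representative draw is the other plausible
reading).

The decay profile anchors each persistent-containing cluster at its
strongest persistent member (the deterministic choice when a cluster has
several), indexes members by ordinal distance in both directions, and
pools two consecutive ordinals per bin — bin 0 is the seed, bin 1 the
first two neighbours each side, and so on — before averaging signal per
bin across clusters.

## Super-enhancer (LDEC) calling

Peaks are stitched when separated by at most 15 kb (the stitching
parameter of rank-ordering super-enhancer callers; no TSS exclusion is
applied since the analysis is transcription-factor- rather than
H3K27ac-based), and stitched regions are ranked ascending by summed
member signal. With ranks and signals both scaled to [0, 1], the cutoff
is where a slope-1 line is tangent to the rank–signal curve, found as
the rank minimising `scaled_signal − scaled_rank`; with ties the *last*
such rank is taken and only regions strictly above it are flagged super,
so the degenerate straight-line curve yields zero super-enhancers rather
than an arbitrary half. Fewer than three stitched regions, or an
all-equal signal vector, are errors: the elbow is undefined.

Association statistics are deliberately plain: direct overlap is ≥ 1 bp
between region spans; "within 100 kb" is edge-to-edge distance; TAD
containment requires the region fully inside a single TAD interval, and
when TAD definitions overlap the smallest containing TAD is recorded
(TAD callers at fine resolution emit nested domains, which is also why
mean lengths in the tens of kilobases are expected here). Gene response
uses fixed windows from 1 kb past the promoter-proximal end to 13 kb
into the gene body, mirrored for minus-strand genes; enhancer RNA is
counted in a ±1 kb window about the peak center with both strands
combined (the window size is configurable since only the strand
combination, not the extent, is canonical). Counting is
`sum(value × overlap_width)` and therefore exactly linear in the track.
Group comparisons are Wilcoxon rank-sum (unpaired) or signed-rank
(paired) via `stats::wilcox.test`.

## 5C normalization and ChIA-PET consensus

Each primer's efficiency factor is its mean raw count against the
gene-desert control primers of the opposite orientation. The default
normalization is the double ratio

    normalized(F, R) = raw(F, R) × mean(desert–desert) / (factor(F) × factor(R)),

which reduces to `raw / c` when every desert interaction equals `c` and
cancels multiplicative per-primer biases exactly: each factor is
proportional to its own primer's efficiency, and the desert–desert mean
restores the overall scale that the product counts twice. The
square-root variant `raw / sqrt(factor(F) × factor(R))` is provided as
`mode = "geometric"` but under-corrects — it removes only half of each
bias in log space — and is kept for sensitivity analysis only. Primers
with no positive desert coverage have an undefined factor and are
dropped with a warning; desert–desert cells are excluded from the
output. What normalization cannot remove is counting noise: at a
Poisson mean of 200 per cell the median per-cell relative error is
~5% from shot noise alone, so recovery of a planted truth matrix is
asserted on the systematic per-primer bias at that depth and per cell
only at higher depth. Binning sums normalized values over region pairs
and conserves mass by construction; primers outside every region are
reported, not silently dropped.

ChIA-PET replicates are merged with the both-end overlap rule (≥ 1 bp
per anchor, either anchor order — the behaviour of the standard
pair-to-pair intersection tool): a pair survives only if every replicate
contains a both-end match. Supported pairs from all replicates are then
clustered by both-end overlap with a union–find pass and each cluster is
reported once with its earliest-replicate coordinates and the cluster
size as support. This makes the consensus *set* independent of replicate
order and idempotent on its own output; the representative coordinates
do follow replicate order, which is why the symmetry guarantee is stated
up to both-end-overlap identity. A site's interaction degree is the
number of distinct consensus pairs touching it with at least one anchor.
Chromatin-entropy values per 100 kb bin are external inputs; the package
only partitions bins (LDEC / peak-but-no-LDEC / other) and tests the
distributions and the −E2→+E2 drops between groups.

## Imaging quantification

The FISH enrichment ratio is the mean protein-channel intensity inside
the spot divided by the mean over the corresponding nucleus, which makes
it invariant to per-cell illumination scale; colocalization is called at
ratio ≥ 1.4, with the boundary inclusive (the threshold defines
colocalized, so a ratio of exactly 1.4 qualifies). The random-ROI null
re-applies the identical ratio to circular ROIs placed uniformly at
positions where the disc fits wholly inside the nucleus mask; cells too
small for the ROI are skipped with a count. FRAP traces are normalized
per frame as `(ROI − background) / whole-cell`, rescaled to a pre-bleach
mean of 1 (at least three pre-bleach frames required), with the
unbleached-ROI curve carried through identically as the
acquisition-bleaching control. The recovery plateau — the mobile
fraction under complete bleaching — is the mean of the final 10% of
frames; a single-exponential fit `I(t) = I∞ − (I∞ − I₀)e^{−t/τ}`
(`frap_fit()`, Levenberg–Marquardt) is provided as the model-based
alternative and reports the classical mobile fraction
`(I∞ − I₀)/(1 − I₀)`.

## The synthetic-data generator

`sim_config()` encodes the study conditions as defaults, derived once
from the experiment's printed scale: 6659 unliganded peaks of which 3779
persist and 2880 are −E2-unique; 18,055 transient peaks; 1400 planted
clusters (700 seeded by a persistent site, 700 transient-only) whose
sizes average ~4.3 sites — the value implied by ~30% of ~21.8k peaks in
~1.5k clusters — with uniform background peaks contributing the further
~130 incidental chains expected analytically at that density, bringing
called clusters to the study's ~1500. Seed signal is lognormal (median
50, σ_log 0.4 — seeds are the strongest and least dispersed sites, which
is also what makes them recoverable as super-enhancers); transient
signal decays by a factor 0.7 per two-site ordinal bin with 0.2 σ_log
multiplicative noise; intra-cluster gaps are uniform on 1–18 kb so
planted clusters chain at the 20 kb rule. TADs are drawn to contain a
planted cluster 85% of the time (the called-super set dilutes this to
roughly the 70% containment the study reports, because incidental
background regions carry no planted TAD); background TAD lengths are
lognormal with median 58 kb. Induced genes peak at 40 min (fold 6) and
fall back by 160 min; ERE and DHS background lists are clumped point
processes (35% / 55% of sites in short chains) so random draws cluster
somewhat — as real motif and accessibility landscapes do — but far less
than the observed peaks. 5C counts are Poisson with lognormal per-primer
efficiencies (σ_log 0.3), a distance-decay baseline (exponent −1,
floored at 5% of the base rate), and a 2× intra-LDEC boost in +E2 only;
trans/desert cells sit at 10% of the base rate. ChIA-PET anchors prefer
persistent sites (weight 6; strongest-quartile 12) with three jittered,
subsampled replicates plus 10% noise pairs. Imaging tables plant a 2×
enrichment on LDEC loci in +E2 (σ_log 0.25) and FRAP traces a 0.6 mobile
fraction with τ = 15 s and 2% Gaussian noise.

A master seed spawns a deterministic child seed per output stream, so
any stage can be regenerated alone and two runs with the same seed are
identical byte for byte. Uniformly placed sites that collide with a peak
of an incompatible class are re-placed (count recorded in the truth
record), so planted class labels are exactly recoverable — which is what
the truth-recovery tests assert.

What the generator does *not* emulate: sequence content and motif
structure, mappability and blacklist artefacts, copy-number and
chromatin-state heterogeneity, peak-width variation, replicate structure
in ChIP-seq, distance-dependent ChIA-PET noise, or optical PSF effects.
Passing the synthetic battery therefore shows the *algorithms* are
correct under the assumed statistical structure, not that the biology of
a new dataset will match it.

## Problem sizes and runtime

Unit and property tests run on a scaled-down genome (4 chromosomes ×
40 Mb, 120 planted clusters) and on exhaustive toy cases — all C(20, 5)
background subsets for the null, all C(10, 5) rank splits for the exact
Wilcoxon check — chosen so the whole suite completes in a couple of
minutes; the study-scale generator (20 × 150 Mb, ~21.8k peaks, 200k
ERE / 150k DHS background sites) is exercised once per run and by
`scripts/acceptance.R`, which completes in a few minutes on one CPU
with the 100-iteration nulls included.

## Known limitations

- The overlap rule behind the published persistent/transient split is
  not stated in the source material; with ≥ 1 bp the deposited lists
  should reproduce, but `reproduce_deposited_stats()` exposes the
  parameter in case summit-distance matching is needed.
- The elbow cutoff, like all rank-ordering callers, is sensitive to the
  background signal distribution: a heavier high-signal tail among
  isolated sites pulls the cutoff down and admits more single-peak
  regions into the super set.
- The 5C desert normalization assumes desert contacts measure primer
  efficiency only (no real structure on the control region) and
  multiplicative biases; it does not model distance-dependent ligation
  noise.
- Entropy values are consumed, never computed; conclusions about
  chromatin mixing inherit whatever resolution and normalization the
  upstream source used.
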