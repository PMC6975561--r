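#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study inputs at the default (study-scale)
# conditions and write them out in standard formats under results/sim/.
# Every later step either reads these files or regenerates the same objects
# from the recorded seed (seed 7 throughout the workflow).

suppressPackageStartupMessages({
  library(ldec)
  library(GenomicRanges)
})

seed <- 7L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config()
ps <- simulate_peakscape(cfg, seed = seed)

write_peaks(ps$minus, file.path(out, "peaks_minusE2.bed"))
write_peaks(ps$plus, file.path(out, "peaks_plusE2.bed"))
write_peaks(ps$tads, file.path(out, "tads.bed"))
write_peaks(ps$ere, file.path(out, "background_ere.bed"))
write_peaks(ps$dhs, file.path(out, "background_dhs.bed"))
genes <- data.frame(chrom = as.character(seqnames(ps$genes)),
                    start = start(ps$genes), end = end(ps$genes),
                    strand = as.character(strand(ps$genes)),
                    name = mcols(ps$genes)$name,
                    gene_class = mcols(ps$genes)$gene_class)
write.table(genes, file.path(out, "genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.csv(ps$expression, file.path(out, "expression_timecourse.csv"),
          row.names = FALSE)
truth <- data.frame(name = ps$truth$sites$name,
                    site_class = ps$truth$sites$class,
                    cluster = ps$truth$sites$cluster)
write.csv(truth, file.path(out, "truth_site_classes.csv"),
          row.names = FALSE)

message(sprintf(
  "simulated %d -E2 and %d +E2 peaks on %d chromosomes (seed %d);",
  length(ps$minus), length(ps$plus), cfg$n_chrom, seed))
message(sprintf(
  "planted %d clusters (%d seeded by a persistent site), %d TADs, %d genes",
  length(ps$truth$cluster_spans),
  sum(mcols(ps$truth$cluster_spans)$seeded), length(ps$tads),
  length(ps$genes)))
message("wrote inputs under ", out)
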