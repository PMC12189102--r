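#!/usr/bin/env Rscript
# Breakpoint density in 100 kb bins; top-1% bins are INS/DEL hotspots,
# then cross-tabulated against QTL trait categories.
library(svscape)

layout <- read_genome_layout("results/cohort/genome.tsv")
vt <- read_vcf("results/filtered.vcf", layout = layout)
qtl <- read_bed("results/cohort/qtl.bed")
nonsnp <- vt_subset(vt, vt$variants$vtype != "SNP")

bins <- count_breakpoints(nonsnp, layout, bin_size = 1e5)
hs <- call_hotspots(bins, top_frac = 0.01, vt = nonsnp)
cat(nrow(hs), "hotspot bin(s) at threshold", attr(hs, "threshold_count"),
    "breakpoints (median bin:", median(bins$count), ")\n")
ov <- hotspot_qtl_overlap(hs, qtl)
print(ov)
write.table(bins, "results/bin_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(hs[names(hs) != "member_variants"], "results/hotspots.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ov, "results/hotspot_qtl_overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
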