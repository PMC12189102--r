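#!/usr/bin/env Rscript
# Hard-filter, proximity-deduplicate and cohort-filter the merged VCF,
# then stratify by size class.
library(svscape)

layout <- read_genome_layout("results/cohort/genome.tsv")
vt <- read_vcf("results/cohort/cohort.vcf", layout = layout)
thr <- filter_thresholds()

hf <- apply_hard_filters(vt, thr)
cat("hard filters removed", n_variants(vt) - n_variants(hf$variants),
    "records; per-rule tally:\n")
print(hf$tally[hf$tally > 0])

is_indel <- hf$variants$variants$vtype != "SNP" & hf$variants$variants$length <= 50
indels <- proximity_dedup(vt_subset(hf$variants, is_indel), thr$proximity_bp)
cat("proximity dedup removed", sum(is_indel) - n_variants(indels),
    "indels within", thr$proximity_bp, "bp of a higher-QUAL indel\n")

qc <- filter_cohort(merge_variant_tables(indels, vt_subset(hf$variants, !is_indel)), thr)
qc$variants$size_class <- ifelse(qc$variants$vtype == "SNP", "SNP",
                                 classify_size(qc$variants$length))
cat("cohort filters retained", n_variants(qc), "of", n_variants(vt), "records\n")
dir.create("results", showWarnings = FALSE)
write.table(qc$variants, "results/qc_variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_vcf(qc, "results/filtered.vcf", layout)
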