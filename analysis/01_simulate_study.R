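#!/usr/bin/env Rscript

# Stage 1: simulate the study with known truth.
#
# Generates the reference databases (mature miRNA; rRNA classes with
# 18S/5.8S/28S embedded in a 45S precursor; intron-carrying tRNA genes
# incl. a histidine tRNA; piRNA; other ncRNA), a single-contig
# mini-genome, a panel of small-RNA features with planted
# lineage x generation fold changes, NB counts for 4 lineages x
# F1-F3 x 4 sperm samples, per-sample FASTQ reads, and the 9-vs-9
# serum comparison with planted cross-species homologs.
#
# Outputs: FASTQ under scratch/sim/fastq (large, regenerated at run
# time), truth tables under results/sim/.

library(sncTrans)

cfg <- sim_config(seed = 1, depth = 5e4)
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
sim <- simulate_dataset(cfg, fastq_dir = "scratch/sim/fastq")

for (bt in unique(sim$refdb$refs$biotype)) {
  write_reference_fasta(sim$refdb$refs[sim$refdb$refs$biotype == bt, ],
                        sprintf("results/sim/ref_%s.fa", bt))
}
writeLines(c(">minigenome", sim$refdb$genome), "results/sim/minigenome.fa")
wt <- function(df, f) write.table(df, file.path("results/sim", f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
wt(sim$mouse$samples, "sample_sheet.tsv")
wt(sim$panel, "feature_truth.tsv")
wt(sim$mouse$effects, "planted_effects.tsv")
wt(sim$serum$features, "serum_features.tsv")
wt(sim$serum$pair_truth, "homolog_pair_truth.tsv")
wt(data.frame(feature_id = rownames(sim$mouse$counts), sim$mouse$counts,
              check.names = FALSE), "true_counts_mouse.tsv")
wt(data.frame(feature_id = rownames(sim$serum$counts), sim$serum$counts,
              check.names = FALSE), "true_counts_serum.tsv")

cat(sprintf("Simulated %d features (%s) across %d sperm samples at ~%d reads each.\n",
            nrow(sim$panel),
            paste(names(table(sim$panel$biotype)), table(sim$panel$biotype),
                  sep = "=", collapse = ", "),
            nrow(sim$mouse$samples), as.integer(cfg$depth)))
cat(sprintf("Planted effects: %d (of which %d transgenerational feature-lineage pairs); %d serum homolog pairs.\n",
            nrow(sim$mouse$effects),
            nrow(unique(sim$mouse$effects[sim$mouse$effects$class == "transgenerational",
                                          c("feature_id", "lineage")])),
            nrow(sim$serum$pair_truth)))
cat("FASTQ written to scratch/sim/fastq; truth tables to results/sim/.\n")
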