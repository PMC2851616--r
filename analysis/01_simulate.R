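#!/usr/bin/env Rscript
# Stage 1: generate the demonstration cohort -- 60 tumours / 20 matched
# normals over two chromosomes with three frequent driver amplicons, one
# high-amplitude amplicon, two germline CNPs and 500 genes -- and write
# every input the downstream stages read (marker tables, expression matrix,
# gene BED, cytobands, sample sheet, ground truth).

suppressPackageStartupMessages(library(cnadriver))

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 101L

cfg <- demo_cohort_config(seed = seed)
print(cfg)

sim <- simulate_cohort(cfg)
ex <- simulate_expression(sim, sim$truth, sigma_e = 0.3, seed = seed + 1L)

write_markers(sim$tumour_markers, file.path(out, "tumour_markers.tsv"))
write_markers(sim$normal_markers, file.path(out, "normal_markers.tsv"))
write_expression(ex$expr, file.path(out, "expression.tsv"))
write_gene_bed(sim$truth$genes, file.path(out, "genes.bed"))
write_sample_sheet(sim$samples, file.path(out, "samples.tsv"))
write_truth(sim$truth, file.path(out, "truth.json"))
write.table(make_cytobands(cfg$chrom_lengths), file.path(out, "cytobands.txt"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

ev <- sim$truth$events
cat("\nPlanted structure:\n")
cat("  driver events:", sum(ev$class == "driver"),
    "| passenger events:", sum(ev$class == "passenger"),
    "| germline CNP events:", sum(ev$class == "cnp"), "\n")
cat("  dosage genes (beta > 0):", sum(sim$truth$genes$beta > 0),
    "of", nrow(sim$truth$genes), "\n")
cat("  wrote inputs to", out, "\n")
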