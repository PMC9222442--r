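#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study.
#
# Emulates the screening study's data situation: 12 control + 23 illicitly
# DEX-treated + 2 therapeutic-dose animals profiled on a 32-target qPCR
# panel (triplicate wells, FFPE-style dropout near the 32-cycle cutoff,
# 15 technical replicate profiles at tenfold dilution -> 52 profiles) plus
# 25 fibre diameters for the 35 animals with usable histology. Writes the
# raw tables under results/study/.

suppressPackageStartupMessages(library(dexscreen))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

study <- generate_study(design = study_design(seed = seed))
print(study)

paths <- write_study_csv(study, "results/study")
cat("\nPlanted truth: 12 differential biomarkers among 28 (",
    paste(planted_de_genes(study$truth), collapse = ", "),
    "); stable reference pair RPLP0 + HSPA8.\n", sep = "")
cat("Wrote:", paste(basename(paths), collapse = ", "), "-> results/study/\n")
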