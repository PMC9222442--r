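#!/usr/bin/env Rscript
# Step 2 — Cq preprocessing and reference-gene selection.
#
# Aggregates triplicate wells (32-cycle cutoff, 0.5-cycle median outlier
# rule) and ranks the four candidate reference genes by geNorm pairwise
# variation and the NormFinder model-based stability value.

suppressPackageStartupMessages(library(dexscreen))

cq <- read_cq_csv("results/study/cq_table.csv")
summ <- aggregate_replicates(cq, cutoff = 32)
cat(sprintf("Wells excluded by the 32-cycle cutoff: %d; replicate outliers: %d; measurements lost entirely: %d\n",
            sum(summ$n_cutoff), sum(summ$n_outlier), sum(summ$n_valid == 0)))

candidates <- c("RPLP0", "HSPA8", "GAPDH", "PPIA")
sel <- select_references(summ, candidates)
tab <- data.frame(gene = names(sel$genorm$m_values),
                  genorm_m = unname(sel$genorm$m_values),
                  normfinder = unname(sel$normfinder$stability[
                    names(sel$genorm$m_values)]))
print(tab, digits = 3)
cat("Selected reference pair:", paste(sel$selected, collapse = " + "),
    if (sel$agreement) "(both methods agree)\n" else
      "(geNorm pair; methods disagree)\n")

dir.create("results", showWarnings = FALSE)
readr::write_csv(summ, "results/cq_summaries.csv")
readr::write_csv(tab, "results/stability_ranking.csv")
writeLines(sel$selected, "results/references.txt")
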