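#!/usr/bin/env Rscript
# Step 3 — delta-delta-Cq relative quantification and differential
# expression.
#
# Normalises each profile against the selected reference pair (delta-Cq),
# imputes targets lost to late Cq at the class-wise worst case, calibrates
# against the control group (delta-delta-Cq) and tests each of the 30
# remaining targets by one-way ANOVA with Tukey's post hoc across the
# three dose groups (undiluted profiles only).

suppressPackageStartupMessages(library(dexscreen))

summ <- readr::read_csv("results/cq_summaries.csv", show_col_types = FALSE)
refs <- readLines("results/references.txt")
meta <- readr::read_csv("results/study/metadata.csv", show_col_types = FALSE)

norm <- normalize_dcq(summ, refs)
cat(sprintf("%d profiles x %d variables after normalisation (%d values imputed)\n",
            nrow(norm$dcq), ncol(norm$dcq), sum(norm$imputed)))

cls <- setNames(meta$class, meta$sample_id)
base <- intersect(rownames(norm$dcq), meta$sample_id[meta$dilution == 1])
res <- delta_delta_cq(norm$dcq[base, ], cls[base])
de <- res$de[order(res$de$p_value), ]
cat(sprintf("\n%d of %d targets significantly differential (p < 0.05):\n",
            sum(de$significant), nrow(de)))
print(as.data.frame(de[de$significant, ]), digits = 3)

write_matrix_csv(norm$dcq, "results/dcq_matrix.csv")
readr::write_csv(de, "results/de_results.csv")     # volcano-plot table
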