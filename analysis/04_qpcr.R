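#!/usr/bin/env Rscript
# Step 4 — expression analysis of the simulated Cq table: geNorm reference
# stability, efficiency-corrected NRQs, fold changes and Student's t-tests.
#
# Reads results/cq*.tsv (step 1); writes qpcr_stability.tsv and
# qpcr_comparison.tsv.

suppressPackageStartupMessages(library(cellumod))
out <- "results"
cfg <- pipeline_config(seed = 1L)

ct <- read_cq_tsv(file.path(out, "cq.tsv"), file.path(out, "cq_genes.tsv"),
                  file.path(out, "cq_samples.tsv"))
res <- nrq_analysis(ct, calibrator = cfg$calibrator, var_equal = cfg$var_equal)

write_tsv_header(data.frame(gene = names(res$stability$stability_m),
                            M = unname(res$stability$stability_m),
                            chosen = names(res$stability$stability_m) %in%
                              res$stability$chosen_refs),
                 file.path(out, "qpcr_stability.tsv"), cfg)
write_tsv_header(res$comparison, file.path(out, "qpcr_comparison.tsv"), cfg)

cat(sprintf("geNorm chose references: %s (elimination order: %s)\n",
            paste(res$stability$chosen_refs, collapse = ", "),
            paste(res$stability$elimination_order, collapse = " > ")))
cat("target comparison (treated vs control):\n")
for (i in seq_len(nrow(res$comparison))) {
  r <- res$comparison[i, ]
  cat(sprintf("  %-9s fold change %.2f, p = %.4f%s\n", r$gene, r$fold_change,
              r$p_value, if (!is.na(r$p_value) && r$p_value < 0.05) " *" else ""))
}
cat(sprintf("tables written under %s/\n", out))
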