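#!/usr/bin/env Rscript
# Step 2 — scan patterns, annotate conserved regions and classify the domain
# architecture of every protein in the simulated panel.
#
# Reads results/proteins.fasta (step 1); writes regions.tsv (GFF-like protein
# coordinates with catalytic roles and detected insertions) and
# architecture.tsv (per-segment table plus the architecture string).

suppressPackageStartupMessages(library(cellumod))
out <- "results"
cfg <- pipeline_config(seed = 1L)

res <- run_pipeline(file.path(out, "proteins.fasta"), config = cfg, out_dir = out)

strings <- vapply(res$architectures, function(a) a$architecture_string, character(1))
cat("recovered domain architectures:\n")
for (nm in names(strings)) cat(sprintf("  %-10s %s\n", nm, strings[nm]))

n_triads <- length(unique(paste(res$regions$sequence_id, res$regions$cd)))
cat(sprintf("%d canonical Region I-II-III triads across %d proteins\n",
            n_triads, length(res$architectures)))

ins <- grepl("insertion=", regions_to_gff(
  res$regions[res$regions$region == "II", ], res$records)$attributes)
cat(sprintf("Region II insertion detected in %d of %d catalytic domains\n",
            sum(ins), length(ins)))
cat(sprintf("tables written under %s/\n", out))
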