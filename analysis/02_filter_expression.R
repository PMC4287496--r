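#!/usr/bin/env Rscript
# Stage 2: expression filtering.
#
# Transcripts must exceed 0.1 FPKM in both biological replicates and reach
# at least 5% of the mean abundance of their gene's most abundant isoform;
# weakly expressed isoforms are the main source of spurious AS calls.
# Writes the surviving per-transcript abundances with isoform ratios.

suppressPackageStartupMessages(library(woodsplice))

for (tag in c("a", "b")) {
  genes <- read_gtf(file.path("results/data",
                              paste0("annotation_", tag, ".gtf")))
  expr <- read_expression(file.path("results/data",
                                    paste0("expression_", tag, ".tsv")))
  filt <- filter_transcripts(genes, expr, filter_config())
  out <- file.path("results", paste0("filtered_expression_", tag, ".tsv"))
  write.table(filt$expression, out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("species %s: %d/%d transcripts survive the filters (%d genes)\n",
              toupper(tag), nrow(filt$expression), nrow(expr),
              length(filt$genes)))
}
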