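#!/usr/bin/env Rscript
# Stage 5: cross-species conservation.
#
# Orthologs are reciprocal best hits over protein local alignments of each
# gene's representative isoform (E < 1e-50, identity > 0.4, coverage > 0.6
# both ways). For every same-type event pair on an ortholog pair, 100-bp
# exonic flanks of the alternative introns are compared by six-frame
# translated local alignment; introns whose upstream AND downstream flanks
# are homologous (E <= 1e-5) are conserved, and such event pairs are
# conserved AS events.

suppressPackageStartupMessages(library(woodsplice))

sp <- list()
for (tag in c("a", "b")) {
  genes <- read_gtf(file.path("results/data",
                              paste0("annotation_", tag, ".gtf")))
  expr <- read_expression(file.path("results/data",
                                    paste0("expression_", tag, ".tsv")))
  genome <- read_genome_fasta(file.path("results/data",
                                        paste0("genome_", tag, ".fa")))
  filt <- filter_transcripts(genes, expr)
  events <- read_events(file.path("results", paste0("events_", tag, ".tsv")))
  sp[[tag]] <- list(genome = genome, filt = filt, events = events)
}

prot_a <- representative_proteins(sp$a$filt$genes, sp$a$genome,
                                  sp$a$filt$expression)
prot_b <- representative_proteins(sp$b$filt$genes, sp$b$genome,
                                  sp$b$filt$expression)
orth <- find_ortholog_pairs(prot_a, prot_b)
write_orthologs(orth, "results/orthologs.tsv")
cat(sprintf("ortholog pairs (RBH): %d; identity %.2f-%.2f\n", nrow(orth),
            min(orth$identity), max(orth$identity)))

cons <- conserved_events(sp$a$events, sp$b$events, orth,
                         sp$a$filt$genes, sp$b$filt$genes,
                         sp$a$genome, sp$b$genome)
write_conserved(cons, "results/conserved.tsv")
cat(sprintf("conserved AS events: %d\n", nrow(cons)))
s <- summarize_events(data.frame(event_type = cons$event_type))
cat(sprintf("  per type: %s\n",
            paste(sprintf("%s %d", s$event_type, s$count), collapse = "  ")))
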