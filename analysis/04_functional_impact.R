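#!/usr/bin/env Rscript
# Stage 4: functional impact of the events.
#
# Each isoform is translated from its longest ORF; events are located in
# mRNA features (5'UTR / ORF / 3'UTR), frame disruption is flagged when the
# changed length is not a multiple of 3, the altered interval is mapped to
# protein coordinates, and protein-domain modification / gain / loss is
# called from the domain hit tables (E <= 1e-10). Domain families enriched
# among AS-modified genes are found by two-sided Fisher exact tests.

suppressPackageStartupMessages(library(woodsplice))

for (tag in c("a", "b")) {
  genes <- read_gtf(file.path("results/data",
                              paste0("annotation_", tag, ".gtf")))
  expr <- read_expression(file.path("results/data",
                                    paste0("expression_", tag, ".tsv")))
  genome <- read_genome_fasta(file.path("results/data",
                                        paste0("genome_", tag, ".fa")))
  domains <- read_domain_table(file.path("results/data",
                                         paste0("domains_", tag, ".tsv")))
  filt <- filter_transcripts(genes, expr)
  events <- read_events(file.path("results", paste0("events_", tag, ".tsv")))
  impacts <- annotate_event_impacts(events, filt$genes, genome, domains)
  write_impacts(impacts, file.path("results", paste0("impacts_", tag, ".tsv")))

  in_orf <- impacts$location == "ORF"
  cat(sprintf("species %s: %.1f%% of events in the ORF, %.1f%% in 5'UTR, %.1f%% in 3'UTR\n",
              toupper(tag), 100 * mean(in_orf),
              100 * mean(impacts$location == "UTR5"),
              100 * mean(impacts$location == "UTR3")))
  cat(sprintf("  frame-disrupting (of ORF events): %.1f%%\n",
              100 * mean(impacts$frameshift[in_orf])))
  cat(sprintf("  domain-modifying events: %d (%.1f%%); gain/loss events: %d\n",
              sum(nzchar(impacts$modified_domains)),
              100 * mean(nzchar(impacts$modified_domains)),
              sum(nzchar(impacts$domains_gained) |
                    nzchar(impacts$domains_lost))))

  tx2gene <- transcript_gene_map(filt$genes)
  hits <- domains[domains$e_value <= 1e-10 &
                    domains$protein_id %in% names(tx2gene), ]
  gene_domains <- unique(data.frame(gene_id = unname(tx2gene[hits$protein_id]),
                                    domain_name = hits$domain_name))
  enr <- fisher_domain_enrichment(
    gene_domains, unique(impacts$gene_id[nzchar(impacts$modified_domains)]))
  write.table(enr, file.path("results", paste0("enrichment_", tag, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  enriched domain families (p < 0.05): %d of %d tested\n",
              sum(enr$significant), nrow(enr)))
}
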