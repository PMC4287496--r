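# End-to-end orchestration: expression filter -> event calling -> intron
# features -> functional impact -> (two species) orthology and conserved
# events, with per-species summary tallies. Pure function of its inputs and
# configuration; all randomness lives in the simulator.

#' Per-type event counts and fractions
#'
#' @param events Event data frame.
#' @return Data frame with `event_type`, `count`, `percent` over all five
#'   types (zeros included); percentages sum to 100 up to rounding, or are
#'   all zero for an empty event set.
#' @export
summarize_events <- function(events) {
  counts <- table(factor(events$event_type, levels = EVENT_TYPES))
  n <- sum(counts)
  data.frame(event_type = EVENT_TYPES,
             count = as.integer(counts),
             percent = if (n > 0) round(100 * as.integer(counts) / n, 1)
             else rep(0, length(EVENT_TYPES)),
             stringsAsFactors = FALSE)
}

# histogram of changed lengths in fixed bins
.changed_length_histogram <- function(events,
                                      breaks = c(0, 30, 60, 100, 200, 500,
                                                 Inf)) {
  labs <- paste0("(", head(breaks, -1L), ",",
                 ifelse(is.finite(breaks[-1L]), breaks[-1L], "inf"), "]")
  h <- table(cut(events$changed_length, breaks = breaks, labels = labs))
  data.frame(bin = labs, count = as.integer(h), stringsAsFactors = FALSE)
}

# analyse one species: filter, events, introns, impacts, enrichment
.run_species <- function(sp, filter_cfg, max_domain_evalue) {
  filt <- filter_transcripts(sp$genes, sp$expression, filter_cfg)
  called <- collect_all_events(filt$genes)
  events <- called$events
  introns <- intron_features(filt$genes, sp$genome, events)
  impacts <- annotate_event_impacts(events, filt$genes, sp$genome,
                                    sp$domains, max_domain_evalue)
  # enrichment universe: genes with >= 1 domain hit on any isoform
  enrichment <- NULL
  if (!is.null(sp$domains) && nrow(sp$domains)) {
    hits <- sp$domains[sp$domains$e_value <= max_domain_evalue, , drop = FALSE]
    tx2gene <- transcript_gene_map(filt$genes)
    hits <- hits[hits$protein_id %in% names(tx2gene), , drop = FALSE]
    if (nrow(hits)) {
      gene_domains <- unique(data.frame(
        gene_id = unname(tx2gene[hits$protein_id]),
        domain_name = hits$domain_name, stringsAsFactors = FALSE))
      mod_genes <- unique(impacts$gene_id[nzchar(impacts$modified_domains)])
      enrichment <- fisher_domain_enrichment(gene_domains, mod_genes)
    }
  }
  n_total <- nrow(filt$expression)
  n_as <- length(called$as_transcripts)
  at_alt <- introns$at_content[introns$status == "alternative"]
  at_con <- introns$at_content[introns$status == "constitutive"]
  summary <- list(
    n_genes = length(filt$genes),
    n_transcripts = n_total,
    n_as_transcripts = n_as,
    pct_as_transcripts = if (n_total > 0)
      percent_as_transcripts(n_as, n_total) else 0,
    n_events = nrow(events),
    events_by_type = summarize_events(events),
    changed_length_histogram = .changed_length_histogram(events),
    pct_orf_located = if (nrow(impacts) > 0)
      round(100 * mean(impacts$location == "ORF"), 1) else 0,
    pct_frameshift_of_orf = if (any(impacts$location == "ORF"))
      round(100 * mean(impacts$frameshift[impacts$location == "ORF"]), 1)
    else 0,
    n_domain_modifying = sum(nzchar(impacts$modified_domains)),
    n_domain_gain_loss = sum(nzchar(impacts$domains_gained) |
                               nzchar(impacts$domains_lost)),
    mean_at_alternative = if (length(at_alt)) mean(at_alt) else NA_real_,
    mean_at_constitutive = if (length(at_con)) mean(at_con) else NA_real_)
  list(filtered = filt, events = events, as_transcripts = called$as_transcripts,
       introns = introns, impacts = impacts, enrichment = enrichment,
       summary = summary)
}

#' Run the full AS analysis on one or two species
#'
#' Executes expression filtering, AS event calling, intron feature
#' computation, functional-impact annotation and domain enrichment per
#' species; with two species, additionally reciprocal-best-hit orthology on
#' representative proteins and conserved AS event detection.
#'
#' @param species_a,species_b Lists with `genome`, `genes`, `expression`
#'   and optionally `domains` (as produced by [generate_species_pair()], or
#'   assembled from [read_gtf()]/[read_genome_fasta()]/[read_expression()]/
#'   [read_domain_table()]); `species_b` may be `NULL` for a single-species
#'   run.
#' @param filter_cfg A [filter_config()].
#' @param align_cfg An [align_config()].
#' @param flank_len Flank length for conserved-intron detection.
#' @param max_domain_evalue Domain hit E-value cutoff (default 1e-10).
#' @param ortholog_pairs Optional precomputed ortholog table (columns
#'   `gene_a`, `gene_b`); when `NULL` it is computed.
#' @return List with per-species results `a` (and `b`), and for two-species
#'   runs `orthologs` and `conserved`, plus `summary` (per-species tallies
#'   and conserved counts per type).
#' @export
run_pipeline <- function(species_a, species_b = NULL,
                         filter_cfg = filter_config(),
                         align_cfg = align_config(),
                         flank_len = 100L, max_domain_evalue = 1e-10,
                         ortholog_pairs = NULL) {
  res_a <- .run_species(species_a, filter_cfg, max_domain_evalue)
  out <- list(a = res_a)
  summary <- list(a = res_a$summary)
  if (!is.null(species_b)) {
    res_b <- .run_species(species_b, filter_cfg, max_domain_evalue)
    out$b <- res_b
    summary$b <- res_b$summary
    if (is.null(ortholog_pairs)) {
      prot_a <- representative_proteins(res_a$filtered$genes,
                                        species_a$genome,
                                        res_a$filtered$expression)
      prot_b <- representative_proteins(res_b$filtered$genes,
                                        species_b$genome,
                                        res_b$filtered$expression)
      ortholog_pairs <- find_ortholog_pairs(prot_a, prot_b, align_cfg)
    }
    conserved <- conserved_events(res_a$events, res_b$events, ortholog_pairs,
                                  res_a$filtered$genes, res_b$filtered$genes,
                                  species_a$genome, species_b$genome,
                                  align_cfg, flank_len)
    out$orthologs <- ortholog_pairs
    out$conserved <- conserved
    summary$n_ortholog_pairs <- nrow(ortholog_pairs)
    summary$n_conserved_events <- nrow(conserved)
    summary$conserved_by_type <- summarize_events(
      data.frame(event_type = conserved$event_type))
  }
  out$summary <- summary
  out
}

#' Write all pipeline output tables
#'
#' Emits the per-species events, introns, impacts and enrichment tables,
#' the ortholog and conserved tables for two-species runs, and a
#' human-readable `report.txt` with the summary tallies. Deterministic for
#' identical results.
#'
#' @param res Result of [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr_species <- function(r, tag) {
    write_events(r$events, file.path(dir, paste0("events_", tag, ".tsv")))
    .write_tsv(r$introns, file.path(dir, paste0("introns_", tag, ".tsv")))
    write_impacts(r$impacts, file.path(dir, paste0("impacts_", tag, ".tsv")))
    if (!is.null(r$enrichment))
      .write_tsv(r$enrichment,
                 file.path(dir, paste0("enrichment_", tag, ".tsv")))
  }
  wr_species(res$a, "a")
  if (!is.null(res$b)) {
    wr_species(res$b, "b")
    write_orthologs(res$orthologs, file.path(dir, "orthologs.tsv"))
    write_conserved(res$conserved, file.path(dir, "conserved.tsv"))
  }
  writeLines(format_report(res), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Format the summary report as text
#'
#' @param res Result of [run_pipeline()].
#' @return Character vector of report lines (percentages at one decimal).
#' @export
format_report <- function(res) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  sp_block <- function(s, tag) {
    add("== species %s ==", tag)
    add("genes: %d  transcripts: %d  AS transcripts: %d (%.1f%%)",
        s$n_genes, s$n_transcripts, s$n_as_transcripts,
        s$pct_as_transcripts)
    add("AS events: %d", s$n_events)
    bt <- s$events_by_type
    for (i in seq_len(nrow(bt)))
      add("  %-4s %5d  (%.1f%%)", bt$event_type[i], bt$count[i],
          bt$percent[i])
    add("ORF-located: %.1f%%  frame-disrupting (of ORF): %.1f%%",
        s$pct_orf_located, s$pct_frameshift_of_orf)
    add("domain-modifying events: %d  domain gain/loss events: %d",
        s$n_domain_modifying, s$n_domain_gain_loss)
    if (!is.na(s$mean_at_alternative))
      add("mean AT content: alternative %.3f, constitutive %.3f",
          s$mean_at_alternative, s$mean_at_constitutive)
    h <- s$changed_length_histogram
    add("changed-length bins: %s",
        paste(sprintf("%s:%d", h$bin, h$count), collapse = " "))
  }
  sp_block(res$summary$a, "A")
  if (!is.null(res$summary$b)) {
    sp_block(res$summary$b, "B")
    add("== conservation ==")
    add("ortholog pairs: %d  conserved AS events: %d",
        res$summary$n_ortholog_pairs, res$summary$n_conserved_events)
    ct <- res$summary$conserved_by_type
    for (i in seq_len(nrow(ct)))
      add("  %-4s %5d", ct$event_type[i], ct$count[i])
  }
  lines
}
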