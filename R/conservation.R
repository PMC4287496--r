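# Conserved AS events between two species. For every alternative intron of
# every event, up to 100 bp of exonic sequence immediately flanking the
# intron is extracted from the intron-bearing isoform; an intron pair is
# conserved when upstream-vs-upstream AND downstream-vs-downstream
# translated local alignments both reach the homology E-value cutoff; a
# pair of same-type events on an accepted ortholog pair sharing a conserved
# intron is a conserved AS event.

#' Extract exonic flanks of an event's alternative introns
#'
#' For each alternative intron of the event, takes up to `flank_len` exonic
#' bases immediately 5' and 3' of the intron, in transcription orientation
#' (minus-strand flanks are reverse-complemented and upstream/downstream
#' swapped). Flanks come from the intron-bearing isoform's annotated exons;
#' when several of the gene's isoforms carry the same intron, the isoform
#' with the longest adjacent exons is used. Flanks shorter than `flank_len`
#' (short exons) are flagged as truncated.
#'
#' @param event One row of an event data frame.
#' @param gene The [gene_model()] the event belongs to.
#' @param genome Named character vector of chromosome sequences.
#' @param flank_len Flank length in bases (default 100).
#' @return Data frame with one row per alternative intron: `intron_start`,
#'   `intron_end`, `upstream_flank`, `downstream_flank`,
#'   `upstream_truncated`, `downstream_truncated`.
#' @export
extract_flanks <- function(event, gene, genome, flank_len = 100L) {
  introns <- rbind(iv_parse(event$alt_introns_a),
                   iv_parse(event$alt_introns_b))
  introns <- unique(introns)
  rows <- list()
  for (k in seq_len(nrow(introns))) {
    s <- introns$start[k]; e <- introns$end[k]
    # isoforms of the gene carrying exactly this intron
    best <- NULL
    for (tid in sort(names(gene$transcripts))) {
      tx <- gene$transcripts[[tid]]
      intr <- transcript_introns(tx)
      hit <- which(intr$start == s & intr$end == e)
      if (!length(hit)) next
      i <- hit[1L]
      left_exon <- tx$exons[i, ]          # exon ending at s
      right_exon <- tx$exons[i + 1L, ]    # exon starting at e
      adj <- min(left_exon$end - left_exon$start,
                 right_exon$end - right_exon$start)
      if (is.null(best) || adj > best$adj)
        best <- list(tx = tx, left = left_exon, right = right_exon, adj = adj)
    }
    if (is.null(best))
      stop("no isoform of gene ", gene$gene_id, " carries intron [",
           s, ",", e, ")")
    left_len <- min(flank_len, best$left$end - best$left$start)
    right_len <- min(flank_len, best$right$end - best$right$start)
    left_seq <- seq_slice(genome, best$tx$chrom, s - left_len, s)
    right_seq <- seq_slice(genome, best$tx$chrom, e, e + right_len)
    if (best$tx$strand == "+") {
      up <- left_seq; down <- right_seq
      up_tr <- left_len < flank_len; down_tr <- right_len < flank_len
    } else {
      up <- revcomp_dna(right_seq); down <- revcomp_dna(left_seq)
      up_tr <- right_len < flank_len; down_tr <- left_len < flank_len
    }
    rows[[length(rows) + 1L]] <- data.frame(
      intron_start = s, intron_end = e,
      upstream_flank = up, downstream_flank = down,
      upstream_truncated = up_tr, downstream_truncated = down_tr,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$intron_start), , drop = FALSE]
}

#' Conserved introns between two flank sets
#'
#' An intron pair is conserved iff the upstream-vs-upstream AND
#' downstream-vs-downstream translated local alignments both reach
#' `config$homology_evalue`.
#'
#' @param flanks_a,flanks_b Data frames from [extract_flanks()] for events
#'   on an accepted ortholog pair.
#' @param config An [align_config()].
#' @return Data frame of matched intron pairs with per-flank E-values:
#'   `intron_a_start`, `intron_a_end`, `intron_b_start`, `intron_b_end`,
#'   `up_evalue`, `down_evalue`. Zero rows when nothing matches.
#' @export
conserved_introns <- function(flanks_a, flanks_b, config = align_config()) {
  rows <- list()
  for (i in seq_len(nrow(flanks_a))) for (j in seq_len(nrow(flanks_b))) {
    up <- translated_local_align(flanks_a$upstream_flank[i],
                                 flanks_b$upstream_flank[j], config)
    if (up$e_value > config$homology_evalue) next
    down <- translated_local_align(flanks_a$downstream_flank[i],
                                   flanks_b$downstream_flank[j], config)
    if (down$e_value > config$homology_evalue) next
    rows[[length(rows) + 1L]] <- data.frame(
      intron_a_start = flanks_a$intron_start[i],
      intron_a_end = flanks_a$intron_end[i],
      intron_b_start = flanks_b$intron_start[j],
      intron_b_end = flanks_b$intron_end[j],
      up_evalue = up$e_value, down_evalue = down$e_value,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(intron_a_start = integer(0), intron_a_end = integer(0),
                      intron_b_start = integer(0), intron_b_end = integer(0),
                      up_evalue = numeric(0), down_evalue = numeric(0)))
  do.call(rbind, rows)
}

#' Conserved AS events between two species
#'
#' For each accepted ortholog pair, every cross-species pair of same-type
#' events whose alternative introns are conserved (both flanks homologous,
#' see [conserved_introns()]) is reported as a conserved AS event. All
#' matching event pairs are emitted; genes with several events can appear
#' in more than one pair.
#'
#' @param events_a,events_b Event data frames for species A and B.
#' @param ortholog_pairs Data frame from [find_ortholog_pairs()] (or read
#'   from a table), with `gene_a`, `gene_b`.
#' @param genes_a,genes_b Named lists of [gene_model()] objects.
#' @param genome_a,genome_b Named character vectors of chromosome
#'   sequences.
#' @param config An [align_config()].
#' @param flank_len Flank length in bases (default 100).
#' @return Data frame with one row per conserved event pair: `gene_a`,
#'   `gene_b`, `event_type`, the matched intron coordinates in each
#'   species, and the two flank E-values.
#' @export
conserved_events <- function(events_a, events_b, ortholog_pairs,
                             genes_a, genes_b, genome_a, genome_b,
                             config = align_config(), flank_len = 100L) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      event_type = character(0),
                      intron_a_start = integer(0), intron_a_end = integer(0),
                      intron_b_start = integer(0), intron_b_end = integer(0),
                      up_evalue = numeric(0), down_evalue = numeric(0))
  if (!nrow(ortholog_pairs) || !nrow(events_a) || !nrow(events_b))
    return(empty)
  rows <- list()
  for (p in seq_len(nrow(ortholog_pairs))) {
    ga <- ortholog_pairs$gene_a[p]; gb <- ortholog_pairs$gene_b[p]
    ev_a <- events_a[events_a$gene_id == ga, , drop = FALSE]
    ev_b <- events_b[events_b$gene_id == gb, , drop = FALSE]
    if (!nrow(ev_a) || !nrow(ev_b)) next
    for (i in seq_len(nrow(ev_a))) for (j in seq_len(nrow(ev_b))) {
      if (ev_a$event_type[i] != ev_b$event_type[j]) next
      fa <- extract_flanks(ev_a[i, ], genes_a[[ga]], genome_a, flank_len)
      fb <- extract_flanks(ev_b[j, ], genes_b[[gb]], genome_b, flank_len)
      ci <- conserved_introns(fa, fb, config)
      if (!nrow(ci)) next
      # one conserved event per matched event pair; report the best-
      # supported intron pair (smallest combined E-value)
      best <- which.min(ci$up_evalue * ci$down_evalue)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = ga, gene_b = gb, event_type = ev_a$event_type[i],
        intron_a_start = ci$intron_a_start[best],
        intron_a_end = ci$intron_a_end[best],
        intron_b_start = ci$intron_b_start[best],
        intron_b_end = ci$intron_b_end[best],
        up_evalue = ci$up_evalue[best], down_evalue = ci$down_evalue[best],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$gene_a, out$gene_b, out$intron_a_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
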