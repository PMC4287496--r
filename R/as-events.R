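# Pairwise splice-chain comparison. Two isoforms of one gene are compared
# over the genomic overlap of their spans; the overlap is partitioned into
# maximal variable regions bounded by shared splice sites (or the overlap
# bounds), and each region whose intron content differs yields exactly one
# typed AS event.
#
# Event types:
#   IR   - one isoform splices >=1 intron where the other is continuously
#          exonic across the region (single-intron retention in the common
#          case; multi-intron retention within one region is still IR).
#   ES   - one isoform spans the whole region with a single intron while the
#          other carries >=1 exon strictly inside it (flanking splice sites
#          shared by construction of the region bounds).
#   AltA - both isoforms have exactly one intron in the region, sharing the
#          donor (5' in transcription orientation) but not the acceptor.
#   AltD - shared acceptor, different donors.
#   AltP - catch-all: both isoforms carry >=1 splice site in the region but
#          none of the above patterns applies (e.g. an intron shifted at
#          both ends).
#
# changed_length is the size of the symmetric difference of the two
# isoforms' exonic base sets within the region: the nucleotides exonic in
# one isoform but intronic/absent in the other. For IR this is the retained
# intron length, for ES the skipped exon length, for AltA/AltD the splice
# site shift.

EVENT_TYPES <- c("IR", "AltA", "AltD", "ES", "AltP")

#' Classify AS events between two isoforms
#'
#' Compares the splice chains of two isoforms of one gene over the genomic
#' overlap of their spans and returns one typed AS event per variable region
#' with differing intron content. Variable regions are bounded by shared
#' splice sites (positions where both isoforms have an exon start, or both
#' an exon end) or by the overlap bounds. Terminal differences outside the
#' overlap, and regions whose introns poke beyond the overlap, are not
#' reported: the five event types are all internal.
#'
#' @param isoform_a,isoform_b [transcript_model()] objects of one gene on
#'   the same chromosome and strand.
#' @return Data frame with one row per event: `gene_id`, `event_type`,
#'   `isoform_a`, `isoform_b`, `chrom`, `strand`, `var_start`, `var_end`
#'   (the variable region), `alt_introns_a`/`alt_introns_b`
#'   (semicolon-separated `start-end` intron lists), `changed_length`,
#'   `inclusion_isoform` (the isoform carrying the altered nucleotides as
#'   exon; for ties, the lexicographically smaller id), and `mrna_start`,
#'   `mrna_end` (the altered interval on the inclusion isoform's mRNA).
#'   Zero rows when the transcripts do not overlap or do not differ.
#' @export
classify_event_pair <- function(isoform_a, isoform_b) {
  a <- isoform_a; b <- isoform_b
  if (a$chrom != b$chrom) stop("isoforms on different chromosomes")
  if (a$strand != b$strand) stop("isoforms on different strands")
  span_a <- transcript_span(a); span_b <- transcript_span(b)
  ol <- c(max(span_a[1L], span_b[1L]), min(span_a[2L], span_b[2L]))
  if (ol[1L] >= ol[2L]) return(.empty_events())

  # shared splice sites strictly inside the overlap, same boundary kind
  ends_a <- a$exons$end[a$exons$end > ol[1L] & a$exons$end < ol[2L]]
  ends_b <- b$exons$end[b$exons$end > ol[1L] & b$exons$end < ol[2L]]
  starts_a <- a$exons$start[a$exons$start > ol[1L] & a$exons$start < ol[2L]]
  starts_b <- b$exons$start[b$exons$start > ol[1L] & b$exons$start < ol[2L]]
  shared <- sort(unique(c(intersect(ends_a, ends_b),
                          intersect(starts_a, starts_b))))
  cuts <- c(ol[1L], shared, ol[2L])

  introns_a <- transcript_introns(a)
  introns_b <- transcript_introns(b)

  rows <- list()
  for (k in seq_len(length(cuts) - 1L)) {
    l <- cuts[k]; r <- cuts[k + 1L]
    ex_a <- iv_clip(a$exons, l, r)
    ex_b <- iv_clip(b$exons, l, r)
    common <- iv_intersect(ex_a, ex_b)
    diff_len <- iv_total_len(ex_a) + iv_total_len(ex_b) -
      2L * iv_total_len(common)
    if (diff_len == 0L) next
    in_a <- introns_a[introns_a$end > l & introns_a$start < r, , drop = FALSE]
    in_b <- introns_b[introns_b$end > l & introns_b$start < r, , drop = FALSE]
    # introns crossing an overlap bound: a terminal difference, not an
    # internal event
    if (any(in_a$start < l | in_a$end > r) ||
        any(in_b$start < l | in_b$end > r)) next
    ev <- .type_region(a, b, in_a, in_b, ex_a, ex_b, l, r, diff_len)
    if (!is.null(ev)) rows[[length(rows) + 1L]] <- ev
  }
  if (!length(rows)) return(.empty_events())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.empty_events <- function() {
  data.frame(gene_id = character(0), event_type = character(0),
             isoform_a = character(0), isoform_b = character(0),
             chrom = character(0), strand = character(0),
             var_start = integer(0), var_end = integer(0),
             alt_introns_a = character(0), alt_introns_b = character(0),
             changed_length = integer(0), inclusion_isoform = character(0),
             mrna_start = integer(0), mrna_end = integer(0),
             stringsAsFactors = FALSE)
}

.type_region <- function(a, b, in_a, in_b, ex_a, ex_b, l, r, diff_len) {
  na <- nrow(in_a); nb <- nrow(in_b)
  strand <- a$strand
  type <- NULL
  if (na > 0L && nb == 0L) {
    type <- "IR"                      # b continuously exonic across region
  } else if (na == 0L && nb > 0L) {
    type <- "IR"
  } else if (nb == 1L && in_b$start[1L] == l && in_b$end[1L] == r && na >= 2L) {
    type <- "ES"                      # a's exon(s) inside b's single intron
  } else if (na == 1L && in_a$start[1L] == l && in_a$end[1L] == r && nb >= 2L) {
    type <- "ES"
  } else if (na == 1L && nb == 1L) {
    same_start <- in_a$start[1L] == in_b$start[1L]
    same_end <- in_a$end[1L] == in_b$end[1L]
    if (same_start && !same_end)
      type <- if (strand == "+") "AltA" else "AltD"
    else if (same_end && !same_start)
      type <- if (strand == "+") "AltD" else "AltA"
    else
      type <- "AltP"                  # both ends differ
  } else {
    type <- "AltP"                    # mixed multi-intron pattern
  }

  # inclusion isoform: the one with more exonic sequence in the region
  len_a <- iv_total_len(ex_a); len_b <- iv_total_len(ex_b)
  inc <- if (len_a > len_b) a else if (len_b > len_a) b else
    if (a$transcript_id <= b$transcript_id) a else b
  exc_ex <- if (identical(inc$transcript_id, a$transcript_id)) ex_b else ex_a
  inc_ex <- if (identical(inc$transcript_id, a$transcript_id)) ex_a else ex_b
  altered <- iv_setdiff(inc_ex, exc_ex)
  mrna <- if (nrow(altered)) genomic_to_mrna(inc, altered) else c(NA_integer_,
                                                                  NA_integer_)
  data.frame(gene_id = a$gene_id, event_type = type,
             isoform_a = a$transcript_id, isoform_b = b$transcript_id,
             chrom = a$chrom, strand = strand,
             var_start = as.integer(l), var_end = as.integer(r),
             alt_introns_a = iv_format(in_a), alt_introns_b = iv_format(in_b),
             changed_length = as.integer(diff_len),
             inclusion_isoform = inc$transcript_id,
             mrna_start = as.integer(mrna[1L]), mrna_end = as.integer(mrna[2L]),
             stringsAsFactors = FALSE)
}

#' Collect deduplicated AS events of a gene
#'
#' Runs [classify_event_pair()] over every unordered isoform pair of the
#' gene and merges events with identical type, variable region and
#' alternative intron sets, recording all supporting isoform pairs. A
#' transcript is an "AS transcript" iff it participates in at least one
#' event.
#'
#' @param gene A [gene_model()] (after expression filtering).
#' @return List with `events` (data frame as in [classify_event_pair()] plus
#'   a `supporting_pairs` column, `"tx1|tx2;tx3|tx4"`) and `as_transcripts`
#'   (character vector of AS transcript ids).
#' @export
collect_gene_events <- function(gene) {
  tids <- sort(names(gene$transcripts))
  n <- length(tids)
  all_ev <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ev <- classify_event_pair(gene$transcripts[[tids[i]]],
                                gene$transcripts[[tids[j]]])
      if (nrow(ev)) all_ev[[length(all_ev) + 1L]] <- ev
    }
  }
  if (!length(all_ev)) {
    ev <- .empty_events()
    ev$supporting_pairs <- character(0)
    return(list(events = ev, as_transcripts = character(0)))
  }
  ev <- do.call(rbind, all_ev)
  # merge events identical in (type, variable region, alt intron sets); the
  # intron-set key is unordered in a/b so role swaps across pairs collapse
  intron_key <- vapply(seq_len(nrow(ev)), function(i)
    paste(sort(c(ev$alt_introns_a[i], ev$alt_introns_b[i])), collapse = "&"),
    character(1))
  key <- paste(ev$event_type, ev$var_start, ev$var_end, intron_key)
  pair_lab <- paste(ev$isoform_a, ev$isoform_b, sep = "|")
  first <- !duplicated(key)
  merged <- ev[first, , drop = FALSE]
  merged$supporting_pairs <- vapply(key[first], function(k)
    paste(sort(pair_lab[key == k]), collapse = ";"), character(1),
    USE.NAMES = FALSE)
  merged <- .sort_events(merged)
  rownames(merged) <- NULL
  as_tx <- sort(unique(c(ev$isoform_a, ev$isoform_b)))
  list(events = merged, as_transcripts = as_tx)
}

#' Collect AS events across a set of genes
#'
#' @param genes Named list of [gene_model()] objects.
#' @return List with `events` (row-bound event table over all genes) and
#'   `as_transcripts` (character vector over all genes).
#' @export
collect_all_events <- function(genes) {
  evs <- list(); astx <- character(0)
  for (gid in sort(names(genes))) {
    res <- collect_gene_events(genes[[gid]])
    if (nrow(res$events)) evs[[length(evs) + 1L]] <- res$events
    astx <- c(astx, res$as_transcripts)
  }
  events <- if (length(evs)) do.call(rbind, evs) else {
    e <- .empty_events(); e$supporting_pairs <- character(0); e
  }
  rownames(events) <- NULL
  list(events = events, as_transcripts = sort(unique(astx)))
}

#' Alternative introns of an event table
#'
#' @param events Event data frame.
#' @return Data frame `chrom`, `strand`, `start`, `end`, unique, sorted.
#' @export
event_alt_introns <- function(events) {
  if (!nrow(events))
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  rows <- lapply(seq_len(nrow(events)), function(i) {
    iv <- rbind(iv_parse(events$alt_introns_a[i]),
                iv_parse(events$alt_introns_b[i]))
    if (!nrow(iv)) return(NULL)
    data.frame(chrom = events$chrom[i], strand = events$strand[i],
               start = iv$start, end = iv$end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- unique(out)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}
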