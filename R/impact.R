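# Functional impact of AS events: localization within mRNA features
# (5'UTR / ORF / 3'UTR), reading-frame disruption, mapping of the altered
# interval onto protein coordinates, protein-domain modification / gain /
# loss, and Fisher exact domain enrichment.

#' Locate an event within the mRNA features of its inclusion isoform
#'
#' The altered mRNA interval is compared with the isoform's ORF: strictly
#' before the ORF start is `UTR5`, strictly at/after the ORF end is `UTR3`,
#' any overlap with the ORF (including boundary-spanning intervals) is
#' `ORF`; events on a noncoding isoform are `noncoding`.
#'
#' @param mrna_start,mrna_end Altered interval on the inclusion isoform's
#'   mRNA (0-based half-open).
#' @param orf An `orf_annotation` (see [longest_orf()]) or `NULL`.
#' @return One of `"UTR5"`, `"ORF"`, `"UTR3"`, `"noncoding"`.
#' @export
locate_event <- function(mrna_start, mrna_end, orf) {
  if (is.null(orf)) return("noncoding")
  stopifnot(mrna_start < mrna_end)
  if (mrna_end <= orf$orf_start) return("UTR5")
  if (mrna_start >= orf$orf_end) return("UTR3")
  "ORF"
}

#' Reading-frame disruption flag
#'
#' An ORF-located event disrupts the reading frame iff its changed length is
#' not a multiple of 3.
#'
#' @param changed_length Changed nucleotides of the event (>= 1).
#' @param location Event location as from [locate_event()].
#' @return `TRUE`/`FALSE` for ORF-located events, `NA` otherwise.
#' @export
frameshift_flag <- function(changed_length, location) {
  stopifnot(changed_length >= 1L)
  if (!identical(location, "ORF")) return(NA)
  (changed_length %% 3L) != 0L
}

#' Map an event's altered mRNA interval to protein coordinates
#'
#' Intersects the altered interval with the ORF and converts to 0-based
#' amino-acid offsets (`floor` at the start, `ceiling` at the end, so a
#' partially covered codon counts). For a frame-disrupting event the
#' affected interval extends to the C-terminus, since all downstream
#' sequence is altered.
#'
#' @param mrna_start,mrna_end Altered mRNA interval (half-open).
#' @param orf An `orf_annotation` of the inclusion isoform.
#' @param frameshift Logical, as from [frameshift_flag()].
#' @return Integer vector `c(aa_start, aa_end)`, half-open, clamped to
#'   `[0, protein length]`.
#' @export
map_event_to_protein <- function(mrna_start, mrna_end, orf, frameshift) {
  prot_len <- nchar(orf$protein)
  s <- max(mrna_start, orf$orf_start)
  e <- min(mrna_end, orf$orf_end)
  if (e <= s) stop("event does not overlap the ORF")
  aa_start <- (s - orf$orf_start) %/% 3L
  aa_end <- as.integer(ceiling((e - orf$orf_start) / 3))
  if (isTRUE(frameshift)) aa_end <- prot_len
  aa_start <- min(aa_start, prot_len)
  aa_end <- min(max(aa_end, aa_start), prot_len)
  c(aa_start, aa_end)
}

#' Domain modification, gain and loss for one event
#'
#' A domain is modified when its amino-acid interval on either isoform's
#' protein overlaps the event's affected interval by at least one residue.
#' Gain/loss is counted per family occurrence (copy number), so an isoform
#' losing one of two copies of a family registers as a loss.
#'
#' @param affected_aa `c(aa_start, aa_end)` from [map_event_to_protein()],
#'   or `NULL` for non-ORF events (no modification is then possible).
#' @param hits_inclusion,hits_exclusion Domain hit data frames (columns of
#'   [read_domain_table()]) for the inclusion and exclusion isoform
#'   proteins, already filtered by E-value.
#' @param frameshift If `TRUE`, the affected region is open-ended: every
#'   residue C-terminal of `aa_start` differs on both proteins (the
#'   inclusion isoform's own interval may be empty when the shift truncates
#'   its protein at the event).
#' @return List with `modified` (character vector of domain families),
#'   `gained` (families with more copies on the exclusion isoform) and
#'   `lost` (families with fewer copies on the exclusion isoform than on the
#'   inclusion isoform).
#' @export
domain_modification <- function(affected_aa, hits_inclusion, hits_exclusion,
                                frameshift = FALSE) {
  empty <- data.frame(domain_name = character(0), aa_start = integer(0),
                      aa_end = integer(0))
  hi <- if (is.null(hits_inclusion)) empty else hits_inclusion
  he <- if (is.null(hits_exclusion)) empty else hits_exclusion
  modified <- character(0)
  if (!is.null(affected_aa)) {
    hi_end <- if (isTRUE(frameshift)) Inf else affected_aa[2L]
    if (hi_end > affected_aa[1L]) {
      both <- rbind(hi[, c("domain_name", "aa_start", "aa_end")],
                    he[, c("domain_name", "aa_start", "aa_end")])
      if (nrow(both)) {
        ov <- pmin(both$aa_end, hi_end) - pmax(both$aa_start, affected_aa[1L])
        modified <- sort(unique(both$domain_name[ov >= 1L]))
      }
    }
  }
  count_i <- table(hi$domain_name)
  count_e <- table(he$domain_name)
  fams <- sort(unique(c(names(count_i), names(count_e))))
  ni <- as.integer(count_i[fams]); ni[is.na(ni)] <- 0L
  ne <- as.integer(count_e[fams]); ne[is.na(ne)] <- 0L
  list(modified = modified,
       gained = fams[ne > ni],
       lost = fams[ne < ni])
}

#' Annotate the functional impact of every AS event
#'
#' For each event: translates both isoforms via [longest_orf()], locates the
#' altered interval in the inclusion isoform's mRNA features, flags
#' reading-frame disruption, maps the affected interval to protein
#' coordinates, and calls domain modification / gain / loss from the domain
#' hit table (filtered at `max_domain_evalue`). The inclusion isoform
#' anchors localization; `location_discordant` flags events where the
#' exclusion isoform's own ORF would place the event elsewhere.
#'
#' @param events Event data frame (see [collect_all_events()]).
#' @param genes Named list of [gene_model()] objects containing the event
#'   isoforms.
#' @param genome Named character vector of chromosome sequences.
#' @param domain_hits Data frame in the layout of [read_domain_table()]
#'   (protein ids are transcript ids), or `NULL` for no domain annotation.
#' @param max_domain_evalue E-value cutoff applied to domain hits
#'   (default 1e-10).
#' @return Data frame with one row per event: the event key columns plus
#'   `location`, `frameshift`, `aa_start`, `aa_end`, `modified_domains`,
#'   `domains_gained`, `domains_lost` (semicolon-joined), `utr3_length` (of
#'   the inclusion isoform; NA for noncoding) and `location_discordant`.
#' @export
annotate_event_impacts <- function(events, genes, genome, domain_hits = NULL,
                                   max_domain_evalue = 1e-10) {
  hits <- if (is.null(domain_hits)) NULL else
    domain_hits[domain_hits$e_value <= max_domain_evalue, , drop = FALSE]
  orf_cache <- new.env(parent = emptyenv())
  get_orf <- function(tx) {
    id <- tx$transcript_id
    if (is.null(orf_cache[[id]]))
      orf_cache[[id]] <- list(orf = longest_orf(mrna_sequence(tx, genome)))
    orf_cache[[id]]$orf
  }
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    g <- genes[[ev$gene_id]]
    inc_id <- ev$inclusion_isoform
    exc_id <- setdiff(c(ev$isoform_a, ev$isoform_b), inc_id)[1L]
    inc <- g$transcripts[[inc_id]]
    exc <- g$transcripts[[exc_id]]
    orf_inc <- get_orf(inc)
    orf_exc <- get_orf(exc)
    loc <- locate_event(ev$mrna_start, ev$mrna_end, orf_inc)
    fs <- frameshift_flag(ev$changed_length, loc)
    aa <- c(NA_integer_, NA_integer_)
    dm <- list(modified = character(0), gained = character(0),
               lost = character(0))
    if (loc == "ORF") {
      aa <- map_event_to_protein(ev$mrna_start, ev$mrna_end, orf_inc, fs)
      hi <- if (!is.null(hits))
        hits[hits$protein_id == inc_id, , drop = FALSE] else NULL
      he <- if (!is.null(hits))
        hits[hits$protein_id == exc_id, , drop = FALSE] else NULL
      dm <- domain_modification(aa, hi, he, frameshift = isTRUE(fs))
    } else if (!is.null(hits)) {
      # UTR/noncoding events can still gain/lose domains via ORF changes
      hi <- hits[hits$protein_id == inc_id, , drop = FALSE]
      he <- hits[hits$protein_id == exc_id, , drop = FALSE]
      dm <- domain_modification(NULL, hi, he)
    }
    # where does the exclusion isoform's own ORF place the junction?
    disc <- FALSE
    if (!is.null(orf_exc) && !is.null(orf_inc) && loc != "noncoding") {
      # map the event's flanking junction onto the exclusion mRNA: use the
      # variable-region bounds restricted to the exclusion isoform's exons
      exc_ex <- iv_clip(exc$exons, ev$var_start, ev$var_end)
      if (nrow(exc_ex)) {
        m <- genomic_to_mrna(exc, exc_ex)
        loc_exc <- locate_event(m[1L], m[2L], orf_exc)
        disc <- !identical(loc_exc, loc)
      }
    }
    utr3 <- if (is.null(orf_inc)) NA_integer_ else
      orf_inc$mrna_length - orf_inc$orf_end
    rows[[i]] <- data.frame(
      gene_id = ev$gene_id, event_type = ev$event_type,
      var_start = ev$var_start, var_end = ev$var_end,
      inclusion_isoform = inc_id, location = loc,
      frameshift = fs, aa_start = aa[1L], aa_end = aa[2L],
      modified_domains = paste(dm$modified, collapse = ";"),
      domains_gained = paste(dm$gained, collapse = ";"),
      domains_lost = paste(dm$lost, collapse = ";"),
      utr3_length = utr3, location_discordant = disc,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), event_type = character(0),
               var_start = integer(0), var_end = integer(0),
               inclusion_isoform = character(0), location = character(0),
               frameshift = logical(0), aa_start = integer(0),
               aa_end = integer(0), modified_domains = character(0),
               domains_gained = character(0), domains_lost = character(0),
               utr3_length = integer(0), location_discordant = logical(0))
  rownames(out) <- NULL
  out
}

#' Fisher exact test for domain enrichment among AS-modified genes
#'
#' For each domain family, tests the 2x2 table over the gene universe (all
#' genes with at least one domain hit): with domain & AS-modified (a), with
#' domain & not (b), without domain & AS-modified (c), neither (d).
#' Two-sided exact p values, no multiplicity correction; significance is
#' flagged at a raw p below `alpha`.
#'
#' @param gene_domains Data frame with columns `gene_id`, `domain_name`
#'   (one row per gene-family presence; duplicates are collapsed).
#' @param as_modified_genes Character vector of gene ids with at least one
#'   domain-modifying AS event.
#' @param alpha Significance cutoff on the raw p value (default 0.05).
#' @return Data frame sorted by p value: `domain_name`, `a`, `b`, `c`, `d`,
#'   `p_value`, `significant`.
#' @export
fisher_domain_enrichment <- function(gene_domains, as_modified_genes,
                                     alpha = 0.05) {
  gd <- unique(gene_domains[, c("gene_id", "domain_name")])
  if (!nrow(gd))
    return(data.frame(domain_name = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      p_value = numeric(0), significant = logical(0)))
  universe <- sort(unique(gd$gene_id))
  mod <- universe %in% as_modified_genes
  doms <- sort(unique(gd$domain_name))
  rows <- lapply(doms, function(d) {
    with_dom <- universe %in% gd$gene_id[gd$domain_name == d]
    a <- sum(with_dom & mod); b <- sum(with_dom & !mod)
    c_ <- sum(!with_dom & mod); d_ <- sum(!with_dom & !mod)
    p <- fisher.test(matrix(c(a, b, c_, d_), nrow = 2L, byrow = TRUE))$p.value
    data.frame(domain_name = d, a = a, b = b, c = c_, d = d_, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$domain_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a protein for exact peptide motifs
#'
#' Stand-in for an HMM-based domain search: every exact occurrence of each
#' motif (including overlapping occurrences) becomes a domain hit with
#' E-value 0.
#'
#' @param protein Amino-acid string.
#' @param motif_table Named character vector mapping `domain_name` to an
#'   exact peptide string.
#' @param protein_id Id recorded in the output (default `"protein"`).
#' @return Data frame in the layout of [read_domain_table()].
#' @export
scan_motif_domains <- function(protein, motif_table, protein_id = "protein") {
  rows <- list()
  for (d in sort(names(motif_table))) {
    pat <- motif_table[[d]]
    if (!nzchar(pat) || nchar(pat) > nchar(protein)) next
    m <- gregexpr(paste0("(?=", gsub("([^A-Za-z])", "\\\\\\1", pat), ")"),
                  protein, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = protein_id, domain_name = d,
      aa_start = as.integer(m) - 1L,
      aa_end = as.integer(m) - 1L + nchar(pat),
      e_value = 0, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(protein_id = character(0), domain_name = character(0),
                      aa_start = integer(0), aa_end = integer(0),
                      e_value = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$domain_name, out$aa_start), , drop = FALSE]
}
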