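# Synthetic two-species data with planted ground truth. Genes are built in
# local transcription-orientation coordinates as UTR5 + CDS + UTR3 with
# GT-AG introns inserted at chosen mRNA points; each AS gene carries a
# major isoform and one minor isoform realizing exactly one planted event.
# Species B orthologs are mutated copies of species A genes (splice
# dinucleotides and start/stop codons protected; coding mutations that
# would create an in-frame stop are reverted), with flank regions of shared
# events mutated at their own configured rate. Every constructed gene is
# verified with the package's own ORF finder before acceptance, so planted
# locations (5'UTR / ORF / 3'UTR) are guaranteed to hold for the emitted
# sequences; a draw that violates them is redrawn.

#' Default exact-peptide motif table for the synthetic domain annotation
#'
#' Six 8-residue peptides standing in for protein domain families; scanned
#' with [scan_motif_domains()], avoiding any HMM dependency. None contains
#' methionine, so embedded motifs never add an ATG codon in frame.
#'
#' @return Named character vector, `domain_name -> peptide`.
#' @export
default_motif_table <- function() {
  c(KinaseCore = "HKWNPDRC", RRMFold = "YGQELFRD", PPaseLoop = "WDHTKENQ",
    ZincKnot = "CHYCKDWE", RasSwitch = "QTEYKLVI", ChapClamp = "NWFEDGTK")
}

#' Simulation configuration for the synthetic species pair
#'
#' Defaults describe a small two-species wood-transcriptome-like study: 60
#' genes per species, 30 planted AS events per species (6 per type), 40% of
#' events shared between species at identical intron placement, orthologous
#' gene copies at 5% nucleotide divergence and event flanks at 10%, FPKM
#' major isoforms at 5-80 with minor/major ratios 0.15-0.8 (well above the
#' 5% retention filter unless sub-threshold isoforms are requested).
#'
#' @param seed Integer RNG seed; the generator is a pure function of the
#'   config, so identical configs give byte-identical outputs.
#' @param n_genes Genes per species.
#' @param events_per_type Named integer vector over IR, AltA, AltD, ES,
#'   AltP: planted events per type, per species.
#' @param conserved_fraction Fraction of each species' events shared with
#'   the other species (same type, identical intron placement).
#' @param ortholog_fraction Fraction of the non-AS filler genes also paired
#'   across species.
#' @param specific_partner_fraction Fraction of species-specific event
#'   genes in A that get an event-less orthologous partner in B (negative
#'   controls for conserved-event calling).
#' @param ortholog_mutation_rate Per-base substitution rate applied to an
#'   ortholog gene copy.
#' @param flank_mutation_rate Substitution rate applied to the 100-bp
#'   exonic flanks of a shared event's alternative introns.
#' @param n_introns_range,intron_len_range Intron count and length ranges.
#' @param n_codons_range Protein length range (amino acids, incl. leading
#'   Met).
#' @param utr_len_range Length range of UTRs not hosting an event.
#' @param utr_event_len Length of a UTR that hosts a planted event.
#' @param gc_content GC fraction of generated sequence.
#' @param location_probs Probabilities of planting an event in the ORF,
#'   5'UTR or 3'UTR (ES events are always ORF-located).
#' @param fpkm_range Major-isoform FPKM range.
#' @param minor_ratio_range Minor/major abundance ratio range.
#' @param plant_subthreshold If `TRUE`, every fifth AS gene of species A
#'   gains a third isoform at 2% of the major (below the 5% filter),
#'   retaining a constitutive intron; its event must vanish after
#'   filtering.
#' @param spacer_len Intergenic spacer length.
#' @param motif_table Named peptide motifs (see [default_motif_table()]).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 60L,
                              events_per_type = c(IR = 6L, AltA = 6L,
                                                  AltD = 6L, ES = 6L,
                                                  AltP = 6L),
                              conserved_fraction = 0.4,
                              ortholog_fraction = 0.5,
                              specific_partner_fraction = 0.5,
                              ortholog_mutation_rate = 0.05,
                              flank_mutation_rate = 0.10,
                              n_introns_range = c(3L, 5L),
                              intron_len_range = c(80L, 200L),
                              n_codons_range = c(140L, 190L),
                              utr_len_range = c(60L, 90L),
                              utr_event_len = 280L,
                              gc_content = 0.45,
                              location_probs = c(ORF = 0.7, UTR5 = 0.15,
                                                 UTR3 = 0.15),
                              fpkm_range = c(5, 80),
                              minor_ratio_range = c(0.15, 0.8),
                              plant_subthreshold = FALSE,
                              spacer_len = 150L,
                              motif_table = default_motif_table()) {
  stopifnot(all(events_per_type >= 0L),
            conserved_fraction >= 0, conserved_fraction <= 1,
            ortholog_fraction >= 0, ortholog_fraction <= 1,
            ortholog_mutation_rate >= 0, ortholog_mutation_rate <= 1,
            flank_mutation_rate >= 0, flank_mutation_rate <= 1,
            all(names(events_per_type) == EVENT_TYPES))
  structure(as.list(environment()), class = "simulation_config")
}

#' Mutate a sequence by per-base substitution
#'
#' Each unprotected position is substituted with probability `rate`,
#' uniformly to one of the other three bases (at rate 1 no unprotected
#' position keeps its base).
#'
#' @param sequence Nucleotide string.
#' @param rate Substitution probability per base, in \[0, 1\].
#' @param protected Integer vector of 0-based positions never mutated
#'   (e.g. splice dinucleotides, start/stop codons).
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Mutated sequence.
#' @export
mutate_sequence <- function(sequence, rate, protected = integer(0),
                            seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  run <- function() {
    ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    hit <- stats::runif(length(ch)) < rate
    if (length(protected)) hit[protected + 1L] <- FALSE
    for (i in which(hit))
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# ---- low-level sequence builders ------------------------------------------

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# break every ATG occurrence (G -> C cannot create a new one)
.break_atg <- function(s) {
  repeat {
    m <- regexpr("ATG", s, fixed = TRUE)
    if (m == -1L) break
    substr(s, m + 2L, m + 2L) <- "C"
  }
  s
}

.random_dna <- function(n, gc, atg_free = TRUE) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  if (atg_free) .break_atg(s) else s
}

.SENSE_CODONS <- local({
  all_codons <- names(Biostrings::GENETIC_CODE)
  setdiff(all_codons, c(.STOP_CODONS, "ATG"))
})

.CODON_FOR_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  aas <- unique(as.character(gc))
  out <- character(0)
  for (aa in aas) out[aa] <- sort(names(gc)[gc == aa])[1L]
  out
})

# intron: GT ... AG with optional planted internal dinucleotides (0-based
# positions within the intron) for minor-isoform splice sites
.make_intron <- function(len, gc, edits = list()) {
  stopifnot(len >= 24L)
  s <- paste0("GT", .random_dna(len - 4L, gc), "AG")
  for (ed in edits) substr(s, ed$pos + 1L, ed$pos + 2L) <- ed$dinuc
  s
}

# major exon chain (local genomic coords) from mRNA length, intron mRNA
# insertion points P (sorted, strictly inside) and intron lengths L
.exons_from_layout <- function(Lm, P, L) {
  bounds <- c(0L, P, Lm)
  cum <- c(0L, cumsum(L))
  k <- length(P)
  data.frame(start = bounds[seq_len(k + 1L)] + cum[seq_len(k + 1L)],
             end = bounds[seq_len(k + 1L) + 1L] + cum[seq_len(k + 1L)])
}

# place n points in [margin, Lm - margin] keeping min_gap between
# themselves and gap_fixed from the fixed points; NULL if infeasible
.place_points <- function(n, Lm, fixed, min_gap = 40L, gap_fixed = 110L,
                          margin = 30L) {
  if (n == 0L) return(integer(0))
  pts <- integer(0)
  for (tries in 1:200) {
    cand <- sample(margin:(Lm - margin), 1L)
    if (length(fixed) && any(abs(cand - fixed) < gap_fixed)) next
    if (length(pts) && any(abs(cand - pts) < min_gap)) next
    pts <- c(pts, cand)
    if (length(pts) == n) return(sort(pts))
  }
  NULL
}

# ---- single-gene construction ---------------------------------------------

# A local gene (transcription orientation): sequence, major/minor exon
# chains, planted event truth, ORF layout, domain placements, protected
# positions, and genomic positions of interior CDS codons (for safe
# mutation of ortholog copies).
.draw_local_gene <- function(cfg, etype, location) {
  n_codons <- sample(cfg$n_codons_range[1L]:cfg$n_codons_range[2L], 1L)
  cds_nt <- 3L * n_codons + 3L
  utr5 <- if (identical(location, "UTR5")) cfg$utr_event_len else
    sample(cfg$utr_len_range[1L]:cfg$utr_len_range[2L], 1L)
  utr3 <- if (identical(location, "UTR3")) cfg$utr_event_len else
    sample(cfg$utr_len_range[1L]:cfg$utr_len_range[2L], 1L)
  Lm <- utr5 + cds_nt + utr3

  # event intron insertion point(s) in mRNA coordinates
  ev_points <- integer(0)
  skip_len <- delta <- d1 <- d2 <- NULL
  if (etype == "none") {
    # no event
  } else if (etype == "ES") {
    # mixed residues mod 3: in-frame and frame-disrupting skips
    skip_len <- sample(c(45L, 47L, 52L, 57L, 62L, 75L), 1L)
    frac <- stats::runif(1L, 0.55, 0.68)
    p1 <- utr5 + as.integer(round(frac * cds_nt))
    ev_points <- c(p1, p1 + skip_len)
  } else if (identical(location, "ORF")) {
    frac <- stats::runif(1L, 0.60, 0.80)
    ev_points <- utr5 + as.integer(round(frac * cds_nt))
  } else if (identical(location, "UTR5")) {
    ev_points <- sample(110L:(utr5 - 110L), 1L)
  } else if (identical(location, "UTR3")) {
    ev_points <- utr5 + cds_nt + sample(110L:(utr3 - 110L), 1L)
  }
  if (length(ev_points) && (min(ev_points) < 110L || max(ev_points) > Lm - 110L))
    stop("event does not fit in gene")

  n_int <- sample(cfg$n_introns_range[1L]:cfg$n_introns_range[2L], 1L)
  n_const <- max(0L, n_int - length(ev_points))
  const_pts <- .place_points(n_const, Lm, ev_points)
  if (is.null(const_pts)) stop("could not place introns")
  P <- sort(c(ev_points, const_pts))
  k_ev <- match(ev_points, P)

  # intron lengths and minor-splice-site edits
  ilens <- sample(cfg$intron_len_range[1L]:cfg$intron_len_range[2L],
                  length(P), replace = TRUE)
  edits <- rep(list(list()), length(P))
  if (etype %in% c("AltA", "AltD")) {
    # mixed residues mod 3: in-frame and frame-disrupting shifts
    delta <- sample(c(15L, 16L, 20L, 21L, 25L, 27L), 1L)
    il <- ilens[k_ev[1L]]
    if (etype == "AltA")
      edits[[k_ev[1L]]] <- list(list(pos = il - delta - 2L, dinuc = "AG"))
    else
      edits[[k_ev[1L]]] <- list(list(pos = delta, dinuc = "GT"))
  } else if (etype == "AltP") {
    d1 <- sample(c(8L, 9L, 11L, 12L, 15L), 1L)
    d2 <- sample(c(8L, 9L, 11L, 12L, 15L), 1L)
    il <- ilens[k_ev[1L]]
    edits[[k_ev[1L]]] <- list(list(pos = d1, dinuc = "GT"),
                              list(pos = il - d2 - 2L, dinuc = "AG"))
  }
  introns <- vapply(seq_along(P), function(i)
    .make_intron(ilens[i], cfg$gc_content, edits[[i]]), character(1))

  # CDS with embedded motifs
  codons <- sample(.SENSE_CODONS, n_codons - 1L, replace = TRUE)
  motifs <- cfg$motif_table
  domains <- data.frame(domain_name = character(0), aa_start = integer(0),
                        aa_end = integer(0), relation = character(0),
                        stringsAsFactors = FALSE)
  embed <- function(codons, pep, aa_start) {
    aa <- strsplit(pep, "", fixed = TRUE)[[1L]]
    codons[aa_start + seq_along(aa) - 1L] <- .CODON_FOR_AA[aa]
    codons
  }
  pick_motif <- function(i) motifs[[((i - 1L) %% length(motifs)) + 1L]]
  motif_name <- function(i) names(motifs)[((i - 1L) %% length(motifs)) + 1L]
  mi <- sample.int(length(motifs), 1L)
  if (etype != "none" && identical(location, "ORF") && etype != "ES") {
    aa_pos <- (ev_points[1L] - utr5) %/% 3L   # codon index at the insertion
    near <- c(aa_pos - 3L, aa_pos + 5L)       # 8-aa motif spanning the point
    codons <- embed(codons, pick_motif(mi), near[1L])
    codons <- embed(codons, pick_motif(mi + 1L), 5L)
    domains <- rbind(
      data.frame(domain_name = motif_name(mi), aa_start = near[1L],
                 aa_end = near[2L], relation = "affected"),
      data.frame(domain_name = motif_name(mi + 1L), aa_start = 5L,
                 aa_end = 13L, relation = "unaffected"))
  } else if (etype == "ES") {
    aa_lo <- as.integer(ceiling((ev_points[1L] - utr5) / 3))
    codons <- embed(codons, pick_motif(mi), aa_lo + 1L)
    codons <- embed(codons, pick_motif(mi), 5L)   # second copy: per-copy loss
    domains <- rbind(
      data.frame(domain_name = motif_name(mi), aa_start = aa_lo + 1L,
                 aa_end = aa_lo + 9L, relation = "affected"),
      data.frame(domain_name = motif_name(mi), aa_start = 5L,
                 aa_end = 13L, relation = "unaffected"))
  } else {
    codons <- embed(codons, pick_motif(mi), 5L)
    domains <- data.frame(domain_name = motif_name(mi), aa_start = 5L,
                          aa_end = 13L, relation = "unaffected")
  }
  cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  stopifnot(nchar(cds) == cds_nt)

  # mRNA: ATG-free UTRs; 3'UTR starts with a stop wall in all three frames
  utr5_seq <- .random_dna(utr5, cfg$gc_content)
  wall <- "TAATTAATTAA"
  utr3_seq <- paste0(wall, .random_dna(utr3 - nchar(wall), cfg$gc_content))
  mrna <- paste0(utr5_seq, cds, utr3_seq)

  # assemble local genomic sequence
  bounds <- c(0L, P, Lm)
  segs <- character(0)
  for (i in seq_len(length(P) + 1L)) {
    segs <- c(segs, substr(mrna, bounds[i] + 1L, bounds[i + 1L]))
    if (i <= length(P)) segs <- c(segs, introns[i])
  }
  gseq <- paste(segs, collapse = "")
  major <- .exons_from_layout(Lm, P, ilens)
  intr_local <- data.frame(start = major$end[-nrow(major)],
                           end = major$start[-1L])

  # minor isoform + event truth
  minor <- NULL; event <- NULL
  if (etype != "none") {
    k <- k_ev[1L]
    s <- intr_local$start[k]; e <- intr_local$end[k]
    minor <- major
    if (etype == "IR") {
      minor$end[k] <- minor$end[k + 1L]
      minor <- minor[-(k + 1L), , drop = FALSE]
      changed <- ilens[k]; ins <- ilens[k]; inclusion <- "minor"
    } else if (etype == "AltA") {
      minor$start[k + 1L] <- e - delta
      changed <- delta; ins <- delta; inclusion <- "minor"
    } else if (etype == "AltD") {
      minor$end[k] <- s + delta
      changed <- delta; ins <- delta; inclusion <- "minor"
    } else if (etype == "AltP") {
      minor$end[k] <- s + d1
      minor$start[k + 1L] <- e - d2
      changed <- d1 + d2; ins <- d1 + d2; inclusion <- "minor"
    } else if (etype == "ES") {
      # drop the exon between the two event introns; the minor isoform
      # joins intron k's donor to intron k+1's acceptor
      minor <- minor[-(k + 1L), , drop = FALSE]
      changed <- skip_len; ins <- 0L; inclusion <- "major"
    }
    rownames(minor) <- NULL
    mrna_iv <- if (etype == "ES") c(ev_points[1L], ev_points[2L]) else
      c(ev_points[1L], ev_points[1L] + ins)
    # exonic flank regions (local coords) of the event's introns, for
    # flank-rate mutation of ortholog copies
    fl <- list(c(max(0L, s - 100L), s), c(e, min(nchar(gseq), e + 100L)))
    if (etype == "ES") {
      s2 <- intr_local$start[k + 1L]; e2 <- intr_local$end[k + 1L]
      fl <- c(fl, list(c(max(0L, s2 - 100L), s2),
                       c(e2, min(nchar(gseq), e2 + 100L))))
    }
    event <- list(type = etype, location = location, changed_length = changed,
                  inclusion = inclusion, ins_len = ins,
                  mrna_start = mrna_iv[1L], mrna_end = mrna_iv[2L],
                  alt_intron = c(s, e), flank_regions = fl,
                  intron_indices = if (etype == "ES") c(k, k + 1L) else k)
  }

  # protected positions: splice dinucleotides (incl. planted minor sites),
  # ATG and stop codon
  prot <- integer(0)
  for (i in seq_len(nrow(intr_local))) {
    s <- intr_local$start[i]; e <- intr_local$end[i]
    prot <- c(prot, s, s + 1L, e - 2L, e - 1L)
    for (ed in edits[[i]]) prot <- c(prot, s + ed$pos, s + ed$pos + 1L)
  }
  g_of_m <- function(x) x + sum(ilens[P <= x])
  atg_g <- g_of_m(utr5) + 0:2
  stop_g <- vapply(0:2, function(o) g_of_m(utr5 + cds_nt - 3L + o), 0L)
  prot <- sort(unique(c(prot, atg_g, stop_g)))

  # genomic positions of interior CDS codons (stop-reversion on mutation)
  n_inner <- n_codons - 1L
  codon_gpos <- matrix(0L, nrow = 3L, ncol = n_inner)
  for (j in seq_len(n_inner))
    codon_gpos[, j] <- vapply(0:2, function(o)
      g_of_m(utr5 + 3L * j + o), 0L)

  list(seq = gseq, major_exons = major, minor_exons = minor,
       introns = intr_local, event = event, utr5 = utr5, cds_nt = cds_nt,
       mrna_len = Lm, domains = domains, protected = prot,
       codon_gpos = codon_gpos)
}

# splice a local exon chain (gene is in transcription orientation)
.splice_local <- function(lg, exons) {
  paste(vapply(seq_len(nrow(exons)), function(i)
    substr(lg$seq, exons$start[i] + 1L, exons$end[i]), character(1)),
    collapse = "")
}

# verify planted layout with the package's own ORF finder
.verify_local_gene <- function(lg) {
  oA <- longest_orf(.splice_local(lg, lg$major_exons))
  if (is.null(oA) || oA$orf_start != lg$utr5 ||
      oA$orf_end != lg$utr5 + lg$cds_nt) return(FALSE)
  ev <- lg$event
  if (is.null(ev)) return(TRUE)
  inc_ex <- if (ev$inclusion == "major") lg$major_exons else lg$minor_exons
  oI <- longest_orf(.splice_local(lg, inc_ex))
  if (is.null(oI)) return(FALSE)
  loc <- locate_event(ev$mrna_start, ev$mrna_end, oI)
  if (!identical(loc, ev$location)) return(FALSE)
  exp_start <- if (ev$location == "UTR5") lg$utr5 + ev$ins_len else lg$utr5
  if (oI$orf_start != exp_start) return(FALSE)
  if (ev$location == "UTR3" && oI$orf_end != lg$utr5 + lg$cds_nt)
    return(FALSE)
  # exclusion isoform must stay coding (it is the gene's reference form)
  TRUE
}

.build_local_gene <- function(cfg, etype, location) {
  for (attempt in 1:80) {
    lg <- tryCatch(.draw_local_gene(cfg, etype, location),
                   error = function(e) NULL)
    if (!is.null(lg) && .verify_local_gene(lg)) return(lg)
  }
  stop("infeasible simulation config: could not realize a ", etype,
       " gene (", location, ")")
}

# ortholog copy: mutate at gene rate (flank regions of a kept event at the
# flank rate), protect splice sites and start/stop, revert coding
# mutations that create in-frame stops, re-verify; redraw on failure
.mutate_local_gene <- function(lg, cfg, keep_event) {
  for (attempt in 1:80) {
    ch <- strsplit(lg$seq, "", fixed = TRUE)[[1L]]
    orig <- ch
    n <- length(ch)
    rate <- rep(cfg$ortholog_mutation_rate, n)
    if (keep_event && !is.null(lg$event)) {
      for (iv in lg$event$flank_regions)
        if (iv[2L] > iv[1L]) rate[(iv[1L] + 1L):iv[2L]] <- cfg$flank_mutation_rate
    }
    rate[lg$protected + 1L] <- 0
    hit <- stats::runif(n) < rate
    for (i in which(hit))
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    # revert interior CDS codons that became stops
    for (j in seq_len(ncol(lg$codon_gpos))) {
      pos <- lg$codon_gpos[, j] + 1L
      if (paste(ch[pos], collapse = "") %in% .STOP_CODONS)
        ch[pos] <- orig[pos]
    }
    lg2 <- lg
    lg2$seq <- paste(ch, collapse = "")
    if (!keep_event) { lg2$event <- NULL; lg2$minor_exons <- NULL }
    lg2$domains <- NULL   # domain truth is recorded for the source species
    if (.verify_local_gene(lg2)) return(lg2)
  }
  stop("could not derive a valid ortholog gene copy")
}

# ---- species assembly ------------------------------------------------------

# transform a local interval set to chromosome coordinates
.tf_iv <- function(iv, off, L, strand) {
  if (strand == "+") {
    data.frame(start = off + iv$start, end = off + iv$end)
  } else {
    d <- data.frame(start = off + L - iv$end, end = off + L - iv$start)
    d[order(d$start), , drop = FALSE]
  }
}

# Assemble one species: lay genes on one chromosome with spacers, build
# transcript/gene models, expression and truth rows.
.assemble_species <- function(specs, chrom, cfg, species_label) {
  seqs <- character(0)
  pos <- 0L
  genes <- list()
  expr_rows <- list()
  truth_event_rows <- list()
  placed <- list()
  for (sp in specs) {
    lg <- sp$lg
    spacer <- .random_dna(cfg$spacer_len, cfg$gc_content, atg_free = FALSE)
    seqs <- c(seqs, spacer)
    pos <- pos + cfg$spacer_len
    L <- nchar(lg$seq)
    gseq <- if (sp$strand == "+") lg$seq else revcomp_dna(lg$seq)
    seqs <- c(seqs, gseq)
    off <- pos
    pos <- pos + L

    gid <- sp$gene_id
    txs <- list()
    major_id <- paste0(gid, ".t1")
    txs[[major_id]] <- transcript_model(
      major_id, gid, chrom, sp$strand,
      .tf_iv(lg$major_exons, off, L, sp$strand))
    minor_id <- NA_character_
    if (!is.null(lg$minor_exons)) {
      minor_id <- paste0(gid, ".t2")
      txs[[minor_id]] <- transcript_model(
        minor_id, gid, chrom, sp$strand,
        .tf_iv(lg$minor_exons, off, L, sp$strand))
    }
    if (isTRUE(sp$subthreshold)) {
      # third isoform retaining the first constitutive intron, planted
      # below the 5% retention filter
      kc <- sp$subthreshold_intron
      ex3 <- lg$major_exons
      ex3$end[kc] <- ex3$end[kc + 1L]
      ex3 <- ex3[-(kc + 1L), , drop = FALSE]
      sub_id <- paste0(gid, ".t3")
      txs[[sub_id]] <- transcript_model(sub_id, gid, chrom, sp$strand,
                                        .tf_iv(ex3, off, L, sp$strand))
    }
    genes[[gid]] <- gene_model(gid, txs)

    base <- stats::runif(1L, cfg$fpkm_range[1L], cfg$fpkm_range[2L])
    jit <- stats::runif(2L, 0.9, 1.1)
    rows <- data.frame(transcript_id = major_id,
                       fpkm_rep1 = base * jit[1L],
                       fpkm_rep2 = base * jit[2L], stringsAsFactors = FALSE)
    if (!is.na(minor_id)) {
      ratio <- stats::runif(1L, cfg$minor_ratio_range[1L],
                            cfg$minor_ratio_range[2L])
      rows <- rbind(rows, data.frame(transcript_id = minor_id,
                                     fpkm_rep1 = base * jit[1L] * ratio,
                                     fpkm_rep2 = base * jit[2L] * ratio))
    }
    if (isTRUE(sp$subthreshold))
      rows <- rbind(rows, data.frame(transcript_id = paste0(gid, ".t3"),
                                     fpkm_rep1 = base * jit[1L] * 0.02,
                                     fpkm_rep2 = base * jit[2L] * 0.02))
    expr_rows[[gid]] <- rows

    if (!is.null(lg$event)) {
      ai <- .tf_iv(data.frame(start = lg$event$alt_intron[1L],
                              end = lg$event$alt_intron[2L]),
                   off, L, sp$strand)
      truth_event_rows[[gid]] <- data.frame(
        species = species_label, gene_id = gid, event_type = lg$event$type,
        major_isoform = major_id, minor_isoform = minor_id,
        inclusion_isoform = if (lg$event$inclusion == "major") major_id else
          minor_id,
        location = lg$event$location,
        changed_length = lg$event$changed_length,
        frame_disrupting = lg$event$location == "ORF" &&
          lg$event$changed_length %% 3L != 0L,
        intron_start = ai$start[1L], intron_end = ai$end[1L],
        stringsAsFactors = FALSE)
    }
    placed[[gid]] <- list(off = off, L = L, strand = sp$strand, lg = lg)
  }
  genome <- setNames(paste(c(seqs, .random_dna(cfg$spacer_len, cfg$gc_content,
                                               atg_free = FALSE)),
                           collapse = ""), chrom)
  expression <- do.call(rbind, unname(expr_rows))
  rownames(expression) <- NULL
  truth_events <- if (length(truth_event_rows))
    do.call(rbind, unname(truth_event_rows)) else NULL
  list(genome = genome, genes = genes, expression = expression,
       truth_events = truth_events, placed = placed)
}

# domain table: scan each isoform's longest-ORF protein for the motifs
.species_domains <- function(genes, genome, motif_table) {
  rows <- list()
  for (gid in sort(names(genes))) {
    for (tid in sort(names(genes[[gid]]$transcripts))) {
      orf <- longest_orf(mrna_sequence(genes[[gid]]$transcripts[[tid]],
                                       genome))
      if (is.null(orf)) next
      h <- scan_motif_domains(orf$protein, motif_table, protein_id = tid)
      if (nrow(h)) rows[[length(rows) + 1L]] <- h
    }
  }
  if (!length(rows))
    return(data.frame(protein_id = character(0), domain_name = character(0),
                      aa_start = integer(0), aa_end = integer(0),
                      e_value = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$protein_id, out$domain_name, out$aa_start), , drop = FALSE]
}

#' Generate a synthetic species pair with planted AS truth
#'
#' Builds two artificial "species" (genome, transcript models, expression
#' and domain tables) with planted AS events of all five types, orthologous
#' gene copies, and a configured fraction of events shared between species
#' at identical intron placement, plus truth tables for every planted
#' record. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `species_a` and `species_b` (each: `genome`, `genes`,
#'   `expression`, `domains`), `truth` (data frames `events`, `orthologs`,
#'   `conserved`, `domains`) and `config`.
#' @export
generate_species_pair <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .generate_pair_impl(config))
}

.generate_pair_impl <- function(cfg) {
  ept <- cfg$events_per_type
  E <- sum(ept)
  # conserved slots per type by largest remainder
  exact <- cfg$conserved_fraction * ept
  cons_counts <- floor(exact)
  rem <- round(cfg$conserved_fraction * E) - sum(cons_counts)
  if (rem > 0L) {
    ord <- order(-(exact - cons_counts), names(ept))
    cons_counts[ord[seq_len(rem)]] <- cons_counts[ord[seq_len(rem)]] + 1L
  }
  spec_counts <- ept - cons_counts
  n_cons <- sum(cons_counts); n_spec <- sum(spec_counts)
  n_partner <- round(cfg$specific_partner_fraction * n_spec)
  need_a <- n_cons + n_spec
  need_b <- n_cons + n_partner + n_spec
  if (cfg$n_genes < need_a || cfg$n_genes < need_b)
    stop("infeasible simulation config: n_genes = ", cfg$n_genes,
         " but the event plan needs ", max(need_a, need_b), " genes")

  draw_location <- function(etype) {
    if (etype == "ES") return("ORF")
    sample(names(cfg$location_probs), 1L, prob = cfg$location_probs)
  }

  specs_a <- list(); specs_b <- list()
  orth_rows <- list(); cons_rows <- list()
  idx_a <- 0L; idx_b <- 0L
  new_id <- function(prefix, i) sprintf("%s%04d", prefix, i)

  # conserved event gene pairs
  cons_types <- rep(names(cons_counts), cons_counts)
  for (t in cons_types) {
    loc <- draw_location(t)
    lg_a <- .build_local_gene(cfg, t, loc)
    lg_b <- .mutate_local_gene(lg_a, cfg, keep_event = TRUE)
    idx_a <- idx_a + 1L; idx_b <- idx_b + 1L
    ga <- new_id("ga", idx_a); gb <- new_id("gb", idx_b)
    specs_a[[ga]] <- list(gene_id = ga, lg = lg_a)
    specs_b[[gb]] <- list(gene_id = gb, lg = lg_b)
    orth_rows[[length(orth_rows) + 1L]] <-
      data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
    cons_rows[[length(cons_rows) + 1L]] <-
      data.frame(gene_a = ga, gene_b = gb, event_type = t,
                 stringsAsFactors = FALSE)
  }

  # species-specific events in A; a fraction get event-less B partners
  spec_types_a <- rep(names(spec_counts), spec_counts)
  for (i in seq_along(spec_types_a)) {
    t <- spec_types_a[i]
    lg_a <- .build_local_gene(cfg, t, draw_location(t))
    idx_a <- idx_a + 1L
    ga <- new_id("ga", idx_a)
    specs_a[[ga]] <- list(gene_id = ga, lg = lg_a)
    if (i <= n_partner) {
      lg_b <- .mutate_local_gene(lg_a, cfg, keep_event = FALSE)
      idx_b <- idx_b + 1L
      gb <- new_id("gb", idx_b)
      specs_b[[gb]] <- list(gene_id = gb, lg = lg_b)
      orth_rows[[length(orth_rows) + 1L]] <-
        data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
    }
  }

  # species-specific events in B (fresh genes)
  for (t in rep(names(spec_counts), spec_counts)) {
    lg_b <- .build_local_gene(cfg, t, draw_location(t))
    idx_b <- idx_b + 1L
    gb <- new_id("gb", idx_b)
    specs_b[[gb]] <- list(gene_id = gb, lg = lg_b)
  }

  # non-AS filler genes; a fraction are ortholog pairs
  nf_a <- cfg$n_genes - idx_a
  nf_b <- cfg$n_genes - idx_b
  n_orth_fill <- round(cfg$ortholog_fraction * min(nf_a, nf_b))
  for (i in seq_len(max(nf_a, nf_b))) {
    make_a <- i <= nf_a; make_b <- i <= nf_b
    if (make_a) {
      lg_a <- .build_local_gene(cfg, "none", "ORF")
      idx_a <- idx_a + 1L
      ga <- new_id("ga", idx_a)
      specs_a[[ga]] <- list(gene_id = ga, lg = lg_a)
      if (make_b && i <= n_orth_fill) {
        lg_b <- .mutate_local_gene(lg_a, cfg, keep_event = FALSE)
        idx_b <- idx_b + 1L
        gb <- new_id("gb", idx_b)
        specs_b[[gb]] <- list(gene_id = gb, lg = lg_b)
        orth_rows[[length(orth_rows) + 1L]] <-
          data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
        next
      }
    }
    if (make_b && (!make_a || i > n_orth_fill)) {
      lg_b <- .build_local_gene(cfg, "none", "ORF")
      idx_b <- idx_b + 1L
      gb <- new_id("gb", idx_b)
      specs_b[[gb]] <- list(gene_id = gb, lg = lg_b)
    }
  }

  # strands, sub-threshold isoforms
  finalize <- function(specs, is_a) {
    ev_count <- 0L
    for (gid in names(specs)) {
      specs[[gid]]$strand <- sample(c("+", "-"), 1L)
      specs[[gid]]$subthreshold <- FALSE
      lg <- specs[[gid]]$lg
      if (is_a && cfg$plant_subthreshold && !is.null(lg$event)) {
        ev_count <- ev_count + 1L
        if (ev_count %% 5L == 1L) {
          # first constitutive intron (not used by the event)
          kc <- setdiff(seq_len(nrow(lg$introns)),
                        lg$event$intron_indices)[1L]
          if (!is.na(kc)) {
            specs[[gid]]$subthreshold <- TRUE
            specs[[gid]]$subthreshold_intron <- kc
          }
        }
      }
    }
    specs
  }
  specs_a <- finalize(specs_a, TRUE)
  specs_b <- finalize(specs_b, FALSE)

  asm_a <- .assemble_species(specs_a, "chrA", cfg, "A")
  asm_b <- .assemble_species(specs_b, "chrB", cfg, "B")

  # truth tables
  orthologs <- if (length(orth_rows)) do.call(rbind, orth_rows) else
    data.frame(gene_a = character(0), gene_b = character(0))
  conserved <- if (length(cons_rows)) do.call(rbind, cons_rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               event_type = character(0))
  if (nrow(conserved)) {
    te_a <- asm_a$truth_events; te_b <- asm_b$truth_events
    conserved$intron_a_start <- te_a$intron_start[match(conserved$gene_a,
                                                        te_a$gene_id)]
    conserved$intron_a_end <- te_a$intron_end[match(conserved$gene_a,
                                                    te_a$gene_id)]
    conserved$intron_b_start <- te_b$intron_start[match(conserved$gene_b,
                                                        te_b$gene_id)]
    conserved$intron_b_end <- te_b$intron_end[match(conserved$gene_b,
                                                    te_b$gene_id)]
  }
  events_truth <- rbind(asm_a$truth_events, asm_b$truth_events)
  rownames(events_truth) <- NULL
  dom_rows <- list()
  for (gid in names(specs_a)) {
    d <- specs_a[[gid]]$lg$domains
    if (!is.null(d) && nrow(d))
      dom_rows[[gid]] <- cbind(data.frame(species = "A", gene_id = gid,
                                          stringsAsFactors = FALSE), d)
  }
  domains_truth <- if (length(dom_rows)) do.call(rbind, unname(dom_rows)) else
    data.frame(species = character(0), gene_id = character(0),
               domain_name = character(0), aa_start = integer(0),
               aa_end = integer(0), relation = character(0))
  rownames(domains_truth) <- NULL

  dom_a <- .species_domains(asm_a$genes, asm_a$genome, cfg$motif_table)
  dom_b <- .species_domains(asm_b$genes, asm_b$genome, cfg$motif_table)

  list(species_a = list(genome = asm_a$genome, genes = asm_a$genes,
                        expression = asm_a$expression, domains = dom_a),
       species_b = list(genome = asm_b$genome, genes = asm_b$genes,
                        expression = asm_b$expression, domains = dom_b),
       truth = list(events = events_truth, orthologs = orthologs,
                    conserved = conserved, domains = domains_truth),
       config = cfg)
}

#' Write a synthetic species pair to disk
#'
#' Emits, per species, genome FASTA, annotation GTF, expression TSV and
#' domain TSV, plus the truth tables, into `dir`. Output is byte-identical
#' for identical configs.
#'
#' @param sim Result of [generate_species_pair()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_species_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))
  paths <- c(
    fasta_a = p("genome_a.fa"), gtf_a = p("annotation_a.gtf"),
    expr_a = p("expression_a.tsv"), domains_a = p("domains_a.tsv"),
    fasta_b = p("genome_b.fa"), gtf_b = p("annotation_b.gtf"),
    expr_b = p("expression_b.tsv"), domains_b = p("domains_b.tsv"),
    truth_events = p("truth_events.tsv"),
    truth_orthologs = p("truth_orthologs.tsv"),
    truth_conserved = p("truth_conserved.tsv"),
    truth_domains = p("truth_domains.tsv"))
  write_genome_fasta(sim$species_a$genome, paths["fasta_a"])
  write_gtf(sim$species_a$genes, paths["gtf_a"])
  write_expression(sim$species_a$expression, paths["expr_a"])
  write_domain_table(sim$species_a$domains, paths["domains_a"])
  write_genome_fasta(sim$species_b$genome, paths["fasta_b"])
  write_gtf(sim$species_b$genes, paths["gtf_b"])
  write_expression(sim$species_b$expression, paths["expr_b"])
  write_domain_table(sim$species_b$domains, paths["domains_b"])
  .write_tsv(sim$truth$events, paths["truth_events"])
  .write_tsv(sim$truth$orthologs, paths["truth_orthologs"])
  .write_tsv(sim$truth$conserved, paths["truth_conserved"])
  .write_tsv(sim$truth$domains, paths["truth_domains"])
  invisible(paths)
}
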