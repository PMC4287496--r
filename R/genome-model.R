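#' @importFrom stats fisher.test t.test setNames
#' @importFrom utils head tail read.delim write.table
NULL

# Internal coordinate convention: 0-based, half-open [start, end) on the
# forward genome strand; strand is metadata. mRNA coordinates are 0-based
# from the 5' end of the transcript (reverse-complemented for "-" strand).

#' Construct a transcript model
#'
#' A transcript model is the unit compared when calling alternative splicing
#' events: one isoform's ordered exon chain on a genome. Exons use 0-based
#' half-open coordinates on the forward strand; introns are derived as the
#' gaps between consecutive exons.
#'
#' @param transcript_id Character scalar, unique isoform identifier.
#' @param gene_id Character scalar, identifier of the parent gene.
#' @param chrom Character scalar, chromosome/contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with integer columns `start`, `end` (0-based,
#'   half-open), sorted by `start`, pairwise non-overlapping, with every
#'   inter-exon gap (intron) at least 1 nt.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got: ", strand)
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) < 1L) stop("transcript ", transcript_id, " has no exons")
  if (any(exons$end <= exons$start))
    stop("transcript ", transcript_id, ": exon with end <= start")
  if (is.unsorted(exons$start, strictly = TRUE) && nrow(exons) > 1L)
    exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L) {
    gaps <- exons$start[-1L] - exons$end[-nrow(exons)]
    if (any(gaps < 1L))
      stop("transcript ", transcript_id,
           ": overlapping or abutting exons (intron length must be >= 1)")
  }
  rownames(exons) <- NULL
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         chrom = chrom, strand = strand, exons = exons),
    class = "transcript_model")
}

#' Construct a gene model
#'
#' @param gene_id Character scalar.
#' @param transcripts List of [transcript_model()] objects, all carrying this
#'   `gene_id` and sharing one chromosome and strand.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcripts) {
  stopifnot(is.list(transcripts), length(transcripts) >= 1L)
  ids <- vapply(transcripts, function(t) t$gene_id, character(1))
  if (!all(ids == gene_id))
    stop("gene ", gene_id, ": transcript with foreign gene_id")
  chroms <- unique(vapply(transcripts, function(t) t$chrom, character(1)))
  strands <- unique(vapply(transcripts, function(t) t$strand, character(1)))
  if (length(chroms) != 1L || length(strands) != 1L)
    stop("gene ", gene_id, ": transcripts on multiple chroms/strands")
  names(transcripts) <- vapply(transcripts, function(t) t$transcript_id,
                               character(1))
  structure(list(gene_id = gene_id, transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (gene %s) %s:%s %d exon(s), %d nt mRNA>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), transcript_length(x)))
  invisible(x)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene %s: %d transcript(s)>\n", x$gene_id,
              length(x$transcripts)))
  invisible(x)
}

#' Map transcript ids to gene ids
#'
#' @param genes Named list of [gene_model()] objects.
#' @return Named character vector: `transcript_id -> gene_id`.
#' @export
transcript_gene_map <- function(genes) {
  ids <- unlist(lapply(genes, function(g) names(g$transcripts)),
                use.names = FALSE)
  gids <- unlist(lapply(genes, function(g)
    rep(g$gene_id, length(g$transcripts))), use.names = FALSE)
  setNames(gids, ids)
}

#' Introns of a transcript
#'
#' @param tx A [transcript_model()].
#' @return Data frame with columns `start`, `end` (0-based half-open), one
#'   row per intron in genomic order; zero rows for single-exon transcripts.
#' @export
transcript_introns <- function(tx) {
  ex <- tx$exons
  n <- nrow(ex)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = ex$end[-n], end = ex$start[-1L])
}

#' Spliced (mRNA) length of a transcript
#' @param tx A [transcript_model()].
#' @return Integer, sum of exon lengths.
#' @export
transcript_length <- function(tx) sum(tx$exons$end - tx$exons$start)

#' Genomic span of a transcript
#' @param tx A [transcript_model()].
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
transcript_span <- function(tx) c(tx$exons$start[1L], tx$exons$end[nrow(tx$exons)])

# ---- internal interval helpers (data frames with start/end, half-open) ----

iv_empty <- function() data.frame(start = integer(0), end = integer(0))

iv_total_len <- function(iv) if (nrow(iv) == 0L) 0L else sum(iv$end - iv$start)

# clip interval set to [l, r), dropping empties
iv_clip <- function(iv, l, r) {
  if (nrow(iv) == 0L) return(iv)
  s <- pmax(iv$start, l); e <- pmin(iv$end, r)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

# intersection of two sorted disjoint interval sets
iv_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_empty())
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start); e <- pmin(a$end[i], b$end)
    keep <- e > s
    out_s <- c(out_s, s[keep]); out_e <- c(out_e, e[keep])
  }
  o <- order(out_s)
  data.frame(start = out_s[o], end = out_e[o])
}

# a minus b, both sorted disjoint
iv_setdiff <- function(a, b) {
  if (nrow(a) == 0L) return(iv_empty())
  if (nrow(b) == 0L) return(a)
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(a))) {
    segs <- data.frame(start = a$start[i], end = a$end[i])
    for (j in seq_len(nrow(b))) {
      new_s <- integer(0); new_e <- integer(0)
      for (k in seq_len(nrow(segs))) {
        s <- segs$start[k]; e <- segs$end[k]
        bs <- b$start[j]; be <- b$end[j]
        if (be <= s || bs >= e) { new_s <- c(new_s, s); new_e <- c(new_e, e); next }
        if (bs > s) { new_s <- c(new_s, s); new_e <- c(new_e, bs) }
        if (be < e) { new_s <- c(new_s, be); new_e <- c(new_e, e) }
      }
      segs <- data.frame(start = new_s, end = new_e)
      if (nrow(segs) == 0L) break
    }
    out_s <- c(out_s, segs$start); out_e <- c(out_e, segs$end)
  }
  o <- order(out_s)
  data.frame(start = out_s[o], end = out_e[o])
}

# serialize intron set as "s-e;s-e" (deterministic, sorted)
iv_format <- function(iv) {
  if (nrow(iv) == 0L) return("")
  o <- order(iv$start)
  paste(sprintf("%d-%d", iv$start[o], iv$end[o]), collapse = ";")
}

iv_parse <- function(s) {
  if (is.na(s) || !nzchar(s)) return(iv_empty())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  data.frame(start = as.integer(vapply(parts, `[`, "", 1L)),
             end = as.integer(vapply(parts, `[`, "", 2L)))
}

# ---- mRNA coordinate mapping ----

# Map a genomic interval [s, e), which must lie within a single exon of tx,
# to forward-strand spliced offsets; strand handled by caller via mrna_len.
.fwd_offsets <- function(tx, s, e) {
  ex <- tx$exons
  cum <- c(0L, cumsum(ex$end - ex$start))
  i <- which(ex$start <= s & e <= ex$end)
  if (length(i) != 1L)
    stop("interval [", s, ",", e, ") not contained in one exon of ",
         tx$transcript_id)
  fs <- cum[i] + (s - ex$start[i])
  c(fs, fs + (e - s))
}

#' Map genomic intervals to an mRNA interval
#'
#' Maps a set of genomic intervals (each contained in a single exon of `tx`)
#' to transcript (mRNA) coordinates, 0-based from the 5' end, and returns the
#' enclosing interval. On the `-` strand mRNA coordinates run against the
#' genome.
#'
#' @param tx A [transcript_model()].
#' @param iv Data frame with `start`, `end` genomic intervals.
#' @return Integer vector `c(mrna_start, mrna_end)`, half-open.
#' @export
genomic_to_mrna <- function(tx, iv) {
  stopifnot(nrow(iv) >= 1L)
  L <- transcript_length(tx)
  offs <- lapply(seq_len(nrow(iv)),
                 function(i) .fwd_offsets(tx, iv$start[i], iv$end[i]))
  lo <- min(vapply(offs, `[`, 0, 1L))
  hi <- max(vapply(offs, `[`, 0, 2L))
  if (tx$strand == "+") c(lo, hi) else c(L - hi, L - lo)
}

# ---- sequence helpers ----

#' Reverse-complement a DNA string
#' @param s Character scalar over the IUPAC DNA alphabet.
#' @return Reverse complement, uppercase.
#' @export
revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# substring of a chromosome, 0-based half-open
seq_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  if (start < 0L || end > nchar(genome[[chrom]]) || start >= end)
    stop(sprintf("slice [%d,%d) out of bounds for %s", start, end, chrom))
  substr(genome[[chrom]], start + 1L, end)
}

#' Spliced mRNA sequence of a transcript
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result for `-` strand transcripts, yielding the mRNA 5'→3'.
#'
#' @param tx A [transcript_model()].
#' @param genome Named character vector of chromosome sequences
#'   (see [read_genome_fasta()]).
#' @return Character scalar.
#' @export
mrna_sequence <- function(tx, genome) {
  ex <- tx$exons
  parts <- vapply(seq_len(nrow(ex)), function(i)
    seq_slice(genome, tx$chrom, ex$start[i], ex$end[i]), character(1))
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") revcomp_dna(s) else s
}
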