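# Translated local alignment with Karlin-Altschul E-values: the in-package
# analogue of a tblastx search for homologous exonic sequence, and plain
# protein local alignment for orthology. Alignments are Smith-Waterman
# (affine gaps, BLOSUM62 by default) via Biostrings; E-values use the
# Karlin-Altschul formula E = K * m * n * exp(-lambda * S) with the search
# space m.n taken per comparison (translated lengths summed over frames),
# not database-wide, so the statistics differ slightly from a database
# tblastx run.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

#' Alignment configuration
#'
#' @param matrix Substitution matrix name; only `"BLOSUM62"` ships with the
#'   package.
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L
#'   costs `gap_open + gap_extend * L` (BLAST's 11/1 convention).
#' @param lambda,K Karlin-Altschul parameters for the gapped BLOSUM62 11/1
#'   regime.
#' @param homology_evalue E-value cutoff for flank homology searches
#'   (default 1e-5).
#' @param ortholog_evalue E-value cutoff for orthology (default 1e-50).
#' @param min_identity,min_coverage Orthology thresholds on identity over
#'   aligned columns and aligned query span over query length.
#' @return An `align_config` list.
#' @export
align_config <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                         lambda = 0.267, K = 0.041,
                         homology_evalue = 1e-5, ortholog_evalue = 1e-50,
                         min_identity = 0.4, min_coverage = 0.6) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  if (matrix != "BLOSUM62") stop("unsupported substitution matrix: ", matrix)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 homology_evalue = homology_evalue,
                 ortholog_evalue = ortholog_evalue,
                 min_identity = min_identity, min_coverage = min_coverage),
            class = "align_config")
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' @param score Raw Smith-Waterman score.
#' @param m,n Effective lengths of the two sequences searched.
#' @param config An [align_config()].
#' @return `E = K * m * n * exp(-lambda * score)`.
#' @export
karlin_altschul_evalue <- function(score, m, n, config = align_config()) {
  config$K * m * n * exp(-config$lambda * score)
}

#' Six-frame translation of a nucleotide sequence
#'
#' @param sequence Nucleotide string.
#' @return Character vector of up to six peptides (three forward frames of
#'   the sequence and of its reverse complement); frames without a full
#'   codon are dropped. Stop codons appear as `*`.
#' @export
six_frame_translate <- function(sequence) {
  s <- toupper(sequence)
  rc <- revcomp_dna(s)
  frames <- c(vapply(0:2, function(f) substr(s, f + 1L, nchar(s)), character(1)),
              vapply(0:2, function(f) substr(rc, f + 1L, nchar(rc)), character(1)))
  peps <- vapply(frames, translate_dna, character(1), USE.NAMES = FALSE)
  peps[nzchar(peps)]
}

# local SW score between two peptides (affine gaps, BLOSUM62 conventions)
.protein_sw_score <- function(p1, p2, config) {
  a <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = .blosum62, gapOpening = config$gap_open,
    gapExtension = config$gap_extend, type = "local", scoreOnly = TRUE)
  a
}

#' Translated local alignment of two nucleotide sequences
#'
#' Aligns every pair of the six translated frames of each sequence by local
#' Smith-Waterman (stop codons score as strong mismatches via the `*` row of
#' BLOSUM62) and converts the best raw score to a Karlin-Altschul E-value
#' with the search space `m * n` given by the translated lengths summed over
#' frames.
#'
#' @param seq_a,seq_b Nucleotide strings of length >= 3.
#' @param config An [align_config()].
#' @return List with `score` (best raw score; `NA` if either sequence has no
#'   full codon), `e_value` (`Inf` in that degenerate case), and `m`, `n`.
#' @export
translated_local_align <- function(seq_a, seq_b, config = align_config()) {
  fr_a <- six_frame_translate(seq_a)
  fr_b <- six_frame_translate(seq_b)
  if (!length(fr_a) || !length(fr_b))
    return(list(score = NA_real_, e_value = Inf, m = 0L, n = 0L))
  m <- sum(nchar(fr_a)); n <- sum(nchar(fr_b))
  pat <- Biostrings::AAStringSet(rep(fr_a, times = length(fr_b)))
  sub <- Biostrings::AAStringSet(rep(fr_b, each = length(fr_a)))
  scores <- Biostrings::pairwiseAlignment(
    pat, sub, substitutionMatrix = .blosum62,
    gapOpening = config$gap_open, gapExtension = config$gap_extend,
    type = "local", scoreOnly = TRUE)
  best <- max(scores)
  list(score = best, e_value = karlin_altschul_evalue(best, m, n, config),
       m = m, n = n)
}
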