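# Longest-ORF translation of mRNA sequences. Isoforms are translated from
# the longest ATG..stop span over the three forward frames of the (already
# oriented) mRNA; ties go to the 5'-most start. Transcripts without any
# ATG-to-stop span encoding at least one amino acid are treated as
# noncoding.

.CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

#' Translate a DNA sequence in frame 0
#'
#' Standard genetic code; stop codons become `*`; codons containing
#' ambiguity codes become `X`; a trailing partial codon is dropped.
#'
#' @param sequence Nucleotide string.
#' @return Amino-acid string.
#' @export
translate_dna <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  codons <- substring(s, starts, starts + 2L)
  aa <- .CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find the longest open reading frame of an mRNA
#'
#' Scans the three forward frames for ATG..stop spans (the span ends at the
#' first in-frame stop after each ATG, so the encoded protein has no
#' internal stop) and returns the longest; ties are broken by the 5'-most
#' start. The search is forward-only: mRNA sequences are already oriented.
#'
#' @param mrna_sequence Nucleotide string (IUPAC alphabet).
#' @param min_protein_length Minimum encoded protein length in amino acids
#'   (default 1; `ATGTAA` is noncoding).
#' @return An `orf_annotation` list with `orf_start`, `orf_end` (0-based
#'   half-open mRNA offsets; the span includes the stop codon), `protein`
#'   (without the stop) and `mrna_length`; or `NULL` when no qualifying ORF
#'   exists (a noncoding transcript).
#' @export
longest_orf <- function(mrna_sequence, min_protein_length = 1L) {
  s <- toupper(mrna_sequence)
  n <- nchar(s)
  if (n < 6L) return(NULL)
  best <- NULL
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    starts <- seq.int(f + 1L, by = 3L, length.out = ncod)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    stop_idx <- which(is_stop)
    atg_idx <- which(is_atg)
    if (!length(stop_idx) || !length(atg_idx)) next
    # first stop at/after each ATG
    pos <- findInterval(atg_idx - 1L, stop_idx) + 1L
    ok <- pos <= length(stop_idx)
    atg_idx <- atg_idx[ok]; pos <- pos[ok]
    if (!length(atg_idx)) next
    # for each stop keep the earliest ATG (the longest span ending there)
    keep <- !duplicated(pos)
    atg_idx <- atg_idx[keep]; stop_for <- stop_idx[pos[keep]]
    prot_len <- stop_for - atg_idx - 1L + 1L   # codons between ATG and stop, incl ATG
    # ORF nt span [orf_start, orf_end) includes the stop codon
    orf_start <- (atg_idx - 1L) * 3L + f
    orf_end <- stop_for * 3L + f
    lens <- orf_end - orf_start
    for (i in seq_along(lens)) {
      if (lens[i] < 3L * (min_protein_length + 2L)) next
      if (is.null(best) || lens[i] > best$len ||
          (lens[i] == best$len && orf_start[i] < best$start)) {
        best <- list(start = orf_start[i], end = orf_end[i], len = lens[i])
      }
    }
  }
  if (is.null(best)) return(NULL)
  prot_nt <- substr(s, best$start + 1L, best$end - 3L)
  structure(list(orf_start = best$start, orf_end = best$end,
                 protein = translate_dna(prot_nt), mrna_length = n),
            class = "orf_annotation")
}

#' @export
print.orf_annotation <- function(x, ...) {
  cat(sprintf("<ORF [%d,%d) on %d-nt mRNA; %d aa>\n",
              x$orf_start, x$orf_end, x$mrna_length, nchar(x$protein)))
  invisible(x)
}
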