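# Cross-species orthology by reciprocal best hit over protein local
# alignments. Each gene is represented by the longest-ORF protein of its
# most abundant surviving isoform; accepted pairs must satisfy the E-value,
# identity and coverage thresholds in both directions.

#' Representative protein per gene
#'
#' The longest-ORF protein of each gene's most abundant surviving isoform
#' (ties broken by transcript id). Genes whose representative isoform is
#' noncoding are omitted.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param genome Named character vector of chromosome sequences.
#' @param expression Data frame with `transcript_id`, `gene_id`,
#'   `mean_fpkm` (as returned by [filter_transcripts()]); when `NULL`, the
#'   lexicographically first transcript represents the gene.
#' @return Named character vector of proteins, names are gene ids.
#' @export
representative_proteins <- function(genes, genome, expression = NULL) {
  out <- character(0)
  for (gid in sort(names(genes))) {
    g <- genes[[gid]]
    tids <- sort(names(g$transcripts))
    if (!is.null(expression)) {
      ex <- expression[expression$gene_id == gid &
                         expression$transcript_id %in% tids, , drop = FALSE]
      if (nrow(ex)) {
        ex <- ex[order(-ex$mean_fpkm, ex$transcript_id), , drop = FALSE]
        tids <- ex$transcript_id[1L]
      } else tids <- tids[1L]
    } else tids <- tids[1L]
    orf <- longest_orf(mrna_sequence(g$transcripts[[tids]], genome))
    if (!is.null(orf)) out[gid] <- orf$protein
  }
  out
}

#' Reciprocal-best-hit ortholog pairs between two protein sets
#'
#' All-vs-all protein local alignment (Smith-Waterman, BLOSUM62, affine
#' gaps); reciprocal best hits by raw score are retained and the thresholds
#' are applied to both directions: Karlin-Altschul E-value below
#' `ortholog_evalue`, identity over aligned columns above `min_identity`,
#' and aligned span over query length above `min_coverage` for both
#' proteins.
#'
#' @param proteins_a,proteins_b Named character vectors (names are gene
#'   ids).
#' @param config An [align_config()].
#' @return Data frame: `gene_a`, `gene_b`, `score`, `e_value`, `identity`,
#'   `coverage_a`, `coverage_b`, sorted by `gene_a`.
#' @export
find_ortholog_pairs <- function(proteins_a, proteins_b,
                                config = align_config()) {
  if (!length(proteins_a) || !length(proteins_b))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), e_value = numeric(0),
                      identity = numeric(0), coverage_a = numeric(0),
                      coverage_b = numeric(0)))
  na <- length(proteins_a); nb <- length(proteins_b)
  ids_a <- names(proteins_a); ids_b <- names(proteins_b)
  bset <- Biostrings::AAStringSet(proteins_b)
  scores <- matrix(0, nrow = na, ncol = nb, dimnames = list(ids_a, ids_b))
  for (i in seq_len(na)) {
    scores[i, ] <- Biostrings::pairwiseAlignment(
      bset, Biostrings::AAString(proteins_a[[i]]),
      substitutionMatrix = .blosum62, gapOpening = config$gap_open,
      gapExtension = config$gap_extend, type = "local", scoreOnly = TRUE)
  }
  best_for_a <- apply(scores, 1L, which.max)
  best_for_b <- apply(scores, 2L, which.max)
  rows <- list()
  for (i in seq_len(na)) {
    j <- best_for_a[i]
    if (best_for_b[j] != i) next      # not reciprocal
    s <- scores[i, j]
    ev <- karlin_altschul_evalue(s, nchar(proteins_a[[i]]),
                                 nchar(proteins_b[[j]]), config)
    if (ev >= config$ortholog_evalue) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(proteins_a[[i]]),
      Biostrings::AAString(proteins_b[[j]]),
      substitutionMatrix = .blosum62, gapOpening = config$gap_open,
      gapExtension = config$gap_extend, type = "local")
    cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
    ident <- Biostrings::nmatch(aln) / cols
    cov_a <- Biostrings::width(Biostrings::pattern(aln)) /
      nchar(proteins_a[[i]])
    cov_b <- Biostrings::width(Biostrings::subject(aln)) /
      nchar(proteins_b[[j]])
    if (ident <= config$min_identity) next
    if (cov_a <= config$min_coverage || cov_b <= config$min_coverage) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_a = ids_a[i], gene_b = ids_b[j], score = s, e_value = ev,
      identity = ident, coverage_a = cov_a, coverage_b = cov_b,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(0), gene_b = character(0),
               score = numeric(0), e_value = numeric(0),
               identity = numeric(0), coverage_a = numeric(0),
               coverage_b = numeric(0))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
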