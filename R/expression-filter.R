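# Expression-level filtering applied before AS detection. Two gates, in
# order: a detection gate (FPKM above a floor in both biological replicates)
# and a relative-abundance gate (mean FPKM at least a configured fraction of
# the gene's most abundant gate-surviving isoform). Weak isoforms are the
# main source of spurious AS calls, which is why both gates precede event
# calling.

#' Expression filter configuration
#'
#' @param min_fpkm Detection floor in FPKM; a transcript must exceed this in
#'   both replicates (default 0.1).
#' @param min_major_fraction Minimum mean FPKM relative to the gene's most
#'   abundant surviving isoform; isoforms strictly below the fraction are
#'   removed (default 0.05, i.e. the 5% rule). Evaluated on the mean of the
#'   two replicates; an isoform at exactly the fraction survives.
#' @param require_both_replicates If `FALSE`, the detection gate passes when
#'   either replicate exceeds `min_fpkm` (default `TRUE`).
#' @param gene_level_detection If `TRUE`, the detection gate is applied per
#'   gene: all isoforms of a gene pass it when any single isoform does
#'   (default `FALSE`, i.e. per-transcript).
#' @param missing_expression What to do with a transcript lacking an
#'   expression record: `"drop"` (with a warning) or `"error"`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_fpkm = 0.1, min_major_fraction = 0.05,
                          require_both_replicates = TRUE,
                          gene_level_detection = FALSE,
                          missing_expression = c("drop", "error")) {
  stopifnot(min_fpkm >= 0, min_major_fraction >= 0, min_major_fraction <= 1)
  missing_expression <- match.arg(missing_expression)
  structure(list(min_fpkm = min_fpkm,
                 min_major_fraction = min_major_fraction,
                 require_both_replicates = require_both_replicates,
                 gene_level_detection = gene_level_detection,
                 missing_expression = missing_expression),
            class = "filter_config")
}

#' Filter transcripts by expression
#'
#' A transcript survives iff it passes the FPKM detection gate (above
#' `min_fpkm` in both replicates, by default) and its mean FPKM is at least
#' `min_major_fraction` times the mean FPKM of the gene's most abundant
#' gate-surviving transcript. Genes left with no transcripts are dropped.
#' Filtering is idempotent, and raising `min_major_fraction` never enlarges
#' the surviving set.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param expression Data frame with `transcript_id`, `fpkm_rep1`,
#'   `fpkm_rep2` (see [read_expression()]).
#' @param config A [filter_config()].
#' @return List with `genes` (the filtered gene models) and `expression`, a
#'   data frame with one row per surviving transcript: `transcript_id`,
#'   `gene_id`, `mean_fpkm`, `major_fpkm` (the gene's top surviving mean) and
#'   `isoform_ratio` (`mean_fpkm / major_fpkm`, in (0, 1]).
#' @export
filter_transcripts <- function(genes, expression, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  expr <- expression
  if (any(expr$fpkm_rep1 < 0 | expr$fpkm_rep2 < 0, na.rm = TRUE))
    stop("validation error: negative FPKM")
  idx <- setNames(seq_len(nrow(expr)), expr$transcript_id)
  out_genes <- list()
  out_rows <- list()
  for (gid in sort(names(genes))) {
    g <- genes[[gid]]
    tids <- sort(names(g$transcripts))
    known <- tids %in% names(idx)
    if (any(!known)) {
      msg <- paste0("gene ", gid, ": no expression record for ",
                    paste(tids[!known], collapse = ", "))
      if (config$missing_expression == "error") stop(msg)
      warning(msg, call. = FALSE)
      tids <- tids[known]
    }
    if (!length(tids)) next
    r1 <- expr$fpkm_rep1[idx[tids]]
    r2 <- expr$fpkm_rep2[idx[tids]]
    detected <- if (config$require_both_replicates)
      r1 > config$min_fpkm & r2 > config$min_fpkm
    else
      r1 > config$min_fpkm | r2 > config$min_fpkm
    if (config$gene_level_detection && any(detected))
      detected[] <- TRUE
    mean_fpkm <- (r1 + r2) / 2
    if (!any(detected)) next
    major <- max(mean_fpkm[detected])
    keep <- detected & mean_fpkm >= config$min_major_fraction * major
    if (!any(keep)) next
    kept_ids <- tids[keep]
    out_genes[[gid]] <- gene_model(gid, g$transcripts[kept_ids])
    out_rows[[gid]] <- data.frame(
      transcript_id = kept_ids, gene_id = gid,
      mean_fpkm = mean_fpkm[keep], major_fpkm = major,
      isoform_ratio = mean_fpkm[keep] / major,
      stringsAsFactors = FALSE)
  }
  expression_out <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(transcript_id = character(0), gene_id = character(0),
               mean_fpkm = numeric(0), major_fpkm = numeric(0),
               isoform_ratio = numeric(0))
  rownames(expression_out) <- NULL
  list(genes = out_genes, expression = expression_out)
}

#' Isoform ratio of an AS event
#'
#' The expression of the minor transcript divided by that of the gene's most
#' abundant transcript.
#'
#' @param minor_fpkm Abundance of the minor isoform (FPKM).
#' @param major_fpkm Abundance of the most abundant isoform (FPKM); must be
#'   positive.
#' @return Ratio in \[0, 1\]; 0 only for a zero-abundance minor isoform,
#'   which no retention filter would keep.
#' @export
isoform_ratio <- function(minor_fpkm, major_fpkm) {
  if (any(major_fpkm <= 0))
    stop("undefined isoform ratio: major_fpkm must be > 0")
  if (any(minor_fpkm < 0)) stop("negative minor_fpkm")
  minor_fpkm / major_fpkm
}

#' Percentage of transcripts affected by AS
#'
#' @param n_as_transcripts Number of transcripts participating in at least
#'   one AS event.
#' @param n_total_transcripts Total number of (filtered) transcripts; must
#'   be positive.
#' @return Percentage, `100 * n_as / n_total`.
#' @export
percent_as_transcripts <- function(n_as_transcripts, n_total_transcripts) {
  stopifnot(n_total_transcripts > 0, n_as_transcripts >= 0,
            n_as_transcripts <= n_total_transcripts)
  100 * n_as_transcripts / n_total_transcripts
}
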