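# Readers/writers for the external formats every stage shares: GTF transcript
# models, genome FASTA, and the pipeline's TSV tables. GTF coordinates are
# 1-based inclusive on disk and converted to the internal 0-based half-open
# convention on read.

#' Read gene models from a GTF file
#'
#' Parses `exon` features (other feature types are ignored), groups them by
#' `transcript_id` within `gene_id`, and converts coordinates from GTF's
#' 1-based inclusive convention to internal 0-based half-open. Single-exon
#' transcripts are retained: they can be the intron-retaining partner of an
#' IR event. Transcripts with identical exon chains under one gene are
#' deduplicated, keeping the lexicographically smallest transcript id.
#'
#' @param path Path to a GTF2.2 file whose exon rows carry `gene_id` and
#'   `transcript_id` attributes.
#' @return Named list of [gene_model()] objects, sorted by gene id.
#' @export
read_gtf <- function(path) {
  .gtf_precheck(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(structure(list(), names = character(0)))
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id))
    stop("GTF exon rows must carry gene_id and transcript_id attributes")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based
    end = GenomicRanges::end(gr),            # inclusive -> half-open
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    stringsAsFactors = FALSE)
  if (any(df$strand == "*"))
    stop("GTF exon without strand")
  genes <- list()
  for (gid in sort(unique(df$gene_id))) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    txs <- list()
    for (tid in sort(unique(gdf$transcript_id))) {
      tdf <- gdf[gdf$transcript_id == tid, , drop = FALSE]
      tdf <- tdf[order(tdf$start), , drop = FALSE]
      txs[[tid]] <- transcript_model(tid, gid, tdf$chrom[1L], tdf$strand[1L],
                                     tdf[, c("start", "end")])
    }
    # deduplicate identical exon chains, keeping smallest id
    keys <- vapply(txs, function(t)
      paste(t$chrom, t$strand, iv_format(t$exons)), character(1))
    keep <- !duplicated(keys)   # txs already sorted by id
    genes[[gid]] <- gene_model(gid, txs[keep])
  }
  genes
}

# cheap structural validation so malformed lines fail with a line number
.gtf_precheck <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, got %d",
                   i, length(f)))
    if (f[3L] != "exon") next
    s <- suppressWarnings(as.integer(f[4L])); e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(s) || is.na(e))
      stop(sprintf("GTF parse error at line %d: non-numeric coordinates", i))
    if (e < s)
      stop(sprintf("GTF validation error at line %d: end (%d) < start (%d)", i, e, s))
  }
  invisible(TRUE)
}

#' Write gene models to a GTF file
#'
#' Emits one `exon` row per exon, converting internal 0-based half-open
#' coordinates back to GTF's 1-based inclusive convention. Rows are ordered
#' by gene id, transcript id, then coordinate, so output is deterministic.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(genes, path) {
  rows <- list()
  for (gid in sort(names(genes))) {
    g <- genes[[gid]]
    for (tid in sort(names(g$transcripts))) {
      tx <- g$transcripts[[tid]]
      ex <- tx$exons
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, source = "woodsplice", feature = "exon",
        start = ex$start + 1L, end = ex$end, score = ".",
        strand = tx$strand, frame = ".",
        attributes = sprintf('gene_id "%s"; transcript_id "%s";', gid, tid),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' Read a genome FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of uppercased sequences; IUPAC ambiguity
#'   codes are preserved. An empty file yields an empty vector.
#' @export
read_genome_fasta <- function(path) {
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1L])
  setNames(toupper(as.character(ss)), ids)
}

#' Write a genome FASTA file
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# ---- TSV tables -----------------------------------------------------------

.read_tsv_schema <- function(path, required, numeric_cols = character(0)) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", basename(path), ": missing column '",
         missing[1L], "'")
  for (cc in intersect(numeric_cols, names(df)))
    df[[cc]] <- as.numeric(df[[cc]])
  df[, required, drop = FALSE]
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-transcript expression table
#'
#' @param path TSV with columns `transcript_id`, `fpkm_rep1`, `fpkm_rep2`
#'   (abundances in FPKM, one biological replicate per column).
#' @return Data frame with those columns; negative FPKM is a validation
#'   error.
#' @export
read_expression <- function(path) {
  df <- .read_tsv_schema(path, c("transcript_id", "fpkm_rep1", "fpkm_rep2"),
                         c("fpkm_rep1", "fpkm_rep2"))
  if (any(df$fpkm_rep1 < 0 | df$fpkm_rep2 < 0, na.rm = TRUE))
    stop("validation error: negative FPKM in ", basename(path))
  df[order(df$transcript_id), , drop = FALSE]
}

#' Write a per-transcript expression table
#' @param df Data frame with `transcript_id`, `fpkm_rep1`, `fpkm_rep2`.
#' @param path Output path.
#' @export
write_expression <- function(df, path) {
  if (any(df$fpkm_rep1 < 0 | df$fpkm_rep2 < 0, na.rm = TRUE))
    stop("validation error: negative FPKM")
  .write_tsv(df[order(df$transcript_id),
                c("transcript_id", "fpkm_rep1", "fpkm_rep2")], path)
}

DOMAIN_COLS <- c("protein_id", "domain_name", "aa_start", "aa_end", "e_value")

#' Read a protein domain hit table
#'
#' @param path TSV with columns `protein_id`, `domain_name`, `aa_start`,
#'   `aa_end` (0-based half-open amino-acid offsets) and `e_value`.
#' @return Data frame of domain hits.
#' @export
read_domain_table <- function(path) {
  df <- .read_tsv_schema(path, DOMAIN_COLS, c("aa_start", "aa_end", "e_value"))
  if (any(df$aa_start < 0 | df$aa_end <= df$aa_start))
    stop("validation error: bad amino-acid interval in ", basename(path))
  if (any(df$e_value < 0)) stop("validation error: negative e_value")
  df[order(df$protein_id, df$domain_name, df$aa_start), , drop = FALSE]
}

#' Write a protein domain hit table
#' @param df Data frame with the columns of [read_domain_table()].
#' @param path Output path.
#' @export
write_domain_table <- function(df, path) {
  .write_tsv(df[order(df$protein_id, df$domain_name, df$aa_start),
                DOMAIN_COLS], path)
}

#' Convert hmmscan domtblout output to the package's domain table
#'
#' Extracts target protein, query domain name, envelope amino-acid
#' coordinates (converted from HMMER's 1-based inclusive columns to 0-based
#' half-open) and the independent E-value from a `--domtblout` file.
#'
#' @param path Path to a hmmscan `--domtblout` file.
#' @return Data frame in the layout of [read_domain_table()].
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(protein_id = character(0), domain_name = character(0),
                      aa_start = integer(0), aa_end = integer(0),
                      e_value = numeric(0)))
  rows <- lapply(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(f) < 22L) stop("malformed domtblout line: ", ln)
    # domtblout: target(1) ... query(4) ... i-Evalue(13) ... env from(20) to(21)
    data.frame(protein_id = f[4L], domain_name = f[1L],
               aa_start = as.integer(f[20L]) - 1L, aa_end = as.integer(f[21L]),
               e_value = as.numeric(f[13L]), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[order(df$protein_id, df$domain_name, df$aa_start), , drop = FALSE]
}

EVENT_COLS <- c("gene_id", "event_type", "isoform_a", "isoform_b", "chrom",
                "strand", "var_start", "var_end", "alt_introns_a",
                "alt_introns_b", "changed_length", "inclusion_isoform",
                "mrna_start", "mrna_end", "supporting_pairs")

.sort_events <- function(ev) {
  ev[order(ev$gene_id, ev$var_start, ev$var_end, ev$event_type), ,
     drop = FALSE]
}

#' Write / read the AS event table
#'
#' Writers emit a fixed column order with rows sorted by gene then
#' coordinate, so serialization is deterministic; `read_events` restores the
#' typed table and is the writer's inverse.
#'
#' @param events Data frame of AS events as produced by
#'   [collect_gene_events()] (one row per deduplicated event).
#' @param path File path.
#' @return `read_events` returns the event data frame.
#' @export
write_events <- function(events, path) {
  ev <- events
  for (cc in setdiff(EVENT_COLS, names(ev))) ev[[cc]] <- NA
  ev <- .sort_events(ev)[, EVENT_COLS, drop = FALSE]
  .write_tsv(ev, path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- .read_tsv_schema(path, EVENT_COLS,
                         c("var_start", "var_end", "changed_length",
                           "mrna_start", "mrna_end"))
  for (cc in c("var_start", "var_end", "changed_length", "mrna_start",
               "mrna_end"))
    df[[cc]] <- as.integer(df[[cc]])
  for (cc in c("alt_introns_a", "alt_introns_b", "supporting_pairs"))
    df[[cc]][is.na(df[[cc]])] <- ""
  .sort_events(df)
}

IMPACT_COLS <- c("gene_id", "event_type", "var_start", "var_end",
                 "inclusion_isoform", "location", "frameshift",
                 "aa_start", "aa_end", "modified_domains", "domains_gained",
                 "domains_lost", "utr3_length", "location_discordant")

#' Write / read the event impact table
#' @param impacts Data frame as produced by [annotate_event_impacts()].
#' @param path File path.
#' @export
write_impacts <- function(impacts, path) {
  im <- impacts
  for (cc in setdiff(IMPACT_COLS, names(im))) im[[cc]] <- NA
  im <- im[order(im$gene_id, im$var_start, im$var_end, im$event_type),
           IMPACT_COLS, drop = FALSE]
  .write_tsv(im, path)
}

#' @rdname write_impacts
#' @export
read_impacts <- function(path) {
  df <- .read_tsv_schema(path, IMPACT_COLS,
                         c("var_start", "var_end", "aa_start", "aa_end",
                           "utr3_length"))
  for (cc in c("var_start", "var_end", "aa_start", "aa_end", "utr3_length"))
    df[[cc]] <- as.integer(df[[cc]])
  df$frameshift <- as.logical(df$frameshift)
  df$location_discordant <- as.logical(df$location_discordant)
  for (cc in c("modified_domains", "domains_gained", "domains_lost"))
    df[[cc]][is.na(df[[cc]])] <- ""
  df[order(df$gene_id, df$var_start, df$var_end, df$event_type), ,
     drop = FALSE]
}

CONSERVED_COLS <- c("gene_a", "gene_b", "event_type", "intron_a_start",
                    "intron_a_end", "intron_b_start", "intron_b_end",
                    "up_evalue", "down_evalue")

#' Write / read the conserved AS event table
#' @param conserved Data frame as produced by [conserved_events()].
#' @param path File path.
#' @export
write_conserved <- function(conserved, path) {
  cv <- conserved
  for (cc in setdiff(CONSERVED_COLS, names(cv))) cv[[cc]] <- NA
  cv <- cv[order(cv$gene_a, cv$gene_b, cv$intron_a_start, cv$intron_b_start),
           CONSERVED_COLS, drop = FALSE]
  .write_tsv(cv, path)
}

#' @rdname write_conserved
#' @export
read_conserved <- function(path) {
  df <- .read_tsv_schema(path, CONSERVED_COLS,
                         c("intron_a_start", "intron_a_end", "intron_b_start",
                           "intron_b_end", "up_evalue", "down_evalue"))
  for (cc in c("intron_a_start", "intron_a_end", "intron_b_start",
               "intron_b_end"))
    df[[cc]] <- as.integer(df[[cc]])
  df[order(df$gene_a, df$gene_b, df$intron_a_start, df$intron_b_start), ,
     drop = FALSE]
}

ORTHOLOG_COLS <- c("gene_a", "gene_b", "score", "e_value", "identity",
                   "coverage_a", "coverage_b")

#' Write / read the ortholog pair table
#' @param pairs Data frame as produced by [find_ortholog_pairs()].
#' @param path File path.
#' @export
write_orthologs <- function(pairs, path) {
  pr <- pairs[order(pairs$gene_a, pairs$gene_b), ORTHOLOG_COLS, drop = FALSE]
  .write_tsv(pr, path)
}

#' @rdname write_orthologs
#' @export
read_orthologs <- function(path) {
  df <- .read_tsv_schema(path, ORTHOLOG_COLS,
                         c("score", "e_value", "identity", "coverage_a",
                           "coverage_b"))
  df[order(df$gene_a, df$gene_b), , drop = FALSE]
}
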