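# Intron-level sequence features: AT content of constitutive versus
# alternative introns, and position frequency matrices over donor/acceptor
# junction windows.

#' AT content of a nucleotide sequence
#'
#' Fraction of unambiguous bases that are A or T; IUPAC ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param sequence Non-empty nucleotide string.
#' @return Fraction in \[0, 1\]; `NaN` if no unambiguous base remains.
#' @export
at_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  s <- toupper(sequence)
  counts <- table(strsplit(s, "", fixed = TRUE)[[1L]])
  at <- sum(counts[names(counts) %in% c("A", "T")])
  acgt <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
  at / acgt
}

#' Compare AT content between two intron groups
#'
#' Two-sided Welch (unequal-variance) t test on two groups of AT-content
#' fractions, e.g. alternative versus constitutive introns.
#'
#' @param group1,group2 Numeric vectors of AT fractions, each of length >= 2.
#' @return List with `statistic` (t), `p_value`, `df`, and the two group
#'   means. Two identical zero-variance groups return `t = 0, p = 1` rather
#'   than an error.
#' @export
compare_at_content <- function(group1, group2) {
  stopifnot(length(group1) >= 2L, length(group2) >= 2L)
  if (stats::var(group1) == 0 && stats::var(group2) == 0 &&
      mean(group1) == mean(group2))
    return(list(statistic = 0, p_value = 1,
                df = length(group1) + length(group2) - 2,
                mean1 = mean(group1), mean2 = mean(group2)))
  tt <- t.test(group1, group2, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean1 = mean(group1), mean2 = mean(group2))
}

#' Classify introns as constitutive or alternative and compute AT content
#'
#' An intron is alternative iff it participates in at least one AS event
#' (i.e. appears among the event table's alternative introns); all other
#' introns of the surviving transcripts are constitutive.
#'
#' @param genes Named list of [gene_model()] objects (post-filtering).
#' @param genome Named character vector of chromosome sequences.
#' @param events Event data frame (see [collect_all_events()]).
#' @return Data frame: `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `status` (`"alternative"`/`"constitutive"`), `at_content`, and
#'   `event_types` (semicolon-joined types the intron participates in, empty
#'   for constitutive introns).
#' @export
intron_features <- function(genes, genome, events) {
  alt <- event_alt_introns(events)
  alt_key <- if (nrow(alt)) paste(alt$chrom, alt$start, alt$end) else character(0)
  # types per alternative intron
  type_map <- new.env(parent = emptyenv())
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      iv <- rbind(iv_parse(events$alt_introns_a[i]),
                  iv_parse(events$alt_introns_b[i]))
      if (!nrow(iv)) next
      for (j in seq_len(nrow(iv))) {
        k <- paste(events$chrom[i], iv$start[j], iv$end[j])
        type_map[[k]] <- sort(unique(c(type_map[[k]], events$event_type[i])))
      }
    }
  }
  rows <- list()
  for (gid in sort(names(genes))) {
    g <- genes[[gid]]
    for (tid in sort(names(g$transcripts))) {
      tx <- g$transcripts[[tid]]
      intr <- transcript_introns(tx)
      if (!nrow(intr)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, chrom = tx$chrom, strand = tx$strand,
        start = intr$start, end = intr$end, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), status = character(0),
                      at_content = numeric(0), event_types = character(0)))
  df <- unique(do.call(rbind, rows))
  key <- paste(df$chrom, df$start, df$end)
  df$status <- ifelse(key %in% alt_key, "alternative", "constitutive")
  df$at_content <- vapply(seq_len(nrow(df)), function(i) {
    s <- seq_slice(genome, df$chrom[i], df$start[i], df$end[i])
    if (df$strand[i] == "-") s <- revcomp_dna(s)
    at_content(s)
  }, numeric(1))
  df$event_types <- vapply(key, function(k) {
    t <- type_map[[k]]
    if (is.null(t)) "" else paste(t, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Position frequency matrices at splice junctions
#'
#' Builds per-position base-frequency matrices over donor windows (the last
#' `exonic` bases of the upstream exon followed by the first `intronic`
#' bases of the intron) and acceptor windows (the last `intronic` intron
#' bases followed by the first `exonic` bases of the downstream exon), in
#' transcription orientation; minus-strand windows are
#' reverse-complemented. For canonical introns the donor intronic positions
#' +1/+2 are G/T and the acceptor intronic positions -2/-1 are A/G.
#'
#' @param introns Data frame with `chrom`, `strand`, `start`, `end`
#'   (0-based half-open, forward-strand coordinates).
#' @param genome Named character vector of chromosome sequences.
#' @param exonic,intronic Window sizes (bases) on each side of the junction.
#' @return List with matrices `donor` and `acceptor` (rows A, C, G, T;
#'   columns positions; each used column sums to 1), plus `n` (introns
#'   counted).
#' @export
junction_pwm <- function(introns, genome, exonic = 3L, intronic = 6L) {
  stopifnot(exonic >= 1L, intronic >= 1L)
  w <- exonic + intronic
  donor_seqs <- character(0); acceptor_seqs <- character(0)
  for (i in seq_len(nrow(introns))) {
    ch <- introns$chrom[i]; s <- introns$start[i]; e <- introns$end[i]
    L <- nchar(genome[[ch]])
    if (introns$strand[i] == "+") {
      if (s - exonic < 0L || e + exonic > L) next
      donor_seqs <- c(donor_seqs, seq_slice(genome, ch, s - exonic, s + intronic))
      acceptor_seqs <- c(acceptor_seqs, seq_slice(genome, ch, e - intronic, e + exonic))
    } else {
      if (s - exonic < 0L || e + exonic > L) next
      donor_seqs <- c(donor_seqs, revcomp_dna(seq_slice(genome, ch, e - intronic, e + exonic)))
      acceptor_seqs <- c(acceptor_seqs, revcomp_dna(seq_slice(genome, ch, s - exonic, s + intronic)))
    }
  }
  count_matrix <- function(seqs) {
    m <- matrix(0, nrow = 4L, ncol = w,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (s in seqs) {
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      for (p in seq_len(w)) if (ch[p] %in% rownames(m))
        m[ch[p], p] <- m[ch[p], p] + 1
    }
    cs <- colSums(m)
    for (p in seq_len(w)) if (cs[p] > 0) m[, p] <- m[, p] / cs[p]
    m
  }
  list(donor = count_matrix(donor_seqs),
       acceptor = count_matrix(acceptor_seqs),
       exonic = exonic, intronic = intronic, n = length(donor_seqs))
}
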