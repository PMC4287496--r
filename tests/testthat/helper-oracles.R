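# Independent oracles: each recomputes a quantity by a different route than
# the implementation (per-position base vectors instead of interval
# arithmetic, exhaustive scans instead of indexed search, dynamic
# programming written from the recurrence, hypergeometric enumeration).

# ---- brute-force splice-chain segmentation oracle --------------------------
# Works on literal per-position exonic indicator vectors over the overlap.
oracle_classify <- function(txa, txb) {
  empty <- data.frame(event_type = character(0), var_start = integer(0),
                      var_end = integer(0), changed_length = integer(0))
  span_a <- c(txa$exons$start[1L], txa$exons$end[nrow(txa$exons)])
  span_b <- c(txb$exons$start[1L], txb$exons$end[nrow(txb$exons)])
  l0 <- max(span_a[1L], span_b[1L]); r0 <- min(span_a[2L], span_b[2L])
  if (l0 >= r0) return(empty)
  pos <- l0:(r0 - 1L)
  indicator <- function(tx) {
    v <- logical(length(pos))
    for (i in seq_len(nrow(tx$exons)))
      v[pos >= tx$exons$start[i] & pos < tx$exons$end[i]] <- TRUE
    v
  }
  ea <- indicator(txa); eb <- indicator(txb)
  # intron runs over each transcript's full span (per-position route)
  intron_runs <- function(tx) {
    sp <- c(tx$exons$start[1L], tx$exons$end[nrow(tx$exons)])
    p <- sp[1L]:(sp[2L] - 1L)
    v <- logical(length(p))
    for (i in seq_len(nrow(tx$exons)))
      v[p >= tx$exons$start[i] & p < tx$exons$end[i]] <- TRUE
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0L, head(ends, -1L))
    runs <- data.frame(start = sp[1L] + starts, end = sp[1L] + ends)
    runs[!r$values, , drop = FALSE]
  }
  ia <- intron_runs(txa); ib <- intron_runs(txb)
  # shared splice sites: positions strictly inside overlap where both have
  # the same kind of boundary
  inside <- function(x) x[x > l0 & x < r0]
  shared <- sort(unique(c(
    intersect(inside(txa$exons$end), inside(txb$exons$end)),
    intersect(inside(txa$exons$start), inside(txb$exons$start)))))
  cuts <- c(l0, shared, r0)
  out <- empty
  for (k in seq_len(length(cuts) - 1L)) {
    l <- cuts[k]; r <- cuts[k + 1L]
    sel <- pos >= l & pos < r
    d <- sum(ea[sel] != eb[sel])
    if (d == 0L) next
    ra <- ia[ia$end > l & ia$start < r, , drop = FALSE]
    rb <- ib[ib$end > l & ib$start < r, , drop = FALSE]
    if (any(ra$start < l | ra$end > r) || any(rb$start < l | rb$end > r))
      next   # intron crossing an overlap bound: terminal, not emitted
    na <- nrow(ra); nb <- nrow(rb)
    type <- if (na > 0L && nb == 0L) "IR"
    else if (na == 0L && nb > 0L) "IR"
    else if (nb == 1L && rb$start[1L] == l && rb$end[1L] == r && na >= 2L) "ES"
    else if (na == 1L && ra$start[1L] == l && ra$end[1L] == r && nb >= 2L) "ES"
    else if (na == 1L && nb == 1L) {
      ss <- ra$start[1L] == rb$start[1L]; se <- ra$end[1L] == rb$end[1L]
      if (ss && !se) { if (txa$strand == "+") "AltA" else "AltD" }
      else if (se && !ss) { if (txa$strand == "+") "AltD" else "AltA" }
      else "AltP"
    } else "AltP"
    out <- rbind(out, data.frame(event_type = type, var_start = l,
                                 var_end = r, changed_length = d))
  }
  out
}

# random two-isoform gene sharing the span [0, L): up to `max_exons` exons
random_isoform_pair <- function(L = sample(200:800, 1L), max_exons = 6L) {
  chain <- function(id) {
    k <- sample(0:(max_exons - 1L), 1L)   # introns
    b <- sort(sample(seq_len(L - 1L), 2L * k))
    starts <- c(0L, b[seq_len(k) * 2L])
    ends <- c(b[seq_len(k) * 2L - 1L], L)
    transcript_model(id, "g", "chr", "+", data.frame(start = starts, end = ends))
  }
  list(a = chain("tA"), b = chain("tB"))
}

# ---- affine-gap Smith-Waterman oracle (Gotoh recurrence) -------------------
blosum62_matrix <- local({
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

oracle_sw_score <- function(p1, p2, mat = blosum62_matrix,
                            open = 11, ext = 1) {
  a <- strsplit(p1, "")[[1L]]; b <- strsplit(p2, "")[[1L]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)
  F <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2:(n + 1L)) for (j in 2:(m + 1L)) {
    E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
    F[i, j] <- max(H[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
    H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[a[i - 1L], b[j - 1L]],
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# ---- exhaustive longest-ORF oracle -----------------------------------------
oracle_longest_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- NULL
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(s, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- substr(s, j, j + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- j + 3L - i
        if (len >= 9L &&
            (is.null(best) || len > best$len ||
             (len == best$len && i - 1L < best$start)))
          best <- list(start = i - 1L, end = j + 2L, len = len)
        break
      }
      j <- j + 3L
    }
  }
  if (is.null(best)) return(NULL)
  c(best$start, best$end)
}

# ---- exhaustive two-sided Fisher oracle ------------------------------------
# Sum of hypergeometric probabilities not exceeding the observed table's
# (with fisher.test's relative tolerance for floating-point ties).
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0L, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(dens[dens <= p0 * (1 + 1e-7)])
}

# random DNA helper for sequence-level tests
random_dna_str <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

random_peptide <- function(n) {
  aas <- setdiff(rownames(blosum62_matrix), c("*", "X", "B", "Z", "J", "U", "O"))
  paste(sample(aas, n, replace = TRUE), collapse = "")
}
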