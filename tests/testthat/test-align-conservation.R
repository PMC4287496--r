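test_that("translated alignment separates identical coding sequence from noise", {
  set.seed(81)
  cds <- paste0("ATG", paste(sample(woodsplice:::.SENSE_CODONS, 32, TRUE),
                             collapse = ""), "TAA")
  self <- translated_local_align(cds, cds)
  expect_lt(self$e_value, 1e-5)
  far <- translated_local_align(strrep("A", 100L), strrep("C", 100L))
  expect_gt(far$e_value, 1e-5)
  # degenerate: no full codon
  none <- translated_local_align("AC", "ACGTACGT")
  expect_true(is.infinite(none$e_value))
})

test_that("alignment scores equal the quadratic Gotoh oracle on peptide pairs", {
  set.seed(91)
  for (i in 1:30) {
    p1 <- random_peptide(sample(5:50, 1L))
    p2 <- random_peptide(sample(5:50, 1L))
    expect_equal(woodsplice:::.protein_sw_score(p1, p2, align_config()),
                 oracle_sw_score(p1, p2))
  }
})

test_that("self-alignment has the minimal E-value among equal-length partners", {
  set.seed(101)
  x <- random_dna_str(90)
  e_self <- translated_local_align(x, x)$e_value
  for (i in 1:10)
    expect_gte(translated_local_align(x, random_dna_str(90))$e_value, e_self)
})

test_that("flank extraction follows transcription orientation and flags truncation", {
  genome <- c(chr = random_dna_str(600))
  g <- gene_model("g", list(
    transcript_model("g.t1", "g", "chr", "+",
                     data.frame(start = c(0L, 200L), end = c(100L, 300L))),
    transcript_model("g.t2", "g", "chr", "+",
                     data.frame(start = 0L, end = 300L))))
  ev <- collect_gene_events(g)$events
  fl <- extract_flanks(ev[1L, ], g, genome, flank_len = 100L)
  expect_equal(fl$upstream_flank, substr(genome[["chr"]], 1L, 100L))
  expect_equal(fl$downstream_flank, substr(genome[["chr"]], 201L, 300L))
  expect_false(fl$upstream_truncated)
  # a 40-bp exon yields a flagged 40-bp flank
  g2 <- gene_model("h", list(
    transcript_model("h.t1", "h", "chr", "+",
                     data.frame(start = c(60L, 200L), end = c(100L, 300L))),
    transcript_model("h.t2", "h", "chr", "+",
                     data.frame(start = 60L, end = 300L))))
  ev2 <- collect_gene_events(g2)$events
  fl2 <- extract_flanks(ev2[1L, ], g2, genome, flank_len = 100L)
  expect_equal(nchar(fl2$upstream_flank), 40L)
  expect_true(fl2$upstream_truncated)
})

test_that("mirrored minus-strand constructions give reverse-complement flanks", {
  L <- 600L
  genome_p <- c(chr = random_dna_str(L))
  genome_m <- c(chr = revcomp_dna(genome_p[["chr"]]))
  gp <- gene_model("g", list(
    transcript_model("g.t1", "g", "chr", "+",
                     data.frame(start = c(100L, 300L), end = c(250L, 450L))),
    transcript_model("g.t2", "g", "chr", "+",
                     data.frame(start = 100L, end = 450L))))
  # mirror image on the minus strand of the reverse-complemented genome
  mir <- function(s, e) c(L - e, L - s)
  e1 <- mir(100L, 250L); e2 <- mir(300L, 450L)
  gm <- gene_model("g", list(
    transcript_model("g.t1", "g", "chr", "-",
                     data.frame(start = c(e2[1L], e1[1L]), end = c(e2[2L], e1[2L]))),
    transcript_model("g.t2", "g", "chr", "-",
                     data.frame(start = L - 450L, end = L - 100L))))
  evp <- collect_gene_events(gp)$events
  evm <- collect_gene_events(gm)$events
  flp <- extract_flanks(evp[1L, ], gp, genome_p, flank_len = 80L)
  flm <- extract_flanks(evm[1L, ], gm, genome_m, flank_len = 80L)
  expect_equal(flm$upstream_flank, flp$upstream_flank)
  expect_equal(flm$downstream_flank, flp$downstream_flank)
})

test_that("conserved introns require both flanks homologous (AND rule)", {
  set.seed(111)
  cds1 <- paste(sample(woodsplice:::.SENSE_CODONS, 34, TRUE), collapse = "")
  cds2 <- paste(sample(woodsplice:::.SENSE_CODONS, 34, TRUE), collapse = "")
  fa <- data.frame(intron_start = 0L, intron_end = 10L,
                   upstream_flank = cds1, downstream_flank = cds2,
                   upstream_truncated = FALSE, downstream_truncated = FALSE)
  # both flanks identical: conserved
  expect_equal(nrow(conserved_introns(fa, fa)), 1L)
  # only one flank homologous: not conserved
  fb <- fa; fb$downstream_flank <- random_dna_str(102)
  expect_equal(nrow(conserved_introns(fa, fb)), 0L)
  # shuffled flanks: not conserved
  shuffle <- function(s) paste(sample(strsplit(s, "")[[1L]]), collapse = "")
  fc <- fa
  fc$upstream_flank <- shuffle(fa$upstream_flank)
  fc$downstream_flank <- shuffle(fa$downstream_flank)
  expect_equal(nrow(conserved_introns(fa, fc)), 0L)
})

test_that("lowering the homology E-value cutoff never enlarges the conserved set", {
  sim <- small_sim()
  res <- small_run()
  n_prev <- Inf
  for (cutoff in c(1e-3, 1e-5, 1e-10, 1e-20)) {
    cv <- conserved_events(res$a$events, res$b$events, res$orthologs,
                           res$a$filtered$genes, res$b$filtered$genes,
                           sim$species_a$genome, sim$species_b$genome,
                           align_config(homology_evalue = cutoff))
    expect_lte(nrow(cv), n_prev)
    n_prev <- nrow(cv)
  }
})

test_that("orthology accepts identical proteins and rejects unrelated ones", {
  set.seed(121)
  p <- random_peptide(160)
  pairs <- find_ortholog_pairs(c(gA = p), c(gB = p))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$identity, 1.0)
  expect_equal(pairs$coverage_a, 1.0)
  expect_equal(pairs$coverage_b, 1.0)
  expect_lt(pairs$e_value, 1e-50)
  none <- find_ortholog_pairs(c(gA = random_peptide(160)),
                              c(gB = random_peptide(160)))
  expect_equal(nrow(none), 0L)
  expect_equal(nrow(find_ortholog_pairs(character(0), c(gB = p))), 0L)
})

test_that("reciprocal best hits recover the planted ortholog map", {
  sim <- small_sim()
  res <- small_run()
  truth <- sim$truth$orthologs
  got <- res$orthologs[, c("gene_a", "gene_b")]
  expect_setequal(paste(got$gene_a, got$gene_b),
                  paste(truth$gene_a, truth$gene_b))
  expect_true(all(res$orthologs$identity > 0.4))
  expect_true(all(res$orthologs$coverage_a > 0.6 &
                    res$orthologs$coverage_b > 0.6))
  expect_true(all(res$orthologs$e_value < 1e-50))
})

test_that("conserved event calling is symmetric under species swap", {
  sim <- small_sim()
  res <- small_run()
  swapped <- conserved_events(res$b$events, res$a$events,
                              data.frame(gene_a = res$orthologs$gene_b,
                                         gene_b = res$orthologs$gene_a),
                              res$b$filtered$genes, res$a$filtered$genes,
                              sim$species_b$genome, sim$species_a$genome)
  expect_setequal(paste(swapped$gene_b, swapped$gene_a, swapped$event_type),
                  paste(res$conserved$gene_a, res$conserved$gene_b,
                        res$conserved$event_type))
})

test_that("same conserved intron with different event types is rejected", {
  sim <- small_sim()
  res <- small_run()
  # relabel one species' event types so no pair can agree
  ev_b <- res$b$events
  ev_b$event_type <- ifelse(ev_b$event_type == "IR", "AltA", "IR")
  cv <- conserved_events(res$a$events, ev_b, res$orthologs,
                         res$a$filtered$genes, res$b$filtered$genes,
                         sim$species_a$genome, sim$species_b$genome)
  truth_pairs <- paste(sim$truth$conserved$gene_a, sim$truth$conserved$gene_b)
  expect_false(any(paste(cv$gene_a, cv$gene_b) %in% truth_pairs))
  # the original same-type pairs were all recovered
  expect_setequal(paste(res$conserved$gene_a, res$conserved$gene_b,
                        res$conserved$event_type),
                  paste(sim$truth$conserved$gene_a, sim$truth$conserved$gene_b,
                        sim$truth$conserved$event_type))
})
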