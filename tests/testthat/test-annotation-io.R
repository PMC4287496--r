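test_that("GTF coordinates convert between 1-based inclusive and internal half-open", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", ".", "exon", "101", "200", ".", "+", ".",
                   'gene_id "g1"; transcript_id "t1";', sep = "\t"), path)
  genes <- read_gtf(path)
  ex <- genes$g1$transcripts$t1$exons
  expect_equal(ex$start, 100L)
  expect_equal(ex$end, 200L)
  expect_equal(ex$end - ex$start, 200L - 101L + 1L)  # length identity
})

test_that("transcripts sharing a gene_id group into one gene model", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", ".", "exon", "1", "100", ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", ".", "exon", "201", "300", ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", ".", "exon", "1", "300", ".", "+", ".",
          'gene_id "g1"; transcript_id "t2";', sep = "\t")), path)
  genes <- read_gtf(path)
  expect_length(genes, 1L)
  expect_length(genes$g1$transcripts, 2L)
  expect_equal(nrow(genes$g1$transcripts$t1$exons), 2L)
})

test_that("GTF reader is independent of row order and dedups identical chains", {
  base <- c(
    paste("chr1", ".", "exon", "1", "100", ".", "+", ".",
          'gene_id "g1"; transcript_id "t2";', sep = "\t"),
    paste("chr1", ".", "exon", "201", "300", ".", "+", ".",
          'gene_id "g1"; transcript_id "t2";', sep = "\t"),
    paste("chr1", ".", "exon", "1", "100", ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("chr1", ".", "exon", "201", "300", ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"))
  p1 <- withr::local_tempfile(fileext = ".gtf")
  p2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(base, p1)
  writeLines(rev(base), p2)
  g1 <- read_gtf(p1); g2 <- read_gtf(p2)
  # t1 and t2 have identical chains: smallest id kept, any row order
  expect_equal(names(g1$g1$transcripts), "t1")
  expect_identical(g1, g2)
})

test_that("malformed GTF lines fail with a line number", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", ".", "exon", "1", "100", ".", "+", ".",
          'gene_id "g"; transcript_id "t";', sep = "\t"),
    "chr1 exon broken"), path)
  expect_error(read_gtf(path), "line 2")
  writeLines(paste("chr1", ".", "exon", "500", "100", ".", "+", ".",
                   'gene_id "g"; transcript_id "t";', sep = "\t"), path)
  expect_error(read_gtf(path), "end.*<.*start|line 1")
})

test_that("GTF write-read round trip is the identity on the model", {
  genes <- tiny_genes()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(genes, path)
  back <- read_gtf(path)
  expect_identical(back, genes)
  # and on a full synthetic annotation
  sim <- small_sim()
  p2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$species_a$genes, p2)
  expect_identical(read_gtf(p2), sim$species_a$genes)
})

test_that("FASTA reading uppercases, preserves ambiguity codes, rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c", "acgtn", ">d", "ACGT"), path)
  g <- read_genome_fasta(path)
  expect_identical(g, c(c = "ACGTN", d = "ACGT"))
  writeLines(c(">c", "AAAA", ">c", "CCCC"), path)
  expect_error(read_genome_fasta(path), "duplicate")
  file.create(p3 <- withr::local_tempfile(fileext = ".fa"))
  expect_length(read_genome_fasta(p3), 0L)
})

test_that("expression and domain tables validate schema and values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tfpkm_rep1\tfpkm_rep2", "t1\t10.0\t12.0"), path)
  df <- read_expression(path)
  expect_equal(df$transcript_id, "t1")
  expect_equal(df$fpkm_rep1, 10.0)
  expect_equal(df$fpkm_rep2, 12.0)
  writeLines(c("transcript_id\tfpkm_rep1", "t1\t10.0"), path)
  expect_error(read_expression(path), "fpkm_rep2")
  writeLines(c("transcript_id\tfpkm_rep1\tfpkm_rep2", "t1\t-1\t2"), path)
  expect_error(read_expression(path), "negative FPKM")
  writeLines(c("protein_id\tdomain_name\taa_start\taa_end\te_value",
               "p1\tPF1\t0\t10\t1e-20"), path)
  dd <- read_domain_table(path)
  expect_equal(dd$aa_end, 10)
})

test_that("tabular writers and readers are inverse on pipeline outputs", {
  res <- small_run()
  d <- withr::local_tempdir()
  write_events(res$a$events, file.path(d, "ev.tsv"))
  expect_equal(read_events(file.path(d, "ev.tsv")),
               .sort_events(res$a$events)[, EVENT_COLS],
               ignore_attr = TRUE)
  write_impacts(res$a$impacts, file.path(d, "im.tsv"))
  im <- read_impacts(file.path(d, "im.tsv"))
  expect_equal(nrow(im), nrow(res$a$impacts))
  expect_setequal(im$location, res$a$impacts$location)
  write_conserved(res$conserved, file.path(d, "cv.tsv"))
  cv <- read_conserved(file.path(d, "cv.tsv"))
  expect_equal(cv[, c("gene_a", "gene_b", "event_type")],
               res$conserved[order(res$conserved$gene_a, res$conserved$gene_b,
                                   res$conserved$intron_a_start),
                             c("gene_a", "gene_b", "event_type")],
               ignore_attr = TRUE)
  write_orthologs(res$orthologs, file.path(d, "or.tsv"))
  expect_equal(read_orthologs(file.path(d, "or.tsv")), res$orthologs,
               ignore_attr = TRUE, tolerance = 1e-12)
  sim <- small_sim()
  write_expression(sim$species_a$expression, file.path(d, "ex.tsv"))
  ex <- read_expression(file.path(d, "ex.tsv"))
  o <- order(sim$species_a$expression$transcript_id)
  expect_equal(ex, sim$species_a$expression[o, ], ignore_attr = TRUE,
               tolerance = 1e-9)
  write_domain_table(sim$species_a$domains, file.path(d, "dm.tsv"))
  expect_equal(read_domain_table(file.path(d, "dm.tsv")),
               sim$species_a$domains, ignore_attr = TRUE)
})

test_that("domtblout conversion extracts protein, domain, envelope and E-value", {
  path <- withr::local_tempfile(fileext = ".domtblout")
  hdr <- "# --- full sequence --- etc"
  ln <- paste("AP2", "PF00847.1", "60", "tx9.t1", "-", "300", "1.2e-30",
              "90.1", "0.1", "1", "2", "4e-28", "2.1e-25", "80.0", "0.1",
              "3", "58", "100", "160", "99", "161", "0.95", "desc here")
  writeLines(c(hdr, ln), path)
  df <- read_domtblout(path)
  expect_equal(df$protein_id, "tx9.t1")
  expect_equal(df$domain_name, "AP2")
  expect_equal(df$aa_start, 98L)   # 1-based env from=99 -> 0-based 98
  expect_equal(df$aa_end, 161L)
  expect_equal(df$e_value, 2.1e-25)
})
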