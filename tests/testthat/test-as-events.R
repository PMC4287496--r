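tx <- function(id, starts, ends, strand = "+", gene = "g") {
  transcript_model(id, gene, "chr", strand,
                   data.frame(start = as.integer(starts), end = as.integer(ends)))
}

test_that("canonical structures are typed IR, AltA, ES with correct changed length", {
  ir <- classify_event_pair(tx("a", c(0, 200), c(100, 300)), tx("b", 0, 300))
  expect_equal(ir$event_type, "IR")
  expect_equal(ir$alt_introns_a, "100-200")
  expect_equal(ir$inclusion_isoform, "b")
  expect_equal(ir$changed_length, 100L)

  aa <- classify_event_pair(tx("a", c(0, 200), c(100, 300)),
                            tx("b", c(0, 230), c(100, 300)))
  expect_equal(aa$event_type, "AltA")
  expect_equal(aa$changed_length, 30L)
  expect_equal(aa$inclusion_isoform, "a")

  es <- classify_event_pair(tx("a", c(0, 200, 400), c(100, 300, 500)),
                            tx("b", c(0, 400), c(100, 500)))
  expect_equal(es$event_type, "ES")
  expect_equal(es$changed_length, 100L)
  expect_equal(es$var_start, 100L)
  expect_equal(es$var_end, 400L)
})

test_that("donor/acceptor typing follows transcription orientation on the minus strand", {
  # shared genomic start, differing genomic end: AltA on +, AltD on -
  plus <- classify_event_pair(tx("a", c(0, 200), c(100, 300)),
                              tx("b", c(0, 230), c(100, 300)))
  minus <- classify_event_pair(tx("a", c(0, 200), c(100, 300), "-"),
                               tx("b", c(0, 230), c(100, 300), "-"))
  expect_equal(plus$event_type, "AltA")
  expect_equal(minus$event_type, "AltD")
  # shared genomic end, differing genomic start: AltD on +, AltA on -
  plus2 <- classify_event_pair(tx("a", c(0, 200), c(100, 300)),
                               tx("b", c(0, 200), c(70, 300)))
  minus2 <- classify_event_pair(tx("a", c(0, 200), c(100, 300), "-"),
                                tx("b", c(0, 200), c(70, 300), "-"))
  expect_equal(plus2$event_type, "AltD")
  expect_equal(minus2$event_type, "AltA")
})

test_that("an intron shifted at both ends is the AltP catch-all", {
  ev <- classify_event_pair(tx("a", c(0, 300), c(100, 400)),
                            tx("b", c(0, 280), c(130, 400)))
  expect_equal(ev$event_type, "AltP")
  expect_equal(ev$changed_length, 30L + 20L)
  expect_equal(ev$inclusion_isoform, "b")
})

test_that("degenerate pairs: no overlap is empty, different strands error", {
  expect_equal(nrow(classify_event_pair(tx("a", 0, 100), tx("b", 500, 600))), 0L)
  expect_error(classify_event_pair(tx("a", 0, 100), tx("b", 0, 100, "-")),
               "strand")
  # identical chains: no events
  expect_equal(nrow(classify_event_pair(tx("a", c(0, 200), c(100, 300)),
                                        tx("b", c(0, 200), c(100, 300)))), 0L)
})

test_that("classification is symmetric in the isoform order", {
  set.seed(21)
  for (i in 1:60) {
    p <- random_isoform_pair()
    e1 <- classify_event_pair(p$a, p$b)
    e2 <- classify_event_pair(p$b, p$a)
    expect_equal(e1$event_type, e2$event_type)
    expect_equal(e1$var_start, e2$var_start)
    expect_equal(e1$var_end, e2$var_end)
    expect_equal(e1$changed_length, e2$changed_length)
    expect_equal(e1$inclusion_isoform, e2$inclusion_isoform)
    expect_equal(e1$alt_introns_a, e2$alt_introns_b)
    if (nrow(e1)) expect_true(all(e1$changed_length >= 1L))
  }
})

test_that("random splice-chain pairs match the per-position segmentation oracle", {
  set.seed(31)
  for (i in 1:100) {
    p <- random_isoform_pair()
    got <- classify_event_pair(p$a, p$b)
    want <- oracle_classify(p$a, p$b)
    expect_equal(got$event_type, want$event_type)
    expect_equal(got$var_start, want$var_start)
    expect_equal(got$var_end, want$var_end)
    expect_equal(got$changed_length, want$changed_length)
  }
})

test_that("every alternative intron belongs to one of the two isoforms", {
  set.seed(41)
  for (i in 1:40) {
    p <- random_isoform_pair()
    ev <- classify_event_pair(p$a, p$b)
    if (!nrow(ev)) next
    ia <- woodsplice:::iv_format(transcript_introns(p$a))
    ib <- woodsplice:::iv_format(transcript_introns(p$b))
    own <- function(fmt, pool) {
      if (!nzchar(fmt)) return(TRUE)
      all(strsplit(fmt, ";")[[1]] %in% strsplit(pool, ";")[[1]])
    }
    for (j in seq_len(nrow(ev))) {
      expect_true(own(ev$alt_introns_a[j], ia))
      expect_true(own(ev$alt_introns_b[j], ib))
    }
  }
})

test_that("gene-level collection deduplicates events across isoform pairs", {
  g <- gene_model("g", list(
    tx("t1", c(0, 200), c(100, 300)),
    tx("t2", 0, 300),
    tx("t3", c(0, 200), c(100, 300))))
  # pairs (t1,t2) and (t2,t3) produce the same IR: one merged event
  res <- collect_gene_events(g)
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$event_type, "IR")
  expect_equal(res$events$supporting_pairs, "t1|t2;t2|t3")
  expect_setequal(res$as_transcripts, c("t1", "t2", "t3"))
  # a single-isoform gene yields nothing
  g1 <- gene_model("h", list(tx("u1", c(0, 200), c(100, 300), gene = "h")))
  expect_equal(nrow(collect_gene_events(g1)$events), 0L)
})

test_that("AT content counts only unambiguous bases", {
  expect_equal(at_content("ATAT"), 1.0)
  expect_equal(at_content("GCGC"), 0.0)
  expect_equal(at_content("ATGC"), 0.5)
  expect_equal(at_content("ATNNGC"), 0.5)   # N excluded from both sides
})

test_that("AT-content comparison is a two-sided Welch t test", {
  ident <- compare_at_content(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  sep <- compare_at_content(c(0, 0, 1e-8), c(1, 1, 1 - 1e-8))
  expect_lt(sep$p_value, 1e-6)
  set.seed(51)
  x <- rnorm(12, 0.6, 0.05); y <- rnorm(9, 0.5, 0.08)
  got <- compare_at_content(x, y)
  # direct Welch formula
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  t_ref <- (mean(x) - mean(y)) / se
  df_ref <- se^4 / ((var(x) / length(x))^2 / (length(x) - 1) +
                    (var(y) / length(y))^2 / (length(y) - 1))
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(got$statistic, t_ref, tolerance = 1e-12)
  expect_equal(got$p_value, p_ref, tolerance = 1e-12)
})

test_that("intron classification marks exactly the event introns as alternative", {
  sim <- small_sim()
  res <- small_run()
  feats <- res$a$introns
  expect_true(all(feats$status %in% c("alternative", "constitutive")))
  alt <- feats[feats$status == "alternative", ]
  want <- event_alt_introns(res$a$events)
  expect_setequal(paste(alt$chrom, alt$start, alt$end),
                  paste(want$chrom, want$start, want$end))
  expect_true(all(nzchar(alt$event_types)))
  expect_true(all(!nzchar(feats$event_types[feats$status == "constitutive"])))
  expect_true(all(feats$at_content >= 0 & feats$at_content <= 1))
})
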