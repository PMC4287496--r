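test_that("the generator is deterministic: same seed gives byte-identical files", {
  cfg <- simulation_config(seed = 77L, n_genes = 12L,
                           events_per_type = c(IR = 1L, AltA = 1L, AltD = 1L,
                                               ES = 1L, AltP = 1L),
                           conserved_fraction = 0.4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_species_data(generate_species_pair(cfg), d1)
  p2 <- write_species_data(generate_species_pair(cfg), d2)
  for (nm in names(p1))
    expect_identical(unname(tools::md5sum(p1[nm])),
                     unname(tools::md5sum(p2[nm])), label = nm)
  # a different seed changes the data
  cfg2 <- cfg; cfg2$seed <- 78L
  d3 <- withr::local_tempdir()
  p3 <- write_species_data(generate_species_pair(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(p1["fasta_a"])),
                         unname(tools::md5sum(p3["fasta_a"]))))
})

test_that("a config with 10 IR events plants exactly 10 intron-retaining isoforms", {
  cfg <- simulation_config(seed = 78L, n_genes = 15L,
                           events_per_type = c(IR = 10L, AltA = 0L, AltD = 0L,
                                               ES = 0L, AltP = 0L),
                           conserved_fraction = 0,
                           specific_partner_fraction = 0)
  sim <- generate_species_pair(cfg)
  ta <- truth_species(sim, "A")
  expect_equal(nrow(ta), 10L)
  expect_true(all(ta$event_type == "IR"))
  # each IR gene's minor isoform has exactly one exon less than the major
  n_retaining <- 0L
  for (gid in ta$gene_id) {
    g <- sim$species_a$genes[[gid]]
    n_ex <- vapply(g$transcripts, function(t) nrow(t$exons), integer(1))
    if (n_ex[paste0(gid, ".t2")] == n_ex[paste0(gid, ".t1")] - 1L)
      n_retaining <- n_retaining + 1L
  }
  expect_equal(n_retaining, 10L)
})

test_that("every emitted transcript passes model validation and introns are GT-AG", {
  sim <- small_sim()
  for (sp in list(sim$species_a, sim$species_b)) {
    for (g in sp$genes) for (t in g$transcripts) {
      # reconstructing the model revalidates all invariants
      expect_silent(transcript_model(t$transcript_id, t$gene_id, t$chrom,
                                     t$strand, t$exons))
      intr <- transcript_introns(t)
      for (i in seq_len(nrow(intr))) {
        s <- if (t$strand == "+")
          substr(sp$genome[[t$chrom]], intr$start[i] + 1L, intr$end[i])
        else revcomp_dna(substr(sp$genome[[t$chrom]], intr$start[i] + 1L,
                                intr$end[i]))
        expect_equal(substr(s, 1L, 2L), "GT")
        expect_equal(substr(s, nchar(s) - 1L, nchar(s)), "AG")
      }
    }
  }
})

test_that("FPKM tables respect the configured minor/major ratio band", {
  sim <- small_sim()
  cfg <- sim$config
  expr <- sim$species_a$expression
  mean_fpkm <- (expr$fpkm_rep1 + expr$fpkm_rep2) / 2
  names(mean_fpkm) <- expr$transcript_id
  for (gid in truth_species(sim, "A")$gene_id) {
    ratio <- mean_fpkm[paste0(gid, ".t2")] / mean_fpkm[paste0(gid, ".t1")]
    expect_gte(ratio, cfg$minor_ratio_range[1L] - 1e-9)
    expect_lte(ratio, cfg$minor_ratio_range[2L] + 1e-9)
  }
})

test_that("sub-threshold isoforms are planted below the filter and removed by it", {
  cfg <- simulation_config(seed = 79L, n_genes = 12L,
                           events_per_type = c(IR = 2L, AltA = 2L, AltD = 1L,
                                               ES = 0L, AltP = 0L),
                           conserved_fraction = 0, plant_subthreshold = TRUE)
  sim <- generate_species_pair(cfg)
  sub_ids <- grep("\\.t3$", sim$species_a$expression$transcript_id,
                  value = TRUE)
  expect_gt(length(sub_ids), 0L)
  filt <- filter_transcripts(sim$species_a$genes, sim$species_a$expression)
  expect_false(any(sub_ids %in% filt$expression$transcript_id))
  # planted events still recovered exactly despite the extra isoform
  called <- collect_all_events(filt$genes)
  ta <- truth_species(sim, "A")
  m <- merge(called$events[, c("gene_id", "event_type", "changed_length")],
             ta[, c("gene_id", "event_type", "changed_length")])
  expect_equal(nrow(m), nrow(ta))
  expect_equal(nrow(called$events), nrow(ta))
})

test_that("sequence mutation hits the requested rate and honors protection", {
  s <- random_dna_str(10000)
  expect_identical(mutate_sequence(s, 0), s)
  m1 <- mutate_sequence(s, 1, protected = c(0L, 1L, 2L))
  expect_equal(substr(m1, 1L, 3L), substr(s, 1L, 3L))
  ch_s <- strsplit(s, "")[[1L]][-(1:3)]
  ch_m <- strsplit(m1, "")[[1L]][-(1:3)]
  expect_true(all(ch_s != ch_m))   # rate 1: nothing unprotected survives
  m2 <- mutate_sequence(s, 0.1, seed = 5L)
  frac <- mean(strsplit(s, "")[[1L]] != strsplit(m2, "")[[1L]])
  sigma <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(frac - 0.1), 3 * sigma)
  expect_identical(mutate_sequence(s, 0.1, seed = 5L), m2)  # seeded: reproducible
})

test_that("an event plan needing more genes than configured is rejected", {
  expect_error(
    simulation_config(seed = 1L, n_genes = 3L) |> generate_species_pair(),
    "infeasible")
})
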