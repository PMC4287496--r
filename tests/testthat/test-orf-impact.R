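test_that("longest ORF handles the canonical small cases", {
  o <- longest_orf("GGATGAAATAAGG")
  expect_equal(o$orf_start, 2L)
  expect_equal(o$orf_end, 11L)
  expect_equal(o$protein, "MK")
  expect_null(longest_orf("ATGTAA"))          # empty-body protein
  expect_null(longest_orf("ACGT"))            # shorter than 6 nt
  expect_null(longest_orf("AAAAAAAAAAAA"))    # no ATG..stop span
  # tie broken by 5'-most start
  s <- paste0("ATGAAATAA", "G", "ATGCCCTAA")
  expect_equal(longest_orf(s)$orf_start, 0L)
})

test_that("longest ORF equals the exhaustive ATG/stop scan on random sequences", {
  set.seed(61)
  for (i in 1:60) {
    s <- random_dna_str(sample(30:1500, 1L))
    want <- oracle_longest_orf(s)
    got <- longest_orf(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(c(got$orf_start, got$orf_end), want)
      expect_false(grepl("*", got$protein, fixed = TRUE))
      expect_equal(nchar(got$protein), (want[2] - want[1]) / 3 - 1)
    }
  }
})

test_that("event localization uses strict UTR bounds and any-overlap for the ORF", {
  orf <- structure(list(orf_start = 50L, orf_end = 250L, protein = strrep("A", 65L),
                        mrna_length = 400L), class = "orf_annotation")
  expect_equal(locate_event(10L, 20L, orf), "UTR5")
  expect_equal(locate_event(100L, 130L, orf), "ORF")
  expect_equal(locate_event(40L, 60L, orf), "ORF")    # boundary-spanning
  expect_equal(locate_event(250L, 260L, orf), "UTR3")
  expect_equal(locate_event(10L, 20L, NULL), "noncoding")
  expect_equal(locate_event(10L, 50L, orf), "UTR5")   # half-open: ends at start
})

test_that("frameshift flag is changed length mod 3 within the ORF", {
  expect_false(frameshift_flag(3L, "ORF"))
  expect_true(frameshift_flag(100L, "ORF"))
  expect_true(is.na(frameshift_flag(100L, "UTR5")))
  expect_error(frameshift_flag(0L, "ORF"))
})

test_that("mRNA-to-protein mapping uses floor/ceil codon arithmetic", {
  orf <- structure(list(orf_start = 0L, orf_end = 300L,
                        protein = strrep("A", 99L), mrna_length = 400L),
                   class = "orf_annotation")
  expect_equal(map_event_to_protein(30L, 45L, orf, FALSE), c(10L, 15L))
  expect_equal(map_event_to_protein(31L, 32L, orf, FALSE), c(10L, 11L))
  # frameshift extends to the C-terminus
  expect_equal(map_event_to_protein(60L, 61L, orf, TRUE), c(20L, 99L))
  # never outside [0, protein length]
  expect_equal(map_event_to_protein(290L, 299L, orf, FALSE)[2L], 99L)
})

test_that("domain modification needs >= 1 aa overlap; gain/loss is per copy", {
  hit <- function(dom, s, e) data.frame(protein_id = "p", domain_name = dom,
                                        aa_start = s, aa_end = e, e_value = 0)
  m1 <- domain_modification(c(50L, 70L), hit("D", 10L, 60L), NULL)
  expect_equal(m1$modified, "D")
  m2 <- domain_modification(c(70L, 80L), hit("D", 10L, 60L), NULL)
  expect_equal(m2$modified, character(0))
  # two AP2 copies vs one after exon skipping: registers as one-copy loss
  inc <- rbind(hit("AP2", 10L, 70L), hit("AP2", 100L, 160L))
  exc <- hit("AP2", 10L, 70L)
  m3 <- domain_modification(c(100L, 140L), inc, exc)
  expect_equal(m3$modified, "AP2")
  expect_equal(m3$lost, "AP2")
  expect_equal(m3$gained, character(0))
  # a frameshift truncating the inclusion protein at the event still
  # modifies downstream domains of the exclusion protein
  m4 <- domain_modification(c(116L, 116L), NULL, hit("D", 113L, 121L),
                            frameshift = TRUE)
  expect_equal(m4$modified, "D")
  m5 <- domain_modification(c(116L, 116L), NULL, hit("D", 113L, 121L),
                            frameshift = FALSE)
  expect_equal(m5$modified, character(0))
})

test_that("planted impacts are recovered: location, frameshift and affected domains", {
  sim <- small_sim()
  res <- small_run()
  for (species in c("A", "B")) {
    truth <- truth_species(sim, species)
    imp <- if (species == "A") res$a$impacts else res$b$impacts
    ix <- match(paste(truth$gene_id, truth$event_type),
                paste(imp$gene_id, imp$event_type))
    expect_false(anyNA(ix))
    expect_equal(imp$location[ix], truth$location)
    in_orf <- truth$location == "ORF"
    expect_equal(imp$frameshift[ix][in_orf], truth$frame_disrupting[in_orf])
  }
  # every planted "affected" domain is reported as modified (species A truth)
  aff <- sim$truth$domains[sim$truth$domains$relation == "affected", ]
  for (i in seq_len(nrow(aff))) {
    row <- res$a$impacts[res$a$impacts$gene_id == aff$gene_id[i], ]
    expect_true(grepl(aff$domain_name[i], row$modified_domains[1L]),
                label = paste("affected domain reported:", aff$gene_id[i]))
  }
})

test_that("Fisher enrichment matches closed-form small tables", {
  gd <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   domain_name = "D")
  # build (1,1,1,1): universe g1..g4 all with D? no - craft via flags
  # direct check of the p values through the enumeration oracle instead
  expect_equal(oracle_fisher_p(1, 1, 1, 1), 1.0)
  expect_equal(oracle_fisher_p(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(oracle_fisher_p(0, 5, 5, 0), 2 / 252, tolerance = 1e-12)
  # and that the implementation agrees on an assembled gene table
  gd2 <- data.frame(
    gene_id = paste0("g", 1:10),
    domain_name = rep(c("D1", "D2"), each = 5))
  enr <- fisher_domain_enrichment(gd2, as_modified_genes = paste0("g", 1:5))
  # D1: a=5,b=0,c=0,d=5 ; D2: a=0,b=5,c=5,d=0
  expect_equal(enr$p_value[enr$domain_name == "D1"],
               oracle_fisher_p(5, 0, 0, 5), tolerance = 1e-12)
  expect_equal(enr$p_value[enr$domain_name == "D2"],
               oracle_fisher_p(0, 5, 5, 0), tolerance = 1e-12)
  expect_true(all(enr$a + enr$b + enr$c + enr$d == 10))
  expect_true(all(enr$significant == (enr$p_value < 0.05)))
})

test_that("motif scanning reports every occurrence including overlaps", {
  hits <- scan_motif_domains("AAKRKRAA", c(KR = "KRKR"))
  expect_equal(hits$aa_start, 2L)
  expect_equal(hits$aa_end, 6L)
  expect_equal(nrow(scan_motif_domains("AAAA", c(KR = "KRKR"))), 0L)
  # overlapping occurrences each reported; oracle = naive all-positions scan
  set.seed(71)
  for (i in 1:20) {
    prot <- paste(sample(c("A", "B", "K", "R"), 40, TRUE), collapse = "")
    pat <- paste(sample(c("A", "K", "R"), 3, TRUE), collapse = "")
    got <- scan_motif_domains(prot, setNames(pat, "m"))$aa_start
    want <- which(vapply(seq_len(nchar(prot) - nchar(pat) + 1L), function(p)
      substr(prot, p, p + nchar(pat) - 1L) == pat, logical(1))) - 1L
    expect_equal(got, as.integer(want))
  }
})
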