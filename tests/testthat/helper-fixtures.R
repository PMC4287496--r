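# Shared fixtures, generated in code and cached for the duration of one
# test run. The "small" pair has 3 planted events per type in each species,
# 40% of them shared, at the generator's default mutation rates.

.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- generate_species_pair(simulation_config(
      seed = 401L, n_genes = 30L,
      events_per_type = c(IR = 3L, AltA = 3L, AltD = 3L, ES = 3L, AltP = 3L),
      conserved_fraction = 0.4))
  }
  .fixture_cache$sim
}

small_run <- function() {
  if (is.null(.fixture_cache$run)) {
    sim <- small_sim()
    .fixture_cache$run <- run_pipeline(sim$species_a, sim$species_b)
  }
  .fixture_cache$run
}

# truth rows for one species
truth_species <- function(sim, species) {
  sim$truth$events[sim$truth$events$species == species, , drop = FALSE]
}

# tiny two-gene fixture with obvious structure for IO tests
tiny_genes <- function() {
  t1 <- transcript_model("g1.t1", "g1", "chr1", "+",
                         data.frame(start = c(100L, 300L), end = c(200L, 400L)))
  t2 <- transcript_model("g1.t2", "g1", "chr1", "+",
                         data.frame(start = 100L, end = 400L))
  t3 <- transcript_model("g2.t1", "g2", "chr1", "-",
                         data.frame(start = c(600L, 800L), end = c(700L, 900L)))
  list(g1 = gene_model("g1", list(t1, t2)), g2 = gene_model("g2", list(t3)))
}
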