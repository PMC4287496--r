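#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-species study data.
#
# Two artificial wood-transcriptome-like "species" are built with planted
# AS events of all five types (IR, AltA, AltD, ES, AltP), orthologous gene
# copies at 5% nucleotide divergence, and 40% of events shared between the
# species at identical intron placement with flanks diverged at 10%.
# Everything downstream (02-06) reads the files written here.

suppressPackageStartupMessages(library(woodsplice))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1L]]) else 2026L

cfg <- simulation_config(seed = seed)
sim <- generate_species_pair(cfg)
paths <- write_species_data(sim, "results/data")

ta <- sim$truth$events[sim$truth$events$species == "A", ]
cat(sprintf("seed %d: %d genes per species, %d planted events per species\n",
            seed, cfg$n_genes, nrow(ta)))
cat(sprintf("planted per type: %s\n",
            paste(sprintf("%s=%d", names(cfg$events_per_type),
                          cfg$events_per_type), collapse = " ")))
cat(sprintf("ortholog pairs: %d, shared (conserved) events: %d\n",
            nrow(sim$truth$orthologs), nrow(sim$truth$conserved)))
cat("wrote:", paste(basename(paths), collapse = " "), "\n")
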