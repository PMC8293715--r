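#!/usr/bin/env Rscript
# Stage 1: generate the synthetic valley survey.
#
# Emulates the study design: 96 plots evenly spaced over 1,800-5,400 m
# a.s.l., a 545-species pool with a planted range-size slope of 0.25 m per m
# of midpoint elevation, six weather stations at their surveyed elevations,
# two towns plus small villages for the population surface, and a
# present-minus-LGM offset layer from three synthetic stand-in climate
# models. All downstream stages read only the CSVs written here.

suppressPackageStartupMessages(library(elevrange))

seed <- 20260101L
cfg <- synthetic_config(seed = seed)
dir.create("results", showWarnings = FALSE)
paths <- write_synthetic_inputs(cfg, "results/synthetic_inputs")

comm <- generate_community(cfg)
cat("wrote", length(paths), "input files under results/synthetic_inputs\n")
cat(sprintf("community: %d plots x %d species, %d presences (fill %.1f%%)\n",
            nrow(comm$occ$plots), ncol(comm$occ$matrix),
            sum(comm$occ$matrix),
            100 * mean(comm$occ$matrix)))
cat(sprintf("latent range sizes: mean %.0f m, planted slope %.2f m/m\n",
            mean(comm$latent$latent_size_m), cfg$rapoport_slope_b))
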