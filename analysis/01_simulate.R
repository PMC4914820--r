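#!/usr/bin/env Rscript
# Stage 1: simulate the study materials.
#
# The anthology corpus behind the published analysis is not deposited, so
# the workflow runs on a synthetic stand-in: four cells (stress- vs
# syllable-timed regime x children's vs folk) of 60 songs whose target
# nPVIs and dispersions are set to the printed cell summaries, plus rating
# panels of 70 monolingual American, 30 bilingual American and 40 French
# listeners. Writes notes.csv, ratings.csv and manifest.json.

suppressPackageStartupMessages(library(songrhythm))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 20260923L

paths <- run_simulate("results/sim", synth_config(), seed = seed)
cat("Corpus and panel simulated; manifest records seed", seed, "\n")
cat("  ", paste(paths, collapse = "\n   "), "\n")
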