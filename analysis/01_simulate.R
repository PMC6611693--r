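#!/usr/bin/env Rscript
# Stage 1: generate the synthetic patent study.
#
# Writes a complete synthetic study - patent corpus, disease lexicon,
# CUI/ICD-9/PheCode mapping tables, and disease-by-year measure tables with
# planted burden/resource fold-imbalances - to results/synthetic_study/.
# Every downstream stage reads only these files, mirroring how the analysis
# would run on a real corpus drop.

suppressPackageStartupMessages(library(patentscape))

seed <- 42L
out <- "results/synthetic_study"
cfg <- synth_preset_demo(seed = seed)
sim <- simulate_study(cfg, out)

cat("Synthetic study written to", out, "\n")
cat(sprintf("  %d documents over %d years (%s)\n",
            nrow(sim$corpus), length(cfg$years),
            paste(range(cfg$years), collapse = "-")))
cat(sprintf("  %d diseases, ambiguity fraction %.3f, biomedical fraction %.2f\n",
            cfg$n_diseases, cfg$ambiguity_fraction, cfg$biomedical_fraction))
cat(sprintf("  planted folds: %s\n",
            paste(cfg$measure_spec$folds, collapse = ", ")))
cat("  ground truth:", sim$paths$ground_truth, "\n")
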