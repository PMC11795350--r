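#!/usr/bin/env Rscript
# Stage 1 - simulate the study cohort.
#
# Generates a 39-subject synthetic cohort (ages 20-81, screened MMSE/BDI),
# one 96-trial paradigm sequence per subject, and raw phase-coupled EEG
# epochs per subject and condition (with a small fraction of
# artifact-contaminated epochs), written as EDF files with JSON sidecars.
#   Rscript analysis/01_simulate.R [--seed 1] [--outdir results/study]

suppressMessages(library(bindnet))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args); if (is.na(i)) default else args[i + 1]
}
seed <- as.integer(arg("--seed", "1"))
outdir <- arg("--outdir", "results/study")

cfg <- run_config(seed = seed, outdir = outdir)
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
write_run_config(cfg, file.path(outdir, "config.txt"))

cohort <- stage_simulate(cfg)
cat(sprintf("simulated %d subjects, ages %.1f-%.1f (mean %.1f)\n",
            nrow(cohort), min(cohort$age), max(cohort$age),
            mean(cohort$age)))
cat(sprintf("MMSE %.2f (%.2f), BDI %.2f (%.2f); %d EDF files under %s/edf\n",
            mean(cohort$mmse), sd(cohort$mmse), mean(cohort$bdi),
            sd(cohort$bdi),
            length(list.files(file.path(outdir, "edf"), "\\.edf$")), outdir))
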