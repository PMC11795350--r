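#!/usr/bin/env Rscript
# Stage 5 - age-effect models and the correlation screen.
#
# Fits penalized cubic-spline additive models of age (basis dimension 10
# for behavioural/cognitive outcomes, 12 for graph outcomes) and screens
# age-partialled metric-cognition correlations (BH-FDR within metric
# family, |r| > 0.400), producing the demographic table, the per-outcome
# model table and the correlation report.
#   Rscript analysis/05_stats.R [--outdir results/study]

suppressMessages(library(bindnet))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args); if (is.na(i)) default else args[i + 1]
}
outdir <- arg("--outdir", "results/study")
cfg <- read_run_config(file.path(outdir, "config.txt"))
cfg$outdir <- outdir

res <- stage_stats(cfg)
cat("cohort summary (table1.csv):\n")
print(res$table1, row.names = FALSE)

tab2 <- res$table2
if (nrow(tab2)) {
  sig <- tab2[tab2$p_value < 0.05, c("outcome", "edf", "F_value", "p_value")]
  cat(sprintf("\n%d of %d outcomes show a significant age effect (p < 0.05):\n",
              nrow(sig), nrow(tab2)))
  print(transform(sig, edf = round(edf, 2), F_value = round(F_value, 2),
                  p_value = signif(p_value, 2)), row.names = FALSE)
}
cr <- res$correlations
if (nrow(cr)) {
  rep_ <- cr[cr$reported, ]
  cat(sprintf("\ncorrelation screen: %d candidate pairs, %d reported (|r| > %.3f, q < %.2f)\n",
              nrow(cr), nrow(rep_), cfg$min_abs_r, cfg$q))
  if (nrow(rep_)) {
    print(transform(rep_[, c("metric", "score", "r", "q_bh")],
                    r = round(r, 3), q_bh = signif(q_bh, 2)),
          row.names = FALSE)
  }
}
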