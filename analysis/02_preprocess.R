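#!/usr/bin/env Rscript
# Stage 2 - artifact rejection.
#
# Screens every epoch of every recording against the four amplitude /
# step / gradient / flatline criteria and writes cleaned EDF files plus
# a per-epoch rejection report.
#   Rscript analysis/02_preprocess.R [--outdir results/study]

suppressMessages(library(bindnet))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args); if (is.na(i)) default else args[i + 1]
}
outdir <- arg("--outdir", "results/study")
cfg <- read_run_config(file.path(outdir, "config.txt"))
cfg$outdir <- outdir

report <- stage_preprocess(cfg)
kept <- sum(report$kept)
cat(sprintf("screened %d epochs across %d recordings: kept %d (%.1f%%), rejected %d\n",
            nrow(report), length(unique(paste(report$subject_id,
                                              report$condition))),
            kept, 100 * kept / nrow(report), sum(!report$kept)))
fired <- table(unlist(strsplit(report$violations[report$violations != ""],
                               ";")))
if (length(fired)) {
  cat("criteria fired (channel:criterion):\n")
  print(utils::head(sort(fired, decreasing = TRUE), 10))
}
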