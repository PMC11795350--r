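#!/usr/bin/env Rscript
# Convenience driver: runs the whole study pipeline (scripts 01-05) in order.
#   Rscript analysis/00_run_all.R [--seed 1] [--outdir results/study]
for (f in sprintf("analysis/%02d_%s.R", 1:5,
                  c("simulate", "preprocess", "connectivity", "graph",
                    "stats"))) {
  cat("\n==>", f, "\n")
  source(f)
}
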