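#!/usr/bin/env Rscript
# Step 1: generate one full experimental session (8 blocks: low/high load
# x oddball/equiprobable tones, each presented once per session half),
# validate every ordering constraint, and export the sequences as TSV.

suppressPackageStartupMessages(library(mmnload))

seed <- 20240101L
out_dir <- "results/sequences"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

session <- compose_session(seed)
violations <- validate_session(session)
stopifnot(nrow(violations) == 0)

for (i in seq_along(session)) {
  b <- session[[i]]
  path <- file.path(out_dir, sprintf("block_%02d_%s_%s.tsv", i,
                                     b$design$load, b$design$tone_condition))
  write_sequence_tsv(b$tones, b$visual, path)
}

cat(sprintf("session seed %d: %d blocks, 0 constraint violations\n",
            seed, length(session)))
for (b in session) {
  main <- b$tones$events[!b$tones$events$is_warmup, ]
  cat(sprintf("  %-4s %-8s %d tones (%d deviant/critical), %d targets\n",
              b$design$load, b$design$tone_condition, nrow(main),
              sum(main$frequency == 500),
              sum(b$visual$events$is_target)))
}
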