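#!/usr/bin/env Rscript
# FC -> SNpc somatic taxonomy on the QC-passed pairs: classify every
# differential variant into de novo / loss / positive shift / negative
# shift, compare per-class rates between cases and controls, and check the
# classification against the generator's truth table.

suppressMessages(library(mthet))
suppressMessages(library(readr))

res <- readRDS("scratch/pipeline.rds")
truth <- read_tsv("results/sim/truth.tsv", show_col_types = FALSE)

write_tsv(res$somatic$events, "results/somatic_events.tsv")
write_tsv(res$somatic$summary$totals, "results/somatic_totals.tsv")
write_tsv(res$somatic$tests$class_tests, "results/somatic_class_tests.tsv")
if (!is.null(res$somatic$tests$locus_tests)) {
  write_tsv(res$somatic$tests$locus_tests, "results/somatic_locus_tests.tsv")
}

tot <- res$somatic$summary$totals
cat("Differential variants:", sum(tot$n), "(",
    paste(tot$class, tot$n, collapse = ", "), ")\n")
ct <- res$somatic$tests$class_tests
for (i in seq_len(nrow(ct))) {
  cat(sprintf("  %-14s %-16s p = %.3g\n", ct$class[i], ct$direction[i], ct$p_value[i]))
}

# agreement with generator truth (retained individuals only)
truth_d <- truth[truth$class != "unchanged" &
                   truth$individual %in% res$qc$retained$individual, ]
ev <- res$somatic$events[res$somatic$events$class != "unchanged", ]
agree <- length(intersect(paste(truth_d$individual, truth_d$position, truth_d$alt, truth_d$class),
                          paste(ev$individual, ev$position, ev$alt, ev$class)))
cat(sprintf("Truth-label agreement: %d/%d (%.1f%%) at error rate %s\n",
            agree, nrow(truth_d), 100 * agree / nrow(truth_d), "1e-3"))
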