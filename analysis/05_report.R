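#!/usr/bin/env Rscript
# Stage 5 — collate the run into a single report.
#
# Reads only the stage outputs under results/ (no recomputation) and
# prints the headline numbers: lesion counts by category, the MAR, its
# recurrence frequency, and the qPCR validation summary.

suppressPackageStartupMessages(library(marscan))

lesions <- read_lesion_file("results/lesions.tsv")
rejected <- read_lesion_file("results/lesions_rejected.tsv")
mar <- read.delim("results/mar.tsv")
conc <- jsonlite::read_json("results/concordance.json")

report <- list(
  n_lesions_kept = nrow(lesions),
  n_lesions_rejected = nrow(rejected),
  categories = as.list(table(lesions$category)),
  mar = as.list(mar),
  taqman_concordance_pct = 100 * conc$fraction)
jsonlite::write_json(report, "results/report.json", auto_unbox = TRUE,
                     digits = NA)

cat("== cohort summary ==\n")
cat(sprintf("lesions kept: %d (rejected by filters: %d)\n",
            report$n_lesions_kept, report$n_lesions_rejected))
for (cat_name in names(report$categories)) {
  cat(sprintf("  %-11s %d\n", cat_name, report$categories[[cat_name]]))
}
cat(sprintf("MAR: %s:%d-%d (%d bp), %d/%d samples (%.0f%%), mean CN %.1f\n",
            mar$chrom, mar$start, mar$end, mar$length, mar$n_affected,
            mar$cohort_size, 100 * mar$frequency, mar$mean_cn))
cat(sprintf("qPCR concordance: %.0f%%\n", report$taqman_concordance_pct))
cat("report written to results/report.json\n")
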