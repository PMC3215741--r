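#!/usr/bin/env Rscript
# Stage 4 — calibrator-free qPCR validation of the MAR copy number.
#
# Simulates a duplex TaqMan plate (4 replicates, per-channel Ct sd 0.05)
# for the 20 tumors and their matched normals, anchors the ΔCt scale at
# the QC-passing median (assumed diploid), and reports concordance
# between the array amplification status at the MAR and the qPCR integer
# copy number.

suppressPackageStartupMessages(library(marscan))

cfg <- read_pipeline_config("results/config.yaml")
lesions <- read_lesion_file("results/lesions.tsv")
truth <- read_truth_file("results/cohort/truth.tsv")
mar <- read.delim("results/mar.tsv")

ids <- sprintf("S%02d", seq_len(cfg$cohort$n_samples))
shared <- cfg$cohort$shared_lesion
carriers <- unique(truth$sample_id[truth$chrom == shared$chrom &
                                     truth$start == shared$start])
tumor_cn <- setNames(ifelse(ids %in% carriers, shared$cn, 2), ids)
plate_cn <- c(tumor_cn, setNames(rep(2, length(ids)),
                                 paste0(ids, "_N")))

set.seed(cfg$seed + 10000)
wells <- simulate_taqman_plate(plate_cn, cfg$taqman$n_replicates,
                               cfg$taqman$ct_sd)
write_wells_csv(wells, "results/wells.csv")
calls <- copy_number_no_calibrator(aggregate_wells(wells,
                                                   cfg$taqman$qc_sd))
write_calls_csv(calls, "results/cn_calls.csv")
cat(sprintf("anchor ΔCt = %.3f; %d/%d samples pass QC (σΔCt < %.2f)\n",
            attr(calls, "anchor_dct"), sum(calls$qc_pass), nrow(calls),
            cfg$taqman$qc_sd))

amp <- vapply(ids, function(sid) {
  any(lesions$sample_id == sid & lesions$chrom == mar$chrom &
        lesions$start < mar$end & lesions$end > mar$start &
        lesions$cn_state == "gain")
}, logical(1))
conc <- concordance(amp, calls[calls$sample_id %in% ids, ],
                    cfg$taqman$amplified_threshold)
jsonlite::write_json(conc[c("fraction", "fraction_qc", "n", "n_qc")],
                     "results/concordance.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("array/qPCR concordance at the MAR: %.0f%% (%d samples)\n",
            100 * conc$fraction, conc$n))
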