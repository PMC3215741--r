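#!/usr/bin/env Rscript
# Stage 2 — segment every tumor against its matched normal and classify
# lesions.
#
# Paired LRR ratio series -> low-density masking -> recursive t-test
# segmentation (10-marker minimum, p <= 0.001) -> five-state
# classification with BAF-based LOH calls and the mirrored-BAF aUPD
# route -> study filters (autosomes only, CNV >= 1 kb, aUPD >= 1 Mb,
# cytoband blacklist). Writes lesions.tsv, the rejection log and a BED9
# track under results/.

suppressPackageStartupMessages(library(marscan))

cfg <- read_pipeline_config("results/config.yaml")
sizes <- read_chrom_sizes("results/cohort/chrom.sizes")
cytobands <- synthetic_cytobands(sizes)
sp <- do.call(seg_params, cfg$segmentation[c("min_markers", "split_alpha",
                                             "merge_alpha")])
lp <- do.call(loh_params, cfg$calling$loh)

ids <- sprintf("S%02d", seq_len(cfg$cohort$n_samples))
lesions <- do.call(rbind, lapply(ids, function(sid) {
  tumor <- read_probe_file(file.path("results/cohort",
                                     paste0(sid, ".tumor.tsv")))
  normal <- read_probe_file(file.path("results/cohort",
                                      paste0(sid, ".normal.tsv")))
  res <- call_sample_lesions(tumor, normal, mode = "paired",
                             sample_id = sid, params = sp,
                             max_gap = cfg$segmentation$max_gap,
                             gain_threshold = cfg$calling$gain_threshold,
                             loss_threshold = cfg$calling$loss_threshold,
                             loh = lp)
  cat(sprintf("%s: %d segments, %d lesions\n", sid, nrow(res$segments),
              nrow(res$lesions)))
  res$lesions
}))

policy <- filter_policy(cfg$filters$excluded_chroms,
                        cfg$filters$min_cnv_length,
                        cfg$filters$min_aupd_length,
                        cfg$filters$blacklist_cytobands)
filt <- apply_filters(lesions, policy, cytobands)
write_lesion_file(filt$kept, "results/lesions.tsv")
write_lesion_file(filt$rejected, "results/lesions_rejected.tsv")
convert_lesions_to_bed(filt$kept, "results/lesions.bed")

cat(sprintf("%d lesions called, %d kept after filters (%d rejected)\n",
            nrow(lesions), nrow(filt$kept), nrow(filt$rejected)))
print(table(filt$kept$category))
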