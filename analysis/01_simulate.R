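#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# 20 tumor/matched-normal pairs on a 4 x 10 Mb genome at 1 kb marker
# spacing: a shared 50 kb CN = 4 amplification implanted in 11/20
# samples (the recurrent-amplification scenario the downstream stages
# must rediscover) plus 5 private lesions per sample. Writes one probe
# TSV per sample, the truth table, chrom.sizes and the configuration
# under results/.

suppressPackageStartupMessages(library(marscan))

cfg <- default_config()
dir.create("results", showWarnings = FALSE)
yaml::write_yaml(cfg, "results/config.yaml")

map <- build_probe_map(unlist(cfg$genome$chromosomes),
                       spacing = cfg$genome$spacing,
                       snp_fraction = cfg$genome$snp_fraction,
                       jitter = cfg$genome$jitter, seed = cfg$seed)
shared <- as.data.frame(cfg$cohort$shared_lesion)
cohort <- simulate_cohort(map, cfg$cohort$n_samples, shared,
                          cfg$cohort$carrier_fraction,
                          cfg$cohort$private_lesion_rate,
                          noise = do.call(noise_model, cfg$noise),
                          seed = cfg$seed)
write_cohort(cohort, "results/cohort")

cat(sprintf("simulated %d samples, %d probes each\n",
            cfg$cohort$n_samples, nrow(map$probes)))
cat(sprintf("shared %s:%d-%d CN=%d implanted in %d carriers: %s\n",
            shared$chrom, shared$start, shared$end, shared$cn,
            length(cohort$carriers),
            paste(cohort$carriers, collapse = " ")))
cat(sprintf("%d truth lesions written to results/cohort/truth.tsv\n",
            nrow(cohort$truth)))
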