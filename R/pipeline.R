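# Configuration and end-to-end pipeline driver:
# simulate -> segment -> call -> filter -> cohort recurrence -> MAR ->
# qPCR validation -> manifest.

CONFIG_BLOCKS <- c("seed", "outdir", "genome", "cohort", "noise", "purity",
                   "segmentation", "calling", "filters", "mar", "taqman")

check_keys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

#' Default pipeline configuration
#'
#' A desk-scale genome of 4 chromosomes x 10 Mb at 1 kb probe spacing
#' (~40k probes/sample), 20 samples, a shared 50 kb CN = 4 amplification
#' carried by 55% of the cohort, 5 private lesions per sample, and the
#' study's segmentation, calling and filtering parameters.
#'
#' @return nested configuration list (the YAML schema).
#' @export
default_config <- function() {
  list(
    seed = 1,
    genome = list(
      chromosomes = list(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7, chr4 = 1e7),
      spacing = 1000, snp_fraction = 0.5, jitter = 200),
    cohort = list(
      n_samples = 20, carrier_fraction = 0.55, private_lesion_rate = 5,
      shared_lesion = list(chrom = "chr1", start = 1550001, end = 1600001,
                           cn = 4, loh = FALSE)),
    noise = list(lrr_sd = 0.2, baf_sd = 0.03, het_fraction = 0.3),
    purity = 1,
    segmentation = list(min_markers = 10, split_alpha = 0.001,
                        merge_alpha = 0.001, max_gap = 1e5),
    calling = list(gain_threshold = 0.15, loss_threshold = -0.2,
                   loh = list(min_informative = 10, min_hom_fraction = 0.9,
                              hom_band = 0.1)),
    filters = list(excluded_chroms = c("X", "Y", "MT"),
                   min_cnv_length = 1000, min_aupd_length = 1e6,
                   blacklist_cytobands = c("7p34", "7p14.1", "14q11.2")),
    mar = list(min_fraction = 0.5, bridge_gap = NULL),
    taqman = list(n_replicates = 4, ct_sd = 0.05, qc_sd = 0.15,
                  amplified_threshold = 3))
}

#' Read and validate a pipeline YAML configuration
#'
#' Unknown keys are rejected; missing blocks fall back to
#' [default_config()] values. Parameter values are checked against their
#' owning constructors' invariants when the pipeline builds its parameter
#' objects.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, CONFIG_BLOCKS, "top level")
  check_keys(cfg$genome, c("chromosomes", "spacing", "snp_fraction",
                           "jitter"), "genome")
  check_keys(cfg$cohort, c("n_samples", "carrier_fraction",
                           "private_lesion_rate", "shared_lesion"),
             "cohort")
  check_keys(cfg$cohort$shared_lesion,
             c("chrom", "start", "end", "cn", "loh"),
             "cohort$shared_lesion")
  check_keys(cfg$noise, c("lrr_sd", "baf_sd", "het_fraction"), "noise")
  check_keys(cfg$segmentation, c("min_markers", "split_alpha",
                                 "merge_alpha", "max_gap"), "segmentation")
  check_keys(cfg$calling, c("gain_threshold", "loss_threshold", "loh"),
             "calling")
  check_keys(cfg$calling$loh, c("min_informative", "min_hom_fraction",
                                "hom_band"), "calling$loh")
  check_keys(cfg$filters, c("excluded_chroms", "min_cnv_length",
                            "min_aupd_length", "blacklist_cytobands"),
             "filters")
  check_keys(cfg$mar, c("min_fraction", "bridge_gap"), "mar")
  check_keys(cfg$taqman, c("n_replicates", "ct_sd", "qc_sd",
                           "amplified_threshold"), "taqman")
  utils::modifyList(default_config(), cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulates the cohort described by `config`, segments every tumor
#' against its matched normal (paired mode), classifies and filters
#' lesions, profiles recurrence, defines the MAR, and validates the MAR
#' copy number with a simulated calibrator-free qPCR plate. Stage outputs
#' are written under `outdir` when given, and a run manifest records
#' every count the reports cite.
#'
#' @param config configuration list (see [default_config()] /
#'   [read_pipeline_config()]).
#' @param outdir optional output directory for stage files.
#' @param seed overrides `config$seed`.
#' @return list with `manifest`, `cohort`, `segments`, `lesions`
#'   (kept), `rejected`, `density`, `recurrence`, `mar`, `taqman`,
#'   `cytobands`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         seed = NULL) {
  t0 <- Sys.time()
  if (!is.null(seed)) config$seed <- seed
  sd0 <- config$seed

  cohort <- stage("simulate", {
    map <- build_probe_map(unlist(config$genome$chromosomes),
                           spacing = config$genome$spacing,
                           snp_fraction = config$genome$snp_fraction,
                           jitter = config$genome$jitter, seed = sd0)
    shared <- config$cohort$shared_lesion
    shared_df <- if (is.null(shared)) NULL else
      data.frame(chrom = shared$chrom, start = shared$start,
                 end = shared$end, cn = shared$cn, loh = shared$loh,
                 stringsAsFactors = FALSE)
    simulate_cohort(map, config$cohort$n_samples, shared_df,
                    config$cohort$carrier_fraction,
                    config$cohort$private_lesion_rate,
                    noise = do.call(noise_model, config$noise),
                    seed = sd0, purity = config$purity)
  })

  sp <- do.call(seg_params, config$segmentation[c("min_markers",
                                                  "split_alpha",
                                                  "merge_alpha")])
  lp <- do.call(loh_params, config$calling$loh)
  segcall <- stage("segment_call", {
    lapply(names(cohort$samples), function(sid) {
      s <- cohort$samples[[sid]]
      call_sample_lesions(s$tumor, s$normal, mode = "paired",
                          sample_id = sid, params = sp,
                          max_gap = config$segmentation$max_gap,
                          gain_threshold = config$calling$gain_threshold,
                          loss_threshold = config$calling$loss_threshold,
                          loh = lp)
    })
  })
  names(segcall) <- names(cohort$samples)
  lesions_raw <- do.call(rbind, lapply(segcall, `[[`, "lesions"))
  rownames(lesions_raw) <- NULL

  cytobands <- synthetic_cytobands(cohort$map$chrom_sizes)
  filt <- stage("filter", {
    policy <- filter_policy(config$filters$excluded_chroms,
                            config$filters$min_cnv_length,
                            config$filters$min_aupd_length,
                            config$filters$blacklist_cytobands)
    apply_filters(lesions_raw, policy, cytobands)
  })

  n <- config$cohort$n_samples
  density <- stage("density",
                   chromosome_density(filt$kept, cohort$map$chrom_sizes))
  recurrence <- stage("recurrence",
                      recurrence_profile(filt$kept, n, "cytoband",
                                         cytobands))
  # bridge marker-free holes between probe-snapped segment bounds
  bridge <- config$mar$bridge_gap
  if (is.null(bridge)) bridge <- 2 * config$genome$spacing
  mar <- stage("mar", define_mar(filt$kept, n, config$mar$min_fraction,
                                 bridge_gap = bridge))

  taqman <- stage("taqman", {
    if (is.null(mar$mar)) {
      NULL
    } else {
      shared <- config$cohort$shared_lesion
      shared_cn <- if (is.null(shared)) 2 else shared$cn
      tumor_cn <- stats::setNames(
        ifelse(names(cohort$samples) %in% cohort$carriers, shared_cn, 2),
        names(cohort$samples))
      # plate mirrors the validation design: tumors plus their matched
      # normals (diploid at the target), so that more than half the plate
      # is copy-neutral and the calibrator-free median anchor is valid
      normal_cn <- stats::setNames(
        rep(2, length(tumor_cn)), paste0(names(tumor_cn), "_N"))
      truth_cn <- c(tumor_cn, normal_cn)
      wells <- simulate_taqman_plate(truth_cn,
                                     config$taqman$n_replicates,
                                     config$taqman$ct_sd,
                                     seed = sd0 + 10000)
      calls <- copy_number_no_calibrator(
        aggregate_wells(wells, config$taqman$qc_sd))
      amp <- vapply(names(cohort$samples), function(sid) {
        k <- filt$kept
        any(k$sample_id == sid & k$chrom == mar$mar$chrom &
              k$start < mar$mar$end & k$end > mar$mar$start &
              k$cn_state == "gain")
      }, logical(1))
      tumor_calls <- calls[calls$sample_id %in% names(cohort$samples), ,
                           drop = FALSE]
      conc <- concordance(amp, tumor_calls,
                          config$taqman$amplified_threshold)
      list(wells = wells, calls = calls, concordance = conc)
    }
  })

  manifest <- list(
    tool = "marscan",
    version = as.character(utils::packageVersion("marscan")),
    seed = sd0,
    config_hash = config_hash(config),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    counts = list(
      n_samples = n,
      n_probes_per_sample = nrow(cohort$map$probes),
      n_truth_lesions = nrow(cohort$truth),
      n_segments = sum(vapply(segcall,
                              function(s) nrow(s$segments), integer(1))),
      n_lesions_raw = nrow(lesions_raw),
      n_lesions_kept = nrow(filt$kept),
      n_lesions_rejected = nrow(filt$rejected)),
    density_p = density$p_value,
    mar = if (is.null(mar$mar)) NULL else as.list(mar$mar),
    taqman_concordance = if (is.null(taqman)) NULL else
      taqman$concordance$fraction)

  if (!is.null(outdir)) {
    stage("write", {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_cohort(cohort, file.path(outdir, "cohort"))
      write_lesion_file(filt$kept, file.path(outdir, "lesions.tsv"))
      write_lesion_file(filt$rejected,
                        file.path(outdir, "lesions_rejected.tsv"))
      convert_lesions_to_bed(filt$kept, file.path(outdir, "lesions.bed"))
      write_tsv(recurrence$profile, file.path(outdir, "recurrence.tsv"))
      write_tsv(density$table, file.path(outdir, "density.tsv"))
      if (!is.null(mar$mar)) {
        write_tsv(mar$mar, file.path(outdir, "mar.tsv"))
        jsonlite::write_json(as.list(mar$mar),
                             file.path(outdir, "mar.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      if (!is.null(taqman)) {
        write_wells_csv(taqman$wells, file.path(outdir, "wells.csv"))
        write_calls_csv(taqman$calls, file.path(outdir, "cn_calls.csv"))
      }
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    })
  }

  list(manifest = manifest, cohort = cohort,
       segments = lapply(segcall, `[[`, "segments"),
       lesions = filt$kept, rejected = filt$rejected,
       density = density, recurrence = recurrence, mar = mar,
       taqman = taqman, cytobands = cytobands)
}

# md5 of the canonical YAML serialization of the config
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}
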