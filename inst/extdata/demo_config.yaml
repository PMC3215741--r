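# Desk-scale demo: 6 samples on a 2 x 5 Mb genome, one shared 50 kb
# CN = 4 amplification carried by ~2/3 of the cohort, 2 private lesions
# per sample. Runs end-to-end in seconds.
seed: 7
genome:
  chromosomes:
    chr1: 5000000
    chr2: 5000000
  spacing: 1000
  snp_fraction: 0.5
  jitter: 200
cohort:
  n_samples: 6
  carrier_fraction: 0.67
  private_lesion_rate: 2
  shared_lesion:
    chrom: chr1
    start: 1550001
    end: 1600001
    cn: 4
    loh: no
noise:
  lrr_sd: 0.2
  baf_sd: 0.03
  het_fraction: 0.3
segmentation:
  min_markers: 10
  split_alpha: 0.001
  merge_alpha: 0.001
  max_gap: 100000
calling:
  gain_threshold: 0.15
  loss_threshold: -0.2
  loh:
    min_informative: 10
    min_hom_fraction: 0.9
    hom_band: 0.1
filters:
  excluded_chroms: [X, Y, MT]
  min_cnv_length: 1000
  min_aupd_length: 1000000
  blacklist_cytobands: ["7p34", "7p14.1", "14q11.2"]
mar:
  min_fraction: 0.5
taqman:
  n_replicates: 4
  ct_sd: 0.05
  qc_sd: 0.15
  amplified_threshold: 3
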