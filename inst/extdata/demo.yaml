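# Demonstration configuration for edsp_pipeline(): a desk-scale cohort with
# a strong additive QTL (half the SBP variance), one fully linked and one
# unlinked 8-allele microsatellite, threshold/difference-rule EDSP selection
# and the default linkage scan. All seeds are explicit; re-running the
# pipeline reproduces the outputs byte for byte.
simulate:
  n_families: 400
  seed: 20230925
  mask_parents: true
  model:
    qtl_allele_freq: 0.5
    additive_effect_sbp: 18
    polygenic_sd_sbp: 9
    env_sd_sbp: 9
    additive_effect_dbp: 9
    polygenic_sd_dbp: 7
    env_sd_dbp: 7.5
  markers:
    - name: D17S799
      n_alleles: 8
      theta: 0.0
      chromosome: 17
    - name: D11S925
      n_alleles: 8
      theta: 0.5
      chromosome: 11
select:
  method: threshold
linkage:
  phenotypes: [sbp, dbp, pp]
  adjust: true
  lrt:
    direction: deficit
    n_perm: 1000
    seed: 7
power:
  run: false
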