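# Synthetic end-to-end demo: small problem sizes chosen so the full
# pipeline (inference + null models + rarefaction) runs in about a minute.
seed: 42
outdir: sagnet_demo_out
simulation:
  n_per_group: 20
  n_taxa: 28
  n_samples: 30
  depth: 20000
  n_families: 40
  block_spec:
    # two correlated blocks inside each group's taxon range (taxa 1-14 are
    # C-depleted, 15-28 C-enriched), so both per-group networks carry
    # recoverable modular structure
    - members: [1, 2, 3, 4, 5, 6]
      rho: 0.8
    - members: [8, 9, 10, 11, 12, 13]
      rho: 0.8
    - members: [15, 16, 17, 18, 19, 20]
      rho: 0.8
    - members: [22, 23, 24, 25, 26, 27]
      rho: 0.8
qc:
  min_completeness: 50
  max_contamination: 10
network:
  r_min: 0.6
  p_max: 0.05
  n_resamples: 10
  n_permutations: 199
  n_null: 200
  rarefaction_k: 8
  rarefaction_iter: 50
  rarefaction_permutations: 39
  rarefaction_resamples: 5
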