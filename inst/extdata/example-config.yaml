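# Example pipeline configuration: simulate a small cohort, segment and
# colocalize every stack, fit the group model, and analyse a matching
# phagocytosis assay. All randomness derives from `seed`.
seed: 1
cohort:
  preset: smoke            # see ?cohort_preset for the full-scale presets
coloc:
  min_overlap_fraction: 0.25
  denominator_rule: min_object
  plaque_distance_um: 10
stats:
  outcome: coloc_volume_um3
  fixed_terms: [group]
  random_group: case_id
kinetics:
  preset: astro-ad-vs-control
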