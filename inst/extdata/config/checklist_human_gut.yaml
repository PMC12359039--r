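# Tiered metadata checklist (human gut flavour), MIxS v6.0 short term names.
# Tiers are cumulative: silver requires all bronze fields, gold all silver fields.
name: human-gut
tiers:
  bronze:
    - sample_name
    - project_name
    - taxonomy_id
    - collection_date
    - lat_lon
    - geo_loc_name
    - env_broad_scale
    - env_local_scale
    - env_medium
  silver:
    - seq_meth
    - neg_cont_type
    - target_gene
    - pcr_primers
    - host_subject_id
    - host_disease_stat
    - host_tot_mass
    - host_sex
  gold:
    - samp_mat_process
    - nucl_acid_ext
    - host_height
    - host_diet
    - host_occupation
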