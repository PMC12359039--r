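# Attribute-name synonym map: canonical MIxS-style term -> raw variants seen in
# INSDC submissions. Matching is case- and separator-insensitive. Only the
# "Sample Name" / "User_sample_ID" pair is documented in the survey literature;
# all other variants are implementation-supplied defaults and non-normative.
sample_name:
  - Sample Name
  - sample_name
  - User_sample_ID
  - sample title
  - sample-id
  - sample id
  - sample_alias
  - isolate
  - specimen name
project_name:
  - project name
  - project
  - study name
  - bioproject title
taxonomy_id:
  - taxonomy id
  - taxid
  - tax_id
  - taxonomy id of dna sample
  - ncbi taxonomy id
collection_date:
  - collection date
  - collection-date
  - date of collection
  - sampling date
  - collection_timestamp
lat_lon:
  - lat lon
  - latitude longitude
  - latitude and longitude
  - geographic location (latitude and longitude)
  - geographic location (latitude/longitude)
geo_loc_name:
  - geo loc name
  - geographic location
  - geographic location (country and/or sea)
  - geographic location (country/region)
  - country
env_broad_scale:
  - broad-scale environmental context
  - env_biome
  - environment (biome)
env_local_scale:
  - local-scale environmental context
  - env_feature
  - environment (feature)
env_medium:
  - environmental medium
  - env_material
  - environment (material)
seq_meth:
  - sequencing method
  - sequencing_method
  - seq technology
neg_cont_type:
  - negative control type
target_gene:
  - target gene
  - gene target
pcr_primers:
  - pcr primers
  - primers
  - primer sequences
host_subject_id:
  - host subject id
  - subject id
  - subject_id
  - patient id
  - participant id
host_disease_stat:
  - host disease status
  - host_disease
  - disease
  - disease state
  - health state
host_tot_mass:
  - host total mass
  - host weight
  - body mass
host_sex:
  - host sex
  - sex
  - gender
samp_mat_process:
  - sample material processing
nucl_acid_ext:
  - nucleic acid extraction
  - dna extraction method
host_height:
  - host height
  - height
host_diet:
  - host diet
  - diet
host_occupation:
  - host occupation
  - occupation
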