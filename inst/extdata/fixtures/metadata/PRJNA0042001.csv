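"sample_id","attribute","value"
"STUDY001_S01","sample_name","S6341"
"STUDY001_S02","sample_name","S9732"
"STUDY001_S03","sample_name","S2274"
"STUDY001_S04","sample_name","S2552"
"STUDY001_S01","project name","gut survey 26"
"STUDY001_S02","project name","gut survey 6"
"STUDY001_S03","project name","gut survey 6"
"STUDY001_S04","project name","gut survey 2"
"STUDY001_S01","taxid","408170"
"STUDY001_S02","taxid","408170"
"STUDY001_S03","taxid","408170"
"STUDY001_S04","taxid","408170"
"STUDY001_S01","collection_timestamp","2015-01-07"
"STUDY001_S02","collection_timestamp","2018-10-09"
"STUDY001_S03","collection_timestamp","2018-09-11"
"STUDY001_S04","collection_timestamp","2017-05-28"
"STUDY001_S01","lat_lon","44.6385 N 55.7243 E"
"STUDY001_S02","lat_lon","37.5747 N 19.5442 E"
"STUDY001_S03","lat_lon","12.9940 N 35.0051 E"
"STUDY001_S04","lat_lon","56.5473 N 86.6347 E"
"STUDY001_S01","geographic location (country/region)","Switzerland: Zurich"
"STUDY001_S02","geographic location (country/region)","Brazil: Sao Paulo"
"STUDY001_S03","geographic location (country/region)","not collected"
"STUDY001_S04","geographic location (country/region)","USA: California"
"STUDY001_S01","env_broad_scale","human-associated habitat [ENVO:00009003]"
"STUDY001_S02","env_broad_scale","human-associated habitat [ENVO:00009003]"
"STUDY001_S03","env_broad_scale","human-associated habitat [ENVO:00009003]"
"STUDY001_S04","env_broad_scale","human-associated habitat [ENVO:00009003]"
"STUDY001_S01","env_local_scale","digestive tract environment"
"STUDY001_S02","env_local_scale","digestive tract environment"
"STUDY001_S03","env_local_scale","digestive tract environment"
"STUDY001_S04","env_local_scale","digestive tract environment"
"STUDY001_S01","env_medium","feces [UBERON:0001988]"
"STUDY001_S02","env_medium","feces [UBERON:0001988]"
"STUDY001_S03","env_medium","feces [UBERON:0001988]"
"STUDY001_S04","env_medium","feces [UBERON:0001988]"
"STUDY001_S01","seq_meth","Illumina MiSeq"
"STUDY001_S02","seq_meth","Illumina MiSeq"
"STUDY001_S03","seq_meth","Illumina NovaSeq 6000"
"STUDY001_S04","seq_meth","Illumina NovaSeq 6000"
"STUDY001_S01","neg_cont_type","blank extraction"
"STUDY001_S02","neg_cont_type","blank extraction"
"STUDY001_S03","neg_cont_type","not collected"
"STUDY001_S04","neg_cont_type","blank extraction"
"STUDY001_S01","target_gene","16S rRNA"
"STUDY001_S02","target_gene","16S rRNA"
"STUDY001_S03","target_gene","16S rRNA"
"STUDY001_S04","target_gene","16S rRNA"
"STUDY001_S01","primers","FWD:GTGYCAGCMGCCGCGGTAA;REV:GGACTACNVGGGTWTCTAAT"
"STUDY001_S02","primers","FWD:GTGYCAGCMGCCGCGGTAA;REV:GGACTACNVGGGTWTCTAAT"
"STUDY001_S03","primers","FWD:GTGYCAGCMGCCGCGGTAA;REV:GGACTACNVGGGTWTCTAAT"
"STUDY001_S04","primers","FWD:GTGYCAGCMGCCGCGGTAA;REV:GGACTACNVGGGTWTCTAAT"
"STUDY001_S01","host_subject_id","subj441"
"STUDY001_S02","host_subject_id","subj669"
"STUDY001_S03","host_subject_id","subj025"
"STUDY001_S04","host_subject_id","subj883"
"STUDY001_S01","host_disease_stat","IBD"
"STUDY001_S02","host_disease_stat","IBS"
"STUDY001_S03","host_disease_stat","IBD"
"STUDY001_S04","host_disease_stat","IBS"
"STUDY001_S01","host_tot_mass","75 kg"
"STUDY001_S02","host_tot_mass","78 kg"
"STUDY001_S03","host_tot_mass","50 kg"
"STUDY001_S04","host_tot_mass","82 kg"
"STUDY001_S01","host_sex","male"
"STUDY001_S02","host_sex","female"
"STUDY001_S03","host_sex","female"
"STUDY001_S04","host_sex","male"
"STUDY001_S01","sample material processing","homogenized before extraction"
"STUDY001_S02","sample material processing","homogenized before extraction"
"STUDY001_S03","sample material processing","homogenized before extraction"
"STUDY001_S04","sample material processing","homogenized before extraction"
"STUDY001_S01","nucl_acid_ext","bead beating with silica columns"
"STUDY001_S02","nucl_acid_ext","bead beating with silica columns"
"STUDY001_S03","nucl_acid_ext","bead beating with silica columns"
"STUDY001_S04","nucl_acid_ext","bead beating with silica columns"
"STUDY001_S01","host_height","192 cm"
"STUDY001_S02","host_height","163 cm"
"STUDY001_S03","host_height","183 cm"
"STUDY001_S04","host_height","missing"
"STUDY001_S01","host_diet","vegetarian"
"STUDY001_S02","host_diet","omnivore"
"STUDY001_S03","host_diet","vegetarian"
"STUDY001_S04","host_diet","omnivore"
"STUDY001_S01","host_occupation","farmer"
"STUDY001_S02","host_occupation","farmer"
"STUDY001_S03","host_occupation","office worker"
"STUDY001_S04","host_occupation","office worker"
"STUDY001_S01","attr_001","attr_001 value 127"
"STUDY001_S02","attr_001","attr_001 value 799"
"STUDY001_S03","attr_001","attr_001 value 493"
"STUDY001_S04","attr_001","attr_001 value 555"
"STUDY001_S01","attr_002","attr_002 value 337"
"STUDY001_S02","attr_002","attr_002 value 955"
"STUDY001_S03","attr_002","attr_002 value 539"
"STUDY001_S04","attr_002","attr_002 value 542"
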