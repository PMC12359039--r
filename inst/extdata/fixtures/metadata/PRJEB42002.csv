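"sample_id","attribute","value"
"STUDY002_S01","sample_name","S5521"
"STUDY002_S02","sample_name","S1293"
"STUDY002_S03","sample_name","S2015"
"STUDY002_S04","sample_name","S1406"
"STUDY002_S01","project_name","gut survey 1"
"STUDY002_S02","project_name","gut survey 17"
"STUDY002_S03","project_name","gut survey 33"
"STUDY002_S04","project_name","gut survey 28"
"STUDY002_S01","tax_id","408170"
"STUDY002_S02","tax_id","408170"
"STUDY002_S03","tax_id","408170"
"STUDY002_S04","tax_id","408170"
"STUDY002_S01","date of collection","2019-08-06"
"STUDY002_S02","date of collection","2021-10-07"
"STUDY002_S03","date of collection","2023-09-25"
"STUDY002_S04","date of collection","n/a"
"STUDY002_S01","lat_lon","8.7240 N 2.9266 E"
"STUDY002_S02","lat_lon","29.0261 N 40.0113 E"
"STUDY002_S03","lat_lon","3.6231 N 29.4755 E"
"STUDY002_S04","lat_lon","52.7057 N 83.7544 E"
"STUDY002_S01","geo_loc_name","USA: California"
"STUDY002_S02","geo_loc_name","USA: California"
"STUDY002_S03","geo_loc_name","USA: California"
"STUDY002_S04","geo_loc_name","Brazil: Sao Paulo"
"STUDY002_S01","env_broad_scale","human-associated habitat [ENVO:00009003]"
"STUDY002_S02","env_broad_scale","human-associated habitat [ENVO:00009003]"
"STUDY002_S03","env_broad_scale","human-associated habitat [ENVO:00009003]"
"STUDY002_S04","env_broad_scale","human-associated habitat [ENVO:00009003]"
"STUDY002_S01","env_local_scale","digestive tract environment"
"STUDY002_S02","env_local_scale","digestive tract environment"
"STUDY002_S03","env_local_scale","digestive tract environment"
"STUDY002_S04","env_local_scale","digestive tract environment"
"STUDY002_S01","env_medium","feces [UBERON:0001988]"
"STUDY002_S02","env_medium","feces [UBERON:0001988]"
"STUDY002_S03","env_medium","feces [UBERON:0001988]"
"STUDY002_S04","env_medium","feces [UBERON:0001988]"
"STUDY002_S01","seq_meth","Illumina MiSeq"
"STUDY002_S02","seq_meth","Illumina NovaSeq 6000"
"STUDY002_S03","seq_meth","Illumina NovaSeq 6000"
"STUDY002_S04","seq_meth","Illumina MiSeq"
"STUDY002_S01","neg_cont_type","blank extraction"
"STUDY002_S02","neg_cont_type","blank extraction"
"STUDY002_S03","neg_cont_type","blank extraction"
"STUDY002_S04","neg_cont_type","blank extraction"
"STUDY002_S01","target gene","16S rRNA"
"STUDY002_S02","target gene","16S rRNA"
"STUDY002_S03","target gene","missing"
"STUDY002_S04","target gene","not provided"
"STUDY002_S01","pcr_primers","FWD:GTGYCAGCMGCCGCGGTAA;REV:GGACTACNVGGGTWTCTAAT"
"STUDY002_S02","pcr_primers","FWD:GTGYCAGCMGCCGCGGTAA;REV:GGACTACNVGGGTWTCTAAT"
"STUDY002_S03","pcr_primers","FWD:GTGYCAGCMGCCGCGGTAA;REV:GGACTACNVGGGTWTCTAAT"
"STUDY002_S04","pcr_primers","FWD:GTGYCAGCMGCCGCGGTAA;REV:GGACTACNVGGGTWTCTAAT"
"STUDY002_S01","subject id","subj457"
"STUDY002_S02","subject id","subj895"
"STUDY002_S03","subject id","subj919"
"STUDY002_S04","subject id","subj858"
"STUDY002_S01","disease state","healthy"
"STUDY002_S02","disease state","IBD"
"STUDY002_S03","disease state","missing"
"STUDY002_S04","disease state","healthy"
"STUDY002_S01","host total mass","65 kg"
"STUDY002_S02","host total mass","91 kg"
"STUDY002_S03","host total mass","n/a"
"STUDY002_S04","host total mass","51 kg"
"STUDY002_S01","host sex","male"
"STUDY002_S02","host sex","male"
"STUDY002_S03","host sex","female"
"STUDY002_S04","host sex","male"
"STUDY002_S01","samp_mat_process","homogenized before extraction"
"STUDY002_S02","samp_mat_process","not provided"
"STUDY002_S03","samp_mat_process","not collected"
"STUDY002_S04","samp_mat_process","homogenized before extraction"
"STUDY002_S01","nucl_acid_ext","bead beating with silica columns"
"STUDY002_S02","nucl_acid_ext","bead beating with silica columns"
"STUDY002_S03","nucl_acid_ext","bead beating with silica columns"
"STUDY002_S04","nucl_acid_ext","bead beating with silica columns"
"STUDY002_S01","host height","182 cm"
"STUDY002_S02","host height","163 cm"
"STUDY002_S03","host height","177 cm"
"STUDY002_S04","host height","182 cm"
"STUDY002_S01","diet","vegetarian"
"STUDY002_S02","diet","omnivore"
"STUDY002_S03","diet","vegan"
"STUDY002_S04","diet","omnivore"
"STUDY002_S01","host_occupation","office worker"
"STUDY002_S02","host_occupation","farmer"
"STUDY002_S03","host_occupation","farmer"
"STUDY002_S04","host_occupation","not collected"
"STUDY002_S01","attr_001","attr_001 value 623"
"STUDY002_S02","attr_001","attr_001 value 989"
"STUDY002_S03","attr_001","attr_001 value 212"
"STUDY002_S04","attr_001","attr_001 value 747"
"STUDY002_S01","attr_002","attr_002 value 711"
"STUDY002_S02","attr_002","attr_002 value 627"
"STUDY002_S03","attr_002","attr_002 value 988"
"STUDY002_S04","attr_002","attr_002 value 594"
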