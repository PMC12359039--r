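"article_id","true_badge","registry","is_amplicon","n_runs","das_style"
"PMC3000001","none","EGA",FALSE,18,"restricted_with_procedure"
"PMC3000002","gold","SRA",TRUE,14,"public_deposit"
"PMC3000003","cannot_be_determined",NA,TRUE,20,"absent"
"PMC3000004","silver","SRA",TRUE,7,"public_deposit"
"PMC3000005","none","SRA",FALSE,7,"public_deposit"
"PMC3000006","bronze","SRA",TRUE,19,"public_deposit"
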