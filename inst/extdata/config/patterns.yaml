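# Evidence-extraction catalogues. All regexes are perl-compatible and matched
# case-sensitively; prepend (?i) inside a pattern for case-insensitive terms.
# 16S/18S/ITS/WGS stay case-sensitive on purpose ("its" is an English word).

accessions:
  # INSDC umbrella projects
  - {pattern: "PRJNA[0-9]{4,}",       registry: "SRA",       record_type: "bioproject"}
  - {pattern: "PRJEB[0-9]{4,}",       registry: "ENA",       record_type: "bioproject"}
  - {pattern: "PRJDB[0-9]{4,}",       registry: "DDBJ",      record_type: "bioproject"}
  - {pattern: "PRJCA[0-9]{4,}",       registry: "CNCB-NGDC", record_type: "bioproject"}
  # studies
  - {pattern: "SRP[0-9]{4,}",         registry: "SRA",       record_type: "study"}
  - {pattern: "ERP[0-9]{4,}",         registry: "ENA",       record_type: "study"}
  - {pattern: "DRP[0-9]{4,}",         registry: "DDBJ",      record_type: "study"}
  - {pattern: "CRA[0-9]{4,}",         registry: "CNCB-NGDC", record_type: "study"}
  # biosamples
  - {pattern: "SAMN[0-9]{4,}",        registry: "SRA",       record_type: "sample"}
  - {pattern: "SAMEA?[0-9]{4,}",      registry: "ENA",       record_type: "sample"}
  - {pattern: "SAMD[0-9]{4,}",        registry: "DDBJ",      record_type: "sample"}
  - {pattern: "SRS[0-9]{4,}",         registry: "SRA",       record_type: "sample"}
  - {pattern: "ERS[0-9]{4,}",         registry: "ENA",       record_type: "sample"}
  - {pattern: "DRS[0-9]{4,}",         registry: "DDBJ",      record_type: "sample"}
  # experiments
  - {pattern: "SRX[0-9]{4,}",         registry: "SRA",       record_type: "experiment"}
  - {pattern: "ERX[0-9]{4,}",         registry: "ENA",       record_type: "experiment"}
  - {pattern: "DRX[0-9]{4,}",         registry: "DDBJ",      record_type: "experiment"}
  # runs (min 5 digits: guards against gene symbols such as SRR1)
  - {pattern: "SRR[0-9]{5,}",         registry: "SRA",       record_type: "run"}
  - {pattern: "ERR[0-9]{5,}",         registry: "ENA",       record_type: "run"}
  - {pattern: "DRR[0-9]{5,}",         registry: "DDBJ",      record_type: "run"}
  # other catalogued archives
  - {pattern: "mgm[0-9]{4,}\\.[0-9]+", registry: "MG-RAST",  record_type: "analysis"}
  - {pattern: "EGAS[0-9]{11}",        registry: "EGA",       record_type: "study"}
  - {pattern: "EGAD[0-9]{11}",        registry: "EGA",       record_type: "unknown"}
  - {pattern: "CNP[0-9]{4,}",         registry: "CNGB",      record_type: "bioproject"}

primer:
  min_length: 12
  window: 200
  keywords:
    - "(?i)\\bprimers?\\b"
    - "(?i)\\bforward\\b"
    - "(?i)\\breverse\\b"
    - "\\b16S\\b"
    - "\\b18S\\b"
    - "\\bITS[12]?\\b"
    - "(?i)\\bV[1-9]\\b"
    - "\\b[0-9]{1,4}[FRfr]\\b"

method_lexicon:
  marker_gene:
    - "\\b16S\\b"
    - "\\b18S\\b"
    - "\\bITS[12]?\\b"
    - "(?i)rRNA gene"
    - "(?i)\\bamplicons?\\b"
    - "(?i)\\bamplicon-based\\b"
    - "(?i)\\bmetabarcoding\\b"
    - "(?i)\\bmarker[- ]gene\\b"
  metagenome:
    - "(?i)\\bshotgun\\b"
    - "(?i)metagenomic sequencing"
    - "(?i)\\bmetagenomes?\\b"
    - "\\bWGS\\b"

code_hosts:
  - github.com
  - gitlab.com
  - bitbucket.org
  - zenodo.org
  - osf.io
  - codeocean.com
code_keywords:
  - "(?i)\\bcode\\b"
  - "(?i)\\bscripts?\\b"
  - "(?i)\\bsoftware\\b"
  - "(?i)\\bpipeline\\b"
  - "(?i)\\bworkflow\\b"
  - "(?i)\\bnotebooks?\\b"
  - "(?i)\\brepository\\b"
code_window: 200

# Data-availability-statement trigger phrases, scanned in precedence order:
# public_deposit > restricted_with_procedure > upon_request > in_paper_only.
das_phrases:
  public_deposit:
    - "(?i)\\bdeposited\\b"
    - "(?i)\\buploaded to\\b"
    - "(?i)\\bsubmitted to\\b"
    - "(?i)publicly available"
    - "(?i)under (the )?(accession|bioproject)"
    - "(?i)available (in|at|from|through) the [^.]{0,60}(repositor|database|sequence read archive|nucleotide archive)"
  restricted_with_procedure:
    - "(?i)controlled[- ]access"
    - "(?i)data access committee"
    - "(?i)access committee"
    - "(?i)authorized researchers"
    - "(?i)data access agreement"
    - "(?i)upon application"
    - "(?i)managed access"
    - "(?i)after approval by"
  upon_request:
    - "(?i)upon (reasonable )?request"
    - "(?i)on (reasonable )?request"
    - "(?i)available from the corresponding author"
    - "(?i)by contacting the (corresponding )?author"
  in_paper_only:
    - "(?i)within th(e|is) (article|paper|manuscript)"
    - "(?i)included in th(e|is) (published )?(article|manuscript|paper)"
    - "(?i)in the supplementary (material|information|file|data)"
    - "(?i)supporting information file"

database_mentions:
  SRA: "\\bSRA\\b|(?i)sequence read archive"
  ENA: "\\bENA\\b|(?i)european nucleotide archive"
  DDBJ: "\\bDDBJ\\b|(?i)dna data bank of japan"
  CNCB-NGDC: "\\bNGDC\\b|(?i)national genomics data center|(?i)genome sequence archive"
  MG-RAST: "(?i)MG-RAST"
  Figshare: "(?i)figshare"
  Zenodo: "(?i)zenodo"
  EGA: "\\bEGA\\b|(?i)genome-phenome archive"
  CNGB: "\\bCNGB\\b|(?i)national genebank"

# Registries retrievable without login or institutional affiliation.
open_registries:
  - SRA
  - ENA
  - DDBJ
  - CNCB-NGDC
  - MG-RAST
  - Figshare
  - Zenodo
  - CNGB

# INSDC-style missing-value vocabulary (lower-cased, compared after trimming).
missing_tokens:
  - ""
  - "na"
  - "n/a"
  - "nan"
  - "missing"
  - "not applicable"
  - "not collected"
  - "not provided"
  - "unknown"
  - "-"
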