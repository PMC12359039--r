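{
  "articles": {
    "PMC3000001": "articles/PMC3000001.xml",
    "PMC3000002": "articles/PMC3000002.xml",
    "PMC3000004": "articles/PMC3000004.xml",
    "PMC3000005": "articles/PMC3000005.xml",
    "PMC3000006": "articles/PMC3000006.xml"
  },
  "accessions": {
    "EGAS34064513913": {
      "registry": "EGA",
      "public": false,
      "n_runs": 18,
      "file_formats": []
    },
    "PRJNA199293": {
      "registry": "SRA",
      "public": true,
      "n_runs": 14,
      "file_formats": [
        "FASTQ"
      ]
    },
    "SRR4538229": {
      "registry": "SRA",
      "public": true,
      "n_runs": 1,
      "file_formats": [
        "FASTQ"
      ]
    },
    "PRJNA845179": {
      "registry": "SRA",
      "public": true,
      "n_runs": 7,
      "file_formats": [
        "FASTQ"
      ]
    },
    "PRJNA318533": {
      "registry": "SRA",
      "public": true,
      "n_runs": 7,
      "file_formats": [
        "other"
      ]
    },
    "PRJNA536954": {
      "registry": "SRA",
      "public": true,
      "n_runs": 19,
      "file_formats": [
        "FASTQ"
      ]
    }
  },
  "metadata": {
    "PRJNA0042001": {
      "path": "metadata/PRJNA0042001.csv",
      "checklist_name": "MIMS.me.human-gut.6.0"
    },
    "PRJEB42002": {
      "path": "metadata/PRJEB42002.csv",
      "checklist_name": "MIMS.me.human-gut.6.0"
    }
  }
}
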