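test_that("accession detection finds catalogued tokens with registry and type", {
  text <- paste("Raw reads were deposited in the NCBI SRA under BioProject",
                "PRJNA765432 and runs SRR1000001.")
  hits <- detect_accessions(text)
  expect_equal(hits$token, c("PRJNA765432", "SRR1000001"))
  expect_equal(hits$registry, c("SRA", "SRA"))
  expect_equal(hits$record_type, c("bioproject", "run"))
  ## 0-based half-open spans point back at the tokens
  for (i in seq_len(nrow(hits))) {
    expect_identical(substring(text, hits$start[i] + 1, hits$end[i]),
                     hits$token[i])
  }

  cases <- list(
    list(text = "ENA study ERP012345 with samples SAMEA7654321 and ERS123456",
         tokens = c("ERP012345", "SAMEA7654321", "ERS123456"),
         registries = c("ENA", "ENA", "ENA")),
    list(text = "DDBJ run DRR123456 under PRJDB12345",
         tokens = c("DRR123456", "PRJDB12345"),
         registries = c("DDBJ", "DDBJ")),
    list(text = "GSA records PRJCA012345 and CRA004321 at the NGDC",
         tokens = c("PRJCA012345", "CRA004321"),
         registries = c("CNCB-NGDC", "CNCB-NGDC")),
    list(text = "MG-RAST analysis mgm4567890.3 and EGA study EGAS00001234567",
         tokens = c("mgm4567890.3", "EGAS00001234567"),
         registries = c("MG-RAST", "EGA")))
  for (cs in cases) {
    hits <- detect_accessions(cs$text)
    expect_equal(hits$token, cs$tokens)
    expect_equal(hits$registry, cs$registries)
  }
})

test_that("accession guards reject short-digit gene symbols and empty input", {
  expect_equal(nrow(detect_accessions("")), 0L)
  expect_equal(nrow(detect_accessions("the protein SRP54 localizes to membranes")), 0L)
  expect_equal(nrow(detect_accessions("SRR1234 has too few digits for a run")), 0L)
  ## embedded in a longer word: word boundary must block it
  expect_equal(nrow(detect_accessions("geneSRR123456x variant")), 0L)
})

test_that("accession hits are deduplicated and ranges flag endpoints only", {
  hits <- detect_accessions("PRJNA765432 was cited twice: PRJNA765432.")
  expect_equal(nrow(hits), 1L)
  rng <- detect_accessions("runs SRR100001-SRR100009 were produced")
  expect_equal(rng$token, c("SRR100001", "SRR100009"))
  expect_true(all(rng$range))
  solo <- detect_accessions("run SRR100001 and later SRR100009 appeared")
  expect_false(any(solo$range))
})

test_that("primer detection needs IUPAC runs plus a context keyword", {
  hits <- detect_primers(paste("amplified with primers 515F",
                               "(GTGYCAGCMGCCGCGGTAA) and 806R",
                               "(GGACTACNVGGGTWTCTAAT)"))
  expect_equal(hits$sequence, c("GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT"))
  expect_equal(hits$label, c("515F", "806R"))
  expect_equal(nrow(detect_primers("the primer set targeted the V4 region")), 0L)
  expect_equal(nrow(detect_primers(
    "GenBank entry GGGGGGGGGGGGGGG was cited in the genome assembly report")), 0L)
  expect_equal(nrow(detect_primers("")), 0L)
})

test_that("primer detection is invariant to sequence case", {
  set.seed(42)
  iupac <- strsplit("ACGTRYSWKMN", "")[[1]]
  for (i in 1:25) {
    seq <- paste(sample(iupac, sample(12:25, 1), replace = TRUE),
                 collapse = "")
    flip <- runif(nchar(seq)) < 0.5
    chars <- strsplit(seq, "")[[1]]
    chars[flip] <- tolower(chars[flip])
    jittered <- paste(chars, collapse = "")
    up <- detect_primers(sprintf("the forward primer (%s) was used", seq))
    lo <- detect_primers(sprintf("the forward primer (%s) was used", jittered))
    expect_equal(lo$sequence, up$sequence)
    expect_equal(up$sequence, seq)
  }
})

test_that("sequencing method classification follows the two lexicons", {
  cases <- list(
    c("16S rRNA gene amplicon sequencing of the V4 region", "marker_gene"),
    c("ITS metabarcoding of fungal communities", "marker_gene"),
    c("shotgun metagenomic sequencing libraries", "metagenome"),
    c("whole-genome WGS libraries were generated", "metagenome"),
    c("we combined 16S amplicon and shotgun metagenome data", "both"),
    c("", "unknown"),
    c("and its derivatives were analysed", "unknown"),  # lower-case "its" != ITS
    c("libraries were run on a NovaSeq instrument", "unknown"))
  for (cs in cases) {
    expect_identical(classify_sequencing_method(cs[1]), cs[2])
  }
})

test_that("code-link detection uses the host catalogue or a keyword window", {
  expect_equal(
    detect_code_links(paste("Code used for analysis and figure generation can",
                            "be found at https://zenodo.org/records/16039307")),
    "https://zenodo.org/records/16039307")
  expect_equal(detect_code_links("Scripts are available at https://github.com/lab/analysis"),
               "https://github.com/lab/analysis")
  expect_equal(detect_code_links("see our institutional website"), character(0))
  ## non-catalogue host with no code keyword nearby is dropped
  expect_equal(detect_code_links("photographs at https://example.org/gallery were taken"),
               character(0))
  ## ... but kept when a keyword co-occurs
  expect_equal(detect_code_links("the pipeline is hosted at https://example.org/tool"),
               "https://example.org/tool")
  ## trailing punctuation stripped, duplicates removed
  expect_equal(detect_code_links(paste("Code at https://github.com/a/b.",
                                       "Again: https://github.com/a/b")),
               "https://github.com/a/b")
})

test_that("DAS classification follows the precedence order", {
  expect_identical(
    classify_das("Data are available upon reasonable request from the corresponding author."),
    "upon_request")
  expect_identical(
    classify_das("Sequences were deposited in the ENA under PRJEB11111."),
    "public_deposit")
  expect_identical(
    classify_das(paste("Qualified researchers may apply to the data access",
                       "committee for controlled access.")),
    "restricted_with_procedure")
  expect_identical(
    classify_das("All data are included in this published article."),
    "in_paper_only")
  expect_identical(classify_das(NULL, "no trigger phrases at all"), "absent")
  expect_identical(classify_das(NULL, ""), "absent")
  ## deposit phrase outranks a request phrase in the same statement
  expect_identical(
    classify_das(paste("Reads were deposited in the SRA; other materials are",
                       "available upon request.")),
    "public_deposit")
  ## fallback text is scanned when no dedicated DAS exists
  expect_identical(
    classify_das(NULL, "Raw reads were uploaded to the SRA under PRJNA123456."),
    "public_deposit")
})

test_that("extract_all composes detectors and keeps the registry superset invariant", {
  doc <- article_document(
    "PMCTEST1",
    sections = list(
      list(label = "Methods",
           body = paste("We performed 16S rRNA gene amplicon sequencing using",
                        "primers 515F (GTGYCAGCMGCCGCGGTAA) and 806R",
                        "(GGACTACNVGGGTWTCTAAT).")),
      list(label = "Code availability",
           body = "Scripts are archived at https://github.com/lab/repo.")),
    das_text = "Reads were deposited in the SRA under BioProject PRJNA765432.")
  ex <- extract_all(doc)
  expect_equal(ex$accessions$token, "PRJNA765432")
  expect_equal(nrow(ex$primers), 2L)
  expect_identical(ex$sequencing_method, "marker_gene")
  expect_identical(ex$das_class, "public_deposit")
  expect_equal(ex$code_links, "https://github.com/lab/repo")
  expect_true(all(ex$accessions$registry %in% ex$databases_mentioned))

  ## identical text yields identical results (determinism)
  expect_identical(ex, extract_all(doc))

  ## an article with only an upon-request DAS
  doc2 <- article_document(
    "PMCTEST2",
    sections = list(list(label = "Results", body = "Communities differed.")),
    das_text = "Data are available upon reasonable request.")
  ex2 <- extract_all(doc2)
  expect_equal(nrow(ex2$accessions), 0L)
  expect_identical(ex2$das_class, "upon_request")
})

test_that("extract_all signals not-determinable for non-ok documents", {
  doc <- article_document("PMCGONE", sections = list(),
                          retrieval_status = "no_fulltext")
  expect_error(extract_all(doc), class = "seqbadge_not_determinable")
})
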