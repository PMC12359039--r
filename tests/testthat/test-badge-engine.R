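test_that("badge assignment matches the tier table on canonical bundles", {
  all_true <- evidence_bundle(determinable = TRUE, has_accession = TRUE,
                              data_public_downloadable = TRUE,
                              raw_format_ok = TRUE,
                              sequencing_method_known = TRUE,
                              is_amplicon = TRUE, primers_found = TRUE,
                              das_clarifies_access = TRUE,
                              repository_open_access = TRUE,
                              code_available = TRUE)
  rep_gold <- assign_sequence_badge(all_true)
  expect_identical(rep_gold$badge, "gold")
  expect_length(rep_gold$missing, 0L)

  bronze_only <- evidence_bundle(has_accession = TRUE,
                                 data_public_downloadable = TRUE,
                                 raw_format_ok = TRUE)
  rep_bronze <- assign_sequence_badge(bronze_only)
  expect_identical(rep_bronze$badge, "bronze")
  expect_identical(rep_bronze$missing, "sequencing_method_provided")

  no_accession <- evidence_bundle(determinable = TRUE, has_accession = FALSE,
                                  raw_format_ok = TRUE,
                                  sequencing_method_known = TRUE,
                                  is_amplicon = TRUE, primers_found = TRUE,
                                  das_clarifies_access = TRUE,
                                  repository_open_access = TRUE,
                                  code_available = TRUE)
  expect_identical(assign_sequence_badge(no_accession)$badge, "none")

  expect_identical(
    assign_sequence_badge(evidence_bundle(determinable = FALSE))$badge,
    "cannot_be_determined")
})

test_that("primer criterion is not applicable for metagenome-only studies", {
  shotgun_silver <- evidence_bundle(
    has_accession = TRUE, data_public_downloadable = TRUE,
    raw_format_ok = TRUE, sequencing_method_known = TRUE,
    is_amplicon = FALSE, primers_found = FALSE)
  rep <- assign_sequence_badge(shotgun_silver)
  expect_identical(rep$badge, "silver")
  expect_identical(unname(rep$criteria["pcr_primer_sequences"]),
                   "not_applicable")
  ## same bundle but amplicon without primers stalls at bronze
  amplicon <- evidence_bundle(
    has_accession = TRUE, data_public_downloadable = TRUE,
    raw_format_ok = TRUE, sequencing_method_known = TRUE,
    is_amplicon = TRUE, primers_found = FALSE)
  expect_identical(assign_sequence_badge(amplicon)$badge, "bronze")
})

test_that("badge reports satisfy tier subsumption and the missing contract", {
  g <- enumerate_bundles()
  for (i in seq_len(nrow(g))) {
    rep <- assign_sequence_badge(row_bundle(g[i, ]))
    expect_identical(length(rep$missing) == 0L, rep$badge == "gold")
    if (rep$badge %in% c("bronze", "silver", "gold")) {
      bronze_crit <- c("data_downloadable_not_paywalled",
                       "accession_numbers_provided",
                       "raw_sequences_bcl_or_fastq")
      expect_true(all(rep$criteria[bronze_crit] != "unsatisfied"))
    }
    if (rep$badge %in% c("silver", "gold")) {
      expect_true(all(rep$criteria[c("sequencing_method_provided",
                                     "pcr_primer_sequences")] != "unsatisfied"))
    }
  }
})

test_that("evidence bundles validate their inputs", {
  expect_error(evidence_bundle(data_public_downloadable = TRUE,
                               has_accession = FALSE),
               "implies")
  expect_error(evidence_bundle(has_accession = NA), "TRUE or FALSE")
})

test_that("binary collapse maps badged tiers together", {
  expect_identical(collapse_binary(c("bronze", "silver", "gold")),
                   rep("badged", 3))
  expect_identical(collapse_binary("none"), "not_badged")
  expect_identical(collapse_binary("cannot_be_determined"), "not_badged")
  expect_error(collapse_binary("platinum"), "unknown badge")
})

test_that("evidence derives field by field from extraction plus resolution", {
  doc <- article_document(
    "PMCDERIVE",
    sections = list(
      list(label = "Methods",
           body = paste("16S rRNA gene amplicon libraries used primers 515F",
                        "(GTGYCAGCMGCCGCGGTAA) and 806R (GGACTACNVGGGTWTCTAAT).")),
      list(label = "Code", body = "Scripts at https://github.com/lab/code.")),
    das_text = "Reads were deposited in the SRA under SRR1000001.")
  ex <- extract_all(doc)
  res <- list(resolution_record("SRR1000001", registry = "SRA", public = TRUE,
                                n_runs = 2L, file_formats = "FASTQ",
                                resolved = TRUE))
  ev <- evidence_from_extraction(ex, res)
  expect_true(ev$has_accession && ev$data_public_downloadable &&
                ev$raw_format_ok && ev$sequencing_method_known &&
                ev$is_amplicon && ev$primers_found &&
                ev$repository_open_access && ev$code_available)
  expect_identical(assign_sequence_badge(ev)$badge, "gold")

  ## zero accessions force the downloadability implication
  doc0 <- article_document("PMC0", sections = list(
    list(label = "Results", body = "No data were produced.")))
  ev0 <- evidence_from_extraction(extract_all(doc0), list())
  expect_false(ev0$has_accession)
  expect_false(ev0$data_public_downloadable)

  ## resolved public project but method unstated blocks silver
  doc1 <- article_document("PMC1", sections = list(
    list(label = "Methods", body = "Libraries were prepared and run.")),
    das_text = "Reads were deposited in the ENA under PRJEB11111.")
  res1 <- list(resolution_record("PRJEB11111", registry = "ENA",
                                 public = TRUE, n_runs = 4L,
                                 file_formats = "FASTQ", resolved = TRUE))
  ev1 <- evidence_from_extraction(extract_all(doc1), res1)
  rep1 <- assign_sequence_badge(ev1)
  expect_identical(rep1$badge, "bronze")
  expect_true("sequencing_method_provided" %in% rep1$missing)

  ## EGA-only citation is not an open registry
  docE <- article_document("PMCE", sections = list(
    list(label = "Data", body = "Dataset EGAS00001234567 holds the reads.")))
  evE <- evidence_from_extraction(extract_all(docE), list())
  expect_false(evE$repository_open_access)
})
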