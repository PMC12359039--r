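## Seeded synthetic fixtures: templated JATS articles whose text embeds
## exactly the evidence implied by a target badge (with a matching offline
## resolution manifest), and multi-study sample metadata with planted
## attribute-population rates. Everything is deterministic under the profile
## seed; noise options are limited to transformations the extractors are
## contracted to tolerate (primer case folding, punctuation spacing, section
## reordering).

.registry_display <- c(
  "SRA" = "NCBI Sequence Read Archive (SRA)",
  "ENA" = "European Nucleotide Archive (ENA)",
  "DDBJ" = "DDBJ Sequence Read Archive",
  "CNCB-NGDC" = "Genome Sequence Archive of the National Genomics Data Center",
  "MG-RAST" = "MG-RAST server",
  "CNGB" = "China National GeneBank Sequence Archive (CNGB)",
  "EGA" = "European Genome-phenome Archive (EGA)")

#' Noise options for the article generator
#'
#' @param case_jitter randomize the letter case of primer sequences (primer
#'   detection is case-insensitive by contract).
#' @param punctuation_jitter vary spacing around sentence punctuation.
#' @param section_shuffle reorder the body sections.
#' @return a list of three logical flags.
#' @export
noise_options <- function(case_jitter = FALSE, punctuation_jitter = FALSE,
                          section_shuffle = FALSE) {
  list(case_jitter = isTRUE(case_jitter),
       punctuation_jitter = isTRUE(punctuation_jitter),
       section_shuffle = isTRUE(section_shuffle))
}

#' Build a self-consistent synthetic article profile
#'
#' Validates that the requested evidence combination actually yields
#' `target_badge` under the badge rules (e.g. a Gold profile must use an
#' open registry and a public-deposit DAS).
#'
#' @param target_badge badge the generated article must earn.
#' @param is_amplicon marker-gene (amplicon) study; controls the primer
#'   requirement.
#' @param registry registry for the embedded accession token.
#' @param n_runs number of runs listed in the fixture resolution.
#' @param das_style DAS class of the generated statement; `NULL` picks a
#'   consistent default for the target badge.
#' @param none_reason for `target_badge = "none"`: `"no_accession"` (no
#'   token at all), `"not_public"` (token resolves private) or `"not_raw"`
#'   (public but no FASTQ/BCL listing).
#' @param undetermined_reason for `target_badge = "cannot_be_determined"`:
#'   `"not_found"`, `"parse_error"` or `"no_fulltext"`.
#' @param noise see [noise_options()].
#' @param seed integer seed; the same profile generates byte-identical
#'   output.
#' @param article_id optional fixed identifier; derived from the seed when
#'   `NULL`.
#' @return an object of class `article_profile`.
#' @export
article_profile <- function(target_badge, is_amplicon = TRUE,
                            registry = "SRA", n_runs = 3L, das_style = NULL,
                            none_reason = c("no_accession", "not_public",
                                            "not_raw"),
                            undetermined_reason = c("not_found", "parse_error",
                                                    "no_fulltext"),
                            noise = noise_options(), seed = 1L,
                            article_id = NULL) {
  target_badge <- match.arg(target_badge, .badges_all)
  none_reason <- match.arg(none_reason)
  undetermined_reason <- match.arg(undetermined_reason)
  stopifnot(registry %in% .registries, n_runs >= 0)
  if (is.null(das_style)) {
    das_style <- switch(target_badge,
      none = switch(none_reason, no_accession = "upon_request",
                    not_public = "restricted_with_procedure",
                    not_raw = "public_deposit"),
      cannot_be_determined = "absent",
      "public_deposit")
  }
  profile <- structure(list(
    target_badge = target_badge, is_amplicon = isTRUE(is_amplicon),
    registry = registry, n_runs = as.integer(n_runs), das_style = das_style,
    none_reason = none_reason, undetermined_reason = undetermined_reason,
    noise = noise, seed = as.integer(seed), article_id = article_id),
    class = "article_profile")
  if (target_badge != "cannot_be_determined") {
    got <- assign_sequence_badge(profile_evidence(profile))$badge
    if (got != target_badge) {
      stop(sprintf("inconsistent profile: evidence yields '%s', not '%s'",
                   got, target_badge), call. = FALSE)
    }
  }
  profile
}

## what the generated article will expose, stated as the evidence bundle the
## extraction + resolution pipeline must reconstruct
profile_evidence <- function(profile) {
  target <- profile$target_badge
  has_acc <- !(target == "none" && profile$none_reason == "no_accession")
  public <- has_acc &&
    (target %in% c("bronze", "silver", "gold") ||
       (target == "none" && profile$none_reason == "not_raw"))
  formats <- if (!public) character(0)
             else if (target == "none") "other" else "FASTQ"
  method_stated <- target %in% c("silver", "gold") ||
    (target == "none" && profile$none_reason == "no_accession")
  primers <- method_stated && profile$is_amplicon
  evidence_bundle(
    determinable = TRUE,
    has_accession = has_acc,
    data_public_downloadable = public && length(formats) > 0L,
    raw_format_ok = public && "FASTQ" %in% formats,
    sequencing_method_known = method_stated,
    is_amplicon = method_stated && profile$is_amplicon,
    primers_found = primers,
    das_clarifies_access = profile$das_style == "restricted_with_procedure",
    repository_open_access =
      !has_acc || profile$registry %in% pattern_config()$open_registries,
    code_available = target == "gold")
}

random_digits <- function(n) {
  paste(sample(0:9, n, replace = TRUE), collapse = "")
}

project_token <- function(registry) {
  switch(registry,
    "SRA" = paste0("PRJNA", random_digits(6)),
    "ENA" = paste0("PRJEB", random_digits(5)),
    "DDBJ" = paste0("PRJDB", random_digits(5)),
    "CNCB-NGDC" = paste0("PRJCA", random_digits(6)),
    "MG-RAST" = paste0("mgm", random_digits(7), ".", sample(1:9, 1)),
    "CNGB" = paste0("CNP", random_digits(7)),
    "EGA" = paste0("EGAS", random_digits(11)),
    paste0("PRJNA", random_digits(6)))
}

run_token <- function(registry) {
  prefix <- switch(registry, "SRA" = "SRR", "ENA" = "ERR", "DDBJ" = "DRR",
                   NULL)
  if (is.null(prefix)) NULL else paste0(prefix, random_digits(7))
}

random_primer <- function(len) {
  ## mostly plain bases with a few degenerate codes, as in real primers
  alphabet <- c(rep(c("A", "C", "G", "T"), 6), "R", "Y", "W", "M", "N", "V")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

jitter_case <- function(x) {
  chars <- strsplit(x, "")[[1]]
  flip <- stats::runif(length(chars)) < 0.5
  chars[flip] <- tolower(chars[flip])
  paste(chars, collapse = "")
}

jitter_punctuation <- function(x) {
  if (stats::runif(1) < 0.5) x <- gsub(", ", " , ", x, fixed = TRUE)
  if (stats::runif(1) < 0.5) x <- gsub("\\. ", " .  ", x)
  x
}

#' Generate a synthetic article with a known ground-truth badge
#'
#' Emits a templated JATS XML article embedding exactly the evidence implied
#' by the profile's target badge (catalogued accession token, primer
#' sequences and method statement when required, DAS sentence from the
#' packaged phrase table, code link for Gold), together with the manifest
#' fragment that makes offline accession resolution consistent with the
#' profile. The returned `true_badge` equals the badge-engine output on the
#' profile's evidence by construction.
#'
#' @param profile an [article_profile()].
#' @return list with `article_id`, `xml` (JATS source; truncated or bodyless
#'   for cannot-be-determined variants), `manifest_accessions` (fragment for
#'   the fixture manifest), `in_manifest` (whether the article itself should
#'   be listed), and `true_badge`.
#' @export
generate_article <- function(profile) {
  stopifnot(inherits(profile, "article_profile"))
  set.seed(profile$seed)
  target <- profile$target_badge
  article_id <- profile$article_id %||%
    sprintf("PMC%07d", sample.int(8999999L, 1) + 1000000L)

  has_acc <- !(target == "none" && profile$none_reason == "no_accession")
  acc <- if (has_acc) project_token(profile$registry) else NULL
  run <- if (has_acc && target != "cannot_be_determined" &&
             stats::runif(1) < 0.5) run_token(profile$registry) else NULL
  method_stated <- target %in% c("silver", "gold") ||
    (target == "none" && profile$none_reason == "no_accession")
  use_primers <- method_stated && profile$is_amplicon

  primer_f <- random_primer(sample(18:22, 1))
  primer_r <- random_primer(sample(18:22, 1))
  if (profile$noise$case_jitter) {
    primer_f <- jitter_case(primer_f)
    primer_r <- jitter_case(primer_r)
  }
  label_f <- paste0(sample(c(341, 515, 799), 1), "F")
  label_r <- paste0(sample(c(806, 805, 1193), 1), "R")

  intro <- paste(
    "Gut microbial communities influence host physiology, immune development,",
    "and nutrient cycling. We profiled stool specimens from adult volunteers",
    "to characterize community structure across diet groups.")
  methods <- if (!method_stated) {
    paste("Libraries were prepared with a standard kit and run on an Illumina",
          "NovaSeq 6000 instrument following the manufacturer protocol.")
  } else if (profile$is_amplicon) {
    paste0("The V4 hypervariable region of the 16S rRNA gene was amplified ",
           "and sequenced. Amplification used primers ", label_f, " (",
           primer_f, ") and ", label_r, " (", primer_r, ").")
  } else {
    paste("Whole-community shotgun metagenomic sequencing libraries were",
          "prepared and run on an Illumina NovaSeq platform.")
  }
  results <- paste(
    "Community composition differed among diet groups, and alpha diversity",
    "was higher in participants consuming fermented foods. Taxonomic shifts",
    "were concentrated in a small number of genera.")
  code_url <- paste0("https://github.com/", "lab", random_digits(3),
                     "/analysis", random_digits(2))
  code_par <- paste0("Analysis code and processing scripts used in this study",
                     " are archived at ", code_url, ".")

  acc_phrase <- if (!is.null(run)) paste0(acc, " (runs including ", run, ")")
                else acc
  das <- switch(profile$das_style,
    public_deposit = paste0("Raw sequence reads generated in this study were ",
                            "deposited in the ",
                            .registry_display[[profile$registry]],
                            " under accession ", acc_phrase, "."),
    upon_request = paste("The datasets generated during the current study are",
                         "available from the corresponding author upon",
                         "reasonable request."),
    restricted_with_procedure = paste0(
      "Participant-level sequence data are under controlled access; ",
      "qualified researchers may apply to the data access committee for ",
      "access to dataset ", if (has_acc) acc else "records", "."),
    in_paper_only = paste("All data generated or analysed during this study",
                          "are included in this published article and its",
                          "supplementary information files."),
    absent = NULL)

  body_secs <- list(
    list(label = "Introduction", body = intro),
    list(label = "Methods", body = methods),
    list(label = "Results", body = results))
  if (target == "gold") {
    body_secs <- c(body_secs,
                   list(list(label = "Code availability", body = code_par)))
  }
  if (profile$noise$punctuation_jitter) {
    body_secs <- lapply(body_secs, function(s) {
      s$body <- jitter_punctuation(s$body)
      s
    })
  }
  if (profile$noise$section_shuffle) {
    body_secs <- body_secs[sample(seq_along(body_secs))]
  }

  sec_xml <- vapply(body_secs, function(s) {
    paste0("    <sec><title>", s$label, "</title><p>", s$body, "</p></sec>")
  }, character(1))
  das_xml <- if (!is.null(das)) {
    paste0("    <sec sec-type=\"data-availability\">",
           "<title>Data Availability</title><p>", das, "</p></sec>")
  } else {
    character(0)
  }
  journal <- sample(c("Journal of Synthetic Microbiology",
                      "Annals of Community Ecology",
                      "Microbial Data Reports"), 1)
  xml <- paste(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<article>",
    "  <front>",
    "    <journal-meta><journal-title-group><journal-title>",
    paste0("      ", journal),
    "    </journal-title></journal-title-group>",
    "    <publisher><publisher-name>Synthetic Press</publisher-name></publisher></journal-meta>",
    "    <article-meta><title-group><article-title>",
    "      A synthetic survey of gut microbial community structure",
    "    </article-title></title-group>",
    paste0("    <pub-date><year>", sample(2015:2024, 1), "</year></pub-date>"),
    "    </article-meta>",
    "  </front>",
    "  <body>",
    sec_xml,
    "  </body>",
    if (length(das_xml)) c("  <back>", das_xml, "  </back>") else NULL,
    "</article>"), collapse = "\n")

  in_manifest <- TRUE
  if (target == "cannot_be_determined") {
    if (profile$undetermined_reason == "parse_error") {
      xml <- substr(xml, 1, 60)
    } else if (profile$undetermined_reason == "no_fulltext") {
      xml <- paste(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        "<article><front><article-meta><title-group><article-title>",
        "Synthetic record without retrievable full text",
        "</article-title></title-group></article-meta></front><body/></article>",
        sep = "\n")
    } else {
      in_manifest <- FALSE
    }
  }

  manifest_acc <- list()
  if (has_acc && target != "cannot_be_determined") {
    public <- target %in% c("bronze", "silver", "gold") ||
      (target == "none" && profile$none_reason == "not_raw")
    formats <- if (!public) list()
               else if (target == "none") list("other") else list("FASTQ")
    manifest_acc[[acc]] <- list(registry = profile$registry, public = public,
                                n_runs = profile$n_runs,
                                file_formats = formats)
    if (!is.null(run) && public) {
      manifest_acc[[run]] <- list(registry = profile$registry, public = TRUE,
                                  n_runs = 1L, file_formats = formats)
    }
  }

  list(article_id = article_id, xml = xml,
       manifest_accessions = manifest_acc, in_manifest = in_manifest,
       true_badge = target, profile = profile)
}

#' Generate a seeded synthetic article corpus on disk
#'
#' Writes `n` articles (JATS XML under `articles/`), the offline resolution
#' `manifest.json`, and a `truth.csv` ground-truth table into `dir`. The
#' default badge mix follows the proportions typical of field surveys of
#' microbiome publications (45% none, 15% bronze, 27% silver, 8% gold, 5%
#' not determinable), with registries weighted towards SRA and ENA.
#'
#' @param dir output directory (created if needed).
#' @param n corpus size.
#' @param seed corpus seed; per-article seeds are derived from it.
#' @param noise [noise_options()] applied to every article.
#' @param badge_mix named proportions over the five badge classes.
#' @return invisibly, the ground-truth data frame (`article_id`,
#'   `true_badge`, `registry`, `is_amplicon`, ...).
#' @export
generate_corpus <- function(dir, n = 200L, seed = 1L,
                            noise = noise_options(),
                            badge_mix = c(none = 0.45, bronze = 0.15,
                                          silver = 0.27, gold = 0.08,
                                          cannot_be_determined = 0.05)) {
  stopifnot(n >= 1, abs(sum(badge_mix) - 1) < 1e-8,
            all(names(badge_mix) %in% .badges_all))
  set.seed(seed)
  counts <- floor(badge_mix * n)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- badge_mix * n - counts
    top <- order(frac, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1L
  }
  badges <- sample(rep(names(counts), counts))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  open_reg <- c("SRA", "ENA", "DDBJ", "CNCB-NGDC", "MG-RAST")
  reg_prob <- c(0.66, 0.18, 0.05, 0.06, 0.05)
  none_reasons <- c("no_accession", "not_public", "not_raw")
  und_reasons <- c("not_found", "parse_error", "no_fulltext")

  dir.create(file.path(dir, "articles"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- list(articles = list(), accessions = list(), metadata = list())
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    badge <- badges[i]
    none_reason <- none_reasons[(i %% 3L) + 1L]
    registry <- if (badge == "none" && none_reason == "not_public" &&
                    stats::runif(1) < 0.5) "EGA"
                else sample(open_reg, 1, prob = reg_prob)
    profile <- article_profile(
      target_badge = badge,
      is_amplicon = stats::runif(1) < 0.7,
      registry = registry,
      n_runs = sample.int(24L, 1),
      none_reason = none_reason,
      undetermined_reason = und_reasons[(i %% 3L) + 1L],
      noise = noise, seed = seeds[i],
      article_id = sprintf("PMC%07d", 3000000L + i))
    art <- generate_article(profile)
    rel <- file.path("articles", paste0(art$article_id, ".xml"))
    if (art$in_manifest) {
      writeLines(art$xml, file.path(dir, rel))
      manifest$articles[[art$article_id]] <- rel
    }
    manifest$accessions <- c(manifest$accessions, art$manifest_accessions)
    rows[[i]] <- data.frame(
      article_id = art$article_id, true_badge = art$true_badge,
      registry = if (badge == "cannot_be_determined") NA_character_ else registry,
      is_amplicon = profile$is_amplicon, n_runs = profile$n_runs,
      das_style = profile$das_style, stringsAsFactors = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}

## ---- synthetic metadata ----------------------------------------------------

#' Default 220-attribute vocabulary for the metadata generator
#'
#' The 22 canonical checklist terms plus anonymous auxiliary attributes, to
#' the requested total.
#'
#' @param n_total vocabulary size.
#' @return character vector of attribute names.
#' @export
default_metadata_vocabulary <- function(n_total = 220L) {
  core <- metadata_checklist()$cumulative$gold
  stopifnot(n_total > length(core))
  c(core, sprintf("attr_%03d", seq_len(n_total - length(core))))
}

#' Default planted population rates
#'
#' Emulates the sparsity profile observed in cross-study metadata surveys:
#' a small consistently-filled core (16 attributes at rate 1), a long tail
#' populated by a single study each (rate 1/n), and a middle band spread
#' between.
#'
#' @param vocabulary attribute vocabulary.
#' @param n_studies number of studies (tail rate is 1/n_studies).
#' @return named numeric vector of rates in (0, 1].
#' @export
default_population_rates <- function(vocabulary = default_metadata_vocabulary(),
                                     n_studies = 42L) {
  n_attr <- length(vocabulary)
  n_core <- min(16L, n_attr)
  n_tail <- min(167L, n_attr - n_core)
  n_mid <- n_attr - n_core - n_tail
  rates <- c(rep(1, n_core),
             if (n_mid > 0) seq(0.15, 0.9, length.out = n_mid),
             rep(1 / n_studies, n_tail))
  stats::setNames(rates, vocabulary)
}

#' Build a synthetic metadata generation profile
#'
#' @param n_studies number of studies.
#' @param attribute_vocabulary canonical attribute names.
#' @param planted_population_rate named rates per attribute; realized counts
#'   are `max(1, round(rate * n_studies))` populated studies each.
#' @param synonym_noise_rate probability that a study reports a canonical
#'   checklist attribute under a raw synonym.
#' @param missing_token_rate probability that a non-counting sample of a
#'   populated attribute carries a missing token instead of a value.
#' @param samples_per_study integer range (min, max).
#' @param seed generator seed.
#' @return an object of class `metadata_profile`.
#' @export
metadata_profile <- function(n_studies = 42L,
                             attribute_vocabulary = default_metadata_vocabulary(),
                             planted_population_rate =
                               default_population_rates(attribute_vocabulary,
                                                        n_studies),
                             synonym_noise_rate = 0.3,
                             missing_token_rate = 0.15,
                             samples_per_study = c(3L, 8L), seed = 1L) {
  stopifnot(n_studies >= 1,
            all(names(planted_population_rate) == attribute_vocabulary),
            all(planted_population_rate >= 0),
            all(planted_population_rate <= 1),
            synonym_noise_rate >= 0, synonym_noise_rate <= 1,
            missing_token_rate >= 0, missing_token_rate <= 1,
            length(samples_per_study) == 2L,
            samples_per_study[1] >= 1,
            samples_per_study[2] >= samples_per_study[1])
  structure(list(n_studies = as.integer(n_studies),
                 attribute_vocabulary = attribute_vocabulary,
                 planted_population_rate = planted_population_rate,
                 synonym_noise_rate = synonym_noise_rate,
                 missing_token_rate = missing_token_rate,
                 samples_per_study = as.integer(samples_per_study),
                 seed = as.integer(seed)),
            class = "metadata_profile")
}

plausible_value <- function(attr) {
  switch(attr,
    sample_name = sprintf("S%04d", sample.int(9999L, 1)),
    project_name = sprintf("gut survey %d", sample.int(99L, 1)),
    taxonomy_id = "408170",
    collection_date = sprintf("20%02d-%02d-%02d", sample(15:23, 1),
                              sample(1:12, 1), sample(1:28, 1)),
    lat_lon = sprintf("%.4f N %.4f E", stats::runif(1, 0, 60),
                      stats::runif(1, 0, 90)),
    geo_loc_name = sample(c("Switzerland: Zurich", "USA: California",
                            "Japan: Tokyo", "Brazil: Sao Paulo"), 1),
    env_broad_scale = "human-associated habitat [ENVO:00009003]",
    env_local_scale = "digestive tract environment",
    env_medium = "feces [UBERON:0001988]",
    seq_meth = sample(c("Illumina MiSeq", "Illumina NovaSeq 6000"), 1),
    neg_cont_type = "blank extraction",
    target_gene = "16S rRNA",
    pcr_primers = "FWD:GTGYCAGCMGCCGCGGTAA;REV:GGACTACNVGGGTWTCTAAT",
    host_subject_id = sprintf("subj%03d", sample.int(999L, 1)),
    host_disease_stat = sample(c("healthy", "IBD", "IBS"), 1),
    host_tot_mass = sprintf("%d kg", sample(45:110, 1)),
    host_sex = sample(c("male", "female"), 1),
    samp_mat_process = "homogenized before extraction",
    nucl_acid_ext = "bead beating with silica columns",
    host_height = sprintf("%d cm", sample(150:200, 1)),
    host_diet = sample(c("omnivore", "vegetarian", "vegan"), 1),
    host_occupation = sample(c("office worker", "farmer", "student"), 1),
    sprintf("%s value %d", attr, sample.int(999L, 1)))
}

#' Generate synthetic multi-study metadata with planted population rates
#'
#' For each attribute, `max(1, round(rate * n_studies))` studies are drawn
#' to populate it; the realized boolean attribute-by-study matrix is
#' returned exactly as planted. Populated cells always keep at least one
#' non-missing sample value, with missing tokens injected into the remaining
#' samples at the profile rate; unpopulated cells occasionally appear as
#' missing-token-only attributes. Checklist attributes are renamed to raw
#' synonyms at the synonym-noise rate, so that harmonization followed by
#' [population_matrix()] recovers the planted matrix exactly.
#'
#' @param profile a [metadata_profile()].
#' @return list with `studies` (list of [study_metadata()]) and `planted`
#'   (a `population_matrix` object with the realized rates).
#' @export
generate_metadata_studies <- function(profile) {
  stopifnot(inherits(profile, "metadata_profile"))
  set.seed(profile$seed)
  n <- profile$n_studies
  vocab <- profile$attribute_vocabulary
  rates <- profile$planted_population_rate
  study_ids <- sprintf("STUDY%03d", seq_len(n))
  size_range <- seq(profile$samples_per_study[1], profile$samples_per_study[2])
  nsamp <- size_range[sample.int(length(size_range), n, replace = TRUE)]
  variants <- synonym_variants()
  missing_pool <- c("not collected", "missing", "n/a", "not provided")

  M <- matrix(FALSE, nrow = length(vocab), ncol = n,
              dimnames = list(vocab, study_ids))
  for (a in vocab) {
    k <- max(1L, round(rates[[a]] * n))
    M[a, sample.int(n, k)] <- TRUE
  }

  studies <- vector("list", n)
  for (j in seq_len(n)) {
    samples <- sprintf("%s_S%02d", study_ids[j], seq_len(nsamp[j]))
    rows <- list()
    for (a in vocab) {
      rendered <- a
      if (!is.null(variants[[a]]) &&
          stats::runif(1) < profile$synonym_noise_rate) {
        rendered <- sample(variants[[a]], 1)
      }
      if (M[a, j]) {
        vals <- vapply(samples, function(s) plausible_value(a), character(1))
        if (length(samples) > 1L) {
          drop <- stats::runif(length(samples) - 1L) < profile$missing_token_rate
          vals[-1][drop] <- sample(missing_pool, sum(drop), replace = TRUE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = samples, attribute = rendered, value = unname(vals),
          stringsAsFactors = FALSE)
      } else if (stats::runif(1) < 0.05) {
        ## attribute present in this study but only as missing tokens
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = samples[1], attribute = rendered,
          value = sample(missing_pool, 1), stringsAsFactors = FALSE)
      }
    }
    studies[[j]] <- study_metadata(
      study_id = study_ids[j],
      checklist_name = if (stats::runif(1) < 0.5) "MIMS.me.human-gut.6.0"
                       else NA_character_,
      records = do.call(rbind, rows))
  }

  ord <- order(rownames(M))
  planted <- structure(list(matrix = M[ord, , drop = FALSE],
                            proportion = rowMeans(M)[ord]),
                       class = "population_matrix")
  list(studies = studies, planted = planted)
}

#' Write metadata fixtures for the offline client
#'
#' Stores each study's records as a long-format CSV under `metadata/` and
#' extends (or creates) the fixture manifest so that
#' [fetch_sample_metadata()] can replay them.
#'
#' @param dir fixtures directory.
#' @param studies list of [study_metadata()] objects.
#' @param accessions accession keys to file the studies under; defaults to
#'   the study ids.
#' @return invisibly, the manifest list.
#' @export
write_metadata_fixtures <- function(dir, studies,
                                    accessions = vapply(studies, `[[`,
                                                        character(1),
                                                        "study_id")) {
  stopifnot(length(studies) == length(accessions))
  dir.create(file.path(dir, "metadata"), recursive = TRUE,
             showWarnings = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) read_manifest(manifest_path)
              else list(articles = list(), accessions = list(),
                        metadata = list())
  for (i in seq_along(studies)) {
    rel <- file.path("metadata", paste0(accessions[i], ".csv"))
    utils::write.csv(studies[[i]]$records, file.path(dir, rel),
                     row.names = FALSE)
    entry <- list(path = rel)
    if (!is.na(studies[[i]]$checklist_name)) {
      entry$checklist_name <- studies[[i]]$checklist_name
    }
    manifest$metadata[[accessions[i]]] <- entry
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
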