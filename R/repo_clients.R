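## Retrieval layer: article full text (JATS XML) and repository resolution /
## sample metadata, behind narrow contracts with a fully offline fixture
## mode. Offline mode reads a manifest (JSON) mapping article ids to stored
## JATS files and accessions to resolution records / metadata CSVs; live mode
## hits the public NCBI/ENA endpoints and is never exercised in the test
## suite.

#' Build a run configuration
#'
#' @param mode `"offline"` (fixture/replay, the default) or `"live"`.
#' @param fixtures_dir directory containing `manifest.json` plus the stored
#'   articles and metadata tables; required in offline mode.
#' @param contact contact identifier sent with live requests (API etiquette).
#' @param include_undetermined include cannot-be-determined items in accuracy
#'   computations downstream.
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode = c("offline", "live"), fixtures_dir = NULL,
                       contact = NULL, include_undetermined = FALSE) {
  mode <- match.arg(mode)
  manifest <- NULL
  if (mode == "offline") {
    if (is.null(fixtures_dir)) {
      stop("offline mode requires `fixtures_dir`", call. = FALSE)
    }
    manifest <- read_manifest(file.path(fixtures_dir, "manifest.json"))
  }
  structure(list(mode = mode, fixtures_dir = fixtures_dir,
                 manifest = manifest, contact = contact,
                 include_undetermined = include_undetermined),
            class = "run_config")
}

#' Read a fixture manifest
#'
#' @param path path to a `manifest.json` with objects `articles`
#'   (article id -> relative JATS path), `accessions` (accession ->
#'   resolution record) and `metadata` (accession -> `{path, checklist_name}`).
#' @return the manifest as a nested list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Construct a repository resolution record
#'
#' @param accession the resolved accession token.
#' @param registry registry name (SRA, ENA, DDBJ, ...).
#' @param public data are retrievable without payment or login.
#' @param n_runs number of sequencing runs listed under the record.
#' @param file_formats subset of FASTQ / BCL / BAM / other.
#' @param resolved whether resolution succeeded (FALSE marks a failure).
#' @param resolved_at timestamp or fixture tag.
#' @return an object of class `resolution_record`.
#' @export
resolution_record <- function(accession, registry = "other", public = FALSE,
                              n_runs = 0L, file_formats = character(0),
                              resolved = FALSE, resolved_at = "fixture") {
  stopifnot(n_runs >= 0)
  structure(list(accession = accession, registry = registry,
                 public = isTRUE(public), n_runs = as.integer(n_runs),
                 file_formats = as.character(file_formats),
                 resolved = isTRUE(resolved), resolved_at = resolved_at),
            class = "resolution_record")
}

## registry implied by the accession token, from the pattern catalogue
guess_registry <- function(accession, config = pattern_config()) {
  cat <- config$accession_catalogue
  for (i in seq_len(nrow(cat))) {
    if (grepl(paste0("^", cat$pattern[i], "$"), accession, perl = TRUE)) {
      return(cat$registry[i])
    }
  }
  "other"
}

#' Fetch article full text
#'
#' Offline mode looks the article up in the fixture manifest and parses the
#' stored JATS XML; live mode fetches from the NCBI efetch endpoint. Expected
#' misses (unknown id, malformed XML, empty body) are reported through
#' `retrieval_status` rather than raised.
#'
#' @param article_id article identifier (e.g. a PMC ID).
#' @param config a [run_config()].
#' @return an [article_document()].
#' @export
fetch_fulltext <- function(article_id, config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "live") return(fetch_fulltext_live(article_id, config))
  rel <- config$manifest$articles[[article_id]]
  if (is.null(rel)) {
    return(article_document(article_id, sections = list(),
                            retrieval_status = "not_found"))
  }
  path <- file.path(config$fixtures_dir, rel)
  if (!file.exists(path)) {
    return(article_document(article_id, sections = list(),
                            retrieval_status = "not_found"))
  }
  xml <- tryCatch(xml2::read_xml(path), error = function(e) NULL)
  if (is.null(xml)) {
    return(article_document(article_id, sections = list(),
                            retrieval_status = "parse_error"))
  }
  parse_jats(xml, article_id)
}

## JATS (PMC dialect) -> article_document; section labels from <title>
parse_jats <- function(xml, article_id) {
  first_text <- function(xpath) {
    node <- xml2::xml_find_first(xml, xpath)
    if (inherits(node, "xml_missing")) NA_character_ else xml2::xml_text(node)
  }
  title <- first_text(".//front//article-title")
  year <- suppressWarnings(as.integer(first_text(".//front//pub-date/year")))
  journal <- first_text(".//front//journal-title")
  publisher <- first_text(".//front//publisher-name")
  secs <- xml2::xml_find_all(xml, ".//body/sec | .//back/sec")
  sections <- lapply(secs, function(s) {
    lab <- xml2::xml_find_first(s, "./title")
    lab <- if (inherits(lab, "xml_missing")) "" else xml2::xml_text(lab)
    ps <- xml2::xml_text(xml2::xml_find_all(s, ".//p"))
    list(label = lab, body = paste(ps, collapse = "\n"))
  })
  das_text <- NULL
  for (i in seq_along(secs)) {
    sec_type <- xml2::xml_attr(secs[[i]], "sec-type")
    lab <- sections[[i]]$label
    if ((!is.na(sec_type) && sec_type == "data-availability") ||
        grepl("data availability", lab, ignore.case = TRUE)) {
      das_text <- sections[[i]]$body
    }
  }
  has_text <- length(sections) > 0L &&
    any(nzchar(vapply(sections, `[[`, character(1), "body")))
  if (!has_text) {
    return(article_document(article_id, title = title,
                            publication_year = year, journal = journal,
                            publisher = publisher, sections = list(),
                            retrieval_status = "no_fulltext"))
  }
  article_document(article_id, title = title, publication_year = year,
                   journal = journal, publisher = publisher,
                   sections = sections, das_text = das_text,
                   retrieval_status = "ok")
}

#' Resolve an accession against a repository
#'
#' Offline mode reads the resolution from the fixture manifest; an
#' unmanifested accession yields an unresolved record with `public = FALSE`.
#' Live mode queries the ENA portal API.
#'
#' @param accession a catalogued accession token.
#' @param config a [run_config()].
#' @return a [resolution_record()].
#' @export
resolve_accession <- function(accession, config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "live") return(resolve_accession_live(accession, config))
  e <- config$manifest$accessions[[accession]]
  if (is.null(e)) {
    return(resolution_record(accession,
                             registry = guess_registry(accession),
                             public = FALSE, resolved = FALSE))
  }
  resolution_record(accession,
                    registry = e$registry %||% guess_registry(accession),
                    public = isTRUE(e$public),
                    n_runs = as.integer(e$n_runs %||% 0L),
                    file_formats = unlist(e$file_formats) %||% character(0),
                    resolved = TRUE)
}

#' Fetch the sample metadata associated with an accession
#'
#' Offline mode reads the stored long-format CSV (`sample_id`, `attribute`,
#' `value`) referenced by the manifest, together with the reported checklist
#' name. Resolution failures and empty record sets are signalled as errors
#' of class `seqbadge_resolution_failure` / `seqbadge_unevaluable`.
#'
#' @param accession a repository accession.
#' @param config a [run_config()].
#' @return a [study_metadata()].
#' @export
fetch_sample_metadata <- function(accession, config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "live") {
    return(fetch_sample_metadata_live(accession, config))
  }
  e <- config$manifest$metadata[[accession]]
  if (is.null(e)) {
    stop(structure(
      class = c("seqbadge_resolution_failure", "error", "condition"),
      list(message = sprintf("no metadata fixture for accession %s", accession),
           call = NULL)))
  }
  df <- utils::read.csv(file.path(config$fixtures_dir, e$path),
                        colClasses = "character")
  if (nrow(df) == 0L) {
    stop(unevaluable_error(sprintf("accession %s has zero samples", accession)))
  }
  study_metadata(study_id = accession, accession = accession,
                 checklist_name = e$checklist_name %||% NA_character_,
                 records = df[, c("sample_id", "attribute", "value")])
}

## ---- live clients (network; never used in the test suite) -----------------

live_user_agent <- function(config) {
  paste0("seqbadge/0.1.0",
         if (!is.null(config$contact)) paste0(" (", config$contact, ")"))
}

fetch_fulltext_live <- function(article_id, config) {
  id <- sub("^PMC", "", article_id)
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=pmc&rettype=xml&id=", id)
  xml <- tryCatch(xml2::read_xml(url), error = function(e) NULL)
  if (is.null(xml)) {
    return(article_document(article_id, sections = list(),
                            retrieval_status = "not_found"))
  }
  Sys.sleep(0.4)  # polite default rate limit
  parse_jats(xml, article_id)
}

resolve_accession_live <- function(accession, config) {
  url <- paste0("https://www.ebi.ac.uk/ena/portal/api/filereport?accession=",
                accession, "&result=read_run&fields=run_accession,fastq_ftp",
                "&format=tsv")
  tab <- tryCatch(utils::read.delim(url, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  Sys.sleep(0.4)
  if (is.null(tab) || nrow(tab) == 0L) {
    return(resolution_record(accession, registry = guess_registry(accession),
                             public = FALSE, resolved = FALSE,
                             resolved_at = format(Sys.time())))
  }
  has_fastq <- any(nzchar(tab$fastq_ftp %||% character(0)))
  resolution_record(accession, registry = guess_registry(accession),
                    public = TRUE, n_runs = nrow(tab),
                    file_formats = if (has_fastq) "FASTQ" else "other",
                    resolved = TRUE, resolved_at = format(Sys.time()))
}

fetch_sample_metadata_live <- function(accession, config) {
  url <- paste0("https://www.ebi.ac.uk/ena/portal/api/filereport?accession=",
                accession, "&result=read_run&fields=sample_accession",
                "&format=tsv")
  tab <- tryCatch(utils::read.delim(url, stringsAsFactors = FALSE),
                  error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L) {
    stop(structure(
      class = c("seqbadge_resolution_failure", "error", "condition"),
      list(message = sprintf("could not resolve %s for metadata", accession),
           call = NULL)))
  }
  ## one attribute row per sample accession; full attribute tables require
  ## the per-sample XML endpoint, kept out of scope for the live client
  recs <- data.frame(sample_id = tab$sample_accession,
                     attribute = "sample accession",
                     value = tab$sample_accession, stringsAsFactors = FALSE)
  study_metadata(study_id = accession, accession = accession, records = recs)
}
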