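## Evidence extraction from article plain text: accession numbers, primer
## sequences, sequencing method, code links, and the DAS class. All offsets
## reported in hit tables are 0-based, half-open [start, end).

accession_hits <- function() {
  data.frame(token = character(0), registry = character(0),
             record_type = character(0), start = integer(0), end = integer(0),
             range = logical(0), stringsAsFactors = FALSE)
}

primer_hits <- function() {
  data.frame(sequence = character(0), label = character(0),
             start = integer(0), end = integer(0), stringsAsFactors = FALSE)
}

#' Detect catalogued accession numbers in text
#'
#' Scans plain text against the packaged accession pattern catalogue (INSDC
#' BioProject/study/sample/experiment/run prefixes plus CNCB-NGDC, MG-RAST,
#' EGA and CNGB). Matches are word-boundary anchored, carry minimum digit
#' counts (5 for runs, 4 elsewhere) to avoid gene-symbol collisions such as
#' "SRP54", and are deduplicated on token, keeping first occurrence order.
#' Two catalogued tokens joined by a dash or "to" are flagged as the
#' endpoints of an accession range (no expansion is attempted).
#'
#' @param text a single plain-text string (markup already stripped).
#' @param config pattern catalogue, see [pattern_config()].
#' @return data frame with columns `token`, `registry`, `record_type`,
#'   `start`, `end` (0-based, half-open) and `range`.
#' @export
#' @examples
#' detect_accessions("Reads are in the SRA under BioProject PRJNA765432.")
detect_accessions <- function(text, config = pattern_config()) {
  assert_scalar_text(text)
  if (is.na(text) || !nzchar(text)) return(accession_hits())
  cat <- config$accession_catalogue
  pieces <- vector("list", nrow(cat))
  for (i in seq_len(nrow(cat))) {
    m <- gregexpr(paste0("\\b", cat$pattern[i], "\\b"), text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    pieces[[i]] <- data.frame(
      token = substring(text, m, m + len - 1L),
      registry = cat$registry[i], record_type = cat$record_type[i],
      start = as.integer(m) - 1L, end = as.integer(m) - 1L + len,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, pieces)
  if (is.null(hits) || nrow(hits) == 0L) return(accession_hits())
  ## first occurrence order; prefer the longer match at equal start, then keep
  ## non-overlapping spans (e.g. SAMEA1234567 over its SAME... sub-pattern)
  hits <- hits[order(hits$start, -hits$end), , drop = FALSE]
  keep <- logical(nrow(hits))
  last_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- hits$end[i]
    }
  }
  hits <- hits[keep, , drop = FALSE]
  n <- nrow(hits)
  rng <- logical(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      gap <- substring(text, hits$end[i] + 1L, hits$start[i + 1L])
      if (grepl("^\\s*(–|—|-|to)\\s*$", gap)) {
        rng[i] <- TRUE
        rng[i + 1L] <- TRUE
      }
    }
  }
  hits$range <- rng
  hits <- hits[!duplicated(hits$token), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Detect PCR primer sequences in text
#'
#' Candidate strings are maximal runs of IUPAC nucleotide characters
#' (ACGTU plus the degenerate codes RYSWKMBDHVN, any case) of at least the
#' configured minimum length (default 12). A candidate is kept only when a
#' primer-context keyword (primer/forward/reverse, a marker-gene token such
#' as 16S or ITS, a variable-region token V1-V9, or a 515F-style label)
#' occurs within the configured window (default 200 characters) around it.
#' Sequences are reported upper-cased and deduplicated; a 515F-style label
#' immediately preceding the sequence is attached when present.
#'
#' @inheritParams detect_accessions
#' @return data frame with columns `sequence`, `label`, `start`, `end`
#'   (0-based, half-open).
#' @export
#' @examples
#' detect_primers("amplified with primers 515F (GTGYCAGCMGCCGCGGTAA)")
detect_primers <- function(text, config = pattern_config()) {
  assert_scalar_text(text)
  if (is.na(text) || !nzchar(text)) return(primer_hits())
  pc <- config$primer
  iupac <- "ACGTURYSWKMBDHVN"
  pat <- sprintf("\\b[%s%s]{%d,}\\b", iupac, tolower(iupac),
                 as.integer(pc$min_length))
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(primer_hits())
  len <- attr(m, "match.length")
  nmax <- nchar(text)
  rows <- list()
  for (i in seq_along(m)) {
    s <- as.integer(m[i])
    e <- s + len[i] - 1L
    ctx <- substring(text, max(1L, s - pc$window), min(nmax, e + pc$window))
    if (!any_pattern(pc$keywords, ctx)) next
    before <- substring(text, max(1L, s - 40L), s - 1L)
    lab <- regmatches(before,
                      gregexpr("\\b[A-Za-z]*[0-9]{1,4}[FRfr]\\b", before))[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = toupper(substring(text, s, e)),
      label = if (length(lab)) lab[length(lab)] else NA_character_,
      start = s - 1L, end = e, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(primer_hits())
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the sequencing method described in text
#'
#' Returns `"marker_gene"` when only amplicon-lexicon terms (16S, 18S, ITS,
#' rRNA gene, amplicon, metabarcoding, marker-gene) match, `"metagenome"`
#' when only shotgun-lexicon terms (shotgun, metagenomic sequencing,
#' metagenome, WGS) match, `"both"` when both do, and `"unknown"` otherwise.
#'
#' @inheritParams detect_accessions
#' @return one of `"marker_gene"`, `"metagenome"`, `"both"`, `"unknown"`.
#' @export
classify_sequencing_method <- function(text, config = pattern_config()) {
  assert_scalar_text(text)
  if (is.na(text) || !nzchar(text)) return("unknown")
  lx <- config$method_lexicon
  marker <- any_pattern(lx$marker_gene, text)
  meta <- any_pattern(lx$metagenome, text)
  if (marker && meta) "both"
  else if (marker) "marker_gene"
  else if (meta) "metagenome"
  else "unknown"
}

#' Detect code-availability links in text
#'
#' URLs whose host is in the code-hosting catalogue (github.com, gitlab.com,
#' bitbucket.org, zenodo.org, osf.io, codeocean.com) are always reported;
#' other URLs are reported only when a code keyword (code, script, software,
#' pipeline, ...) occurs within the configured window. Trailing sentence
#' punctuation is stripped and links are deduplicated in first-occurrence
#' order.
#'
#' @inheritParams detect_accessions
#' @return character vector of URLs.
#' @export
detect_code_links <- function(text, config = pattern_config()) {
  assert_scalar_text(text)
  if (is.na(text) || !nzchar(text)) return(character(0))
  m <- gregexpr("https?://[^\\s<>\"')\\]]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  len <- attr(m, "match.length")
  urls <- substring(text, m, m + len - 1L)
  urls <- sub("[.,;:!?]+$", "", urls)
  hosts <- tolower(sub("^https?://(www\\.)?([^/:]+).*$", "\\2", urls))
  nmax <- nchar(text)
  keep <- logical(length(urls))
  for (i in seq_along(urls)) {
    if (hosts[i] %in% config$code_hosts) {
      keep[i] <- TRUE
    } else {
      s <- as.integer(m[i])
      e <- s + len[i] - 1L
      ctx <- substring(text, max(1L, s - config$code_window),
                       min(nmax, e + config$code_window))
      keep[i] <- any_pattern(config$code_keywords, ctx)
    }
  }
  unique(urls[keep])
}

#' Classify a data-availability statement
#'
#' Scans `das_text` (or, when absent, `fallback_text`) against the packaged
#' trigger-phrase table and returns the first matching class in the fixed
#' precedence order `public_deposit` > `restricted_with_procedure` >
#' `upon_request` > `in_paper_only`; `"absent"` when nothing matches.
#'
#' @param das_text the dedicated data-availability statement, or `NULL`.
#' @param fallback_text full article text scanned when no DAS section exists.
#' @param config pattern catalogue, see [pattern_config()].
#' @return one of `"public_deposit"`, `"restricted_with_procedure"`,
#'   `"upon_request"`, `"in_paper_only"`, `"absent"`.
#' @export
#' @examples
#' classify_das("Data are available upon reasonable request.")
classify_das <- function(das_text, fallback_text = "",
                         config = pattern_config()) {
  target <- if (!is.null(das_text) && length(das_text) == 1L &&
                !is.na(das_text) && nzchar(das_text)) das_text else fallback_text
  if (is.null(target) || is.na(target) || !nzchar(target)) return("absent")
  for (cls in c("public_deposit", "restricted_with_procedure",
                "upon_request", "in_paper_only")) {
    if (any_pattern(config$das_phrases[[cls]], target)) return(cls)
  }
  "absent"
}

#' Run every evidence detector over an article document
#'
#' Composes [detect_accessions()], [detect_primers()],
#' [classify_sequencing_method()], [detect_code_links()] and [classify_das()]
#' over the concatenated section bodies plus the DAS text, and records every
#' database mentioned either through an accession hit or by name.
#'
#' @param document an [article_document()] with `retrieval_status == "ok"`.
#' @param config pattern catalogue, see [pattern_config()].
#' @return an object of class `extraction_result`: a list with `article_id`,
#'   `accessions`, `primers`, `code_links`, `sequencing_method`, `das_class`
#'   and `databases_mentioned`.
#' @export
extract_all <- function(document, config = pattern_config()) {
  stopifnot(inherits(document, "article_document"))
  if (document$retrieval_status != "ok") stop(not_determinable_error(document))
  text <- article_text(document)
  acc <- detect_accessions(text, config)
  mentions <- names(config$database_mentions)[vapply(
    config$database_mentions, function(p) grepl(p, text, perl = TRUE),
    logical(1))]
  structure(list(
    article_id = document$article_id,
    accessions = acc,
    primers = detect_primers(text, config),
    code_links = detect_code_links(text, config),
    sequencing_method = classify_sequencing_method(text, config),
    das_class = classify_das(document$das_text, text, config),
    databases_mentioned = sort(unique(c(acc$registry, mentions)))
  ), class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result> ", x$article_id, "\n", sep = "")
  cat("  accessions: ", join_or_token(x$accessions$token), "\n", sep = "")
  cat("  primers:    ", join_or_token(x$primers$sequence), "\n", sep = "")
  cat("  method:     ", x$sequencing_method, "\n", sep = "")
  cat("  DAS class:  ", x$das_class, "\n", sep = "")
  cat("  code links: ", join_or_token(x$code_links), "\n", sep = "")
  invisible(x)
}
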