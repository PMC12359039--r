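## Sequence-data availability badge rules. Requirements per tier (cumulative):
##   Bronze: data downloadable & not paywalled; accession numbers provided;
##           raw sequences given as BCL or FASTQ.
##   Silver: + sequencing method provided; PCR primer sequences (amplicon
##           studies only; not applicable for pure metagenome work).
##   Gold:   + access clarity (public data, or a stated access procedure);
##           repository open (no login / institutional affiliation);
##           code provided.

.criteria <- c("data_downloadable_not_paywalled", "accession_numbers_provided",
               "raw_sequences_bcl_or_fastq", "sequencing_method_provided",
               "pcr_primer_sequences", "das_clarifies_access_requirements",
               "database_publicly_accessible", "code_provided")

.tier_criteria <- list(bronze = .criteria[1:3], silver = .criteria[4:5],
                       gold = .criteria[6:8])

#' Construct an evidence bundle
#'
#' The boolean evidence consumed by the badge rules. Unknown evidence is
#' represented as `FALSE` (never `NA`); `data_public_downloadable = TRUE`
#' requires `has_accession = TRUE`.
#'
#' @param determinable full text was retrieved and parseable.
#' @param has_accession any catalogued accession detected.
#' @param data_public_downloadable an accession resolves in a repository and
#'   data are retrievable without payment.
#' @param raw_format_ok resolved runs expose BCL or FASTQ files.
#' @param sequencing_method_known sequencing method stated or recoverable.
#' @param is_amplicon the study is marker-gene (amplicon) based.
#' @param primers_found primer sequences detected.
#' @param das_clarifies_access for non-public data, a stated access procedure
#'   exists.
#' @param repository_open_access every cited registry is retrievable with no
#'   login or institutional affiliation.
#' @param code_available code links detected.
#' @return an object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(determinable = TRUE, has_accession = FALSE,
                            data_public_downloadable = FALSE,
                            raw_format_ok = FALSE,
                            sequencing_method_known = FALSE,
                            is_amplicon = FALSE, primers_found = FALSE,
                            das_clarifies_access = FALSE,
                            repository_open_access = FALSE,
                            code_available = FALSE) {
  fields <- list(determinable = determinable, has_accession = has_accession,
                 data_public_downloadable = data_public_downloadable,
                 raw_format_ok = raw_format_ok,
                 sequencing_method_known = sequencing_method_known,
                 is_amplicon = is_amplicon, primers_found = primers_found,
                 das_clarifies_access = das_clarifies_access,
                 repository_open_access = repository_open_access,
                 code_available = code_available)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (!is.logical(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("`%s` must be TRUE or FALSE", nm), call. = FALSE)
    }
  }
  if (fields$data_public_downloadable && !fields$has_accession) {
    stop("`data_public_downloadable` implies `has_accession`", call. = FALSE)
  }
  structure(fields, class = "evidence_bundle")
}

badge_report <- function(badge, criteria, missing) {
  structure(list(badge = badge, criteria = criteria, missing = missing),
            class = "badge_report")
}

#' Assign the sequence-data availability badge
#'
#' Applies the tiered requirement table to an evidence bundle. The badge is
#' the highest tier whose requirements (and those of every lower tier) are
#' all satisfied or not applicable. The primer requirement is marked
#' `not_applicable` for pure metagenome studies, and Gold's access-clarity
#' requirement is `not_applicable` when the data are already public. A
#' non-determinable bundle (full text unavailable or unparseable) yields
#' `cannot_be_determined` regardless of the other fields.
#'
#' @param evidence an [evidence_bundle()].
#' @return an object of class `badge_report`: `badge` (one of none, bronze,
#'   silver, gold, cannot_be_determined), `criteria` (named status vector
#'   with values satisfied / unsatisfied / not_applicable) and `missing`
#'   (criteria blocking the next tier; empty iff gold).
#' @export
#' @examples
#' ev <- evidence_bundle(has_accession = TRUE, data_public_downloadable = TRUE,
#'                       raw_format_ok = TRUE)
#' assign_sequence_badge(ev)$badge
assign_sequence_badge <- function(evidence) {
  stopifnot(inherits(evidence, "evidence_bundle"))
  if (!evidence$determinable) {
    status <- stats::setNames(rep("not_applicable", length(.criteria)),
                              .criteria)
    return(badge_report("cannot_be_determined", status, "article_full_text"))
  }
  sat <- function(x) if (x) "satisfied" else "unsatisfied"
  status <- c(
    data_downloadable_not_paywalled = sat(evidence$data_public_downloadable),
    accession_numbers_provided = sat(evidence$has_accession),
    raw_sequences_bcl_or_fastq = sat(evidence$raw_format_ok),
    sequencing_method_provided = sat(evidence$sequencing_method_known),
    pcr_primer_sequences = if (!evidence$is_amplicon) "not_applicable"
                           else sat(evidence$primers_found),
    das_clarifies_access_requirements =
      if (evidence$data_public_downloadable) "not_applicable"
      else sat(evidence$das_clarifies_access),
    database_publicly_accessible = sat(evidence$repository_open_access),
    code_provided = sat(evidence$code_available))
  ok <- vapply(.tier_criteria, function(f) all(status[f] != "unsatisfied"),
               logical(1))
  badge <- if (!ok[["bronze"]]) "none"
           else if (!ok[["silver"]]) "bronze"
           else if (!ok[["gold"]]) "silver"
           else "gold"
  nxt <- switch(badge, none = "bronze", bronze = "silver", silver = "gold",
                gold = NULL)
  missing <- if (is.null(nxt)) character(0) else {
    f <- .tier_criteria[[nxt]]
    f[status[f] == "unsatisfied"]
  }
  badge_report(badge, status, missing)
}

#' @export
print.badge_report <- function(x, ...) {
  cat("<badge_report> badge:", x$badge, "\n")
  for (nm in names(x$criteria)) {
    mark <- switch(x$criteria[[nm]], satisfied = "[x]",
                   unsatisfied = "[ ]", not_applicable = "[-]")
    cat(" ", mark, nm, "\n")
  }
  if (length(x$missing)) {
    cat("  blocking next tier:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Collapse badges to the binary None-versus-Badged view
#'
#' Bronze, silver and gold map to `"badged"`; none maps to `"not_badged"`.
#' `cannot_be_determined` also maps to `"not_badged"` in this view (it is
#' excluded from accuracy computations by default elsewhere).
#'
#' @param badge character vector of badge values.
#' @return character vector over `{"badged", "not_badged"}`.
#' @export
collapse_binary <- function(badge) {
  bad <- setdiff(unique(badge), .badges_all)
  if (length(bad)) {
    stop("unknown badge value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ifelse(badge %in% c("bronze", "silver", "gold"), "badged", "not_badged")
}

#' Derive an evidence bundle from extraction and resolution results
#'
#' Maps an [extract_all()] result plus per-accession resolution records to
#' the booleans the badge rules consume: public downloadability and raw
#' format come from resolved repository records (never from article prose),
#' amplicon status from the sequencing-method class, access clarity from the
#' DAS class, and repository openness from the open-registry list.
#'
#' @param extraction an `extraction_result`.
#' @param resolutions list of [resolution_record()]s for
#'   `extraction$accessions` (may be empty in offline mode with no manifest).
#' @param config pattern catalogue, see [pattern_config()].
#' @return an [evidence_bundle()].
#' @export
evidence_from_extraction <- function(extraction, resolutions = list(),
                                     config = pattern_config()) {
  stopifnot(inherits(extraction, "extraction_result"))
  if (inherits(resolutions, "resolution_record")) resolutions <- list(resolutions)
  has_acc <- nrow(extraction$accessions) > 0L
  public_with_files <- vapply(resolutions, function(r) {
    isTRUE(r$public) && length(r$file_formats) > 0L
  }, logical(1))
  raw_ok <- vapply(resolutions, function(r) {
    isTRUE(r$public) && any(r$file_formats %in% c("FASTQ", "BCL"))
  }, logical(1))
  method <- extraction$sequencing_method
  evidence_bundle(
    determinable = TRUE,
    has_accession = has_acc,
    data_public_downloadable = has_acc && any(public_with_files),
    raw_format_ok = any(raw_ok),
    sequencing_method_known = method != "unknown",
    is_amplicon = method %in% c("marker_gene", "both"),
    primers_found = nrow(extraction$primers) > 0L,
    das_clarifies_access = extraction$das_class == "restricted_with_procedure",
    repository_open_access =
      all(extraction$accessions$registry %in% config$open_registries),
    code_available = length(extraction$code_links) > 0L)
}
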