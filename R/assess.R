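## Batch assessment surface: one CSV row per article (sequence badge) or one
## long-format row per sample attribute (metadata), with per-item fault
## tolerance — a failed item becomes data (cannot_be_determined / an error
## status), never an aborted batch.

assess_row <- function(article_id, badge = "cannot_be_determined",
                       database = .not_detected, accessions = .not_detected,
                       n_runs = 0L, primers = .not_detected,
                       code_links = .not_detected, das_class = "absent",
                       missing_criteria = .not_detected,
                       retrieval_status = "not_found") {
  data.frame(article_id = article_id, badge = badge, database = database,
             accessions = accessions, n_runs = as.integer(n_runs),
             primers = primers, code_links = code_links,
             das_class = das_class, missing_criteria = missing_criteria,
             retrieval_status = retrieval_status, stringsAsFactors = FALSE)
}

#' Assess a single article end to end
#'
#' Fetch, extract, resolve, badge: retrieves the full text, runs every
#' evidence detector, resolves each detected accession against the
#' repository layer, derives the evidence bundle and assigns the badge.
#'
#' @param article_id article identifier.
#' @param config a [run_config()].
#' @return a one-row data frame (see [assess_sequences()] for the columns).
#' @export
assess_article <- function(article_id, config) {
  doc <- fetch_fulltext(article_id, config)
  if (doc$retrieval_status != "ok") {
    return(assess_row(article_id, retrieval_status = doc$retrieval_status))
  }
  ex <- extract_all(doc)
  res <- lapply(ex$accessions$token, resolve_accession, config = config)
  ev <- evidence_from_extraction(ex, res)
  report <- assign_sequence_badge(ev)
  primer_txt <- if (nrow(ex$primers) == 0L) .not_detected else {
    paste(ifelse(is.na(ex$primers$label), ex$primers$sequence,
                 paste0(ex$primers$label, ":", ex$primers$sequence)),
          collapse = ";")
  }
  assess_row(
    article_id = article_id,
    badge = report$badge,
    database = join_or_token(sort(unique(ex$accessions$registry))),
    accessions = join_or_token(ex$accessions$token),
    n_runs = sum(vapply(res, function(r) r$n_runs, integer(1))),
    primers = primer_txt,
    code_links = join_or_token(ex$code_links),
    das_class = ex$das_class,
    missing_criteria = join_or_token(report$missing),
    retrieval_status = doc$retrieval_status)
}

#' Assess sequence-data availability for a batch of articles
#'
#' One row per article with the badge, the detected evidence components
#' (database, accessions, run count, primers, code links, DAS class) and the
#' criteria blocking the next tier; components that were not detected are
#' emitted as the explicit token `"not_detected"`. Per-article failures are
#' reported as `cannot_be_determined` rows and never abort the batch.
#'
#' @param ids character vector of article identifiers; ignored when
#'   `ids_file` is given.
#' @param config a [run_config()].
#' @param ids_file optional path to a whitespace-separated file of ids.
#' @param quiet suppress per-article progress messages (sent to stderr).
#' @return data frame with columns `article_id`, `badge`, `database`,
#'   `accessions`, `n_runs`, `primers`, `code_links`, `das_class`,
#'   `missing_criteria`, `retrieval_status`.
#' @export
assess_sequences <- function(ids = NULL, config, ids_file = NULL,
                             quiet = TRUE) {
  if (!is.null(ids_file)) {
    if (!file.exists(ids_file)) stop("cannot read ids file: ", ids_file,
                                     call. = FALSE)
    ids <- scan(ids_file, what = character(), quiet = TRUE)
  }
  if (is.null(ids) || length(ids) == 0L) {
    stop("no article ids supplied", call. = FALSE)
  }
  rows <- lapply(seq_along(ids), function(i) {
    if (!quiet) message(sprintf("[%d/%d] %s", i, length(ids), ids[i]))
    tryCatch(assess_article(ids[i], config),
             error = function(e) assess_row(ids[i],
                                            retrieval_status = "parse_error"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Retrieve and optionally tier-assess sample metadata for accessions
#'
#' Returns the full long-format metadata table (study, sample, attribute,
#' value) per accession plus the reported checklist name; with
#' `assess_tiers = TRUE`, also evaluates each study against the tiered
#' checklist (after harmonization). Per-accession resolution failures are
#' reported as error rows and the batch continues.
#'
#' @param accessions character vector of repository accessions.
#' @param config a [run_config()].
#' @param assess_tiers also compute the per-study tier assessment.
#' @param checklist checklist for tier assessment.
#' @param threshold completeness threshold for tier assessment.
#' @return with `assess_tiers = FALSE`, the long metadata data frame
#'   (`study_id`, `sample_id`, `attribute`, `value`, `checklist_name`,
#'   `status`); otherwise a list with elements `metadata` and `assessments`.
#' @export
assess_metadata <- function(accessions, config, assess_tiers = FALSE,
                            checklist = metadata_checklist(), threshold = 1) {
  if (length(accessions) == 0L) stop("no accessions supplied", call. = FALSE)
  meta_rows <- list()
  tier_rows <- list()
  for (acc in accessions) {
    study <- tryCatch(fetch_sample_metadata(acc, config),
                      error = function(e) e)
    if (inherits(study, "error")) {
      meta_rows[[acc]] <- data.frame(
        study_id = acc, sample_id = NA_character_, attribute = NA_character_,
        value = NA_character_, checklist_name = NA_character_,
        status = paste0("error: ", conditionMessage(study)),
        stringsAsFactors = FALSE)
      next
    }
    r <- study$records
    meta_rows[[acc]] <- data.frame(
      study_id = study$study_id, sample_id = r$sample_id,
      attribute = r$attribute, value = r$value,
      checklist_name = study$checklist_name, status = "ok",
      stringsAsFactors = FALSE)
    if (assess_tiers) {
      h <- harmonize_attributes(study)
      a <- evaluate_metadata_tier(h, checklist, threshold)
      tier_rows[[acc]] <- data.frame(
        study_id = a$study_id, tier_awarded = a$tier_awarded,
        blocking_fields = join_or_token(a$blocking_fields),
        stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, meta_rows)
  rownames(metadata) <- NULL
  if (!assess_tiers) return(metadata)
  assessments <- do.call(rbind, tier_rows)
  rownames(assessments) <- NULL
  list(metadata = metadata, assessments = assessments)
}

#' Evaluate a labelled-prediction file
#'
#' Reads a labels CSV (see [read_labeled_predictions()]) and computes both
#' the four-category and the binary None-versus-Badged evaluation reports.
#'
#' @param labels_path path to the labels CSV.
#' @param include_undetermined include cannot-be-determined items.
#' @return list with `four_class` and `binary` `badge_eval` objects.
#' @export
evaluate_predictions_file <- function(labels_path,
                                      include_undetermined = FALSE) {
  df <- read_labeled_predictions(labels_path)
  if (nrow(df) == 0L) stop("labels file is empty", call. = FALSE)
  list(
    four_class = evaluate(df$true_badge, df$predicted_badge,
                          exclude_undetermined = !include_undetermined),
    binary = evaluate_binary(df$true_badge, df$predicted_badge,
                             include_undetermined = include_undetermined))
}
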