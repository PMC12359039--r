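## Metadata tier evaluation, attribute harmonization, and cross-study
## attribute-population analytics. Sample records are held in long format
## (sample_id, attribute, value), one data frame per study.

#' Construct a study metadata object
#'
#' @param study_id study identifier.
#' @param accession repository accession, or `NA`.
#' @param checklist_name GSC checklist / environmental package name as
#'   reported to the repository, or `NA`.
#' @param records long-format data frame with columns `sample_id`,
#'   `attribute`, `value` (all character).
#' @return an object of class `study_metadata`.
#' @export
study_metadata <- function(study_id, accession = NA_character_,
                           checklist_name = NA_character_,
                           records = data.frame(sample_id = character(0),
                                                attribute = character(0),
                                                value = character(0))) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "attribute", "value") %in% names(records)))
  records$sample_id <- as.character(records$sample_id)
  records$attribute <- as.character(records$attribute)
  records$value <- as.character(records$value)
  if (nrow(records) > 0L && any(!nzchar(trimws(records$attribute)))) {
    stop("attribute names must be non-empty after trimming", call. = FALSE)
  }
  structure(list(study_id = study_id, accession = accession,
                 checklist_name = checklist_name, records = records),
            class = "study_metadata")
}

#' @export
print.study_metadata <- function(x, ...) {
  cat("<study_metadata> ", x$study_id,
      " (", length(unique(x$records$sample_id)), " samples, ",
      length(unique(x$records$attribute)), " attributes)\n", sep = "")
  if (!is.na(x$checklist_name)) cat("  checklist:", x$checklist_name, "\n")
  invisible(x)
}

unevaluable_error <- function(what) {
  structure(class = c("seqbadge_unevaluable", "error", "condition"),
            list(message = what, call = NULL))
}

#' Test values against the missing-value vocabulary
#'
#' A value is missing when, after trimming and case-folding, it is empty or
#' one of the INSDC-style missing tokens (`na`, `n/a`, `nan`, `missing`,
#' `not applicable`, `not collected`, `not provided`, `unknown`, `-`).
#'
#' @param value character vector.
#' @param config pattern catalogue supplying `missing_tokens`.
#' @return logical vector.
#' @export
#' @examples
#' is_missing(c("not collected", "Homo sapiens gut metagenome", "   "))
is_missing <- function(value, config = pattern_config()) {
  v <- tolower(trimws(as.character(value)))
  is.na(value) | v %in% config$missing_tokens
}

#' Harmonize attribute names against a synonym map
#'
#' Renames raw attribute names to their canonical form (matching is case-
#' and separator-insensitive, see [normalize_attr_name()]); unmapped names
#' pass through verbatim. When two raw names collapse to one canonical
#' within a sample, the first non-missing value wins and the collision count
#' is recorded in the `"collisions"` attribute. Harmonization is idempotent.
#'
#' @param records long-format records data frame (`sample_id`, `attribute`,
#'   `value`) or a [study_metadata()] object.
#' @param synonym_map named character vector, see [default_synonym_map()].
#' @param config pattern catalogue (for the missing-value vocabulary).
#' @return same shape as the input, with harmonized attribute names.
#' @export
#' @examples
#' r <- data.frame(sample_id = "S1", attribute = "User_sample_ID", value = "a")
#' harmonize_attributes(r)$attribute
harmonize_attributes <- function(records, synonym_map = default_synonym_map(),
                                 config = pattern_config()) {
  if (inherits(records, "study_metadata")) {
    records$records <- harmonize_attributes(records$records, synonym_map, config)
    return(records)
  }
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    attr(records, "collisions") <- 0L
    return(records)
  }
  canon <- unname(synonym_map[normalize_attr_name(records$attribute)])
  records$attribute <- ifelse(is.na(canon), records$attribute, canon)
  key <- paste(records$sample_id, records$attribute, sep = "\r")
  collisions <- 0L
  if (anyDuplicated(key)) {
    collisions <- sum(duplicated(key))
    ## stable sort: non-missing values first, original order preserved
    idx <- seq_len(nrow(records))
    ord <- order(is_missing(records$value, config), idx)
    keep_idx <- idx[ord][!duplicated(key[ord])]
    records <- records[sort(keep_idx), , drop = FALSE]
    rownames(records) <- NULL
  }
  attr(records, "collisions") <- collisions
  records
}

#' Evaluate a study against a tiered metadata checklist
#'
#' A checklist field counts as satisfied when the fraction of samples with a
#' non-missing value for it reaches `threshold` (default 1: every sample).
#' The awarded tier is the highest cumulative tier with all fields
#' satisfied; `blocking_fields` lists the unsatisfied fields of the next
#' tier, in checklist order. Attributes are expected to be harmonized first
#' (see [harmonize_attributes()]).
#'
#' @param study a [study_metadata()] with non-empty records.
#' @param checklist a checklist from [metadata_checklist()].
#' @param threshold completeness fraction required per field, in (0, 1].
#' @param config pattern catalogue (for the missing-value vocabulary).
#' @return an object of class `metadata_assessment`: `study_id`,
#'   `tier_awarded` (none/bronze/silver/gold), `field_completeness` (named
#'   fractions over all checklist fields) and `blocking_fields`.
#' @export
evaluate_metadata_tier <- function(study, checklist = metadata_checklist(),
                                   threshold = 1, config = pattern_config()) {
  stopifnot(inherits(study, "study_metadata"),
            is.numeric(threshold), threshold > 0, threshold <= 1)
  recs <- study$records
  if (nrow(recs) == 0L) {
    stop(unevaluable_error(sprintf("study %s has no sample records",
                                   study$study_id)))
  }
  samples <- unique(recs$sample_id)
  n <- length(samples)
  present <- recs[!is_missing(recs$value, config), , drop = FALSE]
  fields <- checklist$cumulative$gold
  completeness <- vapply(fields, function(f) {
    length(unique(present$sample_id[present$attribute == f])) / n
  }, numeric(1))
  ok <- vapply(c("bronze", "silver", "gold"), function(t) {
    all(completeness[checklist$cumulative[[t]]] >= threshold)
  }, logical(1))
  tier <- if (!ok[["bronze"]]) "none"
          else if (!ok[["silver"]]) "bronze"
          else if (!ok[["gold"]]) "silver"
          else "gold"
  nxt <- switch(tier, none = "bronze", bronze = "silver", silver = "gold",
                gold = NULL)
  blocking <- if (is.null(nxt)) character(0) else {
    f <- checklist$cumulative[[nxt]]
    f[completeness[f] < threshold]
  }
  structure(list(study_id = study$study_id, tier_awarded = tier,
                 field_completeness = completeness,
                 blocking_fields = blocking),
            class = "metadata_assessment")
}

#' @export
print.metadata_assessment <- function(x, ...) {
  cat("<metadata_assessment> ", x$study_id, ": tier ", x$tier_awarded, "\n",
      sep = "")
  if (length(x$blocking_fields)) {
    cat("  blocking:", paste(x$blocking_fields, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cross-study attribute-population matrix
#'
#' An attribute is populated for a study when at least one sample carries a
#' non-missing value for it. The matrix covers the union of attribute names
#' across studies (rows sorted alphabetically for determinism); per-attribute
#' proportions are row means, i.e. the fraction of studies populating the
#' attribute.
#'
#' @param studies non-empty list of [study_metadata()] objects.
#' @param harmonize harmonize attribute names first (caller's choice).
#' @param synonym_map used when `harmonize = TRUE`.
#' @param config pattern catalogue (for the missing-value vocabulary).
#' @return an object of class `population_matrix`: `matrix` (logical,
#'   attribute x study) and `proportion` (named numeric).
#' @export
population_matrix <- function(studies, harmonize = FALSE,
                              synonym_map = default_synonym_map(),
                              config = pattern_config()) {
  if (length(studies) == 0L) stop(unevaluable_error("no studies supplied"))
  stopifnot(all(vapply(studies, inherits, logical(1), "study_metadata")))
  if (harmonize) {
    studies <- lapply(studies, harmonize_attributes, synonym_map = synonym_map,
                      config = config)
  }
  study_ids <- vapply(studies, `[[`, character(1), "study_id")
  attrs <- sort(unique(unlist(lapply(studies,
                                     function(s) unique(s$records$attribute)))))
  M <- matrix(FALSE, nrow = length(attrs), ncol = length(studies),
              dimnames = list(attrs, study_ids))
  for (j in seq_along(studies)) {
    r <- studies[[j]]$records
    pop <- unique(r$attribute[!is_missing(r$value, config)])
    M[pop, j] <- TRUE
  }
  structure(list(matrix = M, proportion = rowMeans(M)),
            class = "population_matrix")
}

#' @export
print.population_matrix <- function(x, ...) {
  cat("<population_matrix> ", nrow(x$matrix), " attributes x ",
      ncol(x$matrix), " studies\n", sep = "")
  cat("  median attribute population: ",
      format(stats::median(x$proportion), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Histogram of attribute-population proportions
#'
#' Bins the per-attribute population proportions into `bin_edges`; bins are
#' left-open/right-closed except the first, which includes 0. Counts sum to
#' the number of attributes.
#'
#' @param matrix a [population_matrix()].
#' @param bin_edges strictly increasing numeric vector starting at 0 and
#'   ending at 1.
#' @return named integer vector of bin counts.
#' @export
sparsity_histogram <- function(matrix, bin_edges = c(0, 0.1, 0.25, 0.5, 0.75, 1)) {
  stopifnot(inherits(matrix, "population_matrix"))
  if (!is.numeric(bin_edges) || length(bin_edges) < 2L ||
      any(diff(bin_edges) <= 0) || bin_edges[1] != 0 ||
      bin_edges[length(bin_edges)] != 1) {
    stop("`bin_edges` must be strictly increasing and span [0, 1]",
         call. = FALSE)
  }
  bins <- cut(matrix$proportion, breaks = bin_edges, include.lowest = TRUE,
              right = TRUE)
  counts <- table(bins)
  stats::setNames(as.integer(counts), names(counts))
}

#' Median attribute-population proportion
#'
#' The median of per-attribute population proportions across studies (mean
#' of the middle two for even attribute counts).
#'
#' @param matrix a [population_matrix()].
#' @return a fraction in \[0, 1\].
#' @export
median_population <- function(matrix) {
  stopifnot(inherits(matrix, "population_matrix"))
  if (length(matrix$proportion) == 0L) {
    stop(unevaluable_error("empty population matrix"))
  }
  stats::median(matrix$proportion)
}
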