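# Independent brute-force oracles used to cross-check the badge rules and the
# evaluation metrics. Kept deliberately literal: requirements are transcribed
# predicate by predicate from the tier table, metrics from the TP/FP/FN
# definitions, so these never share code with the implementation under test.

oracle_requirements <- list(
  bronze = list(
    downloadable = function(b) b$data_public_downloadable,
    accession = function(b) b$has_accession,
    raw_format = function(b) b$raw_format_ok),
  silver = list(
    method = function(b) b$sequencing_method_known,
    primers = function(b) !b$is_amplicon || b$primers_found),
  gold = list(
    access_clarity = function(b) b$data_public_downloadable ||
      b$das_clarifies_access,
    open_database = function(b) b$repository_open_access,
    code = function(b) b$code_available))

oracle_badge <- function(bundle) {
  if (!bundle$determinable) return("cannot_be_determined")
  badge <- "none"
  for (tier in c("bronze", "silver", "gold")) {
    met <- vapply(oracle_requirements[[tier]], function(f) f(bundle),
                  logical(1))
    if (!all(met)) break
    badge <- tier
  }
  badge
}

bundle_fields <- c("determinable", "has_accession",
                   "data_public_downloadable", "raw_format_ok",
                   "sequencing_method_known", "is_amplicon", "primers_found",
                   "das_clarifies_access", "repository_open_access",
                   "code_available")

# all valid evidence bundles (public downloadability implies an accession)
enumerate_bundles <- function() {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), length(bundle_fields)),
                   KEEP.OUT.ATTRS = FALSE)
  names(g) <- bundle_fields
  g[!(g$data_public_downloadable & !g$has_accession), , drop = FALSE]
}

row_bundle <- function(row) do.call(evidence_bundle, as.list(row))

# ordinal rank with cannot_be_determined below none
badge_rank <- function(b) {
  match(b, c("cannot_be_determined", "none", "bronze", "silver", "gold"))
}

# literal per-class TP/FP/FN metric counter
counter_evaluate <- function(truth, predicted, classes) {
  all_classes <- unique(c(classes, truth, predicted))
  f1s <- sup <- numeric(length(all_classes))
  names(f1s) <- names(sup) <- all_classes
  for (cl in all_classes) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[cl] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    sup[cl] <- tp + fn
  }
  list(accuracy = mean(truth == predicted),
       macro_f1 = mean(f1s[classes]),
       weighted_f1 = sum(sup * f1s) / sum(sup),
       f1 = f1s)
}

# all multisets of size n over m categories, as count matrices (stars & bars)
multiset_counts <- function(n, m) {
  if (m == 1L) return(matrix(n, ncol = 1L))
  pieces <- lapply(0:n, function(k) cbind(k, multiset_counts(n - k, m - 1L)))
  do.call(rbind, pieces)
}

badge_classes <- c("none", "bronze", "silver", "gold")

# study whose every sample populates exactly `fields`
make_tier_study <- function(fields, n_samples = 4L, study_id = "S1") {
  samples <- sprintf("%s_%02d", study_id, seq_len(n_samples))
  records <- expand.grid(sample_id = samples, attribute = fields,
                         stringsAsFactors = FALSE)
  records$value <- paste0(records$attribute, "_v")
  study_metadata(study_id = study_id, records = records)
}
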