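## Prediction-vs-label evaluation: confusion matrix, overall accuracy,
## per-class precision/recall/F1 with support, macro-average F1 (unweighted
## mean over classes present in the truth labels by default) and weighted F1
## (weighted by truth support).

order_classes <- function(x) {
  canonical <- c(.badges_all, "not_badged", "badged")
  c(intersect(canonical, x), sort(setdiff(x, canonical)))
}

#' Evaluate predicted badges against manual labels
#'
#' Computes the class-by-class confusion matrix, overall accuracy (correct
#' predictions over all predictions), per-class precision/recall/F1 with
#' support (F1 is 0 when precision + recall is 0), macro-average F1 over
#' `classes` (defaults to the classes present in the truth labels), and
#' weighted F1 (per-class F1 weighted by truth support). Items labelled or
#' predicted `cannot_be_determined` are excluded by default.
#'
#' @param truth character vector of manual badge labels.
#' @param predicted character vector of predicted badges, same length.
#' @param classes classes to macro-average over; `NULL` for the classes
#'   present in truth (in badge order).
#' @param exclude_undetermined drop items where either side is
#'   `cannot_be_determined`.
#' @return an object of class `badge_eval`: `confusion`, `accuracy`,
#'   `per_class` (data frame), `macro_f1`, `weighted_f1`, `n_items`,
#'   `classes`.
#' @export
#' @examples
#' evaluate(c("none", "bronze", "bronze"), c("none", "bronze", "none"))
evaluate <- function(truth, predicted, classes = NULL,
                     exclude_undetermined = TRUE) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (exclude_undetermined) {
    keep <- truth != "cannot_be_determined" &
      predicted != "cannot_be_determined"
    truth <- truth[keep]
    predicted <- predicted[keep]
  }
  if (length(truth) == 0L) {
    stop("no predictions to evaluate (all items excluded or empty input)",
         call. = FALSE)
  }
  if (is.null(classes)) classes <- order_classes(unique(truth))
  all_classes <- order_classes(unique(c(classes, truth, predicted)))
  tf <- factor(truth, levels = all_classes)
  pf <- factor(predicted, levels = all_classes)
  confusion <- table(truth = tf, predicted = pf)
  tp <- diag(confusion)
  support <- rowSums(confusion)
  predn <- colSums(confusion)
  precision <- ifelse(predn > 0, tp / predn, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = all_classes, precision = unname(precision),
                          recall = unname(recall), f1 = unname(f1),
                          support = as.integer(support),
                          stringsAsFactors = FALSE)
  structure(list(
    confusion = confusion,
    accuracy = sum(tp) / length(truth),
    per_class = per_class,
    macro_f1 = mean(f1[classes]),
    weighted_f1 = sum(support * f1) / sum(support),
    n_items = length(truth),
    classes = classes
  ), class = "badge_eval")
}

#' Evaluate predictions in the binary None-versus-Badged view
#'
#' Collapses both truth and prediction with [collapse_binary()] and
#' evaluates over the two classes. By default, items where either side is
#' `cannot_be_determined` are dropped before collapsing; with
#' `include_undetermined = TRUE` they are kept and collapse to
#' `"not_badged"`.
#'
#' @inheritParams evaluate
#' @param include_undetermined keep cannot-be-determined items (collapsed to
#'   not_badged) instead of dropping them.
#' @return a `badge_eval` object over `{"not_badged", "badged"}`.
#' @export
evaluate_binary <- function(truth, predicted, include_undetermined = FALSE) {
  stopifnot(length(truth) == length(predicted))
  if (!include_undetermined) {
    keep <- truth != "cannot_be_determined" &
      predicted != "cannot_be_determined"
    truth <- truth[keep]
    predicted <- predicted[keep]
  }
  if (length(truth) == 0L) {
    stop("no predictions to evaluate after exclusion", call. = FALSE)
  }
  evaluate(collapse_binary(truth), collapse_binary(predicted),
           exclude_undetermined = FALSE)
}

#' @export
print.badge_eval <- function(x, digits = 4, ...) {
  cat("<badge_eval> n =", x$n_items, "\n")
  cat("  accuracy:    ", format(x$accuracy, digits = digits), "\n")
  cat("  macro F1:    ", format(x$macro_f1, digits = digits), "\n")
  cat("  weighted F1: ", format(x$weighted_f1, digits = digits), "\n")
  cat("  per class:\n")
  print(x$per_class, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Read labelled predictions from CSV
#'
#' Accepts a header of either `true,predicted` or
#' `true_badge,predicted_badge` (an optional `item_id` column is preserved).
#'
#' @param path CSV path.
#' @return data frame with columns `item_id`, `true_badge`,
#'   `predicted_badge`.
#' @export
read_labeled_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (all(c("true", "predicted") %in% names(df))) {
    df$true_badge <- df$true
    df$predicted_badge <- df$predicted
  }
  if (!all(c("true_badge", "predicted_badge") %in% names(df))) {
    stop("labels CSV needs columns true,predicted (or true_badge,predicted_badge)",
         call. = FALSE)
  }
  if (is.null(df$item_id)) df$item_id <- as.character(seq_len(nrow(df)))
  bad <- setdiff(unique(c(df$true_badge, df$predicted_badge)), .badges_all)
  if (length(bad)) {
    stop("unknown badge value(s) in labels CSV: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df[, c("item_id", "true_badge", "predicted_badge")]
}

#' Flatten an evaluation report to CSV-ready data frames
#'
#' @param report a `badge_eval`.
#' @return list with `summary` (one row: accuracy, macro F1, weighted F1, n)
#'   and `per_class` data frames.
#' @export
evaluation_tables <- function(report) {
  stopifnot(inherits(report, "badge_eval"))
  list(summary = data.frame(accuracy = report$accuracy,
                            macro_f1 = report$macro_f1,
                            weighted_f1 = report$weighted_f1,
                            n_items = report$n_items),
       per_class = report$per_class)
}
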