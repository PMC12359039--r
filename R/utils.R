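`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize an attribute name for synonym matching
#'
#' Lower-cases, trims, and collapses every run of non-alphanumeric characters
#' (spaces, underscores, hyphens, parentheses, slashes) to a single space, so
#' that e.g. `"User_sample_ID"` and `"user sample id"` compare equal.
#'
#' @param x character vector of raw attribute names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_attr_name(c("User_sample_ID", "Sample  Name "))
normalize_attr_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

## single-string guard used by the text detectors
assert_scalar_text <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("`text` must be a single character string", call. = FALSE)
  }
}

## vectorized grepl over a list of perl regexes: TRUE if any pattern matches
any_pattern <- function(patterns, text) {
  any(vapply(patterns, function(p) grepl(p, text, perl = TRUE), logical(1)))
}

join_or_token <- function(x, collapse = ";") {
  if (length(x) == 0L || all(is.na(x)) || all(!nzchar(x))) return(.not_detected)
  paste(x[!is.na(x) & nzchar(x)], collapse = collapse)
}
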