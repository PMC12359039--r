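#' Construct an article document
#'
#' The in-memory representation of a retrieved full-text article: labelled
#' sections, the data-availability statement (if a dedicated section exists),
#' and a retrieval status. Sections must be non-empty when the status is
#' `"ok"`.
#'
#' @param article_id identifier string (e.g. a PMC ID).
#' @param title article title, or `NA`.
#' @param publication_year integer year, or `NA`.
#' @param journal,publisher journal / publisher name, or `NA`.
#' @param sections list of `list(label =, body =)` entries, in document order.
#' @param das_text text of the data-availability statement, or `NULL`.
#' @param retrieval_status one of `"ok"`, `"not_found"`, `"no_fulltext"`,
#'   `"parse_error"`.
#' @return an object of class `article_document`.
#' @export
article_document <- function(article_id, title = NA_character_,
                             publication_year = NA_integer_,
                             journal = NA_character_, publisher = NA_character_,
                             sections = list(), das_text = NULL,
                             retrieval_status = c("ok", "not_found",
                                                  "no_fulltext", "parse_error")) {
  retrieval_status <- match.arg(retrieval_status)
  stopifnot(is.character(article_id), length(article_id) == 1L)
  if (retrieval_status == "ok" && length(sections) == 0L) {
    stop("an 'ok' article must have at least one section", call. = FALSE)
  }
  for (s in sections) {
    if (!is.list(s) || !all(c("label", "body") %in% names(s))) {
      stop("each section must be a list with `label` and `body`", call. = FALSE)
    }
  }
  structure(list(article_id = article_id, title = title,
                 publication_year = publication_year, journal = journal,
                 publisher = publisher, sections = sections,
                 das_text = das_text, retrieval_status = retrieval_status),
            class = "article_document")
}

#' @export
print.article_document <- function(x, ...) {
  cat("<article_document> ", x$article_id, " [", x$retrieval_status, "]\n",
      sep = "")
  if (!is.na(x$title)) cat("  title:    ", x$title, "\n", sep = "")
  cat("  sections: ", length(x$sections), "\n", sep = "")
  if (!is.null(x$das_text)) {
    cat("  DAS:      ", substr(x$das_text, 1, 70),
        if (nchar(x$das_text) > 70) "..." else "", "\n", sep = "")
  }
  invisible(x)
}

## concatenated plain text of an article (section bodies + DAS)
article_text <- function(document) {
  bodies <- vapply(document$sections, function(s) s$body %||% "", character(1))
  paste(c(bodies, document$das_text), collapse = "\n")
}

## condition signalled when extraction is attempted on a non-ok document
not_determinable_error <- function(document) {
  structure(
    class = c("seqbadge_not_determinable", "error", "condition"),
    list(message = sprintf("article %s is not determinable (status: %s)",
                           document$article_id, document$retrieval_status),
         call = NULL, article_id = document$article_id,
         retrieval_status = document$retrieval_status))
}
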