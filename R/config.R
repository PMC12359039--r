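.seqbadge_cache <- new.env(parent = emptyenv())

config_file <- function(name) {
  system.file("extdata", "config", name, package = "seqbadge", mustWork = TRUE)
}

#' Load the evidence-extraction pattern catalogue
#'
#' The catalogue (accession regexes with registry and record type, primer
#' detection parameters, sequencing-method lexicons, code-host list,
#' data-availability-statement trigger phrases, database-name mentions, the
#' open-registry list, and the missing-value vocabulary) ships as an editable
#' YAML file under `inst/extdata/config/patterns.yaml`. Pass `path` to use a
#' customized catalogue with the same schema.
#'
#' @param path optional path to an alternative YAML catalogue.
#' @param refresh reload from disk even if cached.
#' @return a list with elements `accession_catalogue` (data frame), `primer`,
#'   `method_lexicon`, `code_hosts`, `code_keywords`, `code_window`,
#'   `das_phrases`, `database_mentions`, `open_registries`, `missing_tokens`.
#' @export
pattern_config <- function(path = NULL, refresh = FALSE) {
  key <- path %||% "default"
  cached <- .seqbadge_cache$patterns[[key]]
  if (!refresh && !is.null(cached)) return(cached)
  raw <- yaml::read_yaml(path %||% config_file("patterns.yaml"))
  cat <- do.call(rbind, lapply(raw$accessions, function(a) {
    data.frame(pattern = a$pattern, registry = a$registry,
               record_type = a$record_type, stringsAsFactors = FALSE)
  }))
  cfg <- list(
    accession_catalogue = cat,
    primer = raw$primer,
    method_lexicon = raw$method_lexicon,
    code_hosts = tolower(unlist(raw$code_hosts)),
    code_keywords = unlist(raw$code_keywords),
    code_window = raw$code_window %||% 200L,
    das_phrases = raw$das_phrases,
    database_mentions = raw$database_mentions,
    open_registries = unlist(raw$open_registries),
    missing_tokens = tolower(unlist(raw$missing_tokens))
  )
  if (is.null(.seqbadge_cache$patterns)) .seqbadge_cache$patterns <- list()
  .seqbadge_cache$patterns[[key]] <- cfg
  cfg
}

#' Load a tiered metadata checklist
#'
#' Checklists are YAML files with incremental `tiers` (bronze, silver, gold);
#' the loader also exposes the cumulative field sets (bronze subset of silver
#' subset of gold). The packaged default is the human-gut flavoured checklist.
#'
#' @param path optional path to an alternative checklist YAML.
#' @return a list with `name`, `incremental` and `cumulative` tier field lists.
#' @export
metadata_checklist <- function(path = NULL) {
  raw <- yaml::read_yaml(path %||% config_file("checklist_human_gut.yaml"))
  inc <- lapply(raw$tiers, unlist)
  cum <- list(
    bronze = inc$bronze,
    silver = c(inc$bronze, inc$silver),
    gold = c(inc$bronze, inc$silver, inc$gold)
  )
  list(name = raw$name %||% "checklist", incremental = inc, cumulative = cum)
}

#' Default attribute-name synonym map
#'
#' Returns a named character vector mapping normalized raw attribute names
#' (see [normalize_attr_name()]) to canonical MIxS-style terms. Each canonical
#' term also maps to itself, which makes harmonization idempotent.
#'
#' @param path optional path to an alternative synonyms YAML.
#' @return named character vector (names = normalized raw names, values =
#'   canonical names).
#' @export
default_synonym_map <- function(path = NULL) {
  key <- paste0("syn:", path %||% "default")
  cached <- .seqbadge_cache$patterns[[key]]
  if (!is.null(cached)) return(cached)
  raw <- yaml::read_yaml(path %||% config_file("synonyms.yaml"))
  out <- character(0)
  for (canonical in names(raw)) {
    variants <- unique(normalize_attr_name(c(canonical, unlist(raw[[canonical]]))))
    out[variants] <- canonical
  }
  .seqbadge_cache$patterns[[key]] <- out
  out
}

#' Raw synonym variants per canonical attribute
#'
#' Inverse view of [default_synonym_map()], used by the synthetic metadata
#' generator to inject realistic attribute-name noise.
#'
#' @param path optional path to an alternative synonyms YAML.
#' @return named list: canonical name -> character vector of raw variants.
#' @export
synonym_variants <- function(path = NULL) {
  raw <- yaml::read_yaml(path %||% config_file("synonyms.yaml"))
  lapply(raw, unlist)
}
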