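#' Search specification
#'
#' Describes a PubMed-style search: the query phrases, the date window, the
#' affiliation markers and whether an abstract is required. The same object
#' drives both [build_query()] (restriction inside the search expression) and
#' [filter_corpus()] (post-hoc restriction of already-parsed records) — the
#' two paths are equivalent for the fields both support.
#'
#' @param terms Character vector of query phrases (non-empty).
#' @param date_from,date_to Dates (or `"YYYY-MM-DD"` strings) bounding the
#'   publication window, inclusive; `date_from` must not exceed `date_to`.
#' @param affiliation_markers Character vector of case-insensitive substrings,
#'   at least one of which must appear in at least one affiliation. The
#'   default pair targets UK-aligned publications.
#' @param require_abstract Require a non-empty abstract?
#' @return A `query_spec` list.
#' @export
query_spec <- function(terms,
                       date_from = "2011-01-01",
                       date_to = "2021-12-27",
                       affiliation_markers = c("United Kingdom", "UK"),
                       require_abstract = TRUE) {
  terms <- as.character(terms)
  if (length(terms) == 0 || any(!nzchar(trimws(terms)))) {
    rlang::abort("query_spec: `terms` must be a non-empty vector of non-empty phrases")
  }
  date_from <- as.Date(date_from)
  date_to <- as.Date(date_to)
  if (is.na(date_from) || is.na(date_to) || date_from > date_to) {
    rlang::abort("query_spec: require date_from <= date_to")
  }
  structure(
    list(
      terms = terms, date_from = date_from, date_to = date_to,
      affiliation_markers = as.character(affiliation_markers),
      require_abstract = isTRUE(require_abstract)
    ),
    class = "query_spec"
  )
}

#' The study's default search specification
#'
#' Eight digital-health query phrases, window 2011-01-01 to 2021-12-27,
#' UK affiliation markers and abstract requirement.
#'
#' @return A [query_spec()].
#' @export
default_query_spec <- function() {
  query_spec(
    terms = c(
      "Mobile applications", "digital health", "telemedicine",
      "digital intervention", "health app", "medical informatics",
      "health informatics", "digital technology"
    ),
    date_from = "2011-01-01",
    date_to = "2021-12-27",
    affiliation_markers = c("United Kingdom", "UK"),
    require_abstract = TRUE
  )
}

#' Build a PubMed-syntax boolean search expression
#'
#' Produces a deterministic expression: the quoted phrases OR-joined, then
#' AND-joined with a date-range clause (`"YYYY/MM/DD"[Date - Publication]`),
#' an abstract filter (`hasabstract`) when required, and an OR-joined
#' affiliation clause (`[Affiliation]`) when markers are given.
#'
#' @param spec A [query_spec()].
#' @return A single character string; byte-identical for identical specs.
#' @export
build_query <- function(spec) {
  stopifnot(inherits(spec, "query_spec"))
  phrase_clause <- paste0("(", paste(sprintf("\"%s\"", spec$terms), collapse = " OR "), ")")
  date_clause <- sprintf(
    "(\"%s\"[Date - Publication] : \"%s\"[Date - Publication])",
    format(spec$date_from, "%Y/%m/%d"), format(spec$date_to, "%Y/%m/%d")
  )
  clauses <- c(phrase_clause, date_clause)
  if (length(spec$affiliation_markers)) {
    clauses <- c(clauses, paste0(
      "(", paste(sprintf("\"%s\"[Affiliation]", spec$affiliation_markers),
        collapse = " OR "
      ), ")"
    ))
  }
  if (spec$require_abstract) clauses <- c(clauses, "hasabstract")
  paste(clauses, collapse = " AND ")
}

#' Filter a corpus by date window, abstract availability and affiliation
#'
#' Retains records whose year lies inside `[year(date_from), year(date_to)]`
#' (records with no parseable year are dropped, since their membership in the
#' window cannot be established), that carry an abstract when
#' `require_abstract` is set, and whose affiliation strings contain at least
#' one affiliation marker as a case-insensitive substring (no marker filter
#' when the marker list is empty). Original record order is preserved and an
#' empty result is valid. The operation is idempotent.
#'
#' @param corpus A [pm_corpus()].
#' @param spec A [query_spec()].
#' @return The filtered `pm_corpus`.
#' @export
filter_corpus <- function(corpus, spec) {
  stopifnot(inherits(corpus, "pm_corpus"), inherits(spec, "query_spec"))
  y_lo <- as.integer(format(spec$date_from, "%Y"))
  y_hi <- as.integer(format(spec$date_to, "%Y"))
  keep <- !is.na(corpus$year) & corpus$year >= y_lo & corpus$year <= y_hi
  if (spec$require_abstract) keep <- keep & corpus$has_abstract
  if (length(spec$affiliation_markers)) {
    markers <- tolower(spec$affiliation_markers)
    keep <- keep & vapply(corpus$affiliations, function(affs) {
      if (length(affs) == 0) {
        return(FALSE)
      }
      affs <- tolower(affs)
      any(vapply(markers, function(m) any(grepl(m, affs, fixed = TRUE)), logical(1)))
    }, logical(1))
  }
  corpus[keep, ]
}
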