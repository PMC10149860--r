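#' Bibliographic record corpora
#'
#' A corpus is a tibble with one row per PubMed record and class
#' `"pm_corpus"`. Columns:
#'
#' * `pmid` — character record identifier, unique within the corpus;
#' * `year` — integer publication year, `NA` when the source record carries
#'   no parseable date;
#' * `has_abstract` — logical, `TRUE` when a non-empty abstract is present;
#' * `title` — character, `NA` when absent;
#' * `descriptors` — list column of character vectors: the raw MeSH
#'   descriptor strings (qualifier suffixes such as `"/trends"` retained as
#'   read), duplicates removed, input order preserved;
#' * `affiliations` — list column of character vectors of free-text
#'   affiliation strings.
#'
#' Iteration order is the input order and is deterministic. The attributes
#' `provenance` (a free-text source description) and `retrieved_on` (an
#' optional `Date`) record where the corpus came from.
#'
#' @param pmid Character vector of record identifiers.
#' @param year Integer vector (NA allowed) of 4-digit publication years.
#' @param has_abstract Logical vector.
#' @param title Character vector (NA allowed).
#' @param descriptors List of character vectors.
#' @param affiliations List of character vectors.
#' @param provenance Free-text description of the source.
#' @param retrieved_on Optional `Date` the records were retrieved.
#'
#' @return A `pm_corpus` tibble.
#' @export
pm_corpus <- function(pmid = character(),
                      year = integer(),
                      has_abstract = logical(),
                      title = NA_character_,
                      descriptors = list(),
                      affiliations = list(),
                      provenance = "in-memory",
                      retrieved_on = NULL) {
  n <- length(pmid)
  tbl <- tibble::tibble(
    pmid = as.character(pmid),
    year = as.integer(rep_len(year, n)),
    has_abstract = as.logical(rep_len(has_abstract, n)),
    title = as.character(rep_len(title, n)),
    descriptors = if (n == 0) list() else rep_len(descriptors, n),
    affiliations = if (n == 0) list() else rep_len(affiliations, n)
  )
  tbl$descriptors <- lapply(tbl$descriptors, function(d) unique(as.character(d)))
  tbl$affiliations <- lapply(tbl$affiliations, as.character)
  out <- tibble::new_tibble(tbl, class = "pm_corpus", nrow = nrow(tbl))
  attr(out, "provenance") <- provenance
  attr(out, "retrieved_on") <- retrieved_on
  validate_corpus(out)
}

#' Validate corpus invariants
#'
#' Checks identifier uniqueness, year plausibility and descriptor
#' de-duplication; stops with an informative message on violation.
#'
#' @param corpus A `pm_corpus`.
#' @return The corpus, invisibly unchanged, for chaining.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "pm_corpus"))
  if (anyNA(corpus$pmid) || any(!nzchar(corpus$pmid))) {
    rlang::abort("corpus contains an empty or missing pmid")
  }
  if (anyDuplicated(corpus$pmid)) {
    dup <- unique(corpus$pmid[duplicated(corpus$pmid)])
    rlang::abort(paste0(
      "duplicate pmid(s) in corpus: ",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  yr <- corpus$year[!is.na(corpus$year)]
  if (length(yr) && any(yr < 1000 | yr > 9999)) {
    rlang::abort("corpus contains a year that is not a 4-digit integer")
  }
  bad <- vapply(corpus$descriptors, anyDuplicated, integer(1)) > 0L
  if (any(bad)) {
    rlang::abort(paste0(
      "duplicate descriptor strings within record(s): ",
      paste(utils::head(corpus$pmid[bad], 5), collapse = ", ")
    ))
  }
  invisible(corpus)
}

#' @export
print.pm_corpus <- function(x, ...) {
  cat(sprintf(
    "<pm_corpus> %d record(s) | source: %s\n",
    nrow(x), attr(x, "provenance") %||% "unknown"
  ))
  NextMethod()
}

# Keep the subclass through dplyr verbs that return data frames.
#' @export
`[.pm_corpus` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("pmid", "descriptors") %in% names(out))) {
    out <- tibble::new_tibble(out, class = "pm_corpus", nrow = nrow(out))
    attr(out, "provenance") <- attr(x, "provenance")
    attr(out, "retrieved_on") <- attr(x, "retrieved_on")
  }
  out
}

#' Combine corpora, dropping duplicate identifiers
#'
#' Merged searches can overlap; counts must not double, so for a pmid seen
#' in more than one source the first occurrence is kept and later ones are
#' dropped with a warning.
#'
#' @param ... `pm_corpus` objects.
#' @param provenance Provenance string for the merged corpus.
#' @return A `pm_corpus` in concatenation order, first occurrence of each
#'   pmid retained.
#' @export
merge_corpora <- function(..., provenance = "merged") {
  parts <- list(...)
  stopifnot(length(parts) > 0, all(vapply(parts, inherits, logical(1), "pm_corpus")))
  tbl <- dplyr::bind_rows(lapply(parts, as.data.frame))
  dup <- duplicated(tbl$pmid)
  if (any(dup)) {
    rlang::warn(paste0(
      "dropping ", sum(dup), " duplicate record(s) across sources: ",
      paste(utils::head(unique(tbl$pmid[dup]), 5), collapse = ", ")
    ))
    tbl <- tbl[!dup, , drop = FALSE]
  }
  pm_corpus(
    pmid = tbl$pmid, year = tbl$year, has_abstract = tbl$has_abstract,
    title = tbl$title, descriptors = tbl$descriptors,
    affiliations = tbl$affiliations, provenance = provenance
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
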