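#' Parse MEDLINE nbib flat-file records into a corpus
#'
#' Reads the tagged flat-file convention used by PubMed's "MEDLINE" export
#' (`PMID-`, `MH`, `DP`, `AB`, `AD`, `TI` tags). Continuation lines (leading
#' whitespace) are folded into the previous tag value with a single space.
#' Records are separated by blank lines or by the next `PMID-` line. Major-
#' topic asterisks on `MH` values (e.g. `*Telemedicine/trends`) are removed
#' so the same content parses identically from XML and nbib.
#'
#' Field mapping mirrors [parse_pubmed_xml()]: `MH` lines become descriptors
#' (duplicates dropped, order preserved), `DP` yields the year via the first
#' four-digit substring, `AB` presence sets `has_abstract`, `AD` lines become
#' affiliations. A record block with no `PMID-` line is skipped with a
#' warning.
#'
#' @param source Path to an nbib file, or a character vector of lines.
#' @param provenance Provenance string stored on the corpus.
#' @return A [pm_corpus()].
#' @export
parse_medline_nbib <- function(source, provenance = NULL) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readr::read_lines(source)
    provenance <- provenance %||% paste0("nbib:", source)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
    provenance <- provenance %||% "nbib"
  }

  # Fold continuation lines, then split "TAG - value".
  fields <- list() # per record: list of c(tag, value)
  records <- list()
  cur <- list()
  flush <- function() {
    if (length(cur) > 0) records[[length(records) + 1]] <<- cur
    cur <<- list()
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      flush()
      next
    }
    if (grepl("^\\s", ln)) { # continuation of previous value
      if (length(cur) > 0) {
        i <- length(cur)
        cur[[i]][2] <- paste(cur[[i]][2], trimws(ln))
      }
      next
    }
    m <- regmatches(ln, regexec("^([A-Z]{1,4})\\s*- ?(.*)$", ln))[[1]]
    if (length(m) == 3) {
      tag <- m[2]
      val <- trimws(m[3])
      if (tag == "PMID" && length(cur) > 0 &&
        any(vapply(cur, `[`, character(1), 1) == "PMID")) {
        flush() # new record without an intervening blank line
      }
      cur[[length(cur) + 1]] <- c(tag, val)
    }
    # lines not matching the tag grammar are ignored
  }
  flush()

  rows <- lapply(records, nbib_record_row)
  skipped <- vapply(rows, is.null, logical(1))
  if (any(skipped)) {
    rlang::warn(sprintf("skipped %d nbib block(s) lacking a PMID- line", sum(skipped)))
    rows <- rows[!skipped]
  }
  corpus_from_rows(rows, provenance)
}

nbib_record_row <- function(fields) {
  tags <- vapply(fields, `[`, character(1), 1)
  vals <- vapply(fields, `[`, character(1), 2)
  pmid <- vals[tags == "PMID"]
  if (length(pmid) == 0 || !nzchar(pmid[1])) {
    return(NULL)
  }
  dp <- vals[tags == "DP"]
  ab <- vals[tags == "AB"]
  ti <- vals[tags == "TI"]
  mh <- gsub("*", "", vals[tags == "MH"], fixed = TRUE)
  list(
    pmid = pmid[1],
    year = if (length(dp)) extract_year(dp[1]) else NA_integer_,
    has_abstract = length(ab) > 0 && any(nzchar(ab)),
    title = if (length(ti) && nzchar(ti[1])) ti[1] else NA_character_,
    descriptors = unique(mh),
    affiliations = vals[tags == "AD"]
  )
}
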