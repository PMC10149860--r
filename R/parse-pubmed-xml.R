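#' Parse PubMed XML (PubmedArticleSet) into a corpus
#'
#' Reads the XML export dialect used by PubMed/E-utilities and returns one
#' record per `<PubmedArticle>`. For each MeSH heading the descriptor name
#' is captured; qualifier names, when present, are appended as
#' `"/qualifier"` suffixes so the raw string is preserved losslessly
#' (e.g. `"Telemedicine/trends"`).
#'
#' The publication year is taken from the structured
#' `PubDate/Year` element when present; otherwise the first four-consecutive-
#' digit substring of the free-text `PubDate/MedlineDate` (MEDLINE dates are
#' heterogeneous, e.g. `"2012 Jan-Feb"`); otherwise the year is `NA`.
#' `has_abstract` is `TRUE` iff an `AbstractText` element with non-empty
#' text exists. Articles lacking a PMID are skipped with a warning.
#'
#' @param source Path, connection or literal XML string accepted by
#'   [xml2::read_xml()].
#' @param provenance Provenance string stored on the corpus; defaults to the
#'   source path when `source` is a path.
#' @return A [pm_corpus()].
#' @export
parse_pubmed_xml <- function(source, provenance = NULL) {
  doc <- xml2::read_xml(source)
  if (is.null(provenance)) {
    provenance <- if (is.character(source) && length(source) == 1 &&
      !grepl("^\\s*<", source)) {
      paste0("pubmed-xml:", source)
    } else {
      "pubmed-xml"
    }
  }
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  rows <- lapply(articles, parse_pubmed_article)
  skipped <- vapply(rows, is.null, logical(1))
  if (any(skipped)) {
    rlang::warn(sprintf("skipped %d article(s) lacking a PMID", sum(skipped)))
    rows <- rows[!skipped]
  }
  corpus_from_rows(rows, provenance)
}

parse_pubmed_article <- function(article) {
  pmid <- xml2::xml_text(xml2::xml_find_first(article, ".//MedlineCitation/PMID"))
  if (is.na(pmid) || !nzchar(trimws(pmid))) {
    return(NULL)
  }
  pubdate <- xml2::xml_find_first(article, ".//Article/Journal/JournalIssue/PubDate")
  year <- NA_integer_
  if (!is.na(pubdate)) {
    y <- xml2::xml_text(xml2::xml_find_first(pubdate, "./Year"))
    if (!is.na(y) && grepl("^\\d{4}$", trimws(y))) {
      year <- as.integer(trimws(y))
    } else {
      md <- xml2::xml_text(xml2::xml_find_first(pubdate, "./MedlineDate"))
      year <- extract_year(md)
    }
  }
  abstract <- xml2::xml_find_all(article, ".//Article/Abstract/AbstractText")
  has_abstract <- length(abstract) > 0 &&
    any(nzchar(trimws(xml2::xml_text(abstract))))
  title <- xml2::xml_text(xml2::xml_find_first(article, ".//Article/ArticleTitle"))
  if (!is.na(title) && !nzchar(trimws(title))) title <- NA_character_
  affiliations <- trimws(xml2::xml_text(
    xml2::xml_find_all(article, ".//AffiliationInfo/Affiliation")
  ))
  affiliations <- affiliations[nzchar(affiliations)]
  headings <- xml2::xml_find_all(article, ".//MeshHeadingList/MeshHeading")
  descriptors <- vapply(headings, function(h) {
    d <- xml2::xml_text(xml2::xml_find_first(h, "./DescriptorName"))
    q <- xml2::xml_text(xml2::xml_find_all(h, "./QualifierName"))
    paste(c(trimws(d), trimws(q)), collapse = "/")
  }, character(1))
  list(
    pmid = trimws(pmid), year = year, has_abstract = has_abstract,
    title = title, descriptors = unique(descriptors),
    affiliations = affiliations
  )
}

# First 4-consecutive-digit substring of a free-text date, else NA.
extract_year <- function(x) {
  if (length(x) == 0 || is.na(x)) {
    return(NA_integer_)
  }
  m <- stringr::str_extract(x, "\\d{4}")
  if (is.na(m)) NA_integer_ else as.integer(m)
}

corpus_from_rows <- function(rows, provenance) {
  if (length(rows) == 0) {
    return(pm_corpus(provenance = provenance))
  }
  pm_corpus(
    pmid = vapply(rows, `[[`, character(1), "pmid"),
    year = vapply(rows, `[[`, integer(1), "year"),
    has_abstract = vapply(rows, `[[`, logical(1), "has_abstract"),
    title = vapply(rows, `[[`, character(1), "title"),
    descriptors = lapply(rows, `[[`, "descriptors"),
    affiliations = lapply(rows, `[[`, "affiliations"),
    provenance = provenance
  )
}
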