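#' Corpus TSV cache
#'
#' A plain-text cache so a parsed corpus need not be re-downloaded or
#' re-parsed. One record per line, tab-separated, UTF-8, with header
#' `pmid  year  has_abstract  descriptors  affiliations`. Descriptor and
#' affiliation lists are pipe-joined; backslash, pipe and tab characters
#' inside values are backslash-escaped so the round trip is lossless.
#'
#' @param corpus A [pm_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_tsv <- function(corpus, path) {
  stopifnot(inherits(corpus, "pm_corpus"))
  lines <- c(
    "pmid\tyear\thas_abstract\tdescriptors\taffiliations",
    vapply(seq_len(nrow(corpus)), function(i) {
      paste(
        escape_cell(corpus$pmid[i]),
        ifelse(is.na(corpus$year[i]), "", corpus$year[i]),
        ifelse(corpus$has_abstract[i], "1", "0"),
        join_list(corpus$descriptors[[i]]),
        join_list(corpus$affiliations[[i]]),
        sep = "\t"
      )
    }, character(1))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_tsv
#' @param provenance Provenance string for the reloaded corpus.
#' @return `read_corpus_tsv()` returns the reconstructed [pm_corpus()]
#'   (titles are not cached and come back as `NA`).
#' @export
read_corpus_tsv <- function(path, provenance = NULL) {
  lines <- readr::read_lines(path)
  if (length(lines) == 0 || lines[1] != "pmid\tyear\thas_abstract\tdescriptors\taffiliations") {
    rlang::abort(paste0("not a corpus cache (bad header): ", path))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- lapply(seq_along(body), function(i) {
    cells <- split_escaped(body[i], "\t")
    if (length(cells) != 5) {
      rlang::abort(sprintf("malformed cache line %d in %s", i + 1L, path))
    }
    cells
  })
  pm_corpus(
    pmid = vapply(rows, function(r) unescape_cell(r[1]), character(1)),
    year = vapply(rows, function(r) {
      if (nzchar(r[2])) as.integer(r[2]) else NA_integer_
    }, integer(1)),
    has_abstract = vapply(rows, function(r) r[3] == "1", logical(1)),
    descriptors = lapply(rows, function(r) split_list(r[4])),
    affiliations = lapply(rows, function(r) split_list(r[5])),
    provenance = provenance %||% paste0("tsv-cache:", path)
  )
}

#' Write a corpus as PubMed-shaped XML
#'
#' Emits a `PubmedArticleSet` document so generated corpora can be fed back
#' through [parse_pubmed_xml()], exercising the real parser path. Descriptor
#' strings of the form `"Descriptor/Qualifier"` are split back into
#' `DescriptorName` and `QualifierName` elements; records flagged as having
#' an abstract receive a placeholder `AbstractText`.
#'
#' @param corpus A [pm_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pubmed_xml <- function(corpus, path) {
  stopifnot(inherits(corpus, "pm_corpus"))
  doc <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(corpus))) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", corpus$pmid[i])
    article <- xml2::xml_add_child(cit, "Article")
    journal <- xml2::xml_add_child(article, "Journal")
    issue <- xml2::xml_add_child(journal, "JournalIssue")
    pubdate <- xml2::xml_add_child(issue, "PubDate")
    if (!is.na(corpus$year[i])) {
      xml2::xml_add_child(pubdate, "Year", as.character(corpus$year[i]))
    }
    if (!is.na(corpus$title[i])) {
      xml2::xml_add_child(article, "ArticleTitle", corpus$title[i])
    }
    if (corpus$has_abstract[i]) {
      ab <- xml2::xml_add_child(article, "Abstract")
      xml2::xml_add_child(ab, "AbstractText", "Abstract available.")
    }
    affs <- corpus$affiliations[[i]]
    if (length(affs)) {
      alist <- xml2::xml_add_child(article, "AuthorList")
      author <- xml2::xml_add_child(alist, "Author")
      for (a in affs) {
        info <- xml2::xml_add_child(author, "AffiliationInfo")
        xml2::xml_add_child(info, "Affiliation", a)
      }
    }
    descs <- corpus$descriptors[[i]]
    if (length(descs)) {
      mh_list <- xml2::xml_add_child(cit, "MeshHeadingList")
      for (d in descs) {
        parts <- strsplit(d, "/", fixed = TRUE)[[1]]
        h <- xml2::xml_add_child(mh_list, "MeshHeading")
        xml2::xml_add_child(h, "DescriptorName", parts[1])
        for (q in parts[-1]) xml2::xml_add_child(h, "QualifierName", q)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

escape_cell <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("|", "\\|", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_cell <- function(x) {
  out <- character(length(x))
  for (k in seq_along(x)) {
    chars <- strsplit(x[k], "", fixed = TRUE)[[1]]
    buf <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        buf <- c(buf, if (nxt == "t") "\t" else nxt)
        i <- i + 2L
      } else {
        buf <- c(buf, chars[i])
        i <- i + 1L
      }
    }
    out[k] <- paste(buf, collapse = "")
  }
  out
}

join_list <- function(values) {
  if (length(values) == 0) {
    return("")
  }
  paste(escape_cell(values), collapse = "|")
}

split_list <- function(cell) {
  if (!nzchar(cell)) {
    return(character(0))
  }
  unescape_cell(split_escaped(cell, "|"))
}

# Split on an unescaped single-character delimiter.
split_escaped <- function(x, delim) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  parts <- character(0)
  buf <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\" && i < length(chars)) {
      buf <- c(buf, ch, chars[i + 1L]) # keep escapes for unescape_cell
      i <- i + 2L
    } else if (ch == delim) {
      parts <- c(parts, paste(buf, collapse = ""))
      buf <- character(0)
      i <- i + 1L
    } else {
      buf <- c(buf, ch)
      i <- i + 1L
    }
  }
  c(parts, paste(buf, collapse = ""))
}
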