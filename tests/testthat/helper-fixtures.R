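# Fixture builders: records are lists with fields
#   pmid, year (or medline_date), abstract (logical), affiliations (chr),
#   mesh (list of character vectors: descriptor followed by qualifiers).
# The XML and nbib emitters encode the same content so cross-format
# equivalence can be asserted on shared record lists.

fixture_xml <- function(records) {
  article <- function(r) {
    pubdate <- if (!is.null(r$medline_date)) {
      sprintf("<MedlineDate>%s</MedlineDate>", r$medline_date)
    } else if (!is.null(r$year)) {
      sprintf("<Year>%s</Year>", r$year)
    } else {
      ""
    }
    abstract <- if (isTRUE(r$abstract)) {
      "<Abstract><AbstractText>Some abstract text.</AbstractText></Abstract>"
    } else {
      ""
    }
    affs <- paste(vapply(r$affiliations %||% character(0), function(a) {
      sprintf("<AffiliationInfo><Affiliation>%s</Affiliation></AffiliationInfo>", a)
    }, character(1)), collapse = "")
    affs <- if (nzchar(affs)) sprintf("<AuthorList><Author>%s</Author></AuthorList>", affs) else ""
    mesh <- paste(vapply(r$mesh %||% list(), function(m) {
      quals <- paste(vapply(m[-1], function(q) {
        sprintf("<QualifierName>%s</QualifierName>", q)
      }, character(1)), collapse = "")
      sprintf(
        "<MeshHeading><DescriptorName>%s</DescriptorName>%s</MeshHeading>",
        m[1], quals
      )
    }, character(1)), collapse = "")
    mesh <- if (nzchar(mesh)) sprintf("<MeshHeadingList>%s</MeshHeadingList>", mesh) else ""
    pmid <- if (!is.null(r$pmid)) sprintf("<PMID>%s</PMID>", r$pmid) else ""
    title <- if (!is.null(r$title)) sprintf("<ArticleTitle>%s</ArticleTitle>", r$title) else ""
    sprintf(
      paste0(
        "<PubmedArticle><MedlineCitation>%s<Article>",
        "<Journal><JournalIssue><PubDate>%s</PubDate></JournalIssue></Journal>",
        "%s%s%s</Article>%s</MedlineCitation></PubmedArticle>"
      ),
      pmid, pubdate, title, abstract, affs, mesh
    )
  }
  paste0(
    "<?xml version=\"1.0\"?><PubmedArticleSet>",
    paste(vapply(records, article, character(1)), collapse = ""),
    "</PubmedArticleSet>"
  )
}

fixture_nbib <- function(records) {
  block <- function(r) {
    lines <- character(0)
    if (!is.null(r$pmid)) lines <- c(lines, paste0("PMID- ", r$pmid))
    dp <- r$medline_date %||% r$year
    if (!is.null(dp)) lines <- c(lines, paste0("DP  - ", dp))
    if (!is.null(r$title)) lines <- c(lines, paste0("TI  - ", r$title))
    if (isTRUE(r$abstract)) lines <- c(lines, "AB  - Some abstract text.")
    for (a in r$affiliations %||% character(0)) lines <- c(lines, paste0("AD  - ", a))
    for (m in r$mesh %||% list()) {
      lines <- c(lines, paste0("MH  - ", paste(m, collapse = "/")))
    }
    paste(lines, collapse = "\n")
  }
  paste(vapply(records, block, character(1)), collapse = "\n\n")
}

# Random corpora over an uppercase-letter term alphabet, for property tests
# and oracle comparisons. Descriptor casing is randomised so matching is
# exercised through normalization.
random_corpus <- function(n, terms = LETTERS[1:6], p = 0.35,
                          p_year_missing = 0.15, noise = TRUE) {
  descriptors <- lapply(seq_len(n), function(i) {
    d <- terms[stats::runif(length(terms)) < p]
    flip <- stats::runif(length(d)) < 0.5
    d[flip] <- tolower(d[flip])
    if (noise && stats::runif(1) < 0.5) d <- c(d, "Unrelated Heading")
    unique(d)
  })
  year <- sample(2011:2021, n, replace = TRUE)
  year[stats::runif(n) < p_year_missing] <- NA_integer_
  pm_corpus(
    pmid = sprintf("R%05d", seq_len(n)),
    year = year,
    has_abstract = stats::runif(n) < 0.8,
    descriptors = descriptors,
    affiliations = lapply(seq_len(n), function(i) "Somewhere, UK")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
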