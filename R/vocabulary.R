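#' Normalize a MeSH descriptor or vocabulary term
#'
#' Exact matching against controlled vocabularies must be robust to
#' formatting noise without becoming fuzzy. Normalization lowercases,
#' strips leading/trailing whitespace, collapses internal whitespace runs to
#' single spaces, removes any `"/qualifier"` suffix (everything from the
#' first `/`), and maps typographic dashes (en/em/minus) to the ASCII
#' hyphen. It is idempotent: `normalize_term(normalize_term(x)) ==
#' normalize_term(x)`.
#'
#' @param raw Character vector of raw terms or descriptors.
#' @return Character vector of normalized terms.
#' @export
#' @examples
#' normalize_term("Telemedicine/methods ") # "telemedicine"
#' normalize_term("User-Computer  Interface") # "user-computer interface"
normalize_term <- function(raw) {
  x <- as.character(raw)
  x <- sub("/.*$", "", x)
  x <- stringr::str_replace_all(x, "[‐‑‒–—−]", "-")
  x <- tolower(x)
  x <- stringr::str_squish(x)
  x
}

#' Controlled vocabulary
#'
#' A named, categorised set of normalized terms, optionally with aliases
#' mapping alternative spellings onto canonical terms. Display casing of the
#' input terms is retained for labels (network nodes, exports); matching is
#' always on the normalized form.
#'
#' @param name Vocabulary name (used in tables and provenance).
#' @param category One of `"digital_health"`, `"disease"`, `"age_group"`,
#'   `"gender"`.
#' @param terms Character vector of terms (any casing; normalized and
#'   de-duplicated internally; must be non-empty).
#' @param aliases Optional named character vector `alias = canonical`; each
#'   canonical target must be a vocabulary term (after normalization).
#' @return A `vocabulary` object.
#' @export
vocabulary <- function(name, category, terms, aliases = NULL) {
  category <- match.arg(category, c("digital_health", "disease", "age_group", "gender"))
  terms <- as.character(terms)
  norm <- normalize_term(terms)
  keep <- !duplicated(norm) & nzchar(norm)
  norm_terms <- norm[keep]
  if (length(norm_terms) == 0) {
    rlang::abort(sprintf("vocabulary '%s' has no terms", name))
  }
  labels <- stringr::str_squish(terms[keep])
  names(labels) <- norm_terms
  alias_map <- character(0)
  if (length(aliases)) {
    alias_map <- normalize_term(unname(aliases))
    names(alias_map) <- normalize_term(names(aliases))
    missing <- setdiff(unique(alias_map), norm_terms)
    if (length(missing)) {
      rlang::abort(paste0(
        "alias target(s) not in vocabulary '", name, "': ",
        paste(missing, collapse = ", ")
      ))
    }
    alias_map <- alias_map[!names(alias_map) %in% norm_terms]
  }
  structure(
    list(
      name = name, category = category, terms = norm_terms,
      labels = labels, aliases = alias_map
    ),
    class = "vocabulary"
  )
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf(
    "<vocabulary> %s (%s): %d term(s), %d alias(es)\n",
    x$name, x$category, length(x$terms), length(x$aliases)
  ))
  invisible(x)
}

#' Load a vocabulary from a text or CSV file
#'
#' Accepts UTF-8 text with one term per line; `#`-prefixed comments and
#' blank lines are ignored. A line containing a comma is read as
#' `alias,canonical`: the first field becomes an alias for the second, and
#' the canonical term is added to the vocabulary if not already present.
#' Terms are normalized and de-duplicated; duplicate lines collapse
#' silently.
#'
#' @param path File path.
#' @param name Vocabulary name; defaults to the file name without extension.
#' @param category Vocabulary category; see [vocabulary()].
#' @return A [vocabulary()].
#' @export
load_vocabulary <- function(path, name = NULL, category = "disease") {
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    rlang::abort(paste0("vocabulary file is empty after comment stripping: ", path))
  }
  has_alias <- grepl(",", lines, fixed = TRUE)
  plain <- lines[!has_alias]
  aliases <- NULL
  canon_extra <- character(0)
  if (any(has_alias)) {
    parts <- strsplit(lines[has_alias], ",", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) != 2
    if (any(bad)) {
      rlang::abort(paste0("malformed alias row(s) in ", path, " (expect alias,canonical)"))
    }
    aliases <- trimws(vapply(parts, `[`, character(1), 2))
    names(aliases) <- trimws(vapply(parts, `[`, character(1), 1))
    canon_extra <- unname(aliases)
  }
  vocab <- vocabulary(
    name = name %||% sub("\\.[^.]*$", "", basename(path)),
    category = category,
    terms = c(plain, canon_extra),
    aliases = aliases
  )
  rlang::inform(sprintf(
    "loaded vocabulary '%s': %d term(s) from %s",
    vocab$name, length(vocab$terms), path
  ))
  vocab
}

#' Match one record's descriptors against a vocabulary
#'
#' A vocabulary term matches iff the normalized form of at least one
#' descriptor equals the term or one of its aliases — whole-descriptor exact
#' match, never substring. The result is a set: descriptor multiplicity
#' within the record (e.g. qualifier variants `"Telemedicine"` and
#' `"Telemedicine/trends"`) is ignored.
#'
#' @param record A single-row [pm_corpus()] slice, or a character vector of
#'   raw descriptor strings.
#' @param vocab A [vocabulary()].
#' @return Character vector of matched canonical (normalized) terms.
#' @export
match_record <- function(record, vocab) {
  descriptors <- if (inherits(record, "pm_corpus")) {
    stopifnot(nrow(record) == 1)
    record$descriptors[[1]]
  } else {
    as.character(record)
  }
  match_descriptor_set(normalize_term(descriptors), vocab)
}

# Sort in the C locale so pair canonicalization and rankings are
# platform-independent.
sort_c <- function(x) withr::with_locale(c(LC_COLLATE = "C"), sort(x))

# Core matcher on already-normalized descriptor strings.
match_descriptor_set <- function(norm_descriptors, vocab) {
  hits <- norm_descriptors[norm_descriptors %in% vocab$terms]
  if (length(vocab$aliases)) {
    via_alias <- vocab$aliases[norm_descriptors[norm_descriptors %in% names(vocab$aliases)]]
    hits <- c(hits, unname(via_alias))
  }
  sort_c(unique(hits))
}

# Matched-term sets for every record at once; normalization is done once on
# the unique descriptor strings (the corpus repeats few distinct headings).
match_corpus <- function(corpus, vocab) {
  all_desc <- unlist(corpus$descriptors, use.names = FALSE)
  n_per <- lengths(corpus$descriptors)
  uniq <- unique(all_desc)
  norm_map <- stats::setNames(normalize_term(uniq), uniq)
  canon <- norm_map
  if (length(vocab$aliases)) {
    is_alias <- canon %in% names(vocab$aliases)
    canon[is_alias] <- vocab$aliases[canon[is_alias]]
  }
  in_vocab <- canon %in% vocab$terms
  canon[!in_vocab] <- NA_character_
  mapped <- unname(canon[all_desc])
  idx <- rep.int(seq_len(nrow(corpus)), n_per)
  out <- rep(list(character(0)), nrow(corpus))
  keep <- !is.na(mapped)
  if (any(keep)) {
    hits <- split(mapped[keep], idx[keep])
    out[as.integer(names(hits))] <- withr::with_locale(
      c(LC_COLLATE = "C"),
      lapply(hits, function(h) sort(unique(h)))
    )
  }
  out
}

#' Built-in digital-health vocabulary
#'
#' The 26 MeSH descriptors used to characterise digital approaches, methods
#' and applications, from remote sensing technology through population
#' surveillance. Membership testing is case-insensitive because probes go
#' through [normalize_term()].
#'
#' @return A [vocabulary()] named `"digital_health"`.
#' @export
builtin_digital_health_vocabulary <- function() {
  vocabulary(
    name = "digital_health", category = "digital_health",
    terms = readr::read_lines(
      system.file("extdata", "digital_health_terms.txt", package = "meshcooc")
    ) |> strip_comment_lines()
  )
}

#' Built-in age-group vocabulary with MeSH age bands
#'
#' The eight MeSH check-tag age groups, with their month bands: infant
#' (1–23 months), child, preschool (2–5 years), child (6–12), adolescent
#' (13–18), adult (19–44), middle aged (45–64), aged (65–79) and aged, 80
#' and over (open upper bound).
#'
#' @return A list with elements `vocabulary` (a [vocabulary()]) and `bands`
#'   (a tibble with `label`, `lo_months`, `hi_months`; `hi_months` is `Inf`
#'   for the open-ended top band).
#' @export
builtin_age_group_vocabulary <- function() {
  bands <- tibble::tibble(
    label = c(
      "Infant", "Child, Preschool", "Child", "Adolescent",
      "Adult", "Middle Aged", "Aged", "Aged, 80 and over"
    ),
    lo_months = c(1, 24, 72, 156, 228, 540, 780, 960),
    hi_months = c(23, 71, 155, 227, 539, 779, 959, Inf)
  )
  list(
    vocabulary = vocabulary("age_group", "age_group", terms = bands$label),
    bands = bands
  )
}

#' Built-in sample disease vocabulary
#'
#' A small disease list for tests and demos: the ten most prevalent
#' conditions in UK digital-health publications. Real analyses should load
#' a full disease list with [load_vocabulary()].
#'
#' @return A [vocabulary()] named `"disease_sample"`.
#' @export
builtin_disease_sample_vocabulary <- function() {
  vocabulary(
    name = "disease_sample", category = "disease",
    terms = readr::read_lines(
      system.file("extdata", "disease_sample.txt", package = "meshcooc")
    ) |> strip_comment_lines()
  )
}

#' Resolve a builtin vocabulary by name
#'
#' @param name One of `"digital_health"`, `"disease_sample"`, `"age_group"`.
#' @return A [vocabulary()].
#' @export
builtin_vocabulary <- function(name) {
  switch(name,
    digital_health = builtin_digital_health_vocabulary(),
    disease_sample = builtin_disease_sample_vocabulary(),
    age_group = builtin_age_group_vocabulary()$vocabulary,
    rlang::abort(paste0(
      "unknown builtin vocabulary '", name,
      "' (expected digital_health, disease_sample or age_group)"
    ))
  )
}

strip_comment_lines <- function(lines) {
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

# Category registry used when typing network nodes: a term appearing in two
# vocabularies keeps the first-registered category, with a warning.
vocab_category_map <- function(vocabs) {
  out <- character(0)
  for (v in vocabs) {
    clash <- intersect(names(out), v$terms)
    if (length(clash)) {
      rlang::warn(paste0(
        "term(s) in multiple vocabularies keep their first category: ",
        paste(utils::head(clash, 5), collapse = ", ")
      ))
    }
    new_terms <- setdiff(v$terms, names(out))
    out[new_terms] <- v$category
  }
  out
}
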