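#' Count record-level term occurrences
#'
#' The counting unit is the record, binary per record: a term counts once
#' per record however many descriptor variants repeat it. Every vocabulary
#' term appears in the result, zero counts included, so serializations are
#' complete.
#'
#' @param corpus A [pm_corpus()].
#' @param vocab A [vocabulary()].
#' @return A `count_table`: tibble with columns `term` (normalized) and
#'   `count`, ordered as the vocabulary, carrying attributes `vocab_name`,
#'   `category`, `n_records` and `labels` (normalized term -> display label).
#' @export
count_occurrences <- function(corpus, vocab) {
  stopifnot(inherits(corpus, "pm_corpus"), inherits(vocab, "vocabulary"))
  matched <- match_corpus(corpus, vocab)
  tab <- table(factor(unlist(matched, use.names = FALSE), levels = vocab$terms))
  new_count_table(
    term = vocab$terms, count = as.integer(tab),
    vocab = vocab, n_records = nrow(corpus)
  )
}

new_count_table <- function(term, count, vocab, n_records) {
  out <- tibble::new_tibble(
    tibble::tibble(term = term, count = as.integer(count)),
    class = "count_table", nrow = length(term)
  )
  attr(out, "vocab_name") <- vocab$name
  attr(out, "category") <- vocab$category
  attr(out, "n_records") <- as.integer(n_records)
  attr(out, "labels") <- vocab$labels
  out
}

#' Count term occurrences by publication year
#'
#' Year-binned record-level counts for longitudinal trends. Records with no
#' parseable year contribute to [count_occurrences()] totals but to no year
#' cell. The result is dense: every (term, year) cell over the covered years
#' is present, zeros included.
#'
#' @param corpus A [pm_corpus()].
#' @param vocab A [vocabulary()].
#' @param years Optional integer vector of years to cover (e.g.
#'   `2011:2021`); defaults to the sorted distinct years observed in the
#'   corpus.
#' @return A `year_count_table`: tibble with columns `term`, `year`, `count`,
#'   dense over `years`, with attributes `vocab_name` and `years`.
#' @export
count_by_year <- function(corpus, vocab, years = NULL) {
  stopifnot(inherits(corpus, "pm_corpus"), inherits(vocab, "vocabulary"))
  dated <- corpus[!is.na(corpus$year), ]
  if (is.null(years)) {
    years <- sort(unique(dated$year))
  } else {
    years <- sort(unique(as.integer(years)))
    dated <- dated[dated$year %in% years, ]
  }
  matched <- match_corpus(dated, vocab)
  term_vec <- unlist(matched, use.names = FALSE)
  year_vec <- rep.int(dated$year, lengths(matched))
  tab <- table(
    factor(term_vec, levels = vocab$terms),
    factor(year_vec, levels = years)
  )
  out <- tibble::new_tibble(
    tidyr::expand_grid(term = vocab$terms, year = as.integer(years)) |>
      dplyr::mutate(count = as.integer(t(tab))[
        (match(term, vocab$terms) - 1L) * length(years) + match(year, years)
      ]),
    class = "year_count_table",
    nrow = length(vocab$terms) * length(years)
  )
  attr(out, "vocab_name") <- vocab$name
  attr(out, "years") <- as.integer(years)
  out
}

#' Count record-level binary term co-occurrences
#'
#' For each record, every unordered pair `{a, b}` with `a` matched from
#' `vocab_a`, `b` matched from `vocab_b` and `a != b` increments the pair
#' count once — a pair can never be counted twice within one record. Pairs
#' never observed are absent. When both vocabularies are the same object the
#' result contains within-vocabulary pairs.
#'
#' @param corpus A [pm_corpus()].
#' @param vocab_a,vocab_b [vocabulary()] objects (may be identical).
#' @return A `cooccurrence_table`: tibble with columns `term_a`, `term_b`
#'   (canonical order `term_a < term_b`) and positive `count`, sorted by
#'   pair, with attributes `left_vocab`, `right_vocab` and `n_records`.
#' @export
count_cooccurrences <- function(corpus, vocab_a, vocab_b = vocab_a) {
  stopifnot(
    inherits(corpus, "pm_corpus"),
    inherits(vocab_a, "vocabulary"), inherits(vocab_b, "vocabulary")
  )
  same <- identical(vocab_a$terms, vocab_b$terms) &&
    identical(vocab_a$aliases, vocab_b$aliases)
  m_a <- match_corpus(corpus, vocab_a)
  m_b <- if (same) m_a else match_corpus(corpus, vocab_b)
  acc_a <- vector("list", nrow(corpus))
  acc_b <- vector("list", nrow(corpus))
  old_collate <- Sys.getlocale("LC_COLLATE")
  Sys.setlocale("LC_COLLATE", "C") # canonical pair order is locale-free
  on.exit(Sys.setlocale("LC_COLLATE", old_collate), add = TRUE)
  for (i in seq_len(nrow(corpus))) {
    a <- m_a[[i]]
    b <- m_b[[i]]
    if (length(a) == 0 || length(b) == 0) next
    if (same) {
      if (length(a) < 2) next
      combs <- utils::combn(a, 2) # a is sorted, so cols are canonical
      acc_a[[i]] <- combs[1, ]
      acc_b[[i]] <- combs[2, ]
    } else {
      grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
      grid <- grid[grid$a != grid$b, , drop = FALSE]
      if (nrow(grid) == 0) next
      lo <- pmin(grid$a, grid$b)
      hi <- pmax(grid$a, grid$b)
      key <- !duplicated(paste(lo, hi, sep = "\r")) # one increment per record
      acc_a[[i]] <- lo[key]
      acc_b[[i]] <- hi[key]
    }
  }
  pair_a <- unlist(acc_a, use.names = FALSE)
  pair_b <- unlist(acc_b, use.names = FALSE)
  if (length(pair_a)) {
    counts <- dplyr::count(
      tibble::tibble(term_a = pair_a, term_b = pair_b),
      .data$term_a, .data$term_b,
      name = "count"
    ) |> dplyr::arrange(.data$term_a, .data$term_b)
  } else {
    counts <- tibble::tibble(
      term_a = character(0), term_b = character(0), count = integer(0)
    )
  }
  out <- tibble::new_tibble(counts, class = "cooccurrence_table", nrow = nrow(counts))
  attr(out, "left_vocab") <- vocab_a$name
  attr(out, "right_vocab") <- vocab_b$name
  attr(out, "n_records") <- nrow(corpus)
  out
}

#' Aggregate vocabulary terms into labelled groups
#'
#' A record counts once toward a group iff it matches at least one member
#' term — union semantics recomputed from the corpus, never the sum of
#' member counts (which would double-count records matching several
#' members). Typical use: pooling `infant`, `child, preschool` and `child`
#' into a children group.
#'
#' @param corpus A [pm_corpus()].
#' @param vocab The [vocabulary()] the group members belong to.
#' @param groups Named list: group label -> character vector of member terms
#'   (any casing; normalized before validation). Unknown members are an
#'   error.
#' @return A `count_table` keyed by group label.
#' @export
aggregate_groups <- function(corpus, vocab, groups) {
  stopifnot(inherits(corpus, "pm_corpus"), inherits(vocab, "vocabulary"), is.list(groups))
  members <- lapply(groups, normalize_term)
  unknown <- setdiff(unique(unlist(members)), vocab$terms)
  if (length(unknown)) {
    rlang::abort(paste0(
      "group member(s) not in vocabulary '", vocab$name, "': ",
      paste(unknown, collapse = ", ")
    ))
  }
  matched <- match_corpus(corpus, vocab)
  counts <- vapply(members, function(mem) {
    sum(vapply(matched, function(m) any(m %in% mem), logical(1)))
  }, integer(1))
  group_vocab <- list(
    name = paste0(vocab$name, "_groups"), category = vocab$category,
    labels = stats::setNames(names(groups), names(groups))
  )
  new_count_table(
    term = names(groups), count = counts,
    vocab = group_vocab, n_records = nrow(corpus)
  )
}

#' Top-ranked terms of a count table
#'
#' Descending by count, ties broken by ascending lexicographic term, so the
#' ranking is stable across runs and platforms (comparison in the C locale).
#'
#' @param table A `count_table`.
#' @param k Number of rows to keep (`k >= 1`); a `k` beyond the table size
#'   returns the whole ranked table.
#' @return A tibble `term`, `count` with at most `k` rows.
#' @export
top_k <- function(table, k) {
  stopifnot(inherits(table, "count_table"), k >= 1)
  ranked <- rank_terms(table)
  ranked[seq_len(min(k, nrow(ranked))), ]
}

rank_terms <- function(table) {
  ord <- withr::with_locale(
    c(LC_COLLATE = "C"),
    order(-table$count, table$term)
  )
  tibble::tibble(term = table$term[ord], count = table$count[ord])
}

#' Word-cloud frequency table
#'
#' The frequency table underlying a word cloud: terms with at least one
#' occurrence, ranked like [top_k()] (count descending, term ascending).
#' Feed this to any word-cloud renderer; no image is drawn here.
#'
#' @param table A `count_table`.
#' @return A tibble `term`, `count` with all zero-count terms dropped.
#' @export
wordcloud_frequencies <- function(table) {
  stopifnot(inherits(table, "count_table"))
  ranked <- rank_terms(table)
  ranked[ranked$count >= 1, ]
}

#' Write counting outputs as tidy TSV
#'
#' Stable column order, UTF-8, header row. `write_count_tsv()` writes
#' `term`, `count` (all vocabulary terms, zeros included);
#' `write_year_count_tsv()` writes `term`, `year`, `count` dense over the
#' covered window; `write_cooccurrence_tsv()` writes `term_a`, `term_b`,
#' `count` with `term_a < term_b`.
#'
#' @param table The table to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_tsv <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  readr::write_tsv(tibble::as_tibble(table)[, c("term", "count")], path)
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
write_year_count_tsv <- function(table, path) {
  stopifnot(inherits(table, "year_count_table"))
  readr::write_tsv(tibble::as_tibble(table)[, c("term", "year", "count")], path)
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
write_cooccurrence_tsv <- function(table, path) {
  stopifnot(inherits(table, "cooccurrence_table"))
  readr::write_tsv(tibble::as_tibble(table)[, c("term_a", "term_b", "count")], path)
  invisible(path)
}
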