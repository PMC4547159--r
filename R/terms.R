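# Cache for the bundled stop-word list.
.pc_env <- new.env(parent = emptyenv())

#' The bundled English stop-word list
#'
#' About a hundred very common English function words excluded from term
#' ranking. Shipped as a plain-text data file (one word per line) so the
#' exclusions are auditable.
#'
#' @return Character vector of stop words.
#' @export
stop_words <- function() {
  if (is.null(.pc_env$stopwords)) {
    path <- system.file("extdata", "stopwords.txt", package = "pathcausal")
    .pc_env$stopwords <- readLines(path, warn = FALSE)
  }
  .pc_env$stopwords
}

#' Tokenise description text
#'
#' Lowercases, splits on non-alphanumeric characters, and drops tokens
#' shorter than 3 characters and tokens on the bundled stop-word list.
#'
#' @param texts Character vector of descriptions.
#' @return A list of character token vectors, one per input text.
#' @export
tokenize <- function(texts) {
  sw <- stop_words()
  lapply(tolower(texts), function(tx) {
    toks <- strsplit(tx, "[^a-z0-9]+")[[1]]
    toks[nchar(toks) >= 3L & !toks %in% sw]
  })
}

#' Top-k most common terms in descriptions
#'
#' Ranks terms by total frequency across all texts (per occurrence by
#' default; `per_document = TRUE` counts each term at most once per text).
#' Ties are broken lexicographically. The default `k = 20` matches the
#' term-list panel of the reaction-centric view.
#'
#' @param texts Character vector of descriptions.
#' @param k Number of terms to return.
#' @param per_document Count presence per text instead of raw occurrences.
#' @return Data frame with columns `term` and `frequency`, sorted by
#'   decreasing frequency then term.
#' @export
top_terms <- function(texts, k = 20L, per_document = FALSE) {
  if (k < 1L) pc_usage_error("k must be >= 1")
  toks <- tokenize(texts)
  if (per_document) toks <- lapply(toks, unique)
  all_toks <- unlist(toks, use.names = FALSE)
  if (!length(all_toks))
    return(data.frame(term = character(), frequency = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(all_toks)
  df <- data.frame(term = names(tab), frequency = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$frequency, df$term), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, k)
}

#' Term co-occurrence across descriptions
#'
#' For each unordered pair of the supplied terms, counts the number of
#' descriptions whose token set contains both (presence, not multiplicity).
#' These counts drive the arcs connecting terms in the term-list panel; any
#' display threshold is a rendering option, the counts are raw.
#'
#' @param texts Character vector of descriptions.
#' @param terms Nonempty character vector of terms.
#' @return Data frame with columns `term1`, `term2` (lexicographically
#'   ordered within a pair) and `count`.
#' @export
term_cooccurrence <- function(texts, terms) {
  if (!length(terms)) pc_usage_error("terms must be nonempty")
  terms <- sort(unique(terms))
  toks <- lapply(tokenize(texts), unique)
  presence <- vapply(terms, function(t)
    vapply(toks, function(tk) t %in% tk, logical(1)), logical(length(toks)))
  presence <- matrix(presence, nrow = length(toks), ncol = length(terms),
                     dimnames = list(NULL, terms))
  pairs <- utils::combn(terms, 2L)
  data.frame(
    term1 = pairs[1L, ], term2 = pairs[2L, ],
    count = apply(pairs, 2L, function(pr)
      sum(presence[, pr[1L]] & presence[, pr[2L]])),
    stringsAsFactors = FALSE
  )
}

#' Filter reactions and entities by a search phrase
#'
#' Case-insensitive substring match against names and descriptions. The
#' empty phrase matches nothing.
#'
#' @param p A `pc_pathway`.
#' @param phrase Search string.
#' @return List with character vectors `reactions` and `entities`.
#' @export
search_filter <- function(p, phrase) {
  if (!is.character(phrase) || length(phrase) != 1L)
    pc_usage_error("phrase must be a single string")
  if (!nzchar(phrase))
    return(list(reactions = character(), entities = character()))
  needle <- tolower(phrase)
  hit <- function(name, desc)
    grepl(needle, tolower(paste(name, desc)), fixed = TRUE)
  rids <- reaction_ids(p)[vapply(p$reactions, function(r)
    hit(r$name, r$description), logical(1))]
  eids <- entity_ids(p)[vapply(p$entities, function(e)
    hit(e$name, e$description), logical(1))]
  list(reactions = rids, entities = eids)
}
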