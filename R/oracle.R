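#' Brute-force reference matcher (test oracle)
#'
#' Decides whether one XML document satisfies a search query by direct
#' matching, without any XPath: the document is walked along the model's
#' structure tree, section texts are extracted and normalized, label regexes
#' are applied with PCRE lookaround boundaries, composite terms are checked
#' by counting intervening whitespace tokens, and the boolean expression is
#' evaluated in R.  It shares no code with the XPath compiler, so agreement
#' between [evaluate_query()] (compile + interpret route) and `oracle_match()`
#' (direct route) is a meaningful equivalence check.
#'
#' @param doc Path to an XML file, or an `xml2` document.
#' @param query A [search_query()] or query id in `model`.
#' @param model The owning [sox_model()].
#' @return `TRUE` iff the document satisfies the query.  A document with no
#'   matching sections satisfies a purely negated query (negation is
#'   "no such section matches", including when the section is absent).
#' @export
oracle_match <- function(doc, query, model) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  if (is.character(query)) query <- model$queries[[query]]
  if (is.null(query)) stop("unknown query", call. = FALSE)
  texts <- doc_section_texts(doc, model$structure)
  concept_holds <- function(cid) {
    cc <- model$concepts[[cid]]
    tm <- model_term(model, cc$term)
    secs <- texts[[cc$node]]
    if (is.null(secs) || !length(secs)) return(FALSE)
    if (inherits(tm, "sox_composite_term")) {
      for (s in secs) {
        if (composite_tokens_match(tm, model, tokenize(s))) return(TRUE)
      }
      FALSE
    } else {
      any(vapply(secs, function(s) simple_term_text_match(tm, s), TRUE))
    }
  }
  rec <- function(e) {
    switch(e$kind,
      ref = concept_holds(e$concept),
      not = !rec(e$arg),
      and = all(vapply(e$args, rec, TRUE)),
      or = any(vapply(e$args, rec, TRUE)))
  }
  rec(query$expr)
}

#' Evaluate a query on a corpus with the oracle
#'
#' Convenience wrapper applying [oracle_match()] to every document of a
#' corpus; the brute-force counterpart of [evaluate_query()].
#'
#' @inheritParams oracle_match
#' @param corpus A [corpus_open()] handle.
#' @return Character vector of matching doc_ids (lexicographic).
#' @export
oracle_evaluate <- function(corpus, query, model) {
  hits <- character(0)
  for (id in corpus$doc_ids) {
    ok <- tryCatch(oracle_match(corpus_doc_path(corpus, id), query, model),
                   error = function(e) FALSE)
    if (ok) hits <- c(hits, id)
  }
  hits
}
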