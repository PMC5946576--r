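# XPath 2.0 generation from a search model.
#
# Dialect notes: regex predicates use fn:matches on
# normalize-space(string(.)) of the section element, so the emitted strings
# need an XPath 2.0 processor (BaseX, eXist, Saxon); they deliberately avoid
# constructs absent from the XPath 2.0 regex flavour (no lookaround, no
# non-capturing groups, no inline flags).  Case-insensitivity is the global
# 'i' flag of fn:matches.  This package's own engine interprets exactly the
# emitted grammar (see eval.R).

xpath_word_gap <- function(d) paste0("(\\s[^\\s]+){0,", d, "}\\s")

xpath_string_literal <- function(x) {
  paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
}

#' Compile one term label to a regular expression
#'
#' Wraps the label pattern according to its flags: with `whole_word`, the
#' pattern is anchored on both sides at word boundaries, a boundary being the
#' text start/end or any character outside the word class `[\\wäöüÄÖÜß]`
#' (umlauts included because the XPath regex flavour has no lookaround and
#' PCRE's `\\w` is ASCII-only here).  Case-insensitivity is not rewritten into
#' the pattern; it is carried as the engine's `'i'` flag.
#'
#' @param label A [term_label()] or bare pattern string.
#' @return Regex string.
#' @export
compile_label <- function(label) {
  if (is.character(label)) label <- term_label(label)
  if (!nzchar(label$pattern)) stop("empty label pattern", call. = FALSE)
  if (!pattern_compiles(label$pattern)) {
    stop("label pattern does not compile: ", label$pattern, call. = FALSE)
  }
  if (!label$whole_word) return(label$pattern)
  wc <- word_class_chars
  paste0("(^|[^", wc, "])(", label$pattern, ")([^", wc, "]|$)")
}

# Location path of a node as prefixed XPath steps.  `pmap` from prefix_map().
xpath_steps <- function(path_df, pmap) {
  vapply(seq_len(nrow(path_df)), function(k) {
    ns <- path_df$namespace[k]
    if (!nzchar(ns)) return(path_df$local_name[k])
    pfx <- names(pmap)[match(ns, pmap)]
    if (is.na(pfx)) stop("namespace not in prefix map: ", ns, call. = FALSE)
    paste0(pfx, ":", path_df$local_name[k])
  }, "")
}

matches_call <- function(regex, case_sensitive) {
  flags <- if (case_sensitive) "" else ", 'i'"
  paste0("matches(normalize-space(string(.)), ",
         xpath_string_literal(regex), flags, ")")
}

exists_fragment <- function(rel_steps, match_disjuncts) {
  path <- if (length(rel_steps)) paste(rel_steps, collapse = "/") else "."
  paste0("exists(", path, "[", paste(match_disjuncts, collapse = " or "), "])")
}

new_predicate <- function(fragment, concept_id, polarity = "positive") {
  structure(list(xpath_fragment = fragment, concept_id = concept_id,
                 polarity = polarity), class = "sox_predicate")
}

#' Compile a simple term bound to a structure node
#'
#' Emits an existential XPath predicate that is true for a document iff at
#' least one element at the node's location path has a normalized string
#' value matching at least one of the term's labels; one `matches()` disjunct
#' per label, in label order.
#'
#' @param term A [simple_term()] (or its id within `model`).
#' @param node A structure node id.
#' @param model The owning [sox_model()].
#' @param concept_id Concept id recorded on the predicate (optional).
#' @return A `sox_predicate` with fields `xpath_fragment`, `concept_id`,
#'   `polarity`.
#' @export
compile_simple_term <- function(term, node, model, concept_id = NA_character_) {
  if (is.character(term)) term <- model$simple_terms[[term]]
  if (is.null(term) || !length(term$labels)) {
    stop("simple term has no labels", call. = FALSE)
  }
  pmap <- prefix_map(model$structure)
  steps <- xpath_steps(resolve_path(model, node), pmap)
  disjuncts <- vapply(term$labels, function(l) {
    matches_call(compile_label(l), l$case_sensitive)
  }, "")
  new_predicate(exists_fragment(steps[-1L], disjuncts), concept_id)
}

# Proximity regex for an ordered sequence of labels: consecutive labels are
# joined by the token-counting gap template; outer word boundaries come from
# the first/last label's whole_word flag (inner boundaries are implied by the
# gap's whitespace).
composite_regex <- function(labels, d) {
  wc <- word_class_chars
  core <- paste(vapply(labels, function(l) l$pattern, ""),
                collapse = xpath_word_gap(d))
  pre <- if (labels[[1L]]$whole_word) paste0("(^|[^", wc, "])") else ""
  post <- if (labels[[length(labels)]]$whole_word) paste0("([^", wc, "]|$)") else ""
  paste0(pre, core, post)
}

# All label tuples of a composite: one label picked per part, part-1 index
# most significant (tuple order lexicographic over part indices), plus the
# reversed part order when unordered.
composite_alternatives <- function(term, model) {
  parts <- lapply(term$parts, function(p) model$simple_terms[[p]])
  if (any(vapply(parts, is.null, TRUE))) {
    stop("composite term '", term$id, "' has unresolved parts", call. = FALSE)
  }
  orders <- list(seq_along(parts))
  if (!term$ordered && length(parts) > 1L) {
    orders <- c(orders, list(rev(seq_along(parts))))
  }
  out <- list()
  for (ord in orders) {
    seqs <- parts[ord]
    counts <- vapply(seqs, function(p) length(p$labels), 1L)
    idx <- rep(1L, length(seqs))
    repeat {
      out[[length(out) + 1L]] <- lapply(seq_along(seqs), function(k) {
        seqs[[k]]$labels[[idx[k]]]
      })
      k <- length(seqs)
      repeat {
        idx[k] <- idx[k] + 1L
        if (idx[k] <= counts[k]) break
        idx[k] <- 1L
        k <- k - 1L
        if (k == 0L) break
      }
      if (k == 0L) break
    }
  }
  out
}

#' Compile a composite (proximity) term bound to a structure node
#'
#' For every tuple in the cross product of the parts' label sets (and for
#' both part orders when the term is unordered), one proximity regex joins
#' consecutive labels with the gap template `(\\s[^\\s]+){0,d}\\s`, `d` the
#' term's `max_distance`: between consecutive part matches, at most `d`
#' whole whitespace-delimited tokens may intervene; `d = 0` means the next
#' part starts on the immediately following word.  The predicate is the
#' disjunction over all alternatives, existentially over section elements.
#'
#' @inheritParams compile_simple_term
#' @param term A [composite_term()] (or its id within `model`).
#' @return A `sox_predicate`.
#' @export
compile_composite_term <- function(term, node, model,
                                   concept_id = NA_character_) {
  if (is.character(term)) term <- model$composite_terms[[term]]
  alts <- composite_alternatives(term, model)
  cs <- vapply(alts[[1L]], function(l) l$case_sensitive, TRUE)[1L]
  pmap <- prefix_map(model$structure)
  steps <- xpath_steps(resolve_path(model, node), pmap)
  disjuncts <- vapply(alts, function(labels) {
    matches_call(composite_regex(labels, term$max_distance), cs)
  }, "")
  new_predicate(exists_fragment(steps[-1L], disjuncts), concept_id)
}

compile_concept <- function(concept_id, model) {
  cc <- model$concepts[[concept_id]]
  if (is.null(cc)) stop("unknown concept: ", concept_id, call. = FALSE)
  tm <- model_term(model, cc$term)
  if (is.null(tm)) stop("concept '", concept_id, "' has unresolved term",
                        call. = FALSE)
  if (inherits(tm, "sox_composite_term")) {
    compile_composite_term(tm, cc$node, model, concept_id = concept_id)
  } else {
    compile_simple_term(tm, cc$node, model, concept_id = concept_id)
  }
}

#' Compile a search query to one XPath expression
#'
#' Maps the boolean expression tree homomorphically: concept references
#' become their existential predicates, `and`/`or` become parenthesised XPath
#' `and`/`or`, `not` becomes `not(...)`.  The result selects document root
#' elements of matching documents.  Output is a pure function of
#' (query, model): label order and tuple order are fixed, so identical input
#' gives an identical string.
#'
#' @param query A [search_query()] or query id.
#' @param model A validated [sox_model()].
#' @return A `sox_compiled_query` with fields `query_id`, `xpath`,
#'   `prefix_map`.
#' @export
compile_query <- function(query, model) {
  if (is.character(query)) query <- model$queries[[query]]
  if (is.null(query)) stop("unknown query", call. = FALSE)
  rec <- function(e) {
    switch(e$kind,
      ref = compile_concept(e$concept, model)$xpath_fragment,
      not = paste0("not(", rec(e$arg), ")"),
      and = ,
      or = paste0("(", paste(vapply(e$args, rec, ""),
                             collapse = paste0(" ", e$kind, " ")), ")"))
  }
  pmap <- prefix_map(model$structure)
  root_step <- xpath_steps(resolve_path(model, model$structure$root), pmap)
  xp <- paste0("/", root_step, "[", rec(query$expr), "]")
  structure(list(query_id = query$id, xpath = xp, prefix_map = pmap),
            class = "sox_compiled_query")
}

#' @export
print.sox_compiled_query <- function(x, ...) {
  cat("<sox_compiled_query> ", x$query_id, "\n  ", x$xpath, "\n", sep = "")
  if (length(x$prefix_map)) {
    cat("  prefixes: ",
        paste(names(x$prefix_map), x$prefix_map, sep = "=", collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Compile every query of a model
#'
#' @param model A validated [sox_model()].
#' @return Named list of `sox_compiled_query`, one per query, in model order.
#' @export
compile_model <- function(model) {
  out <- lapply(model$queries, compile_query, model = model)
  stats::setNames(out, names(model$queries))
}

#' Write compiled XPaths back into the model file
#'
#' Fills each query's `xpath` annotation and writes the model: in the native
#' YAML format, or -- when the model was loaded from OWL -- as OWL with an
#' `xpath` annotation property on each Search_Query (previous annotations are
#' overwritten).
#'
#' @param model A [sox_model()].
#' @param compiled List of `sox_compiled_query` (e.g. from [compile_model()]).
#' @param out Output file path.
#' @return `out`, invisibly.
#' @export
annotate_model <- function(model, compiled, out) {
  if (inherits(compiled, "sox_compiled_query")) compiled <- list(compiled)
  xpaths <- list()
  for (cq in compiled) {
    if (is.null(model$queries[[cq$query_id]])) {
      stop("unknown query id: ", cq$query_id, call. = FALSE)
    }
    xpaths[[cq$query_id]] <- cq$xpath
  }
  if (!is.null(attr(model, "owl_source"))) {
    return(annotate_owl_model(model, xpaths, out))
  }
  for (qid in names(xpaths)) {
    model$queries[[qid]]$xpath_annotation <- xpaths[[qid]]
  }
  save_model(model, out)
}

#' Export compiled queries as a plain-text XPath listing
#'
#' One XPath per line, each preceded by a header comment line naming the
#' query id; the shared prefix map is written as JSON alongside
#' (`<path>.prefixes.json`).
#'
#' @param compiled List of `sox_compiled_query`.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_xpath_listing <- function(compiled, path) {
  if (inherits(compiled, "sox_compiled_query")) compiled <- list(compiled)
  lines <- unlist(lapply(compiled, function(cq) {
    c(paste0("# ", cq$query_id), cq$xpath)
  }))
  writeLines(lines, path, useBytes = TRUE)
  pmap <- if (length(compiled)) compiled[[1L]]$prefix_map else character(0)
  jsonlite::write_json(as.list(pmap), paste0(path, ".prefixes.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read/write a compiled query as JSON
#'
#' The interchange form `{query_id, xpath, prefix_map}` used by the
#' command-line interface.
#'
#' @param compiled A `sox_compiled_query`.
#' @param path JSON file path.
#' @return `write_compiled_query()`: `path`, invisibly.
#'   `read_compiled_query()`: a `sox_compiled_query`.
#' @export
write_compiled_query <- function(compiled, path) {
  jsonlite::write_json(
    list(query_id = compiled$query_id, xpath = compiled$xpath,
         prefix_map = as.list(compiled$prefix_map)),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_compiled_query
#' @export
read_compiled_query <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(query_id = x$query_id, xpath = x$xpath,
                 prefix_map = unlist(x$prefix_map)),
            class = "sox_compiled_query")
}
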