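#' Term label
#'
#' A label carries one regular expression over words (PCRE/XPath-2.0 common
#' subset), e.g. a German word stem such as `"florid(\\w)*"`, plus matching
#' flags.  `whole_word` anchors the pattern at word boundaries (boundary =
#' text start/end or any character outside the word class
#' `[\\wäöüÄÖÜß]`); `case_sensitive`
#' controls the engine's case flag.
#'
#' @param pattern Non-empty regex string.
#' @param case_sensitive,whole_word Logical flags, default `TRUE`.
#' @return A list of class `sox_label`.
#' @export
term_label <- function(pattern, case_sensitive = TRUE, whole_word = TRUE) {
  out <- list(pattern = as.character(pattern),
              case_sensitive = isTRUE(case_sensitive),
              whole_word = isTRUE(whole_word))
  class(out) <- "sox_label"
  out
}

#' Simple search term
#'
#' An atomic search term: a set of labels (writing variations, synonyms,
#' abbreviations) any one of which counts as a match.
#'
#' @param id Term identifier.
#' @param labels List of [term_label()]s; bare strings are promoted with
#'   default flags.  Duplicates (same pattern + flags) are dropped.
#' @return A list of class `sox_simple_term`.
#' @export
simple_term <- function(id, labels) {
  labels <- lapply(labels, function(l) {
    if (inherits(l, "sox_label")) l else term_label(l)
  })
  key <- vapply(labels, function(l) {
    paste(l$pattern, l$case_sensitive, l$whole_word, sep = "\r")
  }, "")
  labels <- labels[!duplicated(key)]
  out <- list(id = as.character(id), labels = labels)
  class(out) <- "sox_simple_term"
  out
}

#' Composite search term
#'
#' A proximity phrase: an ordered list of simple-term references whose matches
#' must occur within `max_distance` intervening words of each other.
#' `max_distance = 0` means one word immediately follows the other.  With
#' `ordered = FALSE` (default) both part orders are accepted.
#'
#' @param id Term identifier.
#' @param parts Character vector (length >= 2) of simple-term ids.
#' @param max_distance Non-negative integer word gap bound; required.
#' @param ordered Logical; must parts appear in the given order?
#' @return A list of class `sox_composite_term`.
#' @export
composite_term <- function(id, parts, max_distance, ordered = FALSE) {
  if (missing(max_distance) || is.null(max_distance)) {
    stop("composite term '", id, "' has no max_distance", call. = FALSE)
  }
  out <- list(id = as.character(id), parts = as.character(parts),
              max_distance = as.integer(max_distance),
              ordered = isTRUE(ordered))
  class(out) <- "sox_composite_term"
  out
}

#' Search concept
#'
#' Binds exactly one search term to exactly one structure node (the `in`
#' relation): the concept holds for a document when at least one element at
#' that node's location path matches the term.
#'
#' @param id Concept identifier.
#' @param term Id of a simple or composite term.
#' @param node Id of a structure node.
#' @return A list of class `sox_concept`.
#' @export
search_concept <- function(id, term, node) {
  out <- list(id = as.character(id), term = as.character(term),
              node = as.character(node))
  class(out) <- "sox_concept"
  out
}

#' Boolean query expressions
#'
#' Constructors for the boolean expression tree over search concepts that a
#' search query compiles: `sox_ref(id)` references a concept, `sox_and()` /
#' `sox_or()` take two or more sub-expressions, `sox_not()` one.
#'
#' @param id Concept id (for `sox_ref`).
#' @param ... Sub-expressions (for `sox_and` / `sox_or`).
#' @param x Sub-expression (for `sox_not`).
#' @return A list of class `sox_expr`.
#' @export
sox_ref <- function(id) {
  structure(list(kind = "ref", concept = as.character(id)),
            class = "sox_expr")
}

#' @rdname sox_ref
#' @export
sox_and <- function(...) {
  structure(list(kind = "and", args = list(...)), class = "sox_expr")
}

#' @rdname sox_ref
#' @export
sox_or <- function(...) {
  structure(list(kind = "or", args = list(...)), class = "sox_expr")
}

#' @rdname sox_ref
#' @export
sox_not <- function(x) {
  structure(list(kind = "not", arg = x), class = "sox_expr")
}

#' Search query
#'
#' A named boolean combination of search concepts; the unit of XPath
#' generation.
#'
#' @param id Query identifier.
#' @param expr A [sox_ref()]/[sox_and()]/[sox_or()]/[sox_not()] expression.
#' @param xpath_annotation Optional compiled XPath string (filled by
#'   [annotate_model()]).
#' @return A list of class `sox_query`.
#' @export
search_query <- function(id, expr, xpath_annotation = NULL) {
  out <- list(id = as.character(id), expr = expr,
              xpath_annotation = xpath_annotation)
  class(out) <- "sox_query"
  out
}

#' Assemble a search model
#'
#' Collects the structure tree, terms, concepts and queries into one model
#' object.  Construction is deliberately lenient: broken cross-references or
#' invariant violations are reported by [validate_model()], not here, so that
#' diagnostic tooling can load and inspect faulty models.
#'
#' @param structure A [structure_tree()].
#' @param simple_terms,composite_terms,concepts,queries Lists of the
#'   respective objects (named by id or not; they are re-keyed by id).
#' @return A list of class `sox_model`.
#' @export
sox_model <- function(structure, simple_terms = list(),
                      composite_terms = list(), concepts = list(),
                      queries = list()) {
  key_by_id <- function(xs) {
    stats::setNames(xs, vapply(xs, function(x) x$id, ""))
  }
  out <- list(structure = structure,
              simple_terms = key_by_id(simple_terms),
              composite_terms = key_by_id(composite_terms),
              concepts = key_by_id(concepts),
              queries = key_by_id(queries))
  class(out) <- "sox_model"
  out
}

#' @export
print.sox_model <- function(x, ...) {
  cat("<sox_model>\n",
      "  structure nodes : ", length(x$structure$nodes), "\n",
      "  simple terms    : ", length(x$simple_terms), "\n",
      "  composite terms : ", length(x$composite_terms), "\n",
      "  concepts        : ", length(x$concepts), "\n",
      "  queries         : ", paste(names(x$queries), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Look up a term (simple or composite) by id; NULL when absent.
model_term <- function(model, id) {
  if (!is.null(model$simple_terms[[id]])) return(model$simple_terms[[id]])
  model$composite_terms[[id]]
}

# Concept ids appearing in an expression, with the polarity they occur under.
# Returns data.frame(concept, positive).
expr_concepts <- function(expr, positive = TRUE) {
  switch(expr$kind,
    ref = data.frame(concept = expr$concept, positive = positive,
                     stringsAsFactors = FALSE),
    not = expr_concepts(expr$arg, !positive),
    {
      do.call(rbind, lapply(expr$args, expr_concepts, positive = positive))
    })
}

# Positive concept ids of a query expression (occurring under even negation).
positive_concepts <- function(expr) {
  df <- expr_concepts(expr)
  unique(df$concept[df$positive])
}

word_class_chars <- "\\wäöüÄÖÜß"

# Does a pattern compile under PCRE?  Used by validation and load.
pattern_compiles <- function(pattern) {
  ok <- tryCatch({
    grepl(pattern, "", perl = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  isTRUE(ok)
}

#' Validate a search model
#'
#' Checks every model invariant and returns machine-readable diagnostics
#' instead of raising: tree shape (single root, acyclic, unique sibling
#' names), label presence and regex validity, composite arity and
#' max_distance, reference resolution of concepts and query expressions, and
#' global id uniqueness.  An empty result means the model is sound and every
#' other operation in the package will accept it.
#'
#' @param model A [sox_model()].
#' @return A data.frame with columns `code`, `id`, `message`; zero rows when
#'   the model is valid.
#' @export
validate_model <- function(model) {
  diags <- list()
  bad <- function(code, id, message) {
    diags[[length(diags) + 1L]] <<- data.frame(
      code = code, id = id, message = message, stringsAsFactors = FALSE)
  }

  tree <- model$structure
  ids <- names(tree$nodes)

  # tree shape: every non-root has a parent that lists it as child; no cycles;
  # all reachable from root
  if (is.null(tree$nodes[[tree$root]])) {
    bad("structure_no_root", tree$root, "declared root is not a node")
  } else {
    roots <- ids[vapply(tree$nodes, function(n) is.na(n$parent), TRUE)]
    if (length(roots) != 1L || roots != tree$root) {
      bad("structure_multiple_roots", paste(roots, collapse = ","),
          "exactly one parentless node (the root) is required")
    }
    reach <- structure_preorder(tree)
    unreach <- setdiff(ids, reach)
    for (u in unreach) {
      bad("structure_not_tree", u, "node not reachable from root (cycle or detached)")
    }
    for (id in ids) {
      nd <- tree$nodes[[id]]
      for (ch in nd$children) {
        cn <- tree$nodes[[ch]]
        if (is.null(cn)) {
          bad("structure_dangling_child", id, paste0("unknown child '", ch, "'"))
        } else if (!identical(cn$parent, id)) {
          bad("structure_not_tree", ch, "child/parent links disagree")
        }
      }
      key <- vapply(nd$children, function(ch) {
        cn <- tree$nodes[[ch]]
        if (is.null(cn)) "" else paste(cn$namespace, cn$local_name, sep = "\r")
      }, "")
      if (anyDuplicated(key[nzchar(key)])) {
        bad("structure_duplicate_sibling", id,
            "sibling (namespace, local_name) pairs must be unique")
      }
    }
  }

  for (tm in model$simple_terms) {
    if (!length(tm$labels)) {
      bad("term_no_labels", tm$id, "simple term needs at least one label")
    }
    for (lb in tm$labels) {
      if (!nzchar(lb$pattern)) {
        bad("label_empty", tm$id, "empty label pattern")
      } else if (!pattern_compiles(lb$pattern)) {
        bad("label_invalid", tm$id,
            paste0("pattern does not compile: ", lb$pattern))
      }
    }
  }

  for (tm in model$composite_terms) {
    if (length(tm$parts) < 2L) {
      bad("composite_arity", tm$id, "composite term needs >= 2 parts")
    }
    if (is.na(tm$max_distance) || tm$max_distance < 0L) {
      bad("composite_distance", tm$id, "max_distance must be >= 0")
    }
    cs <- logical(0)
    for (p in tm$parts) {
      pt <- model$simple_terms[[p]]
      if (is.null(pt)) {
        if (!is.null(model$composite_terms[[p]])) {
          bad("composite_nested", tm$id,
              paste0("part '", p, "' is a composite term; parts must be simple"))
        } else {
          bad("composite_dangling_part", tm$id, paste0("unknown part '", p, "'"))
        }
      } else {
        cs <- c(cs, vapply(pt$labels, function(l) l$case_sensitive, TRUE))
        for (lb in pt$labels) {
          if (grepl("\\s|\\\\s", lb$pattern)) {
            bad("composite_part_whitespace", tm$id,
                paste0("part '", p, "' label may match whitespace; ",
                       "proximity parts must be single-word patterns"))
          }
        }
      }
    }
    if (length(unique(cs)) > 1L) {
      bad("composite_mixed_case_flags", tm$id,
          "all parts of a composite must share the case_sensitive flag")
    }
  }

  for (cc in model$concepts) {
    if (is.null(model_term(model, cc$term))) {
      bad("concept_dangling_term", cc$id, paste0("unknown term '", cc$term, "'"))
    }
    if (is.null(model$structure$nodes[[cc$node]])) {
      bad("concept_dangling_node", cc$id, paste0("unknown node '", cc$node, "'"))
    }
  }

  check_expr <- function(qid, e) {
    if (!is.list(e) || is.null(e$kind)) {
      bad("expr_malformed", qid, "expression node is not a sox_expr")
      return(invisible(NULL))
    }
    switch(e$kind,
      ref = {
        if (is.null(model$concepts[[e$concept]])) {
          bad("expr_dangling_concept", qid,
              paste0("unknown concept '", e$concept, "'"))
        }
      },
      not = check_expr(qid, e$arg),
      and = ,
      or = {
        if (length(e$args) < 2L) {
          bad("expr_arity", qid, paste0("'", e$kind, "' needs >= 2 operands"))
        }
        for (a in e$args) check_expr(qid, a)
      },
      bad("expr_malformed", qid, paste0("unknown operator '", e$kind, "'")))
    invisible(NULL)
  }
  for (q in model$queries) check_expr(q$id, q$expr)

  all_ids <- c(names(tree$nodes), names(model$simple_terms),
               names(model$composite_terms), names(model$concepts),
               names(model$queries))
  dup <- unique(all_ids[duplicated(all_ids)])
  for (d in dup) bad("id_collision", d, "id used by more than one entity")

  if (!length(diags)) {
    return(data.frame(code = character(0), id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, diags)
}
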