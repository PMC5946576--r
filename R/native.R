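# Native declarative model format (YAML).
#
# Layout:
#   structure:        nested {name, namespace, id?, children: [...]}
#   simple_terms:     id -> [ {pattern, case_sensitive?, whole_word?} | "pattern" ]
#   composite_terms:  id -> {parts: [...], max_distance, ordered?}
#   concepts:         id -> {term, node}
#   queries:          id -> {expr: <prefix s-expression>, xpath?}
#
# The boolean expression syntax is a small prefix s-expression over YAML
# lists: ["and", "c1", ["not", "c2"], ["or", "c3", "c4"]]; a bare string is a
# concept reference.  "and"/"or"/"not" are reserved words and cannot name
# concepts referenced inside expressions.

parse_native_structure <- function(x) {
  build <- function(nd) {
    if (is.null(nd$name)) stop("structure node without 'name'", call. = FALSE)
    kids <- lapply(nd$children %||% list(), build)
    structure_node(local_name = nd$name,
                   namespace = nd$namespace %||% "",
                   id = nd$id %||% nd$name,
                   children = kids)
  }
  structure_tree(build(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_expr_sexp <- function(x) {
  # yaml gives either a character vector (homogeneous list) or a list
  if (is.character(x) && length(x) == 1L) return(sox_ref(x))
  if (is.character(x)) x <- as.list(x)
  if (!is.list(x) || !length(x)) {
    stop("malformed query expression", call. = FALSE)
  }
  head <- x[[1L]]
  if (!is.character(head)) stop("malformed query expression", call. = FALSE)
  rest <- lapply(x[-1L], parse_expr_sexp)
  switch(head,
    and = structure(list(kind = "and", args = rest), class = "sox_expr"),
    or  = structure(list(kind = "or", args = rest), class = "sox_expr"),
    not = {
      if (length(rest) != 1L) stop("'not' takes one operand", call. = FALSE)
      structure(list(kind = "not", arg = rest[[1L]]), class = "sox_expr")
    },
    {
      if (length(x) != 1L) {
        stop("unknown operator '", head, "' in query expression",
             call. = FALSE)
      }
      sox_ref(head)
    })
}

expr_to_sexp <- function(e) {
  switch(e$kind,
    ref = e$concept,
    not = list("not", expr_to_sexp(e$arg)),
    c(list(e$kind), lapply(e$args, expr_to_sexp)))
}

load_native_model <- function(path) {
  doc <- yaml::yaml.load_file(path)
  if (is.null(doc$structure)) stop("native model lacks 'structure'", call. = FALSE)
  tree <- parse_native_structure(doc$structure)

  sts <- list()
  for (id in names(doc$simple_terms %||% list())) {
    raw <- doc$simple_terms[[id]]
    if (is.character(raw)) raw <- as.list(raw)
    labels <- lapply(raw, function(l) {
      if (is.character(l)) return(term_label(l))
      if (is.null(l$pattern)) {
        stop("label without 'pattern' in simple term '", id, "'", call. = FALSE)
      }
      term_label(l$pattern,
                 case_sensitive = l$case_sensitive %||% TRUE,
                 whole_word = l$whole_word %||% TRUE)
    })
    if (!length(labels)) {
      stop("simple term '", id, "' has no labels", call. = FALSE)
    }
    sts[[id]] <- simple_term(id, labels)
  }

  cts <- list()
  for (id in names(doc$composite_terms %||% list())) {
    raw <- doc$composite_terms[[id]]
    if (is.null(raw$max_distance)) {
      stop("composite term '", id, "' has no max_distance", call. = FALSE)
    }
    cts[[id]] <- composite_term(id, parts = unlist(raw$parts),
                                max_distance = raw$max_distance,
                                ordered = raw$ordered %||% FALSE)
  }

  ccs <- list()
  for (id in names(doc$concepts %||% list())) {
    raw <- doc$concepts[[id]]
    if (is.null(raw$term) || is.null(raw$node)) {
      stop("concept '", id, "' needs 'term' and 'node'", call. = FALSE)
    }
    ccs[[id]] <- search_concept(id, term = raw$term, node = raw$node)
  }

  qs <- list()
  for (id in names(doc$queries %||% list())) {
    raw <- doc$queries[[id]]
    ex <- if (!is.null(raw$expr)) raw$expr else raw
    qs[[id]] <- search_query(id, parse_expr_sexp(ex),
                             xpath_annotation = raw$xpath %||% NULL)
  }

  sox_model(tree, simple_terms = sts, composite_terms = cts,
            concepts = ccs, queries = qs)
}

structure_to_native <- function(tree) {
  rec <- function(id) {
    nd <- tree$nodes[[id]]
    out <- list(name = nd$local_name)
    if (nzchar(nd$namespace)) out$namespace <- nd$namespace
    if (!identical(nd$id, nd$local_name)) out$id <- nd$id
    if (length(nd$children)) out$children <- lapply(nd$children, rec)
    out
  }
  rec(tree$root)
}

#' Write a search model in the native YAML format
#'
#' Serialises a model (including any XPath annotations on its queries) so that
#' `load_model(path, "native")` returns a structurally identical model:
#' load -> save -> load is a fixed point.
#'
#' @param model A [sox_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  doc <- list(structure = structure_to_native(model$structure))
  if (length(model$simple_terms)) {
    doc$simple_terms <- lapply(model$simple_terms, function(tm) {
      lapply(tm$labels, function(l) {
        list(pattern = l$pattern, case_sensitive = l$case_sensitive,
             whole_word = l$whole_word)
      })
    })
  }
  if (length(model$composite_terms)) {
    doc$composite_terms <- lapply(model$composite_terms, function(tm) {
      list(parts = as.list(tm$parts), max_distance = tm$max_distance,
           ordered = tm$ordered)
    })
  }
  if (length(model$concepts)) {
    doc$concepts <- lapply(model$concepts, function(cc) {
      list(term = cc$term, node = cc$node)
    })
  }
  if (length(model$queries)) {
    doc$queries <- lapply(model$queries, function(q) {
      out <- list(expr = expr_to_sexp(q$expr))
      if (!is.null(q$xpath_annotation)) out$xpath <- q$xpath_annotation
      out
    })
  }
  txt <- yaml::as.yaml(doc, indent.mapping.sequence = TRUE)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' Load a search model
#'
#' Reads a model from the native YAML format or from OWL (RDF/XML `.owl` /
#' `.rdf`, or Turtle `.ttl`).  OWL reading interprets `someValuesFrom`
#' restrictions on the `described_by` and `in` properties, `has_part`
#' assertions, `max_distance` data properties, `rdfs:label` values on term
#' instances and boolean class expressions
#' (`intersectionOf`/`unionOf`/`complementOf`) on search queries; upper-level
#' ontology classes are accepted and ignored beyond typing.
#'
#' @param path Model file.
#' @param format `"native"` or `"owl"`; the default guesses from the file
#'   extension (`.yaml`/`.yml` native, `.owl`/`.rdf`/`.xml`/`.ttl` OWL).
#' @param validate Stop with the diagnostic listing when [validate_model()]
#'   reports problems (default `TRUE`).
#' @param iri_config Vocabulary IRI local names for OWL reading; see
#'   [sox_iri_config()].
#' @return A [sox_model()].
#' @export
load_model <- function(path, format = c("auto", "native", "owl"),
                       validate = TRUE, iri_config = sox_iri_config()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such model file: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("yaml", "yml")) "native" else "owl"
  }
  model <- if (format == "native") {
    load_native_model(path)
  } else {
    load_owl_model(path, iri_config = iri_config)
  }
  if (validate) {
    d <- validate_model(model)
    if (nrow(d)) {
      stop("invalid model '", path, "':\n",
           paste0("  [", d$code, "] ", d$id, ": ", d$message, collapse = "\n"),
           call. = FALSE)
    }
  }
  model
}
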