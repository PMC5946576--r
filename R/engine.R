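# Query execution against a directory corpus of XML documents.  A corpus is
# a plain directory of <doc_id>.xml files; compiled XPaths stay portable to
# XML database servers, but no server is required here.

#' Open a directory corpus
#'
#' @param root_dir Directory containing `<doc_id>.xml` files.
#' @param prefix_map Namespace prefix map shared with compilation; defaults
#'   to the compiled query's own map at evaluation time.
#' @return A list of class `sox_corpus` with `root_dir`, sorted `doc_ids`,
#'   `prefix_map`.
#' @export
corpus_open <- function(root_dir, prefix_map = NULL) {
  if (!dir.exists(root_dir)) stop("no such corpus directory: ", root_dir,
                                  call. = FALSE)
  files <- list.files(root_dir, pattern = "\\.xml$")
  ids <- sort(tools::file_path_sans_ext(files))
  structure(list(root_dir = root_dir, doc_ids = ids, prefix_map = prefix_map),
            class = "sox_corpus")
}

#' @export
print.sox_corpus <- function(x, ...) {
  cat("<sox_corpus> ", length(x$doc_ids), " documents in ", x$root_dir, "\n",
      sep = "")
  invisible(x)
}

corpus_doc_path <- function(corpus, doc_id) {
  file.path(corpus$root_dir, paste0(doc_id, ".xml"))
}

#' Evaluate a compiled query on a corpus
#'
#' Returns exactly the doc_ids of documents whose root satisfies the
#' compiled XPath, in lexicographic order.  Malformed XML files are skipped
#' and reported in the `errors` attribute (a data.frame of doc_id/message)
#' rather than aborting the run.
#'
#' @param corpus A [corpus_open()] handle.
#' @param compiled A `sox_compiled_query` (from [compile_query()] or
#'   [read_compiled_query()]).
#' @return Character vector of matching doc_ids with attribute `errors`.
#' @export
evaluate_query <- function(corpus, compiled) {
  parsed <- parse_compiled_xpath(compiled$xpath)
  pmap <- corpus$prefix_map %||% compiled$prefix_map
  hits <- character(0)
  errs <- list()
  for (id in corpus$doc_ids) {
    doc <- tryCatch(xml2::read_xml(corpus_doc_path(corpus, id)),
                    error = function(e) e)
    if (inherits(doc, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(doc_id = id,
                                              message = conditionMessage(doc),
                                              stringsAsFactors = FALSE)
      next
    }
    if (eval_compiled_on_doc(parsed, doc, pmap)) hits <- c(hits, id)
  }
  errors <- if (length(errs)) {
    do.call(rbind, errs)
  } else {
    data.frame(doc_id = character(0), message = character(0),
               stringsAsFactors = FALSE)
  }
  structure(hits, errors = errors)
}

# Element namespace URI + local name, via the document's namespace map.
element_ns_local <- function(el, nsmap) {
  full <- xml2::xml_name(el, ns = nsmap)
  local <- xml2::xml_name(el)
  if (identical(full, local)) return(c(ns = "", local = local))
  pfx <- sub(":.*$", "", full)
  ns <- if (pfx %in% names(nsmap)) unname(nsmap[pfx]) else ""
  c(ns = ns, local = local)
}

# Walk a document along the structure tree; returns node_id -> list of xml
# elements sitting at that node's location path.
doc_section_elements <- function(doc, tree) {
  nsmap <- tryCatch(xml2::xml_ns(doc), error = function(e) character(0))
  out <- list()
  root_el <- xml2::xml_root(doc)
  root_nd <- tree$nodes[[tree$root]]
  nl <- element_ns_local(root_el, nsmap)
  if (!identical(unname(nl["local"]), root_nd$local_name) ||
      !identical(unname(nl["ns"]), root_nd$namespace)) {
    return(out)
  }
  rec <- function(el, node_id) {
    out[[node_id]] <<- c(out[[node_id]], list(el))
    nd <- tree$nodes[[node_id]]
    if (!length(nd$children)) return(invisible(NULL))
    for (ch_el in xml2::xml_children(el)) {
      cnl <- element_ns_local(ch_el, nsmap)
      for (ch_id in nd$children) {
        cn <- tree$nodes[[ch_id]]
        if (identical(unname(cnl["local"]), cn$local_name) &&
            identical(unname(cnl["ns"]), cn$namespace)) {
          rec(ch_el, ch_id)
        }
      }
    }
    invisible(NULL)
  }
  rec(root_el, tree$root)
  out
}

# Normalized string values per structure node id.
doc_section_texts <- function(doc, tree) {
  els <- doc_section_elements(doc, tree)
  lapply(els, function(xs) {
    vapply(xs, function(e) normalize_space(xml2::xml_text(e)), "")
  })
}

#' Fetch reviewable snippets for a query's matches
#'
#' For every matching document, emits one snippet record per section element
#' positively matched by each positive (non-negated) concept of the query.
#' Records carry the document id, the section location path and 1-based
#' element ordinal, the normalized section text, and the character spans the
#' term labels matched.  Records are written as JSON Lines
#' (`<query_id>_snippets.jsonl`) and each section's raw XML fragment is
#' saved under `out_dir/<doc_id>/<section_index>.xml` for manual review.
#'
#' @param corpus A [corpus_open()] handle.
#' @param compiled The compiled query to run.
#' @param model The [sox_model()] the query came from.
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing.
#' @return List of snippet records (class `sox_snippet`), invisibly returns
#'   the same.
#' @export
fetch_snippets <- function(corpus, compiled, model, out_dir = NULL) {
  hits <- evaluate_query(corpus, compiled)
  query <- model$queries[[compiled$query_id]]
  if (is.null(query)) stop("query not in model: ", compiled$query_id,
                           call. = FALSE)
  pos <- positive_concepts(query$expr)
  pmap <- prefix_map(model$structure)
  records <- list()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  for (id in hits) {
    doc <- xml2::read_xml(corpus_doc_path(corpus, id))
    els <- doc_section_elements(doc, model$structure)
    for (cid in pos) {
      cc <- model$concepts[[cid]]
      tm <- model_term(model, cc$term)
      sec_els <- els[[cc$node]]
      if (is.null(sec_els)) next
      path_str <- paste(xpath_steps(resolve_path(model, cc$node), pmap),
                        collapse = "/")
      for (k in seq_along(sec_els)) {
        text <- normalize_space(xml2::xml_text(sec_els[[k]]))
        spans <- term_match_spans(tm, text, model)
        if (!nrow(spans)) next
        rec <- structure(list(doc_id = id, query_id = compiled$query_id,
                              concept_id = cid, section_path = path_str,
                              section_index = k, text = text,
                              matched_spans = spans),
                         class = "sox_snippet")
        records[[length(records) + 1L]] <- rec
        if (!is.null(out_dir)) {
          ddir <- file.path(out_dir, id)
          dir.create(ddir, showWarnings = FALSE)
          writeLines(as.character(sec_els[[k]]),
                     file.path(ddir, paste0(k, ".xml")), useBytes = TRUE)
        }
      }
    }
  }
  if (!is.null(out_dir)) {
    con <- file(file.path(out_dir, paste0(compiled$query_id,
                                          "_snippets.jsonl")),
                open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (rec in records) {
      writeLines(jsonlite::toJSON(list(
        doc_id = rec$doc_id, query_id = rec$query_id,
        concept_id = rec$concept_id, section_path = rec$section_path,
        section_index = rec$section_index, text = rec$text,
        matched_spans = rec$matched_spans), auto_unbox = TRUE,
        dataframe = "rows"), con)
    }
  }
  records
}
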