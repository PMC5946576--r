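#' Shipped five-question pathology model
#'
#' Loads the packaged native-format model encoding the five research
#' questions (seven query variants: with/without residual tissue for the
#' capsule question, numerator/denominator for the Barrett question).
#'
#' @return A validated [sox_model()].
#' @export
pathology_questions_model <- function() {
  load_model(system.file("extdata", "pathology_questions.yaml",
                         package = "soxpath"),
             format = "native")
}

#' Write a single synthetic report document
#'
#' Convenience writer for targeted fixtures: builds one well-formed XML
#' report for the given structure tree from a named list of leaf-section
#' texts (missing names mean the section is omitted).
#'
#' @param path Output file.
#' @param tree A `sox_structure` (default [default_structure_tree()]).
#' @param texts Named list/character: structure node id -> section text.
#' @return `path`, invisibly.
#' @export
write_pehr_doc <- function(path, texts, tree = default_structure_tree()) {
  present <- list()
  leaf_ids <- names(Filter(function(n) !length(n$children), tree$nodes))
  for (id in leaf_ids) present[[id]] <- id %in% names(texts)
  lines <- render_doc_xml(tree, as.list(texts), present)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
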