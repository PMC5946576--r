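#' SOX vocabulary configuration for OWL reading
#'
#' The OWL reader matches vocabulary terms by IRI local name (the fragment
#' after `#`, or the last path segment), since the original ontology's
#' namespace IRIs are not fixed.  Defaults follow the published class and
#' property names; override any entry to read ontologies using different
#' spellings.
#'
#' @param ... Named overrides, e.g. `in_rel = "contained_in"`.
#' @return Named list of local names.
#' @export
sox_iri_config <- function(...) {
  cfg <- list(
    xml_structure = "XML_Structure",
    simple_term = "Simple_Term",
    composite_term = "Composite_Term",
    search_concept = "Search_Concept",
    search_query = "Search_Query",
    described_by = "described_by",
    in_rel = "in",
    has_part = "has_part",
    max_distance = "max_distance",
    xpath = "xpath",
    local_name = "local_name",
    namespace = "namespace",
    has_child = "has_child",
    case_sensitive = "case_sensitive",
    whole_word = "whole_word",
    ordered = "ordered"
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

owl_lit <- function(df, s, local) {
  v <- df$o[df$s == s & df$lit & iri_local(df$p) == local]
  if (length(v)) v else character(0)
}

owl_obj <- function(df, s, local) {
  df$o[df$s == s & !df$lit & iri_local(df$p) == local]
}

owl_bool <- function(x, default) {
  if (!length(x)) return(default)
  tolower(x[1L]) %in% c("true", "1")
}

# Subjects typed (rdf:type) or subclassed (rdfs:subClassOf) under a named
# class whose IRI local name is `class_local`.
owl_members <- function(df, class_local) {
  type_p <- paste0(RDF_NS, "type")
  sub_p <- paste0(RDFS_NS, "subClassOf")
  hit <- (df$p == type_p | df$p == sub_p) & !df$lit &
    iri_local(df$o) == class_local
  unique(df$s[hit])
}

parse_owl_class_expr <- function(df, node) {
  inter <- df$o[df$s == node & df$p == paste0(OWL_NS, "intersectionOf")]
  if (length(inter)) {
    members <- rdf_list_members(df, inter[1L])
    args <- lapply(members, function(m) parse_owl_class_expr(df, m))
    return(structure(list(kind = "and", args = args), class = "sox_expr"))
  }
  un <- df$o[df$s == node & df$p == paste0(OWL_NS, "unionOf")]
  if (length(un)) {
    members <- rdf_list_members(df, un[1L])
    args <- lapply(members, function(m) parse_owl_class_expr(df, m))
    return(structure(list(kind = "or", args = args), class = "sox_expr"))
  }
  comp <- df$o[df$s == node & df$p == paste0(OWL_NS, "complementOf")]
  if (length(comp)) {
    return(sox_not(parse_owl_class_expr(df, comp[1L])))
  }
  if (grepl("^_:", node)) {
    stop("unsupported anonymous class expression in query", call. = FALSE)
  }
  sox_ref(iri_local(node))
}

load_owl_model <- function(path, iri_config = sox_iri_config()) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "ttl") parse_turtle(path) else parse_rdfxml(path)
  cfg <- iri_config

  restriction_values <- function(subj, prop_local) {
    # someValuesFrom restrictions attached via rdfs:subClassOf or
    # owl:equivalentClass
    sup <- c(owl_obj(df, subj, "subClassOf"), owl_obj(df, subj, "equivalentClass"))
    out <- character(0)
    for (r in sup) {
      onp <- df$o[df$s == r & df$p == paste0(OWL_NS, "onProperty")]
      if (!length(onp) || iri_local(onp[1L]) != prop_local) next
      sv <- df$o[df$s == r & df$p == paste0(OWL_NS, "someValuesFrom")]
      if (length(sv)) out <- c(out, sv[1L])
    }
    out
  }

  # structure nodes
  node_subjects <- owl_members(df, cfg$xml_structure)
  children_of <- function(s) owl_obj(df, s, cfg$has_child)
  kids_all <- unlist(lapply(node_subjects, children_of))
  roots <- setdiff(node_subjects, kids_all)
  if (length(node_subjects) && length(roots) != 1L) {
    stop("OWL structure must have exactly one root XML_Structure node",
         call. = FALSE)
  }
  build_node <- function(s) {
    ln <- owl_lit(df, s, cfg$local_name)
    ns <- owl_lit(df, s, cfg$namespace)
    structure_node(
      local_name = if (length(ln)) ln[1L] else iri_local(s),
      namespace = if (length(ns)) ns[1L] else "",
      id = iri_local(s),
      children = lapply(children_of(s), build_node))
  }
  if (!length(node_subjects)) stop("OWL model has no XML_Structure nodes",
                                   call. = FALSE)
  tree <- structure_tree(build_node(roots))

  # simple terms: labels in file order
  sts <- list()
  for (s in owl_members(df, cfg$simple_term)) {
    id <- iri_local(s)
    labs <- df$o[df$s == s & df$lit & df$p == paste0(RDFS_NS, "label")]
    if (!length(labs)) stop("term without labels: ", id, call. = FALSE)
    cs <- owl_bool(owl_lit(df, s, cfg$case_sensitive), TRUE)
    ww <- owl_bool(owl_lit(df, s, cfg$whole_word), TRUE)
    sts[[id]] <- simple_term(id, lapply(labs, term_label,
                                        case_sensitive = cs, whole_word = ww))
  }

  cts <- list()
  for (s in owl_members(df, cfg$composite_term)) {
    id <- iri_local(s)
    parts <- vapply(owl_obj(df, s, cfg$has_part), iri_local, "")
    md <- owl_lit(df, s, cfg$max_distance)
    if (!length(md)) {
      stop("composite term '", id, "' has no max_distance", call. = FALSE)
    }
    cts[[id]] <- composite_term(id, parts, max_distance = as.integer(md[1L]),
                                ordered = owl_bool(owl_lit(df, s, cfg$ordered),
                                                   FALSE))
  }

  ccs <- list()
  concept_subjects <- owl_members(df, cfg$search_concept)
  for (s in concept_subjects) {
    id <- iri_local(s)
    tm <- restriction_values(s, cfg$described_by)
    nd <- restriction_values(s, cfg$in_rel)
    if (!length(tm)) stop("concept '", id, "' lacks a described_by restriction",
                          call. = FALSE)
    if (!length(nd)) stop("concept '", id, "' lacks an 'in' restriction",
                          call. = FALSE)
    ccs[[id]] <- search_concept(id, term = iri_local(tm[1L]),
                                node = iri_local(nd[1L]))
  }

  qs <- list()
  subj_iris <- list()
  for (s in owl_members(df, cfg$search_query)) {
    id <- iri_local(s)
    # the query's class description: an equivalentClass or anonymous
    # subClassOf carrying a boolean class expression
    cands <- c(owl_obj(df, s, "equivalentClass"), owl_obj(df, s, "subClassOf"))
    expr <- NULL
    for (cand in cands) {
      has_bool <- any(df$s == cand &
                        df$p %in% paste0(OWL_NS, c("intersectionOf", "unionOf",
                                                   "complementOf")))
      if (has_bool) { expr <- parse_owl_class_expr(df, cand); break }
    }
    if (is.null(expr)) {
      # single-concept query: subClassOf a named Search_Concept
      named <- cands[!grepl("^_:", cands) &
                       iri_local(cands) != cfg$search_query &
                       iri_local(cands) %in% names(ccs)]
      if (!length(named)) {
        stop("query '", id, "' has no boolean class description", call. = FALSE)
      }
      expr <- sox_ref(iri_local(named[1L]))
    }
    xp <- owl_lit(df, s, cfg$xpath)
    qs[[id]] <- search_query(id, expr,
                             xpath_annotation = if (length(xp)) xp[1L] else NULL)
    subj_iris[[id]] <- s
  }

  model <- sox_model(tree, simple_terms = sts, composite_terms = cts,
                     concepts = ccs, queries = qs)
  attr(model, "owl_source") <- list(path = path, format = ext,
                                    query_iris = subj_iris,
                                    iri_config = cfg)
  model
}

# Write an annotated OWL model: re-serialise the source triples with old
# xpath annotations dropped and the new ones appended, in the source
# serialisation family (Turtle stays Turtle, everything else RDF/XML).
annotate_owl_model <- function(model, xpaths, out) {
  src <- attr(model, "owl_source")
  if (is.null(src)) {
    stop("model was not loaded from OWL; cannot annotate as OWL", call. = FALSE)
  }
  df <- if (src$format == "ttl") parse_turtle(src$path) else parse_rdfxml(src$path)
  cfg <- src$iri_config

  keep <- !(df$lit & iri_local(df$p) == cfg$xpath &
              df$s %in% unlist(src$query_iris))
  df <- df[keep, , drop = FALSE]

  # annotation property IRI: reuse the namespace of an existing SOX property
  sox_ns <- {
    cand <- df$p[iri_local(df$p) %in% c(cfg$described_by, cfg$has_part,
                                        cfg$local_name, cfg$has_child)]
    if (length(cand)) split_iri(cand[1L])[["ns"]] else "urn:sox#"
  }
  for (qid in names(xpaths)) {
    s <- src$query_iris[[qid]]
    if (is.null(s)) stop("unknown query id for annotation: ", qid, call. = FALSE)
    df <- rbind(df, data.frame(s = s, p = paste0(sox_ns, cfg$xpath),
                               o = xpaths[[qid]], lit = TRUE,
                               stringsAsFactors = FALSE))
  }
  if (src$format == "ttl") write_triples_turtle(df, out)
  else write_triples_rdfxml(df, out)
  invisible(out)
}
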