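# Synthetic pathology-EHR corpus generator with ground-truth manifest.
#
# Documents mimic section-structured pathology reports: a root/content
# envelope with Material, Macroscopy, Microscopy, Overall_interpretation,
# Overall_staging, Localisation, Typification and staging sections, three
# namespaces across the subtrees, optional numbered enumeration lists in the
# narrative sections, planted term surface forms with optional physical
# quantities (value + unit token), an exclusion (negation) phrase, and the
# two reviewer-issue injections: misaligned enumeration ordinals (ECRI) and
# stray unit tokens unrelated to any term (PQCRI).

PEHR_NS_MAIN <- "http://example.org/pehr"
PEHR_NS_A <- "http://example.org/pehr/sections-a"
PEHR_NS_B <- "http://example.org/pehr/sections-b"

# Sections that may carry enumeration lists.
ENUM_SECTIONS <- c("material", "macroscopy", "overall_interpretation")

#' Default reference structure tree for synthetic pathology reports
#'
#' `report/content` with the eight standard sections; narrative sections in
#' one namespace, staging/coding sections in another, to exercise prefix
#' handling for identical local names under different namespaces.
#'
#' @return A `sox_structure`.
#' @export
default_structure_tree <- function() {
  sec_a <- function(nm, id) structure_node(nm, PEHR_NS_A, id = id)
  sec_b <- function(nm, id) structure_node(nm, PEHR_NS_B, id = id)
  structure_tree(structure_node(
    "report", PEHR_NS_MAIN, id = "report",
    children = list(structure_node(
      "content", PEHR_NS_MAIN, id = "content",
      children = list(
        sec_a("Material", "material"),
        sec_a("Macroscopy", "macroscopy"),
        sec_a("Microscopy", "microscopy"),
        sec_a("Overall_interpretation", "overall_interpretation"),
        sec_b("Overall_staging", "overall_staging"),
        sec_b("Localisation", "localisation"),
        sec_b("Typification", "typification"),
        sec_b("staging", "staging")
      )))))
}

#' Term plan for the corpus generator
#'
#' Describes how one search concept is planted into generated documents: the
#' surface forms written into the text (including inflected variants that
#' exercise stem regexes), the target section, the per-document planting
#' probability, an optional physical quantity rendered next to the surface
#' form, and the full list of concepts a planting satisfies (one surface can
#' satisfy several concepts, e.g. an exclusion phrase containing the term it
#' negates, or a weight whose unit token is itself a search term).
#'
#' @param concept_id Primary concept this plan plants.
#' @param surface_forms Non-empty character vector.
#' @param section Structure node id the text goes into.
#' @param prevalence Planting probability in `[0, 1]`.
#' @param quantity Optional list
#'   `list(distribution = "normal"|"uniform", p1, p2, unit, attach_within)`:
#'   normal(mu = p1, sigma = p2) truncated at 0, or uniform(p1, p2); rendered
#'   with a German decimal comma at one decimal place, the unit token
#'   immediately after the value, the value within `attach_within` tokens of
#'   the surface form.
#' @param satisfies Concept ids satisfied by a planting (defaults to
#'   `concept_id`).
#' @return A list of class `sox_term_plan`.
#' @export
term_plan <- function(concept_id, surface_forms, section, prevalence,
                      quantity = NULL, satisfies = concept_id) {
  stopifnot(length(surface_forms) >= 1L, prevalence >= 0, prevalence <= 1)
  structure(list(concept_id = concept_id, surface_forms = surface_forms,
                 section = section, prevalence = prevalence,
                 quantity = quantity, satisfies = unique(satisfies)),
            class = "sox_term_plan")
}

#' Corpus generation settings
#'
#' Bundles everything [generate_corpus()] needs.  Defaults encode the study
#' conditions the package's tests reproduce: enumeration lists in about 64%
#' of documents, prostate flake weights drawn from normal(18.26, 10.18)
#' grams truncated at 0, leiomyoma diameters from normal(2.76, 1.42) cm, and
#' the exclusion phrase "ohne Nachweis einer Barrett-Schleimhaut" planted in
#' the interpretation section.
#'
#' @param n_docs Number of documents (>= 1).
#' @param seed Integer seed; identical spec + seed give byte-identical
#'   corpora.
#' @param structure Structure tree (default [default_structure_tree()]).
#' @param term_plans List of [term_plan()]s (default [default_term_plans()]).
#' @param enumeration_prob Probability a document's Material / Macroscopy /
#'   Interpretation sections are enumerated lists.
#' @param misalignment_prob Probability that a document with >= 2 plantings
#'   in enumerated sections puts them into different item ordinals (ECRI
#'   injection).
#' @param stray_unit_prob Probability of planting a stray `value unit` pair
#'   unrelated to any term (PQCRI injection).
#' @param negation_prob Planting probability of the exclusion phrase.
#' @return A list of class `sox_corpus_spec`.
#' @export
corpus_spec <- function(n_docs, seed = 1L, structure = default_structure_tree(),
                        term_plans = default_term_plans(negation_prob),
                        enumeration_prob = 0.64, misalignment_prob = 0,
                        stray_unit_prob = 0, negation_prob = 0.15) {
  probs <- c(enumeration_prob, misalignment_prob, stray_unit_prob,
             negation_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_docs) || n_docs < 1) {
    stop("n_docs must be >= 1", call. = FALSE)
  }
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 structure = structure, term_plans = term_plans,
                 enumeration_prob = enumeration_prob,
                 misalignment_prob = misalignment_prob,
                 stray_unit_prob = stray_unit_prob,
                 negation_prob = negation_prob),
            class = "sox_corpus_spec")
}

#' Default term plans matching the shipped pathology question model
#'
#' One plan per concept of the five-question model
#' (`pathology_questions.yaml`), with prevalences chosen to give each query
#' a non-trivial positive set.  The prostate-weight plan satisfies both the
#' flake concept and the gram-unit concept (its quantity carries the unit
#' token); the exclusion-phrase plan satisfies the Barrett concept too,
#' because the phrase contains the term it negates.
#'
#' @param negation_prob Planting probability of the exclusion phrase.
#' @return List of [term_plan()]s.
#' @export
default_term_plans <- function(negation_prob = 0.15) {
  list(
    term_plan("flake_in_macro", c("Prostataspäne", "Prostatastanzen"),
              "macroscopy", 0.25,
              quantity = list(distribution = "normal", p1 = 18.26,
                              p2 = 10.18, unit = "g", attach_within = 1L),
              satisfies = c("flake_in_macro", "g_unit_in_macro")),
    term_plan("k_no_rest_in_macro", "ohne Rest", "macroscopy", 0.30),
    term_plan("k_rest_in_macro", "mit Rest", "macroscopy", 0.20),
    term_plan("blister_in_interp", "Blister", "overall_interpretation", 0.10),
    term_plan("adeno_in_interp", c("Adenokarzinom", "Adenokarzinome"),
              "overall_interpretation", 0.30),
    term_plan("c61_in_loc", "ICD-O-C-61", "localisation", 0.25),
    term_plan("m8140_in_typ", "ICD-O-M-8140/3", "typification", 0.25),
    term_plan("leiomyom_in_interp", c("Leiomyom", "Leiomyome"),
              "overall_interpretation", 0.20,
              quantity = list(distribution = "normal", p1 = 2.76, p2 = 1.42,
                              unit = "cm", attach_within = 2L),
              satisfies = c("leiomyom_in_interp", "cm_in_interp")),
    term_plan("uterus_in_material", "Uterus", "material", 0.30),
    term_plan("c18_in_loc", "C18", "localisation", 0.15),
    term_plan("colon_in_material", c("Kolon", "Kolonkarzinom"), "material",
              0.20),
    term_plan("t2_in_staging", c("pT2", "pT2a", "pT2b"), "overall_staging",
              0.25),
    term_plan("pn_in_staging", c("pN0", "pN1"), "staging", 0.30),
    term_plan("barrett_in_interp", "Barrett-Schleimhaut",
              "overall_interpretation", 0.35),
    term_plan("cave_in_interp", "ohne Nachweis einer Barrett-Schleimhaut",
              "overall_interpretation", negation_prob,
              satisfies = c("cave_in_interp", "barrett_in_interp")),
    term_plan("esoph_in_material",
              c("Ösophagusbiopsie", "Ösophagusbiopsien"), "material", 0.40)
  )
}

#' Draw and render one physical quantity
#'
#' Draws from the plan's distribution (normal truncated at 0 by rejection,
#' or uniform), rounds to one decimal, renders with a German decimal comma,
#' and reports the token pair `c(value, unit)`.
#'
#' @param quantity Quantity description as in [term_plan()].
#' @return List with `value` (numeric, as rendered) and `tokens` (value
#'   token and unit token).
#' @export
realize_quantity <- function(quantity) {
  val <- switch(quantity$distribution,
    normal = {
      repeat {
        v <- stats::rnorm(1L, quantity$p1, quantity$p2)
        if (v >= 0) break
      }
      v
    },
    uniform = stats::runif(1L, quantity$p1, quantity$p2),
    stop("unknown distribution: ", quantity$distribution, call. = FALSE))
  val <- round(val, 1L)
  tok <- sub(".", ",", sprintf("%.1f", val), fixed = TRUE)
  list(value = val, tokens = c(tok, quantity$unit))
}

sample_filler <- function(n) {
  filler_words[sample.int(length(filler_words), n, replace = TRUE)]
}

# Token sequence of one planting: surface form, then (gap) value + unit.
planting_tokens <- function(surface, quantity) {
  toks <- tokenize(surface)
  value <- NULL
  if (!is.null(quantity)) {
    q <- realize_quantity(quantity)
    gap <- sample.int(quantity$attach_within + 1L, 1L) - 1L
    toks <- c(toks, sample_filler(gap), q$tokens)
    value <- q$value
  }
  list(tokens = toks, value = value)
}

# Interleave plantings with filler; each planting's token run stays
# contiguous (insertions happen between atomic units, never inside one).
interleave_plants <- function(filler, plant_runs) {
  units <- as.list(filler)
  for (run in plant_runs) {
    at <- sample.int(length(units) + 1L, 1L)
    units <- append(units, list(run), after = at - 1L)
  }
  unlist(units)
}

render_section <- function(plants, enumerated, n_items) {
  # plants: list of list(tokens=..., ordinal=NA or int)
  if (!enumerated) {
    toks <- interleave_plants(sample_filler(sample.int(4L, 1L) + 2L),
                              lapply(plants, function(p) p$tokens))
    return(paste(toks, collapse = " "))
  }
  items <- character(n_items)
  for (k in seq_len(n_items)) {
    here <- Filter(function(p) !is.na(p$ordinal) && p$ordinal == k, plants)
    toks <- interleave_plants(sample_filler(sample.int(3L, 1L) + 1L),
                              lapply(here, function(p) p$tokens))
    toks[length(toks)] <- paste0(toks[length(toks)], ".")
    items[k] <- paste(c(paste0(k, "."), toks), collapse = " ")
  }
  paste(items, collapse = " ")
}

xml_text_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Serialise one document as prefixed XML using the tree's prefix map.
render_doc_xml <- function(tree, section_texts, present_sections) {
  pmap <- prefix_map(tree)
  qname <- function(id) {
    nd <- tree$nodes[[id]]
    if (!nzchar(nd$namespace)) return(nd$local_name)
    paste0(names(pmap)[match(nd$namespace, pmap)], ":", nd$local_name)
  }
  decls <- paste0(" xmlns:", names(pmap), "=\"", pmap, "\"", collapse = "")
  rec <- function(id, indent) {
    nd <- tree$nodes[[id]]
    qn <- qname(id)
    pad <- strrep("  ", indent)
    if (length(nd$children)) {
      kids <- unlist(lapply(nd$children, function(ch) {
        if (!present_sections[[ch]] %||% TRUE) return(character(0))
        rec(ch, indent + 1L)
      }))
      c(paste0(pad, "<", qn, if (indent == 0L) decls, ">"), kids,
        paste0(pad, "</", qn, ">"))
    } else {
      txt <- section_texts[[id]] %||% ""
      paste0(pad, "<", qn, ">", xml_text_escape(txt), "</", qn, ">")
    }
  }
  c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", rec(tree$root, 0L))
}

eval_expr_presence <- function(expr, present) {
  switch(expr$kind,
    ref = expr$concept %in% present,
    not = !eval_expr_presence(expr$arg, present),
    and = all(vapply(expr$args, eval_expr_presence, TRUE, present = present)),
    or = any(vapply(expr$args, eval_expr_presence, TRUE, present = present)))
}

# Alignment truth from planting records, mirroring enum_alignment_report's
# rule: concept ordinal sets from plantings; a planting without ordinal makes
# its concepts unconstrained; aligned iff < 2 constrained concepts or their
# ordinal sets intersect.
plantings_aligned <- function(plantings, concepts) {
  ords <- list()
  wild <- character(0)
  for (p in plantings) {
    for (cid in intersect(p$concepts, concepts)) {
      if (is.na(p$ordinal)) {
        wild <- c(wild, cid)
      } else {
        ords[[cid]] <- c(ords[[cid]], p$ordinal)
      }
    }
  }
  constrained <- setdiff(names(ords), wild)
  if (length(constrained) < 2L) return(TRUE)
  inter <- ords[[constrained[1L]]]
  for (cid in constrained[-1L]) inter <- intersect(inter, ords[[cid]])
  length(inter) > 0L
}

#' Generate a synthetic corpus with ground-truth manifest
#'
#' Writes `n_docs` well-formed XML reports under `out_dir`, plus
#' `manifest.json` (per-document plantings with section, item ordinal,
#' surface form and quantity value; per-query intended positive sets under
#' the declared existential-section semantics, alignment ignored) and
#' `spec.yaml` (an echo of the effective generation settings).  Identical
#' spec + seed reproduce byte-identical output.
#'
#' @param spec A [corpus_spec()].
#' @param out_dir Output directory (created if missing).
#' @param model Optional [sox_model()] whose queries get truth sets in the
#'   manifest (default: the shipped five-question model).
#' @return List with `corpus` (a [corpus_open()] handle) and `manifest`.
#' @export
generate_corpus <- function(spec, out_dir, model = pathology_questions_model()) {
  if (!inherits(spec, "sox_corpus_spec")) stop("spec must be a corpus_spec",
                                               call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tree <- spec$structure

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  docs <- list()
  leaf_ids <- names(Filter(function(n) !length(n$children), tree$nodes))

  for (i in seq_len(spec$n_docs)) {
    doc_id <- sprintf("doc%04d", i)
    enumerated <- stats::runif(1L) < spec$enumeration_prob
    n_items <- sample.int(6L, 1L) + 2L

    plantings <- list()
    for (plan in spec$term_plans) {
      if (stats::runif(1L) >= plan$prevalence) next
      surface <- plan$surface_forms[sample.int(length(plan$surface_forms), 1L)]
      pt <- planting_tokens(surface, plan$quantity)
      plantings[[length(plantings) + 1L]] <- list(
        plan = plan$concept_id, concepts = plan$satisfies,
        section = plan$section, surface = surface, tokens = pt$tokens,
        value = pt$value,
        unit = if (!is.null(plan$quantity)) plan$quantity$unit,
        stray = FALSE, ordinal = NA_integer_)
    }

    if (stats::runif(1L) < spec$stray_unit_prob) {
      q <- realize_quantity(list(distribution = "uniform", p1 = 0.5,
                                 p2 = 5, unit = "cm"))
      plantings[[length(plantings) + 1L]] <- list(
        plan = "stray_unit", concepts = "cm_in_interp",
        section = "overall_interpretation", surface = "",
        tokens = q$tokens, value = q$value, unit = "cm", stray = TRUE,
        ordinal = NA_integer_)
    }

    # ordinal assignment: aligned by default, split on misalignment injection
    enum_idx <- which(vapply(plantings, function(p) {
      enumerated && p$section %in% ENUM_SECTIONS
    }, TRUE))
    if (length(enum_idx)) {
      o <- sample.int(n_items, 1L)
      for (k in enum_idx) plantings[[k]]$ordinal <- o
      if (length(enum_idx) >= 2L && stats::runif(1L) < spec$misalignment_prob) {
        o2 <- sample.int(n_items - 1L, 1L)
        if (o2 >= o) o2 <- o2 + 1L
        for (k in enum_idx[-1L]) plantings[[k]]$ordinal <- o2
      }
    }

    # section presence: unplanted leaves may be absent
    present <- list()
    planted_secs <- unique(vapply(plantings, function(p) p$section, ""))
    for (id in leaf_ids) {
      present[[id]] <- id %in% planted_secs || stats::runif(1L) >= 0.15
    }

    texts <- list()
    for (id in leaf_ids) {
      if (!present[[id]]) next
      sec_plants <- Filter(function(p) p$section == id, plantings)
      sec_enum <- enumerated && id %in% ENUM_SECTIONS
      texts[[id]] <- render_section(sec_plants, sec_enum, n_items)
    }

    lines <- render_doc_xml(tree, texts, present)
    writeLines(lines, file.path(out_dir, paste0(doc_id, ".xml")),
               useBytes = TRUE)
    docs[[doc_id]] <- list(enumerated = enumerated, plantings = plantings)
  }

  # query truth sets + alignment truth
  queries <- list()
  misaligned <- list()
  if (!is.null(model)) {
    for (q in model$queries) {
      pos <- character(0)
      mis <- character(0)
      pc <- positive_concepts(q$expr)
      for (doc_id in names(docs)) {
        present_concepts <- unique(unlist(lapply(docs[[doc_id]]$plantings,
                                                 function(p) p$concepts)))
        if (eval_expr_presence(q$expr, present_concepts %||% character(0))) {
          pos <- c(pos, doc_id)
          if (!plantings_aligned(docs[[doc_id]]$plantings, pc)) {
            mis <- c(mis, doc_id)
          }
        }
      }
      queries[[q$id]] <- pos
      misaligned[[q$id]] <- mis
    }
  }

  manifest <- list(n_docs = spec$n_docs, seed = spec$seed, docs = docs,
                   queries = queries, misaligned = misaligned)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  spec_echo <- spec[c("n_docs", "seed", "enumeration_prob",
                      "misalignment_prob", "stray_unit_prob",
                      "negation_prob")]
  writeLines(yaml::as.yaml(spec_echo), file.path(out_dir, "spec.yaml"),
             useBytes = TRUE)

  list(corpus = corpus_open(out_dir, prefix_map = prefix_map(tree)),
       manifest = manifest)
}
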