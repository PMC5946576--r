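# Random model and corpus generation for property testing: models draw terms
# from a catalogue of stem/code patterns with known matching and near-miss
# tokens, and corpora mix those tokens (plus punctuated variants and filler)
# into section texts, so that compiled-XPath evaluation and the brute-force
# oracle can be compared on inputs neither was written against.

label_catalogue <- function() {
  list(
    list(pattern = "florid(\\w)*",
         pos = c("florid", "floride", "florides"),
         neg = c("nonfloride", "flori")),
    list(pattern = "Adenokarzinom(\\w)*",
         pos = c("Adenokarzinom", "Adenokarzinome"),
         neg = c("Karzinom", "adenokarzinom")),
    list(pattern = "cm", pos = "cm", neg = c("bcm", "cmx", "Cm")),
    list(pattern = "g", pos = "g", neg = c("gg", "mg", "G")),
    list(pattern = "pT2(a|b)?", pos = c("pT2", "pT2a", "pT2b"),
         neg = c("pT1", "pT2c", "apT2")),
    list(pattern = "Leiomyom(\\w)*", pos = c("Leiomyom", "Leiomyome"),
         neg = c("Myom", "leiomyom")),
    list(pattern = "Uterus", pos = "Uterus", neg = c("Uteri", "uterus")),
    list(pattern = "ICD-O-C-61", pos = "ICD-O-C-61",
         neg = c("ICD-O-C-62", "ICD-O-C-619")),
    list(pattern = "Barrett-Schleimhaut", pos = "Barrett-Schleimhaut",
         neg = c("Schleimhaut", "Barrett")),
    list(pattern = "Blister", pos = "Blister", neg = c("Blistern", "blister"))
  )
}

#' Generate a random search model for property testing
#'
#' Draws simple terms (1-2 labels each, occasionally case-insensitive or
#' substring-matching), composite proximity terms (2-3 parts, max_distance
#' 0-3, ordered or not), concepts binding them to random structure nodes of
#' the default tree, and 1-3 queries with random boolean expressions
#' (depth <= 3, including negation).  Uses the current RNG state; seed with
#' `set.seed()` for reproducibility.
#'
#' @param n_concepts Number of concepts (default random 2-10).
#' @return A validated [sox_model()].
#' @export
random_search_model <- function(n_concepts = sample(2:10, 1L)) {
  cat <- label_catalogue()
  tree <- default_structure_tree()
  nodes <- c("material", "macroscopy", "microscopy", "overall_interpretation",
             "overall_staging", "localisation", "typification", "staging",
             "content")

  n_simple <- sample(2:5, 1L)
  picks <- sample(seq_along(cat), n_simple)
  sts <- list()
  for (k in seq_len(n_simple)) {
    extra <- if (stats::runif(1L) < 0.3) sample(seq_along(cat), 1L)
    idx <- unique(c(picks[k], extra))
    labels <- lapply(idx, function(i) {
      term_label(cat[[i]]$pattern,
                 case_sensitive = stats::runif(1L) > 0.2,
                 whole_word = stats::runif(1L) > 0.2)
    })
    id <- paste0("st", k)
    sts[[id]] <- simple_term(id, labels)
    attr(sts[[id]], "cat_idx") <- idx
  }

  cts <- list()
  n_comp <- sample(0:2, 1L)
  for (k in seq_len(n_comp)) {
    np <- if (length(sts) >= 3L) sample(2:3, 1L) else 2L
    parts <- sample(names(sts), np, replace = FALSE)
    id <- paste0("ct", k)
    cts[[id]] <- composite_term(id, parts, max_distance = sample(0:3, 1L),
                                ordered = stats::runif(1L) < 0.5)
  }
  if (length(cts)) {
    # composite parts must share the case_sensitive flag; one draw covers all
    # parts of all composites (they may share parts)
    cs <- stats::runif(1L) > 0.2
    for (p in unique(unlist(lapply(cts, function(ct) ct$parts)))) {
      sts[[p]]$labels <- lapply(sts[[p]]$labels, function(l) {
        l$case_sensitive <- cs
        l
      })
    }
  }

  term_ids <- c(names(sts), names(cts))
  ccs <- list()
  for (k in seq_len(n_concepts)) {
    id <- paste0("c", k)
    ccs[[id]] <- search_concept(id, term = sample(term_ids, 1L),
                                node = sample(nodes, 1L))
  }

  random_expr <- function(depth) {
    if (depth <= 0L || stats::runif(1L) < 0.4) {
      return(sox_ref(sample(names(ccs), 1L)))
    }
    op <- sample(c("and", "or", "not"), 1L)
    if (op == "not") return(sox_not(random_expr(depth - 1L)))
    nargs <- sample(2:3, 1L)
    args <- lapply(seq_len(nargs), function(i) random_expr(depth - 1L))
    structure(list(kind = op, args = args), class = "sox_expr")
  }
  qs <- list()
  for (k in seq_len(sample(1:3, 1L))) {
    id <- paste0("q", k)
    qs[[id]] <- search_query(id, random_expr(3L))
  }

  m <- sox_model(tree, simple_terms = sts, composite_terms = cts,
                 concepts = ccs, queries = qs)
  d <- validate_model(m)
  if (nrow(d)) stop("random model generator produced an invalid model: ",
                    paste(d$code, collapse = ", "))
  m
}

#' Generate a random corpus exercising a model's terms
#'
#' Writes `n_docs` documents whose section texts mix tokens that match the
#' model's labels, near-miss tokens, punctuated variants and filler words;
#' sections are sometimes empty, omitted, or duplicated (two elements at the
#' same path).  Uses the current RNG state.
#'
#' @param model A [sox_model()] from [random_search_model()].
#' @param n_docs Number of documents.
#' @param out_dir Output directory.
#' @return A [corpus_open()] handle.
#' @export
random_corpus_for_model <- function(model, n_docs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cat <- label_catalogue()
  idx <- sort(unique(unlist(lapply(model$simple_terms, attr, "cat_idx"))))
  if (!length(idx)) idx <- seq_along(cat)
  pool <- unlist(lapply(cat[idx], function(e) c(e$pos, e$neg)))
  pool <- c(pool, paste0(pool, ","), paste0(pool, "."),
            filler_words[1:10], "2,5", "38")
  tree <- model$structure
  leaf_ids <- names(Filter(function(n) !length(n$children), tree$nodes))

  for (i in seq_len(n_docs)) {
    texts <- list()
    present <- list()
    for (id in leaf_ids) {
      r <- stats::runif(1L)
      present[[id]] <- r >= 0.15
      if (!present[[id]]) next
      ntok <- sample(0:8, 1L)
      texts[[id]] <- paste(pool[sample.int(length(pool), ntok,
                                           replace = TRUE)],
                           collapse = " ")
    }
    lines <- render_doc_xml(tree, texts, present)
    # occasionally duplicate one present section element
    dup_ok <- names(Filter(isTRUE, present))
    if (length(dup_ok) && stats::runif(1L) < 0.3) {
      id <- sample(dup_ok, 1L)
      nd <- tree$nodes[[id]]
      pmap <- prefix_map(tree)
      qn <- paste0(names(pmap)[match(nd$namespace, pmap)], ":", nd$local_name)
      extra_txt <- paste(pool[sample.int(length(pool), sample(1:5, 1L),
                                         replace = TRUE)], collapse = " ")
      dup_line <- paste0("    <", qn, ">", xml_text_escape(extra_txt),
                         "</", qn, ">")
      at <- grep(paste0("<", qn, ">"), lines)[1L]
      lines <- append(lines, dup_line, after = at)
    }
    writeLines(lines, file.path(out_dir, sprintf("rdoc%03d.xml", i)),
               useBytes = TRUE)
  }
  corpus_open(out_dir, prefix_map = prefix_map(tree))
}
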