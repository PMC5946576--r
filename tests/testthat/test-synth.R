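test_that("identical spec and seed reproduce byte-identical corpora", {
  d1 <- tempfile("det1"); d2 <- tempfile("det2")
  r1 <- generate_corpus(corpus_spec(n_docs = 40, seed = 42,
                                    misalignment_prob = 0.2,
                                    stray_unit_prob = 0.1), d1)
  r2 <- generate_corpus(corpus_spec(n_docs = 40, seed = 42,
                                    misalignment_prob = 0.2,
                                    stray_unit_prob = 0.1), d2)
  expect_identical(r1$corpus$doc_ids, r2$corpus$doc_ids)
  for (id in r1$corpus$doc_ids) {
    expect_identical(readLines(file.path(d1, paste0(id, ".xml"))),
                     readLines(file.path(d2, paste0(id, ".xml"))))
  }
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  # a different seed changes the corpus
  r3 <- generate_corpus(corpus_spec(n_docs = 40, seed = 43), tempfile())
  expect_false(identical(r1$manifest$docs, r3$manifest$docs))
})

test_that("a plan with prevalence zero plants nothing and empties its query", {
  m <- pathology_questions_model()
  plans <- default_term_plans()
  is_esoph <- vapply(plans, function(p) p$concept_id == "esoph_in_material",
                     TRUE)
  plans[[which(is_esoph)]]$prevalence <- 0
  res <- generate_corpus(corpus_spec(n_docs = 80, seed = 5,
                                     term_plans = plans), tempfile("prev0"))
  planted <- unlist(lapply(res$manifest$docs, function(d) {
    unlist(lapply(d$plantings, function(p) p$concepts))
  }))
  expect_false("esoph_in_material" %in% planted)
  expect_length(unlist(res$manifest$queries$q5_denominator), 0L)
  hits <- evaluate_query(res$corpus, compile_query("q5_denominator", m))
  expect_length(hits, 0L)
})

test_that("generated documents validate against the structure tree", {
  res <- generate_corpus(corpus_spec(n_docs = 15, seed = 8), tempfile("val"))
  tree <- default_structure_tree()
  known <- vapply(tree$nodes, function(n) paste(n$namespace, n$local_name),
                  "")
  for (id in res$corpus$doc_ids) {
    doc <- xml2::read_xml(file.path(res$corpus$root_dir, paste0(id, ".xml")))
    nsmap <- xml2::xml_ns(doc)
    check <- function(el) {
      nl <- soxpath:::element_ns_local(el, nsmap)
      expect_true(paste(nl[["ns"]], nl[["local"]]) %in% known)
      for (ch in xml2::xml_children(el)) check(ch)
    }
    check(xml2::xml_root(doc))
  }
})

test_that("the full pipeline retrieves exactly the manifest truth", {
  # no misalignment / stray injection: precision = recall = 1 per query
  m <- pathology_questions_model()
  res <- generate_corpus(corpus_spec(n_docs = 150, seed = 21),
                         tempfile("round"))
  for (qid in names(m$queries)) {
    hits <- sort(as.character(evaluate_query(res$corpus,
                                             compile_query(qid, m))))
    truth <- unlist(res$manifest$queries[[qid]])
    truth <- sort(if (is.null(truth)) character(0) else truth)
    expect_identical(hits, truth, info = qid)
  }
})

test_that("enumeration prevalence matches its probability", {
  res <- generate_corpus(corpus_spec(n_docs = 1000, seed = 64,
                                     enumeration_prob = 0.64),
                         tempfile("enum"))
  n_enum <- sum(vapply(res$manifest$docs, function(d) isTRUE(d$enumerated),
                       TRUE))
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.64)
  expect_gte(n_enum, bounds[1L])
  expect_lte(n_enum, bounds[2L])
  # enumerated documents actually carry detectable item markers
  some <- names(res$manifest$docs)[vapply(res$manifest$docs,
                                          function(d) isTRUE(d$enumerated),
                                          TRUE)][1:10]
  tree <- default_structure_tree()
  for (id in some) {
    doc <- xml2::read_xml(file.path(res$corpus$root_dir, paste0(id, ".xml")))
    texts <- soxpath:::doc_section_texts(doc, tree)
    enum_secs <- unlist(texts[c("material", "macroscopy",
                                "overall_interpretation")])
    expect_true(any(vapply(enum_secs, soxpath:::text_is_enumerated, TRUE)))
  }
})

test_that("realized quantities respect their distribution and rendering", {
  set.seed(3)
  u <- replicate(200, realize_quantity(list(distribution = "uniform",
                                            p1 = 2, p2 = 3, unit = "cm")),
                 simplify = FALSE)
  vals <- vapply(u, function(x) x$value, 1)
  expect_true(all(vals >= 2 & vals <= 3))
  toks <- vapply(u, function(x) x$tokens[1L], "")
  expect_true(all(grepl("^[0-9]+,[0-9]$", toks)))  # decimal comma, 1 digit
  expect_true(all(vapply(u, function(x) x$tokens[2L], "") == "cm"))

  # attach_within = 0: unit immediately follows the value, value immediately
  # follows the surface form
  set.seed(4)
  pt <- soxpath:::planting_tokens("Leiomyom",
                                  list(distribution = "uniform", p1 = 1,
                                       p2 = 2, unit = "cm",
                                       attach_within = 0L))
  expect_identical(pt$tokens[1L], "Leiomyom")
  expect_identical(length(pt$tokens), 3L)
  expect_identical(pt$tokens[3L], "cm")

  expect_error(realize_quantity(list(distribution = "lognormal", p1 = 1,
                                     p2 = 1, unit = "g")), "distribution")
})

test_that("corpus_spec rejects invalid settings", {
  expect_error(corpus_spec(n_docs = 0), "n_docs")
  expect_error(corpus_spec(n_docs = 10, enumeration_prob = 1.5), "probabilities")
})
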