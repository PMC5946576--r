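test_that("compile_label anchors word stems at word boundaries", {
  re <- compile_label(term_label("florid(\\w)*"))
  expect_true(grepl(re, "eine floride Entzuendung", perl = TRUE))
  expect_true(grepl(re, "florides Gewebe", perl = TRUE))
  expect_true(grepl(re, "florid", perl = TRUE))
  expect_false(grepl(re, "nonfloride", perl = TRUE))

  re_cm <- compile_label(term_label("cm"))
  expect_true(grepl(re_cm, "2 cm breit", perl = TRUE))
  expect_false(grepl(re_cm, "bcm", perl = TRUE))

  # umlauts count as word characters for boundary purposes
  expect_false(grepl(compile_label(term_label("Sp")), "Späne", perl = TRUE))

  # without whole_word the pattern passes through untouched
  expect_identical(compile_label(term_label("cm", whole_word = FALSE)), "cm")

  expect_error(compile_label(term_label("")), "empty")
  expect_error(compile_label(term_label("((")), "compile")
})

test_that("simple-term predicates contain one matches() disjunct per label", {
  m <- q1_model()
  two <- simple_term("two", list("alpha", "beta"))
  pred <- compile_simple_term(two, "overall_interpretation", m)
  expect_identical(length(gregexpr("matches\\(", pred$xpath_fragment)[[1L]]),
                   2L)
  expect_match(pred$xpath_fragment, "^exists\\(")
  expect_match(pred$xpath_fragment, "ns2:Overall_interpretation", fixed = TRUE)

  # case-insensitive labels carry the 'i' flag instead of a rewritten pattern
  ci <- simple_term("ci", list(term_label("Uterus", case_sensitive = FALSE)))
  pred_ci <- compile_simple_term(ci, "material", m)
  expect_match(pred_ci$xpath_fragment, "', 'i')", fixed = TRUE)
  expect_match(pred_ci$xpath_fragment, "(Uterus)", fixed = TRUE)
})

test_that("composite cross product enumerates label tuples times part orders", {
  m <- sox_model(
    default_structure_tree(),
    simple_terms = list(simple_term("p1", list("a1", "a2")),
                        simple_term("p2", list("b1", "b2", "b3"))),
    composite_terms = list(
      composite_term("both", c("p1", "p2"), max_distance = 2L),
      composite_term("ord", c("p1", "p2"), max_distance = 2L,
                     ordered = TRUE)))
  pred <- compile_composite_term("both", "macroscopy", m)
  n_alts <- length(gregexpr("matches\\(", pred$xpath_fragment)[[1L]])
  expect_identical(n_alts, 12L)  # 2 x 3 tuples x 2 orders

  pred_o <- compile_composite_term("ord", "macroscopy", m)
  expect_identical(length(gregexpr("matches\\(", pred_o$xpath_fragment)[[1L]]),
                   6L)

  # the gap template counts whole intervening tokens
  expect_match(pred$xpath_fragment, "(\\s[^\\s]+){0,2}\\s", fixed = TRUE)
})

test_that("max_distance 0 joins parts with an immediate-adjacency gap", {
  m <- proximity_model(0L)
  pred <- compile_composite_term("leiomyom_cm", "overall_interpretation", m)
  expect_match(pred$xpath_fragment, "(\\s[^\\s]+){0,0}\\s", fixed = TRUE)
})

test_that("the Q1 query compiles to the expected boolean shape", {
  m <- q1_model()
  cq <- compile_query("q1", m)
  expect_s3_class(cq, "sox_compiled_query")
  expect_identical(length(gregexpr("not\\(", cq$xpath)[[1L]]), 1L)
  expect_identical(length(gregexpr(" and ", cq$xpath)[[1L]]), 3L)
  expect_identical(length(gregexpr(" or ", cq$xpath)[[1L]]), 1L)
  expect_match(cq$xpath, "^/ns1:report\\[")
  # every prefix used is declared in the prefix map
  used <- unique(unlist(regmatches(cq$xpath, gregexpr("ns[0-9]+", cq$xpath))))
  expect_true(all(used %in% names(cq$prefix_map)))

  # compilation is a pure function of (query, model)
  expect_identical(compile_query("q1", m)$xpath, cq$xpath)

  # a single-concept query is that predicate wrapped in the root selector
  m2 <- m
  m2$queries$solo <- search_query("solo", sox_ref("adeno_in_interp"))
  solo <- compile_query("solo", m2)
  pred <- compile_simple_term("adenocarcinoma", "overall_interpretation", m2)
  expect_identical(solo$xpath,
                   paste0("/ns1:report[", pred$xpath_fragment, "]"))
})

test_that("annotation round-trips through the native format", {
  m <- pathology_questions_model()
  compiled <- compile_model(m)
  expect_length(compiled, 7L)  # five questions, seven variants
  out <- tempfile(fileext = ".yaml")
  annotate_model(m, compiled, out)
  m2 <- load_model(out, format = "native")
  for (qid in names(compiled)) {
    expect_identical(m2$queries[[qid]]$xpath_annotation, compiled[[qid]]$xpath)
  }
  # re-annotation overwrites
  annotate_model(m2, compiled, out)
  m3 <- load_model(out, format = "native")
  expect_identical(m3$queries$q1$xpath_annotation, compiled$q1$xpath)
})

test_that("annotation round-trips through both OWL serialisations", {
  for (ext in c("ttl", "owl")) {
    m <- load_model(q1_fixture_path(ext), format = "owl")
    compiled <- compile_model(m)
    out <- tempfile(fileext = paste0(".", ext))
    annotate_model(m, compiled, out)
    m2 <- load_model(out, format = "owl")
    expect_identical(m2$queries$q1$xpath_annotation, compiled$q1$xpath)
    expect_identical(canon_model(m2)$concepts, canon_model(m)$concepts)
  }
})

test_that("the xpath listing writes one header + one expression per query", {
  m <- pathology_questions_model()
  compiled <- compile_model(m)
  out <- tempfile(fileext = ".txt")
  write_xpath_listing(compiled, out)
  lines <- readLines(out)
  expect_identical(sum(startsWith(lines, "# ")), 7L)
  expect_identical(length(lines), 14L)
  expect_true(file.exists(paste0(out, ".prefixes.json")))
})

test_that("compiled queries survive the JSON interchange form", {
  m <- q1_model()
  cq <- compile_query("q1", m)
  f <- tempfile(fileext = ".json")
  write_compiled_query(cq, f)
  cq2 <- read_compiled_query(f)
  expect_identical(cq2$xpath, cq$xpath)
  expect_identical(cq2$prefix_map, cq$prefix_map)
})
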