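# Helper: run one query on a directory and return the alignment reports.
ecri_reports <- function(dir, model, qid) {
  corpus <- corpus_open(dir)
  snips <- fetch_snippets(corpus, compile_query(qid, model), model)
  enum_alignment_report(snips, model)
}

# Two-concept model: weight unit in macroscopy + adenocarcinoma in
# interpretation, the narrated coreference setting.
weight_adeno_model <- function() {
  sox_model(default_structure_tree(),
            simple_terms = list(simple_term("g_unit", list("g")),
                                simple_term("adeno",
                                            list("Adenokarzinom(\\w)*"))),
            concepts = list(
              search_concept("w_in_macro", "g_unit", "macroscopy"),
              search_concept("a_in_interp", "adeno",
                             "overall_interpretation")),
            queries = list(search_query("q", sox_and(sox_ref("w_in_macro"),
                                                     sox_ref("a_in_interp")))))
}

enum_text <- function(assignments, n_items) {
  # assignments: named list ordinal -> extra tokens
  items <- vapply(seq_len(n_items), function(k) {
    extra <- assignments[[as.character(k)]]
    toks <- c(paste0(k, "."), "Gewebe", extra, "Probe.")
    paste(toks, collapse = " ")
  }, "")
  paste(items, collapse = " ")
}

test_that("matches in the same enumeration item are aligned (x = y)", {
  dir <- tempfile("ecri1")
  dir.create(dir)
  write_pehr_doc(file.path(dir, "same.xml"), list(
    macroscopy = enum_text(list(`13` = c("12,0", "g")), 15),
    overall_interpretation = enum_text(list(`13` = "Adenokarzinom"), 15)))
  rep <- ecri_reports(dir, weight_adeno_model(), "q")
  expect_length(rep, 1L)
  expect_true(rep[[1L]]$aligned)
  expect_identical(rep[[1L]]$item_indices$w_in_macro, 13L)
  expect_identical(rep[[1L]]$item_indices$a_in_interp, 13L)
})

test_that("weight in item 13 without adenocarcinoma in item 13 is flagged", {
  dir <- tempfile("ecri2")
  dir.create(dir)
  write_pehr_doc(file.path(dir, "mis.xml"), list(
    macroscopy = enum_text(list(`13` = c("12,0", "g")), 15),
    overall_interpretation = enum_text(list(`7` = "Adenokarzinom"), 15)))
  rep <- ecri_reports(dir, weight_adeno_model(), "q")
  expect_length(rep, 1L)
  expect_false(rep[[1L]]$aligned)
  expect_match(rep[[1L]]$details, "disjoint")
})

test_that("Leiomyom in item 11 vs Uterus in item 15 is flagged", {
  m <- sox_model(default_structure_tree(),
                 simple_terms = list(
                   simple_term("leiomyom", list("Leiomyom(\\w)*")),
                   simple_term("uterus", list("Uterus"))),
                 concepts = list(
                   search_concept("l_in_interp", "leiomyom",
                                  "overall_interpretation"),
                   search_concept("u_in_mat", "uterus", "material")),
                 queries = list(search_query("q",
                                             sox_and(sox_ref("l_in_interp"),
                                                     sox_ref("u_in_mat")))))
  dir <- tempfile("ecri3")
  dir.create(dir)
  write_pehr_doc(file.path(dir, "mis.xml"), list(
    overall_interpretation = enum_text(list(`11` = "Leiomyom"), 15),
    material = enum_text(list(`15` = "Uterus"), 15)))
  rep <- ecri_reports(dir, m, "q")
  expect_false(rep[[1L]]$aligned)
  expect_identical(rep[[1L]]$item_indices$l_in_interp, 11L)
  expect_identical(rep[[1L]]$item_indices$u_in_mat, 15L)
})

test_that("sections without enumeration are wildcards that align with anything", {
  dir <- tempfile("ecri4")
  dir.create(dir)
  write_pehr_doc(file.path(dir, "wild.xml"), list(
    macroscopy = "Gewebe 12,0 g Probe",  # no enumeration
    overall_interpretation = enum_text(list(`5` = "Adenokarzinom"), 8)))
  rep <- ecri_reports(dir, weight_adeno_model(), "q")
  expect_true(rep[[1L]]$aligned)
})

test_that("the report never flags documents whose matches share an item", {
  set.seed(17)
  m <- pathology_questions_model()
  res <- generate_corpus(corpus_spec(n_docs = 200, seed = 17,
                                     misalignment_prob = 0.4),
                         tempfile("ecri5"))
  for (qid in c("q1", "q3")) {
    snips <- fetch_snippets(res$corpus, compile_query(qid, m), m)
    rep <- enum_alignment_report(snips, m)
    flagged <- vapply(Filter(function(r) !r$aligned, rep),
                      function(r) r$doc_id, "")
    truth <- unlist(res$manifest$misaligned[[qid]])
    expect_setequal(flagged, if (is.null(truth)) character(0) else truth)
  }
})

test_that("quantity extraction parses number+unit pairs with both decimals", {
  mk_snip <- function(id, text) {
    structure(list(doc_id = id, query_id = "q", concept_id = "c",
                   section_path = "p", section_index = 1L, text = text,
                   matched_spans = data.frame(pattern = character(0),
                                              start = integer(0),
                                              end = integer(0))),
              class = "sox_snippet")
  }
  snips <- list(mk_snip("a", "Gewicht 3 g entnommen"),
                mk_snip("b", "Gewicht 38 g entnommen"))
  q <- extract_quantities(snips, "g")
  expect_identical(q$value, c(3, 38))
  expect_identical(q$unit, c("g", "g"))

  q2 <- extract_quantities(list(mk_snip("c", "Durchmesser 2,5 cm")), "cm")
  expect_identical(q2$value, 2.5)

  # proximity filter: no Leiomyom within 2 tokens of the value
  prox <- simple_term("leiomyom", list("Leiomyom(\\w)*"))
  far <- mk_snip("d", "Leiomyom im Fundus breit Abstand 2,0 cm")
  expect_identical(nrow(extract_quantities(list(far), "cm",
                                           proximity_term = prox,
                                           max_distance = 2L)), 0L)
  near <- mk_snip("e", "Leiomyom von 2,0 cm")
  expect_identical(extract_quantities(list(near), "cm",
                                      proximity_term = prox,
                                      max_distance = 2L)$value, 2)
})

test_that("quantity summaries use population sd and handle edge cases", {
  s <- summarize_quantities(c(3, 38), "g")
  expect_identical(s$min, 3)
  expect_identical(s$max, 38)
  expect_identical(s$mean, 20.5)
  expect_equal(s$sd, 17.5)  # population form: sqrt(mean((x - 20.5)^2))

  expect_identical(summarize_quantities(5)$sd, 0)
  s0 <- summarize_quantities(numeric(0), "g")
  expect_identical(s0$n, 0L)
  expect_true(is.na(s0$mean))

  # summarise-after-extract is invariant under document permutation
  v <- c(4.2, 1.1, 9.9, 3.3)
  expect_identical(summarize_quantities(sample(v))[c("n", "min", "max",
                                                     "mean", "sd")],
                   summarize_quantities(v)[c("n", "min", "max", "mean",
                                             "sd")])
})

test_that("seeded sampling recovers the generating moments", {
  set.seed(1234)
  q <- list(distribution = "normal", p1 = 18.26, p2 = 10.18, unit = "g",
            attach_within = 0L)
  vals <- vapply(1:1000, function(i) realize_quantity(q)$value, 1)
  expect_true(all(vals >= 0))
  # closed-form truncated-normal moments (truncation at 0)
  a <- -q$p1 / q$p2
  lam <- dnorm(a) / (1 - pnorm(a))
  tmean <- q$p1 + q$p2 * lam
  tvar <- q$p2^2 * (1 + a * lam - lam^2)
  se <- sqrt(tvar / length(vals))
  expect_lt(abs(mean(vals) - tmean), 3 * se)
})
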