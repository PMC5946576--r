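test_that("simple-term retrieval agrees with a direct regex scan", {
  dir <- tempfile("fix6")
  dir.create(dir)
  texts <- list(
    d1 = list(overall_interpretation = "Befund Adenokarzinom der Prostata"),
    d2 = list(overall_interpretation = "mehrere Adenokarzinome gefunden"),
    d3 = list(overall_interpretation = "kein NichtAdenokarzinomx hier"),
    d4 = list(macroscopy = "Adenokarzinom im falschen Abschnitt"),
    d5 = list(overall_interpretation = "unauffaelliger Befund"),
    d6 = list(material = "Probe")  # interpretation section absent
  )
  for (id in names(texts)) {
    write_pehr_doc(file.path(dir, paste0(id, ".xml")), texts[[id]])
  }
  m <- sox_model(default_structure_tree(),
                 simple_terms = list(simple_term("adeno",
                                                 list("Adenokarzinom(\\w)*"))),
                 concepts = list(search_concept("a_in_i", "adeno",
                                                "overall_interpretation")),
                 queries = list(search_query("q", sox_ref("a_in_i"))))
  corpus <- corpus_open(dir)
  hits <- evaluate_query(corpus, compile_query("q", m))
  expect_identical(as.character(hits), c("d1", "d2"))

  # independent scan: xml2 XPath 1.0 for the section + PCRE with lookaround
  ns <- c(ns1 = "http://example.org/pehr",
          ns2 = "http://example.org/pehr/sections-a")
  expected <- Filter(function(id) {
    scan_section_regex(file.path(dir, paste0(id, ".xml")),
                       "/ns1:report/ns1:content/ns2:Overall_interpretation",
                       "(?<![\\wäöüÄÖÜß])Adenokarzinom(\\w)*(?![\\wäöüÄÖÜß])",
                       ns)
  }, names(texts))
  expect_identical(as.character(hits), expected)

  # a document lacking the section entirely is not matched...
  expect_false("d6" %in% hits)
  # ...but satisfies the negated concept (no such section matches)
  m$queries$nq <- search_query("nq", sox_not(sox_ref("a_in_i")))
  nhits <- evaluate_query(corpus, compile_query("nq", m))
  expect_setequal(as.character(nhits), c("d3", "d4", "d5", "d6"))
  expect_true(oracle_match(file.path(dir, "d6.xml"), "nq", m))
  expect_false(oracle_match(file.path(dir, "d6.xml"), "q", m))
})

test_that("an empty corpus yields an empty result", {
  dir <- tempfile("empty")
  dir.create(dir)
  m <- q1_model()
  hits <- evaluate_query(corpus_open(dir), compile_query("q1", m))
  expect_length(hits, 0L)
})

test_that("malformed XML is reported per document and evaluation continues", {
  dir <- tempfile("mal")
  dir.create(dir)
  write_pehr_doc(file.path(dir, "good.xml"),
                 list(overall_interpretation = "Adenokarzinom",
                      macroscopy = "12,0 g"))
  writeLines("<broken><unclosed>", file.path(dir, "bad.xml"))
  m <- q1_model()
  hits <- evaluate_query(corpus_open(dir), compile_query("q1", m))
  errs <- attr(hits, "errors")
  expect_identical(errs$doc_id, "bad")
  expect_identical(as.character(hits), "good")
})

test_that("snippets cover each positively matched section with valid spans", {
  dir <- tempfile("snip")
  dir.create(dir)
  # one doc matching the flake concept via two different sections
  m <- pathology_questions_model()
  m$queries <- list(both = search_query("both",
                                        sox_or(sox_ref("flake_in_macro"),
                                               sox_ref("flake_in_interp"))))
  write_pehr_doc(file.path(dir, "two.xml"),
                 list(macroscopy = "Prostataspäne 12,0 g",
                      overall_interpretation = "Prostatastanzen entnommen"))
  corpus <- corpus_open(dir)
  out <- tempfile("snipout")
  snips <- fetch_snippets(corpus, compile_query("both", m), m, out_dir = out)
  expect_length(snips, 2L)
  expect_setequal(vapply(snips, function(s) s$concept_id, ""),
                  c("flake_in_macro", "flake_in_interp"))

  for (s in snips) {
    expect_gte(s$section_index, 1L)
    for (r in seq_len(nrow(s$matched_spans))) {
      frag <- substr(s$text, s$matched_spans$start[r], s$matched_spans$end[r])
      expect_true(grepl(paste0("^(?:", s$matched_spans$pattern[r], ")$"),
                        frag, perl = TRUE))
    }
    # snippet text equals the independently extracted normalized section text
    doc <- xml2::read_xml(file.path(dir, paste0(s$doc_id, ".xml")))
    nodes <- xml2::xml_find_all(doc, paste0("/", s$section_path),
                                ns = prefix_map(m$structure))
    ref <- gsub("\\s+", " ",
                trimws(xml2::xml_text(nodes[[s$section_index]])))
    expect_identical(s$text, ref)
  }

  # JSONL + raw fragments were written for review
  expect_true(file.exists(file.path(out, "both_snippets.jsonl")))
  expect_length(readLines(file.path(out, "both_snippets.jsonl")), 2L)
  expect_true(file.exists(file.path(out, "two", "1.xml")))
})

test_that("snippet spans are complete against the oracle's matcher", {
  set.seed(99)
  m <- pathology_questions_model()
  res <- generate_corpus(corpus_spec(n_docs = 60, seed = 99), tempfile("sc"))
  cq <- compile_query("q1", m)
  snips <- fetch_snippets(res$corpus, cq, m)
  # every snippet's doc was retrieved, and every retrieved doc with a
  # positive section match appears among the snippets
  hits <- as.character(evaluate_query(res$corpus, cq))
  expect_true(all(vapply(snips, function(s) s$doc_id, "") %in% hits))
  texts_of <- function(id) {
    soxpath:::doc_section_texts(
      xml2::read_xml(file.path(res$corpus$root_dir, paste0(id, ".xml"))),
      m$structure)
  }
  for (id in hits) {
    texts <- texts_of(id)
    macro <- if (is.null(texts$macroscopy)) character(0) else texts$macroscopy
    oracle_secs <- which(vapply(macro, function(tx) {
      nrow(soxpath:::label_occurrences("g", tx)) > 0
    }, TRUE))
    snip_secs <- vapply(Filter(function(s) {
      s$doc_id == id && s$concept_id == "g_unit_in_macro"
    }, snips), function(s) s$section_index, 1L)
    expect_setequal(as.integer(snip_secs), as.integer(oracle_secs))
  }
})

test_that("double negation changes the XPath text but not the result set", {
  set.seed(7)
  m <- pathology_questions_model()
  m$queries$dn <- search_query("dn",
                               sox_not(sox_not(sox_ref("adeno_in_interp"))))
  m$queries$plain <- search_query("plain", sox_ref("adeno_in_interp"))
  res <- generate_corpus(corpus_spec(n_docs = 80, seed = 123), tempfile("dn"))
  cq_dn <- compile_query("dn", m)
  cq_plain <- compile_query("plain", m)
  expect_false(identical(cq_dn$xpath, cq_plain$xpath))
  expect_identical(as.character(evaluate_query(res$corpus, cq_dn)),
                   as.character(evaluate_query(res$corpus, cq_plain)))
})
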