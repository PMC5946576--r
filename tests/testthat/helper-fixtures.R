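# Shared builders for the test suite; everything is generated in code.

q1_fixture_path <- function(ext = "yaml") {
  system.file("extdata", paste0("q1.", ext), package = "soxpath")
}

q1_model <- function() load_model(q1_fixture_path("yaml"), format = "native")

# Canonical projection for structural model comparison: sort collections by
# id, drop load-source attributes.
canon_model <- function(m) {
  attr(m, "owl_source") <- NULL
  for (slot in c("simple_terms", "composite_terms", "concepts", "queries")) {
    m[[slot]] <- m[[slot]][sort(names(m[[slot]]))]
  }
  m
}

# A minimal model with one composite proximity term (Leiomyom within d words
# of cm) bound to the interpretation section.
proximity_model <- function(d, ordered = FALSE) {
  sox_model(
    default_structure_tree(),
    simple_terms = list(simple_term("leiomyom", list("Leiomyom(\\w)*")),
                        simple_term("cm_unit", list("cm"))),
    composite_terms = list(composite_term("leiomyom_cm",
                                          c("leiomyom", "cm_unit"),
                                          max_distance = d,
                                          ordered = ordered)),
    concepts = list(search_concept("lc_in_interp", "leiomyom_cm",
                                   "overall_interpretation")),
    queries = list(search_query("q", sox_ref("lc_in_interp"))))
}

# 20-document fixture for proximity semantics: token gaps 0..9 between the
# two part matches, a reversed-order pair, and assorted negatives.
write_proximity_corpus <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gap in 0:9) {
    mid <- if (gap > 0) paste(rep("Wort", gap), collapse = " ")
    txt <- paste(c("Leiomyom", mid, "cm"), collapse = " ")
    write_pehr_doc(file.path(dir, sprintf("gap%02d.xml", gap)),
                   list(overall_interpretation = txt))
  }
  write_pehr_doc(file.path(dir, "rev00.xml"),
                 list(overall_interpretation = "cm Leiomyom"))
  write_pehr_doc(file.path(dir, "rev02.xml"),
                 list(overall_interpretation = "cm Wort Wort Leiomyome"))
  write_pehr_doc(file.path(dir, "neg_noterm.xml"),
                 list(overall_interpretation = "Befund cm unauffaellig"))
  write_pehr_doc(file.path(dir, "neg_nounit.xml"),
                 list(overall_interpretation = "Leiomyom im Fundus"))
  write_pehr_doc(file.path(dir, "neg_glued.xml"),
                 list(overall_interpretation = "Leiomyomcm Befund"))
  write_pehr_doc(file.path(dir, "neg_wrongsec.xml"),
                 list(macroscopy = "Leiomyom cm"))
  write_pehr_doc(file.path(dir, "neg_bcm.xml"),
                 list(overall_interpretation = "Leiomyom bcm"))
  write_pehr_doc(file.path(dir, "neg_empty.xml"),
                 list(overall_interpretation = ""))
  write_pehr_doc(file.path(dir, "neg_nosec.xml"), list(material = "Probe"))
  write_pehr_doc(file.path(dir, "gap02b.xml"),
                 list(overall_interpretation = "Leiomyom von 2,0 cm"))
  corpus_open(dir)
}

# Independent reference for simple-term retrieval used in engine tests:
# extract the section text by hand with xml2 and scan with a regex.
scan_section_regex <- function(path, section_xpath, regex, ns) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, section_xpath, ns = ns)
  txts <- vapply(nodes, function(n) gsub("\\s+", " ", trimws(xml2::xml_text(n))), "")
  any(grepl(regex, txts, perl = TRUE))
}
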