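---
title: "Ontology-based query engineering for section-structured XML health records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-based query engineering for section-structured XML health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soxpath)
```

## The problem

Pathology reports are narrative documents with a stable internal section
discipline: material/specimen, macroscopic findings, microscopic findings, an
overall interpretation, staging and coding sections.  Once such reports have
been section-structured into XML (an openEHR-style layout with one element
per section), research questions like *"from what flake weight upwards do we
find prostate carcinomas?"* become answerable by retrieval: find the
documents where a weight expression occurs in the macroscopy section, an
adenocarcinoma term (or the corresponding ICD-O codes) in the interpretation
or coding sections, and no contradicting phrase elsewhere.

Writing the XPath expressions for such questions by hand is error-prone and
requires syntax expertise that domain experts do not have.  `soxpath`
implements the alternative: a declarative *search model* in the Search
Ontology XML extension (SOX) style, from which XPath expressions are
generated mechanically.

## The model

A search model has four layers:

* **Structure tree** — the reference XML layout as a tree of
  `(namespace, local name)` nodes.  This is the source of all location
  paths; namespace prefixes `ns1`, `ns2`, … are assigned deterministically
  in preorder of first appearance, which matters because real layouts reuse
  local names under different namespaces.
* **Search terms** — *simple terms* carry one or more labels, each a word
  regex (typically a stem such as `florid(\w)*`, so that "floride" and
  "florides" match); *composite terms* combine two or more simple terms
  with a `max_distance` word-gap bound, the proximity-search remedy for
  units that do not refer to the concept of interest.
* **Search concepts** — one term bound to one structure node (the `in`
  relation).  A concept holds for a document when at least one element at
  that path matches the term.  Disjunction over terms or sections is
  expressed at the query level, which keeps the existential reading
  unambiguous.
* **Search queries** — boolean (AND/OR/NOT) combinations of concepts; each
  query compiles to exactly one XPath.

Models are written either in a native YAML format (scriptable, testable) or
in OWL — RDF/XML or Turtle — following the SOX class layout
(`XML_Structure`, `Simple_Term`, `Composite_Term`, `Search_Concept`,
`Search_Query`, `someValuesFrom` restrictions on `described_by` and `in`,
`has_part`, `max_distance`).  Vocabulary IRIs are matched by local name and
are configurable (`sox_iri_config()`), since no canonical namespace exists
for these class names.  One OWL caveat: per-label matching flags cannot be
attached to a plain `rdfs:label` literal, so in OWL the
`case_sensitive`/`whole_word` flags are per-term data properties; the native
format keeps them per-label.

## Compilation

`compile_query()` maps the boolean expression homomorphically to an
XPath 2.0 expression over the document root:

* A simple-term concept becomes
  `exists(path[matches(normalize-space(string(.)), 'regex') or …])`,
  one `matches()` disjunct per label.
* `whole_word` labels are wrapped as `(^|[^\wäöüÄÖÜß])(pattern)([^\wäöüÄÖÜß]|$)`.
  The explicit boundary class (rather than lookaround, which the XPath 2.0
  regex flavour lacks) includes the German umlauts and ß because the
  PCRE `\w` used at evaluation time is ASCII-only; without them, a stem
  would spuriously "end" before an umlaut.
* Case-insensitivity is the `'i'` flag of `fn:matches`, never a rewritten
  pattern.  Because that flag is global per regex, all parts of one
  composite term must share the `case_sensitive` flag (validation enforces
  this).  The default is case-sensitive: German nouns are capitalised, and
  sensitivity avoids false positives on short code-like labels.
* A composite term with parts *p₁ … p_k* and distance *d* emits, for every
  tuple of the parts' label cross product (and for both part orders when
  `ordered = FALSE`), one proximity regex joining consecutive labels with
  the gap template `(\s[^\s]+){0,d}\s`.  The template counts whole
  whitespace-delimited tokens, so punctuation-bearing tokens such as
  "2,5" or hyphenated compounds count as one intervening word; `d = 0`
  means the second word immediately follows the first.
* `NOT` compiles to `not(exists(…))`: a negated concept holds when *no*
  element at its path matches — including when the document has no such
  section at all.  That is the reading needed to exclude an explicit
  negation phrase wherever it occurs.

Output is deterministic: label order follows the model, tuple order is
lexicographic over part indices, so identical input yields byte-identical
XPath strings.  `annotate_model()` writes the strings back into the model
file (native or OWL, as an `xpath` annotation).

## Execution and the independence argument

The compiled strings target XPath 2.0 because regex matching needs
`fn:matches`; they are portable verbatim to BaseX, eXist or Saxon.  The
package's own engine executes them without an XPath 2.0 processor by
interpreting exactly the emitted grammar: location steps are delegated to
libxml2 (via xml2, namespace-aware), the boolean structure and the
`matches()` predicates are evaluated in R with PCRE.  Evaluation is a
function of the compiled *string*, not of the model.

`oracle_match()` is the package's second, deliberately separate route: it
walks the document along the structure tree, extracts normalised section
texts, applies label regexes with PCRE lookaround boundaries, checks
proximity by counting tokens, and evaluates the boolean tree directly — no
XPath, no shared code with the compiler.  The headline property test runs
both routes over hundreds of randomly generated model/corpus pairs and
requires exact agreement on every (document, query) pair.  Both routes
share one tokenizer (split on single spaces after whitespace
normalisation), which is what makes token-counted proximity well-defined on
both sides; label patterns are restricted to the regex subset PCRE and the
XPath 2.0 flavour interpret identically (character classes, quantifiers,
alternation, groups; no whitespace inside composite part labels).

## Reviewer diagnostics

Retrieval on section text alone has two systematic false-positive modes,
and the package turns both into automated reports rather than silent
filters:

* **Enumeration coreference (ECRI).**  Specimen and findings sections are
  often parallel numbered lists; a match pair is only meaningful when both
  matches sit in the same item ordinal (*x = y*).  The classic failures are
  a weight in item 13 with the carcinoma mentioned in a different item, or
  "Leiomyom" in item 11 of the interpretation against "Uterus" in item 15
  of the specimen list.  `enum_alignment_report()` detects items (a token
  `\d{1,2}[.)]` at text start or after a sentence end — the numbered style;
  nested or exotic enumeration styles are not modelled), assigns each match
  its ordinal, and flags documents where the positive concepts' ordinal
  sets have empty intersection.  Matches in unenumerated sections are
  wildcards.  The report *flags* documents; it never removes them, because
  alignment is a review aid, not part of the declared query semantics.
* **Physical-quantity coreference (PQCRI).**  A unit token in a section
  need not refer to the concept of interest.  `extract_quantities()` finds
  number+unit token pairs (decimal comma and point both accepted) and can
  require a term match within a token distance; `summarize_quantities()`
  reports n/min/max/mean/σ, with σ the population form (divide by *n*) —
  declared explicitly so tests are deterministic.

## The synthetic corpus generator

Real pathology corpora cannot be shipped, so `generate_corpus()` emulates
the phenomena the queries exercise, with a per-document ground-truth
manifest.  Its defaults are the package's study conditions:

* structure: `report/content` with the eight standard sections, three
  namespaces across the subtrees (to exercise prefix handling);
* enumeration lists in the material/macroscopy/interpretation sections with
  probability 0.64 per document (3–8 items, the numbered "k." style);
* term plantings per concept of the shipped five-question model, with
  prevalences (0.10–0.40) chosen so every query variant has a non-trivial
  positive set at a few hundred documents;
* prostate flake weights drawn from normal(18.26, 10.18) grams and
  leiomyoma diameters from normal(2.76, 1.42) cm — both truncated at zero
  by rejection, since weights and sizes are non-negative and the weight σ
  exceeds half the mean — rendered with a German decimal comma at one
  decimal place, the unit token adjacent to the value;
* an exclusion phrase ("ohne Nachweis einer Barrett-Schleimhaut") planted
  in the interpretation section; note it *contains* the Barrett term, so a
  planting satisfies the Barrett concept while defeating the negated query
  — exactly the situation the negation semantics must handle;
* optional injections: misaligned enumeration ordinals (ECRI cases) and
  stray unit tokens unrelated to any term (PQCRI cases).

Plantings are atomic token runs (filler is interleaved between, never
inside them), manifests record section, item ordinal, surface form and
quantity value, and query truth sets are derived from the plantings under
the declared existential semantics.  Identical spec + seed give
byte-identical corpora.  What the generator does **not** emulate: free-text
reports needing section-boundary detection, realistic German syntax,
spelling errors, nested enumerations, or corpus-scale class imbalance — so
green tests demonstrate the correctness of compilation, evaluation and
diagnostics under the declared semantics, not retrieval quality on real
clinical text.

## Numerical and design choices

* Quantity values are rounded to one decimal at rendering, and the
  manifest stores the rendered value, so extraction can be checked for
  *exact* recovery; moment checks compare against the closed-form
  zero-truncated-normal moments of the generator at 3 standard errors.
* Problem sizes in tests: the equivalence property uses 200 random pairs of
  up to 10 concepts and 8–25 documents; the five-question reproduction uses
  500 documents; the quantity pipeline 1100 planted values.  These sizes
  give the property tests real variety while keeping the whole suite under
  a minute.
* Degenerate inputs: documents with missing sections make positive concepts
  false and negated concepts true; malformed XML files are reported
  per-document and skipped, never aborting a corpus run; empty label
  patterns and invalid regexes are load-time errors.
* Open points resolved as design choices: one concept binds exactly one
  term (use OR at query level for unions); `has_part` does not imply word
  order — the `ordered` flag defaults to FALSE and both orders are matched;
  `max_distance` is required, with no silent default.

## Limitations

The OWL reader supports the SOX subset (typed individuals/classes,
`someValuesFrom` restrictions, boolean class expressions over
intersections/unions/complements, RDF collections), not arbitrary OWL;
reasoning over upper-level ontologies is out of scope.  The engine's XPath
interpreter accepts exactly the compiler's grammar — it is an executor for
generated queries, not a general XPath 2.0 processor.  Enumeration
detection covers the numbered style; the alignment report is advisory.
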