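# Reviewer-support diagnostics: enumeration coreference (ECRI) and physical
# quantity extraction/summarisation (PQCRI side).  These produce reports for
# the manual review; they flag documents but never remove them from result
# sets.

# Enumeration item detection on a normalized section text.  An item starts at
# a token `\d{1,2}[.)]` standing at the text start or right after a sentence
# end (previous token ending in . : or ;).  Returns per token the item
# ordinal it belongs to (NA before the first marker or when the section has
# no enumeration).
enum_item_of_tokens <- function(tokens) {
  n <- length(tokens)
  ord <- rep(NA_integer_, n)
  if (!n) return(ord)
  cur <- NA_integer_
  for (k in seq_len(n)) {
    is_marker <- grepl("^[0-9]{1,2}[.)]$", tokens[k]) &&
      (k == 1L || grepl("[.:;]$", tokens[k - 1L]))
    if (is_marker) cur <- as.integer(sub("[.)]$", "", tokens[k]))
    ord[k] <- cur
  }
  ord
}

# Item ordinals covered by character spans within a text; NA span positions
# (outside items / unenumerated) are dropped.
span_item_ordinals <- function(text, spans) {
  tokens <- tokenize(text)
  if (!length(tokens) || !nrow(spans)) return(integer(0))
  starts <- token_starts(tokens)
  ends <- starts + nchar(tokens) - 1L
  item <- enum_item_of_tokens(tokens)
  out <- integer(0)
  for (r in seq_len(nrow(spans))) {
    covered <- which(ends >= spans$start[r] & starts <= spans$end[r])
    out <- c(out, item[covered])
  }
  sort(unique(out[!is.na(out)]))
}

# Does the text contain any enumeration item marker at all?
text_is_enumerated <- function(text) {
  any(!is.na(enum_item_of_tokens(tokenize(text))))
}

#' Enumeration-coreference alignment report (ECRI)
#'
#' Co-occurring matches inside enumerated sections are false positives when
#' they sit in different enumeration items: a weight in item 13 of the
#' specimen list only belongs to an adenocarcinoma mentioned in item 13 of
#' the interpretation list (x = y); item 11 vs item 15 is a coreference
#' mismatch.  For each document (per query) the report collects, for every
#' positive concept, the set of item ordinals its matches fall into;
#' `aligned` is `TRUE` iff the intersection of all constrained concepts'
#' ordinal sets is non-empty.  Matches in sections without enumeration (or
#' outside any item) are wildcards: they align with anything.  The report
#' flags documents; it never removes them.
#'
#' @param snippets List of snippet records from [fetch_snippets()].
#' @param model The [sox_model()].
#' @return List of reports, one per (doc_id, query_id) present in
#'   `snippets`: each has `doc_id`, `query_id`, `item_indices` (named list
#'   concept -> integer ordinals), `aligned`, `details`.
#' @export
enum_alignment_report <- function(snippets, model) {
  if (!length(snippets)) return(list())
  keys <- vapply(snippets, function(s) paste(s$doc_id, s$query_id, sep = "\r"),
                 "")
  out <- list()
  for (key in unique(keys)) {
    group <- snippets[keys == key]
    doc_id <- group[[1L]]$doc_id
    query_id <- group[[1L]]$query_id
    cids <- unique(vapply(group, function(s) s$concept_id, ""))
    item_indices <- list()
    wildcard <- character(0)
    for (cid in cids) {
      recs <- group[vapply(group, function(s) s$concept_id == cid, TRUE)]
      ords <- integer(0)
      any_wild <- FALSE
      for (rec in recs) {
        o <- span_item_ordinals(rec$text, rec$matched_spans)
        if (length(o)) ords <- c(ords, o)
        # a match with no ordinal (unenumerated section or outside items)
        # imposes no constraint
        tokens <- tokenize(rec$text)
        starts <- token_starts(tokens)
        ends <- starts + nchar(tokens) - 1L
        item <- enum_item_of_tokens(tokens)
        for (r in seq_len(nrow(rec$matched_spans))) {
          covered <- which(ends >= rec$matched_spans$start[r] &
                             starts <= rec$matched_spans$end[r])
          if (!length(covered) || anyNA(item[covered])) any_wild <- TRUE
        }
      }
      item_indices[[cid]] <- sort(unique(ords))
      if (any_wild || !length(ords)) wildcard <- c(wildcard, cid)
    }
    constrained <- setdiff(cids, wildcard)
    aligned <- TRUE
    if (length(constrained) >= 2L) {
      inter <- item_indices[[constrained[1L]]]
      for (cid in constrained[-1L]) {
        inter <- intersect(inter, item_indices[[cid]])
      }
      aligned <- length(inter) > 0L
    }
    details <- if (aligned) {
      "positive concepts share an enumeration item (or are unconstrained)"
    } else {
      paste0("disjoint item ordinals: ",
             paste(vapply(constrained, function(cid) {
               paste0(cid, "={", paste(item_indices[[cid]], collapse = ","),
                      "}")
             }, ""), collapse = " vs "))
    }
    out[[length(out) + 1L]] <- structure(
      list(doc_id = doc_id, query_id = query_id, item_indices = item_indices,
           aligned = aligned, details = details),
      class = "sox_enum_report")
  }
  out
}

value_token_re <- "^[0-9]+([.,][0-9]+)?$"

parse_decimal <- function(x) as.numeric(sub(",", ".", x, fixed = TRUE))

#' Extract physical quantities from snippets
#'
#' Scans snippet texts for number+unit token pairs: a numeric token (decimal
#' comma and decimal point both accepted) immediately followed by a token
#' matching `unit_pattern` at a word boundary.  With a `proximity_term`, a
#' quantity is kept only when a match of that term occurs within
#' `max_distance` intervening tokens of the value token -- the composite-term
#' remedy for unit mentions that do not refer to the concept of interest.
#'
#' @param snippets List of snippet records ([fetch_snippets()]).
#' @param unit_pattern Regex for the unit token (e.g. `"g"`, `"cm"`).
#' @param proximity_term Optional [simple_term()] that must occur nearby.
#' @param max_distance Token gap bound for the proximity filter.
#' @return data.frame with columns `doc_id`, `value`, `unit`.
#' @export
extract_quantities <- function(snippets, unit_pattern, proximity_term = NULL,
                               max_distance = 2L) {
  rows <- list()
  seen <- character(0)
  for (rec in snippets) {
    key <- paste(rec$doc_id, rec$section_path, rec$section_index, sep = "\r")
    if (key %in% seen) next  # one concept per section is enough for scanning
    seen <- c(seen, key)
    tokens <- tokenize(rec$text)
    if (length(tokens) < 2L) next
    term_pos <- if (!is.null(proximity_term)) {
      hit <- rep(FALSE, length(tokens))
      for (lb in proximity_term$labels) {
        hit <- hit | vapply(tokens, function(tk) {
          nrow(label_occurrences(lb$pattern, tk, lb$case_sensitive,
                                 lb$whole_word)) > 0L
        }, TRUE)
      }
      which(hit)
    } else {
      integer(0)
    }
    for (k in 2L:length(tokens)) {
      val_tok <- tokens[k - 1L]
      unit_tok <- tokens[k]
      if (!grepl(value_token_re, val_tok)) next
      unit_hit <- label_occurrences(unit_pattern, unit_tok)
      if (!nrow(unit_hit)) next
      if (!is.null(proximity_term)) {
        gaps <- abs((k - 1L) - term_pos) - 1L
        if (!length(term_pos) || min(gaps) > max_distance) next
      }
      val <- parse_decimal(val_tok)
      if (is.na(val)) {
        warning("skipping unparsable quantity token: ", val_tok,
                call. = FALSE)
        next
      }
      unit <- substr(unit_tok, unit_hit$start[1L], unit_hit$end[1L])
      rows[[length(rows) + 1L]] <- data.frame(doc_id = rec$doc_id,
                                              value = val, unit = unit,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(doc_id = character(0), value = numeric(0),
                      unit = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Summarise extracted quantities
#'
#' Reporting shape for answering quantitative questions from retrieved
#' records: n, min, max, arithmetic mean and population standard deviation
#' (divide by n -- declared so tests are deterministic).  An empty input
#' yields `n = 0` with `NA` statistics.
#'
#' @param values Numeric vector.
#' @param unit Unit string carried through.
#' @return A list of class `sox_quantity_summary` with `unit`, `values`, `n`,
#'   `min`, `max`, `mean`, `sd`.
#' @export
summarize_quantities <- function(values, unit = "") {
  values <- as.numeric(values)
  n <- length(values)
  out <- if (n == 0L) {
    list(unit = unit, values = values, n = 0L, min = NA_real_, max = NA_real_,
         mean = NA_real_, sd = NA_real_)
  } else {
    m <- mean(values)
    list(unit = unit, values = values, n = n, min = min(values),
         max = max(values), mean = m, sd = sqrt(mean((values - m)^2)))
  }
  structure(out, class = "sox_quantity_summary")
}

#' @export
print.sox_quantity_summary <- function(x, ...) {
  if (x$n == 0L) {
    cat("<quantity summary> no values\n")
    return(invisible(x))
  }
  cat(sprintf("<quantity summary> n=%d  min=%g %s  max=%g %s  mean=%.2f %s  sd=%.2f %s\n",
              x$n, x$min, x$unit, x$max, x$unit, x$mean, x$unit, x$sd,
              x$unit))
  invisible(x)
}
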