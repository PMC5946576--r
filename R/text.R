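# Shared text utilities: whitespace normalisation and the single tokenizer
# used by the snippet/diagnostic side and the oracle (tokens are maximal
# non-space runs of the normalize-space'd text; punctuation stays attached).
# Nothing here is used by the XPath compiler.

normalize_space <- function(x) {
  gsub("[ \t\r\n]+", " ", trimws(x))
}

tokenize <- function(text) {
  if (!nzchar(text)) return(character(0))
  strsplit(text, " ", fixed = TRUE)[[1L]]
}

# Start offsets (1-based) of each token within the normalized text.
token_starts <- function(tokens) {
  if (!length(tokens)) return(integer(0))
  cumsum(c(1L, nchar(tokens[-length(tokens)]) + 1L))
}

# Character spans of word-boundary-respecting occurrences of a label pattern.
# Independent of the compiler: boundaries are enforced with PCRE lookaround,
# which the compiled XPath dialect cannot use.
label_occurrences <- function(pattern, text, case_sensitive = TRUE,
                              whole_word = TRUE) {
  wc <- word_class_chars
  re <- if (whole_word) {
    paste0("(?<![", wc, "])(?:", pattern, ")(?![", wc, "])")
  } else {
    paste0("(?:", pattern, ")")
  }
  m <- gregexpr(re, text, perl = TRUE, ignore.case = !case_sensitive)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# --- token-level part matching for proximity phrases ------------------------
#
# The proximity gap template forces every part except the first to start at a
# token start, and every part except the last to end at a token end.  The
# helpers below test one token for each role.

part_match_end <- function(token, pattern, whole_word, case_sensitive) {
  wc <- word_class_chars
  re <- paste0(if (whole_word) paste0("(?<![", wc, "])"), "(?:", pattern, ")$")
  grepl(re, token, perl = TRUE, ignore.case = !case_sensitive)
}

part_match_start <- function(token, pattern, whole_word, case_sensitive) {
  wc <- word_class_chars
  re <- paste0("^(?:", pattern, ")", if (whole_word) paste0("(?![", wc, "])"))
  grepl(re, token, perl = TRUE, ignore.case = !case_sensitive)
}

part_match_full <- function(token, pattern, case_sensitive) {
  grepl(paste0("^(?:", pattern, ")$"), token, perl = TRUE,
        ignore.case = !case_sensitive)
}

# Token positions where any label of `st` matches in role "first" / "middle" /
# "last" of a proximity sequence.
part_positions <- function(st, tokens, role) {
  hit <- rep(FALSE, length(tokens))
  for (lb in st$labels) {
    h <- switch(role,
      first = vapply(tokens, part_match_end, TRUE, pattern = lb$pattern,
                     whole_word = lb$whole_word,
                     case_sensitive = lb$case_sensitive),
      last = vapply(tokens, part_match_start, TRUE, pattern = lb$pattern,
                    whole_word = lb$whole_word,
                    case_sensitive = lb$case_sensitive),
      middle = vapply(tokens, part_match_full, TRUE, pattern = lb$pattern,
                      case_sensitive = lb$case_sensitive))
    hit <- hit | h
  }
  which(hit)
}

part_role <- function(k, n) {
  if (k == 1L) "first" else if (k == n) "last" else "middle"
}

# Does a composite term match the token sequence?  Checks both part orders
# when unordered.  Returns TRUE/FALSE.
composite_tokens_match <- function(term, model, tokens) {
  parts <- lapply(term$parts, function(p) model$simple_terms[[p]])
  d <- term$max_distance
  orders <- list(seq_along(parts))
  if (!term$ordered) orders <- c(orders, list(rev(seq_along(parts))))
  for (ord in orders) {
    seqs <- parts[ord]
    n <- length(seqs)
    reach <- part_positions(seqs[[1L]], tokens, part_role(1L, n))
    ok <- length(reach) > 0L
    if (ok && n > 1L) {
      for (k in 2L:n) {
        pk <- part_positions(seqs[[k]], tokens, part_role(k, n))
        reach <- pk[vapply(pk, function(j) {
          any(reach < j & (j - reach - 1L) <= d)
        }, TRUE)]
        if (!length(reach)) { ok <- FALSE; break }
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# Token indices (per part) that participate in at least one valid proximity
# chain, over both orders; returns sorted unique token indices.
composite_participants <- function(term, model, tokens) {
  parts <- lapply(term$parts, function(p) model$simple_terms[[p]])
  d <- term$max_distance
  orders <- list(seq_along(parts))
  if (!term$ordered) orders <- c(orders, list(rev(seq_along(parts))))
  out <- integer(0)
  for (ord in orders) {
    seqs <- parts[ord]
    n <- length(seqs)
    pos <- lapply(seq_len(n), function(k) {
      part_positions(seqs[[k]], tokens, part_role(k, n))
    })
    fwd <- vector("list", n)  # reachable from the chain start
    fwd[[1L]] <- pos[[1L]]
    if (n > 1L) for (k in 2L:n) {
      fwd[[k]] <- pos[[k]][vapply(pos[[k]], function(j) {
        any(fwd[[k - 1L]] < j & (j - fwd[[k - 1L]] - 1L) <= d)
      }, TRUE)]
    }
    bwd <- vector("list", n)  # can reach the chain end
    bwd[[n]] <- fwd[[n]]
    if (n > 1L) for (k in (n - 1L):1L) {
      bwd[[k]] <- fwd[[k]][vapply(fwd[[k]], function(i) {
        any(bwd[[k + 1L]] > i & (bwd[[k + 1L]] - i - 1L) <= d)
      }, TRUE)]
    }
    out <- c(out, unlist(bwd))
  }
  sort(unique(out))
}

# Does a simple term match anywhere in the text?
simple_term_text_match <- function(term, text) {
  for (lb in term$labels) {
    if (nrow(label_occurrences(lb$pattern, text, lb$case_sensitive,
                               lb$whole_word))) {
      return(TRUE)
    }
  }
  FALSE
}

# Character spans matched by a term within a normalized section text;
# data.frame(pattern, start, end).  For composite terms, the spans of the
# part-label matches that participate in a valid proximity chain.
term_match_spans <- function(term, text, model) {
  empty <- data.frame(pattern = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (inherits(term, "sox_simple_term")) {
    out <- lapply(term$labels, function(lb) {
      occ <- label_occurrences(lb$pattern, text, lb$case_sensitive,
                               lb$whole_word)
      if (!nrow(occ)) return(NULL)
      cbind(data.frame(pattern = lb$pattern, stringsAsFactors = FALSE), occ)
    })
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out)) return(empty)
    return(do.call(rbind, out))
  }
  tokens <- tokenize(text)
  idx <- composite_participants(term, model, tokens)
  if (!length(idx)) return(empty)
  starts <- token_starts(tokens)
  rows <- list()
  for (i in idx) {
    tok <- tokens[i]
    for (pid in term$parts) {
      st <- model$simple_terms[[pid]]
      for (lb in st$labels) {
        # locate the part match inside the token (any role)
        m <- regexpr(paste0("(?:", lb$pattern, ")"), tok, perl = TRUE,
                     ignore.case = !lb$case_sensitive)
        if (m > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            pattern = lb$pattern,
            start = starts[i] + as.integer(m) - 1L,
            end = starts[i] + as.integer(m) + attr(m, "match.length") - 2L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  unique(do.call(rbind, rows))
}
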