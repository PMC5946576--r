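# Interpreter for the compiled XPath dialect.
#
# libxml2 speaks XPath 1.0 only, so the engine re-parses the compiled
# XPath 2.0 string: location steps are delegated to xml2 (namespace-aware
# node selection), while the boolean structure and the fn:matches regex
# predicates are evaluated in R.  Only the grammar the compiler emits is
# accepted; anything else is a parse error.  This keeps evaluation a pure
# function of the compiled *string*, independent of the oracle's direct
# matching route.

xpath_cursor <- function(s) {
  env <- new.env(parent = emptyenv())
  env$s <- s
  env$pos <- 1L
  env$n <- nchar(s)
  env
}

xc_rest <- function(cur) substr(cur$s, cur$pos, cur$n)

xc_ws <- function(cur) {
  m <- regexpr("^[ \t\r\n]+", xc_rest(cur))
  if (m > 0L) cur$pos <- cur$pos + attr(m, "match.length")
  invisible(NULL)
}

xc_lit <- function(cur, lit, required = TRUE) {
  if (startsWith(xc_rest(cur), lit)) {
    cur$pos <- cur$pos + nchar(lit)
    return(TRUE)
  }
  if (required) {
    stop("compiled XPath parse error: expected '", lit, "' at ...",
         substr(xc_rest(cur), 1L, 40L), call. = FALSE)
  }
  FALSE
}

xc_take <- function(cur, regex) {
  m <- regexpr(paste0("^", regex), xc_rest(cur), perl = TRUE)
  if (m < 0L) {
    stop("compiled XPath parse error at ...", substr(xc_rest(cur), 1L, 40L),
         call. = FALSE)
  }
  out <- substr(cur$s, cur$pos, cur$pos + attr(m, "match.length") - 1L)
  cur$pos <- cur$pos + attr(m, "match.length")
  out
}

# XPath single-quoted string literal; '' escapes a quote.
xc_string <- function(cur) {
  xc_lit(cur, "'")
  out <- character(0)
  repeat {
    rest <- xc_rest(cur)
    q <- regexpr("'", rest, fixed = TRUE)
    if (q < 0L) stop("unterminated XPath string literal", call. = FALSE)
    out <- c(out, substr(rest, 1L, q - 1L))
    cur$pos <- cur$pos + q
    if (startsWith(xc_rest(cur), "'")) {  # escaped quote
      out <- c(out, "'")
      cur$pos <- cur$pos + 1L
    } else {
      break
    }
  }
  paste0(out, collapse = "")
}

xc_step <- function(cur) xc_take(cur, "[A-Za-z_][\\w.-]*(:[A-Za-z_][\\w.-]*)?")

parse_matches_call <- function(cur) {
  xc_lit(cur, "matches(normalize-space(string(.)), ")
  regex <- xc_string(cur)
  ci <- FALSE
  xc_ws(cur)
  if (xc_lit(cur, ",", required = FALSE)) {
    xc_ws(cur)
    flags <- xc_string(cur)
    ci <- grepl("i", flags, fixed = TRUE)
  }
  xc_ws(cur)
  xc_lit(cur, ")")
  list(regex = regex, ci = ci)
}

parse_exists <- function(cur) {
  xc_lit(cur, "exists(")
  steps <- character(0)
  if (startsWith(xc_rest(cur), ".")) {
    xc_lit(cur, ".")
  } else {
    steps <- xc_step(cur)
    while (startsWith(xc_rest(cur), "/")) {
      xc_lit(cur, "/")
      steps <- c(steps, xc_step(cur))
    }
  }
  xc_lit(cur, "[")
  disjuncts <- list(parse_matches_call(cur))
  repeat {
    xc_ws(cur)
    if (!xc_lit(cur, "or ", required = FALSE)) break
    xc_ws(cur)
    disjuncts[[length(disjuncts) + 1L]] <- parse_matches_call(cur)
  }
  xc_lit(cur, "]")
  xc_lit(cur, ")")
  list(kind = "exists", steps = steps, disjuncts = disjuncts)
}

parse_unary <- function(cur) {
  xc_ws(cur)
  rest <- xc_rest(cur)
  if (startsWith(rest, "not(")) {
    xc_lit(cur, "not(")
    inner <- parse_or_expr(cur)
    xc_lit(cur, ")")
    return(list(kind = "not", arg = inner))
  }
  if (startsWith(rest, "exists(")) return(parse_exists(cur))
  if (startsWith(rest, "(")) {
    xc_lit(cur, "(")
    inner <- parse_or_expr(cur)
    xc_lit(cur, ")")
    return(inner)
  }
  stop("compiled XPath parse error at ...", substr(rest, 1L, 40L),
       call. = FALSE)
}

parse_and_expr <- function(cur) {
  args <- list(parse_unary(cur))
  repeat {
    xc_ws(cur)
    if (!xc_lit(cur, "and ", required = FALSE)) break
    args[[length(args) + 1L]] <- parse_unary(cur)
  }
  if (length(args) == 1L) args[[1L]] else list(kind = "and", args = args)
}

parse_or_expr <- function(cur) {
  args <- list(parse_and_expr(cur))
  repeat {
    xc_ws(cur)
    if (!xc_lit(cur, "or ", required = FALSE)) break
    args[[length(args) + 1L]] <- parse_and_expr(cur)
  }
  if (length(args) == 1L) args[[1L]] else list(kind = "or", args = args)
}

# Parse a compiled query string into {root_step, expr}.
parse_compiled_xpath <- function(xpath) {
  cur <- xpath_cursor(xpath)
  xc_lit(cur, "/")
  root_step <- xc_step(cur)
  xc_lit(cur, "[")
  expr <- parse_or_expr(cur)
  xc_ws(cur)
  xc_lit(cur, "]")
  xc_ws(cur)
  if (cur$pos <= cur$n) {
    stop("trailing characters in compiled XPath", call. = FALSE)
  }
  list(root_step = root_step, expr = expr)
}

# Evaluate a parsed compiled query against one xml2 document.
eval_compiled_on_doc <- function(parsed, doc, pmap) {
  find_nodes <- function(steps) {
    path <- paste0("/", paste(c(parsed$root_step, steps), collapse = "/"))
    if (length(pmap)) {
      xml2::xml_find_all(doc, path, ns = pmap)
    } else {
      xml2::xml_find_all(doc, path)
    }
  }
  rec <- function(e) {
    switch(e$kind,
      exists = {
        nodes <- find_nodes(e$steps)
        if (!length(nodes)) return(FALSE)
        texts <- vapply(nodes, function(nd) {
          normalize_space(xml2::xml_text(nd))
        }, "")
        for (d in e$disjuncts) {
          if (any(grepl(d$regex, texts, perl = TRUE, ignore.case = d$ci))) {
            return(TRUE)
          }
        }
        FALSE
      },
      not = !rec(e$arg),
      and = all(vapply(e$args, rec, TRUE)),
      or = any(vapply(e$args, rec, TRUE)))
  }
  rec(parsed$expr)
}
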