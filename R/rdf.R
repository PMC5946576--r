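# Minimal RDF triple reading/writing for the OWL subset the SOX class layout
# uses.  No installed R package parses RDF, so this is purpose-built: it
# covers typed node elements, rdf:about/rdf:ID/rdf:nodeID, nested blank
# nodes, rdf:parseType="Collection", literals, and (for Turtle) prefixed
# names, blank-node property lists, collections and literal datatypes/tags.
# Triples are kept in file order; list structures use rdf:first/rest/nil.

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"

new_triple_store <- function() {
  env <- new.env(parent = emptyenv())
  env$s <- character(0); env$p <- character(0)
  env$o <- character(0); env$lit <- logical(0)
  env$bn <- 0L
  env
}

ts_add <- function(ts, s, p, o, lit = FALSE) {
  # force all arguments first: an `o` expression may itself append triples
  # (rdf list construction), which must land before this triple
  force(s); force(p); force(o); force(lit)
  ts$s <- c(ts$s, s); ts$p <- c(ts$p, p); ts$o <- c(ts$o, o)
  ts$lit <- c(ts$lit, lit)
}

ts_bnode <- function(ts) {
  ts$bn <- ts$bn + 1L
  paste0("_:b", ts$bn)
}

ts_df <- function(ts) {
  data.frame(s = ts$s, p = ts$p, o = ts$o, lit = ts$lit,
             stringsAsFactors = FALSE)
}

# Local part of an IRI: after '#', else after the last '/' (or ':' for urns).
iri_local <- function(iri) {
  x <- sub("^.*#", "", iri)
  if (identical(x, iri)) x <- sub("^.*/", "", x)
  if (identical(x, iri)) x <- sub("^.*:", "", x)
  x
}

# ---------------------------------------------------------------- RDF/XML --

ns_lookup <- function(nsmap, pfx) {
  # nsmap is a named character vector; a missing prefix yields NA, not an
  # error (namespace declaration pseudo-attributes carry an "xmlns" prefix)
  if (pfx %in% names(nsmap)) unname(nsmap[pfx]) else NA_character_
}

rdfxml_name <- function(node, nsmap) {
  full <- xml2::xml_name(node, ns = nsmap)
  local <- xml2::xml_name(node)
  if (identical(full, local)) return(local)  # no namespace
  uri <- ns_lookup(nsmap, sub(":.*$", "", full))
  if (is.na(uri)) local else paste0(uri, local)
}

rdfxml_attr <- function(node, local, nsmap) {
  attrs <- xml2::xml_attrs(node, ns = nsmap)
  if (!length(attrs)) return(NA_character_)
  want <- paste0(RDF_NS, local)
  keys <- names(attrs)
  expanded <- vapply(keys, function(k) {
    if (!grepl(":", k)) return(k)
    uri <- ns_lookup(nsmap, sub(":.*$", "", k))
    if (!is.na(uri)) paste0(uri, sub("^[^:]*:", "", k)) else k
  }, "")
  hit <- which(expanded == want)
  if (!length(hit)) NA_character_ else unname(attrs[hit[1L]])
}

parse_rdfxml <- function(path) {
  doc <- xml2::read_xml(path)
  nsmap <- xml2::xml_ns(doc)
  ts <- new_triple_store()

  node_subject <- function(el) {
    about <- rdfxml_attr(el, "about", nsmap)
    if (!is.na(about)) return(about)
    id <- rdfxml_attr(el, "ID", nsmap)
    if (!is.na(id)) return(paste0("#", id))
    nid <- rdfxml_attr(el, "nodeID", nsmap)
    if (!is.na(nid)) return(paste0("_:", nid))
    ts_bnode(ts)
  }

  parse_node <- function(el) {
    subj <- node_subject(el)
    nm <- rdfxml_name(el, nsmap)
    if (!identical(nm, paste0(RDF_NS, "Description"))) {
      ts_add(ts, subj, paste0(RDF_NS, "type"), nm)
    }
    for (prop in xml2::xml_children(el)) {
      pred <- rdfxml_name(prop, nsmap)
      res <- rdfxml_attr(prop, "resource", nsmap)
      nid <- rdfxml_attr(prop, "nodeID", nsmap)
      ptype <- rdfxml_attr(prop, "parseType", nsmap)
      kids <- xml2::xml_children(prop)
      if (!is.na(res)) {
        ts_add(ts, subj, pred, res)
      } else if (!is.na(nid)) {
        ts_add(ts, subj, pred, paste0("_:", nid))
      } else if (!is.na(ptype) && ptype == "Collection") {
        items <- vapply(kids, parse_node, "")
        ts_add(ts, subj, pred, rdf_list_triples(ts, items))
      } else if (length(kids)) {
        obj <- parse_node(kids[[1L]])
        ts_add(ts, subj, pred, obj)
      } else {
        ts_add(ts, subj, pred, xml2::xml_text(prop), lit = TRUE)
      }
    }
    subj
  }

  # parse_node appends the object triples before the referring triple; that is
  # fine for interpretation (order matters only among same-predicate triples
  # of one subject, which parse in document order)
  for (el in xml2::xml_children(doc)) parse_node(el)
  ts_df(ts)
}

rdf_list_triples <- function(ts, items) {
  nil <- paste0(RDF_NS, "nil")
  if (!length(items)) return(nil)
  heads <- vapply(items, function(i) ts_bnode(ts), "")
  for (k in seq_along(items)) {
    ts_add(ts, heads[k], paste0(RDF_NS, "first"), items[[k]])
    ts_add(ts, heads[k], paste0(RDF_NS, "rest"),
           if (k < length(items)) heads[k + 1L] else nil)
  }
  heads[1L]
}

# Follow an rdf:first/rdf:rest chain; returns character vector of members.
rdf_list_members <- function(df, head) {
  nil <- paste0(RDF_NS, "nil")
  out <- character(0)
  guard <- 0L
  while (!identical(head, nil)) {
    first <- df$o[df$s == head & df$p == paste0(RDF_NS, "first")]
    rest <- df$o[df$s == head & df$p == paste0(RDF_NS, "rest")]
    if (!length(first) || !length(rest)) {
      stop("malformed RDF list at ", head, call. = FALSE)
    }
    out <- c(out, first[1L])
    head <- rest[1L]
    guard <- guard + 1L
    if (guard > nrow(df)) stop("cyclic RDF list", call. = FALSE)
  }
  out
}

# ------------------------------------------------------------------ Turtle --

turtle_tokens <- function(text) {
  n <- nchar(text)
  toks <- list()
  i <- 1L
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(type = type,
                                                                   value = value)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "#") {
      while (i <= n && substr(text, i, i) != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (j < 0) stop("unterminated IRI in Turtle input", call. = FALSE)
      push("iri", substr(text, i + 1L, i + j - 2L))
      i <- i + j
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      buf <- character(0)
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") {
          esc <- substr(text, j + 1L, j + 1L)
          buf <- c(buf, switch(esc, n = "\n", t = "\t", r = "\r",
                               "\"" = "\"", "\\" = "\\", esc))
          j <- j + 2L
        } else if (cj == "\"") {
          break
        } else {
          buf <- c(buf, cj)
          j <- j + 1L
        }
      }
      if (j > n) stop("unterminated string in Turtle input", call. = FALSE)
      push("literal", paste0(buf, collapse = ""))
      i <- j + 1L
      # consume optional datatype / language tag
      rest <- substr(text, i, n)
      m <- regmatches(rest, regexpr("^(\\^\\^<[^>]*>|\\^\\^[A-Za-z_][\\w.-]*:[\\w.-]*|@[A-Za-z-]+)",
                                    rest, perl = TRUE))
      if (length(m) && nzchar(m)) i <- i + nchar(m)
      next
    }
    if (ch %in% c("(", ")", "[", "]", ";", ",")) {
      push(ch, ch); i <- i + 1L; next
    }
    if (ch == ".") {
      push(".", "."); i <- i + 1L; next
    }
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^@?[A-Za-z0-9_][A-Za-z0-9_.:-]*", rest,
                                  perl = TRUE))
    if (length(m) && nzchar(m)) {
      tok <- sub("\\.+$", "", m)  # statement-final dot glued to a name
      push("name", tok)
      i <- i + nchar(tok)
      next
    }
    stop("cannot tokenize Turtle input at: ",
         substr(text, i, min(n, i + 20L)), call. = FALSE)
  }
  toks
}

parse_turtle <- function(path) {
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  toks <- turtle_tokens(text)
  ts <- new_triple_store()
  prefixes <- list()
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type) {
      stop("Turtle parse error: expected '", type, "'", call. = FALSE)
    }
    advance()
  }

  expand_name <- function(nm) {
    if (nm == "a") return(paste0(RDF_NS, "type"))
    if (grepl("^_:", nm)) return(nm)
    if (!grepl(":", nm)) stop("bare name in Turtle: ", nm, call. = FALSE)
    pfx <- sub(":.*$", "", nm)
    local <- sub("^[^:]*:", "", nm)
    base <- prefixes[[pfx]]
    if (is.null(base)) stop("undeclared Turtle prefix: ", pfx, call. = FALSE)
    paste0(base, local)
  }

  parse_object <- function() {
    t <- peek()
    if (is.null(t)) stop("Turtle parse error: unexpected end", call. = FALSE)
    if (t$type == "iri") { advance(); return(list(v = t$value, lit = FALSE)) }
    if (t$type == "literal") { advance(); return(list(v = t$value, lit = TRUE)) }
    if (t$type == "name") {
      advance()
      if (grepl("^[0-9]+(\\.[0-9]+)?$", t$value) ||
          t$value %in% c("true", "false")) {
        return(list(v = t$value, lit = TRUE))
      }
      return(list(v = expand_name(t$value), lit = FALSE))
    }
    if (t$type == "[") {
      advance()
      b <- ts_bnode(ts)
      if (peek()$type != "]") parse_predicate_objects(b)
      expect("]")
      return(list(v = b, lit = FALSE))
    }
    if (t$type == "(") {
      advance()
      items <- character(0)
      while (peek()$type != ")") items <- c(items, parse_object()$v)
      expect(")")
      return(list(v = rdf_list_triples(ts, as.list(items)), lit = FALSE))
    }
    stop("Turtle parse error near '", t$value, "'", call. = FALSE)
  }

  parse_predicate_objects <- function(subj) {
    repeat {
      t <- peek()
      if (is.null(t) || !(t$type %in% c("name", "iri"))) break
      advance()
      pred <- if (t$type == "iri") t$value else expand_name(t$value)
      repeat {
        obj <- parse_object()
        ts_add(ts, subj, pred, obj$v, obj$lit)
        if (!is.null(peek()) && peek()$type == ",") advance() else break
      }
      if (!is.null(peek()) && peek()$type == ";") advance() else break
    }
  }

  while (!is.null(peek())) {
    t <- peek()
    if (t$type == "name" && t$value %in% c("@prefix", "@base")) {
      advance()
      if (t$value == "@prefix") {
        pfx <- expect("name")$value
        pfx <- sub(":$", "", pfx)
        iri <- expect("iri")$value
        prefixes[[pfx]] <- iri
      } else {
        expect("iri")
      }
      expect(".")
      next
    }
    subj <- {
      if (t$type == "iri") { advance(); t$value }
      else if (t$type == "name") { advance(); expand_name(t$value) }
      else if (t$type == "[") {
        advance(); b <- ts_bnode(ts)
        if (peek()$type != "]") parse_predicate_objects(b)
        expect("]"); b
      } else stop("Turtle parse error near '", t$value, "'", call. = FALSE)
    }
    parse_predicate_objects(subj)
    expect(".")
  }
  ts_df(ts)
}

# -------------------------------------------------------- generic writers --

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

split_iri <- function(iri) {
  m <- regexpr("[#/][^#/]*$", iri, perl = TRUE)
  if (m < 0) return(c(ns = "", local = iri))
  c(ns = substr(iri, 1L, m), local = substr(iri, m + 1L, nchar(iri)))
}

write_triples_rdfxml <- function(df, path) {
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<rdf:RDF xmlns:rdf=\"", RDF_NS, "\">"))
  ref_attr <- function(x) {
    if (grepl("^_:", x)) {
      paste0("rdf:nodeID=\"", sub("^_:", "", x), "\"")
    } else {
      paste0("rdf:about=\"", xml_escape(x), "\"")
    }
  }
  for (k in seq_len(nrow(df))) {
    sp <- split_iri(df$p[k])
    ptag <- paste0("p:", sp[["local"]])
    pdecl <- paste0(" xmlns:p=\"", xml_escape(sp[["ns"]]), "\"")
    obj <- df$o[k]
    body <- if (df$lit[k]) {
      paste0("<", ptag, pdecl, ">", xml_escape(obj), "</", ptag, ">")
    } else if (grepl("^_:", obj)) {
      paste0("<", ptag, pdecl, " rdf:nodeID=\"", sub("^_:", "", obj), "\"/>")
    } else {
      paste0("<", ptag, pdecl, " rdf:resource=\"", xml_escape(obj), "\"/>")
    }
    lines <- c(lines,
               paste0("  <rdf:Description ", ref_attr(df$s[k]), ">",
                      body, "</rdf:Description>"))
  }
  lines <- c(lines, "</rdf:RDF>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

turtle_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x
}

write_triples_turtle <- function(df, path) {
  term <- function(x, lit) {
    if (lit) return(paste0("\"", turtle_escape(x), "\""))
    if (grepl("^_:", x)) return(x)
    paste0("<", x, ">")
  }
  lines <- vapply(seq_len(nrow(df)), function(k) {
    paste(term(df$s[k], FALSE), term(df$p[k], FALSE),
          term(df$o[k], df$lit[k]), ".")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
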