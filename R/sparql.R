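# SPARQL subset engine over in-memory graphs.
#
# Supports the query shape needed for cohort retrieval over the materialized
# graph: PREFIX declarations, SELECT [DISTINCT] over named variables, basic
# graph patterns with ';'/','/'[ ]' abbreviations, FILTER expressions
# (comparisons, && / ||, parentheses, function calls) and BIND(expr AS ?v).
# Extension functions are registered by IRI; ofn:daysBetween is the custom
# datetime-duration function the demonstration queries require.

#' Duration between two dateTime literals, in days
#'
#' Exact decimal of seconds/86400; negative when `end` precedes `start`.
#' Registered as the SPARQL extension function `ofn:daysBetween`. Rows whose
#' literals do not parse as ISO-8601 evaluate to an error for that binding:
#' the row is dropped with a warning, consistent with SPARQL expression
#' error semantics.
#'
#' @param start,end Character vectors of ISO-8601 dateTime (or date)
#'   lexical forms.
#' @return Numeric vector of day counts (`NA` where unparseable).
#' @export
duration_days <- function(start, end) {
  parse_instant <- function(x) {
    out <- rep(NA_real_, length(x))
    dt <- grepl("T", x, fixed = TRUE)
    out[dt] <- as.numeric(as.POSIXct(x[dt], format = "%Y-%m-%dT%H:%M:%S",
                                     tz = "UTC"))
    out[!dt] <- as.numeric(as.POSIXct(x[!dt], format = "%Y-%m-%d",
                                      tz = "UTC"))
    out
  }
  s <- parse_instant(start)
  e <- parse_instant(end)
  bad <- (!is.na(start) & is.na(s)) | (!is.na(end) & is.na(e))
  if (any(bad)) {
    warning("duration_days: dropped ", sum(bad),
            " binding(s) with unparseable dateTime literal(s)",
            call. = FALSE)
  }
  (e - s) / 86400
}

#' Default SPARQL extension function registry
#'
#' @return Named list keyed by function IRI. `ofn:daysBetween(start, end)`
#'   returns decimal days; `ofn:toDate(dt)` extracts the date part of a
#'   dateTime literal as `xsd:date`.
#' @export
sparql_functions <- function() {
  out <- list()
  out[[paste0(NS_OFN, "daysBetween")]] <- function(args) {
    list(value = duration_days(args[[1]]$value, args[[2]]$value),
         datatype = xsd_iri("decimal"))
  }
  out[[paste0(NS_OFN, "toDate")]] <- function(args) {
    list(value = substr(args[[1]]$value, 1L, 10L),
         datatype = xsd_iri("date"))
  }
  out
}

# --- parsing ---------------------------------------------------------------

sparql_tokenize <- function(text) {
  n <- nchar(text)
  pos <- 1L
  toks <- list()
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(
    type = type, value = value)
  kw <- c("PREFIX", "SELECT", "DISTINCT", "WHERE", "FILTER", "BIND", "AS")
  while (pos <= n) {
    rest <- substring(text, pos)
    ws <- regmatches(rest, regexpr("^[[:space:]]+", rest))
    if (length(ws) == 1) { pos <- pos + nchar(ws); next }
    if (startsWith(rest, "#")) {
      nl <- regexpr("\n", rest, fixed = TRUE)
      if (nl == -1L) break
      pos <- pos + nl; next
    }
    m <- regmatches(rest, regexpr("^<[^<>\"{}|^`\\\\[:space:]]*>", rest))
    if (length(m) == 1) {
      push("iri", substring(m, 2L, nchar(m) - 1L)); pos <- pos + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^\\?[A-Za-z_][A-Za-z0-9_]*", rest))
    if (length(m) == 1) { push("var", substring(m, 2L)); pos <- pos + nchar(m); next }
    two <- substring(rest, 1L, 2L)
    if (two %in% c("&&", "||", "<=", ">=", "!=")) {
      push("op", two); pos <- pos + 2L; next
    }
    ch <- substring(rest, 1L, 1L)
    if (ch %in% c("{", "}", "(", ")", ".", ";", ",", "[", "]")) {
      push("punct", ch); pos <- pos + 1L; next
    }
    if (ch %in% c("=", "<", ">", "+", "-", "*", "/")) {
      push("op", ch); pos <- pos + 1L; next
    }
    if (ch == "'" || ch == "\"") {
      m <- regmatches(rest, regexpr(
        paste0("^", ch, "(\\\\.|[^", ch, "\\\\])*", ch), rest))
      if (length(m) == 0) stop("sparql parse error: unterminated string",
                               call. = FALSE)
      push("string", unescape_turtle(substring(m, 2L, nchar(m) - 1L)))
      pos <- pos + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^[0-9]+\\.[0-9]+", rest))
    if (length(m) == 1) { push("decimal", m); pos <- pos + nchar(m); next }
    m <- regmatches(rest, regexpr("^[0-9]+", rest))
    if (length(m) == 1) { push("integer", m); pos <- pos + nchar(m); next }
    m <- regmatches(rest, regexpr(
      "^[A-Za-z_][A-Za-z0-9_.-]*(:[A-Za-z0-9_][A-Za-z0-9_.-]*|:)?", rest))
    if (length(m) == 1) {
      if (toupper(m) %in% kw) push("kw", toupper(m))
      else if (identical(m, "a")) push("a", "a")
      else if (grepl(":", m, fixed = TRUE)) push("pname", m)
      else stop("sparql parse error: unexpected token '", m, "'",
                call. = FALSE)
      pos <- pos + nchar(m); next
    }
    stop("sparql parse error: unexpected character '", ch, "'", call. = FALSE)
  }
  toks
}

#' Parse a SPARQL SELECT query (subset)
#'
#' @param text Query text.
#' @return A `sparql_query` object: `vars`, `distinct`, and `elements` — the
#'   ordered sequence of triple patterns, filters and binds.
#' @export
sparql_parse <- function(text) {
  toks <- sparql_tokenize(text)
  env <- new.env(parent = emptyenv())
  env$i <- 1L
  env$prefixes <- ckg_namespaces()
  env$anon <- 0L
  env$elements <- list()
  peek <- function() if (env$i <= length(toks)) toks[[env$i]] else NULL
  advance <- function() { t <- peek(); env$i <- env$i + 1L; t }
  expect <- function(type, value = NULL) {
    t <- advance()
    if (is.null(t) || t$type != type ||
        (!is.null(value) && t$value != value)) {
      stop("sparql parse error: expected ", value %||% type, call. = FALSE)
    }
    t
  }
  resolve <- function(x) expand_curie(x, env$prefixes)

  term_iri <- function(v) list(kind = "iri", value = v)
  term_var <- function(v) list(kind = "var", value = v)
  term_lit <- function(v, dt) list(kind = "literal", value = v, datatype = dt)

  add_pattern <- function(s, p, o) {
    env$elements[[length(env$elements) + 1L]] <- list(
      type = "pattern", s = s, p = p, o = o)
  }

  parse_term <- function(t) {
    if (t$type == "var") return(term_var(t$value))
    if (t$type == "iri") return(term_iri(t$value))
    if (t$type == "pname") return(term_iri(resolve(t$value)))
    if (t$type == "string") {
      nxt <- peek()
      dt <- xsd_iri("string")
      # ^^datatype is tokenized as op '^'? not supported; typed literals in
      # patterns are matched by lexical form via FILTER instead
      return(term_lit(t$value, dt))
    }
    if (t$type == "integer") return(term_lit(t$value, xsd_iri("integer")))
    if (t$type == "decimal") return(term_lit(t$value, xsd_iri("decimal")))
    stop("sparql parse error: unexpected term '", t$value, "'",
         call. = FALSE)
  }

  parse_object <- function(subject, predicate) {
    t <- advance()
    if (t$type == "punct" && t$value == "[") {
      env$anon <- env$anon + 1L
      node <- term_var(paste0(".anon", env$anon))
      add_pattern(subject, predicate, node)
      parse_po_list(node)
      expect("punct", "]")
      return(invisible())
    }
    add_pattern(subject, predicate, parse_term(t))
  }

  parse_po_list <- function(subject) {
    repeat {
      t <- peek()
      if (is.null(t) || (t$type == "punct" && t$value %in% c("]", ".", "}")))
        return()
      t <- advance()
      predicate <- if (t$type == "a") term_iri(RDF_TYPE)
        else if (t$type == "iri") term_iri(t$value)
        else if (t$type == "pname") term_iri(resolve(t$value))
        else if (t$type == "var") term_var(t$value)
        else stop("sparql parse error: expected predicate", call. = FALSE)
      repeat {
        parse_object(subject, predicate)
        nxt <- peek()
        if (!is.null(nxt) && nxt$type == "punct" && nxt$value == ",") advance()
        else break
      }
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "punct" && nxt$value == ";") {
        advance(); next
      }
      return()
    }
  }

  parse_expr <- function() {
    left <- parse_and()
    repeat {
      t <- peek()
      if (!is.null(t) && t$type == "op" && t$value == "||") {
        advance()
        left <- list(kind = "or", left = left, right = parse_and())
      } else return(left)
    }
  }
  parse_and <- function() {
    left <- parse_cmp()
    repeat {
      t <- peek()
      if (!is.null(t) && t$type == "op" && t$value == "&&") {
        advance()
        left <- list(kind = "and", left = left, right = parse_cmp())
      } else return(left)
    }
  }
  parse_cmp <- function() {
    left <- parse_primary()
    t <- peek()
    if (!is.null(t) && t$type == "op" &&
        t$value %in% c("=", "!=", "<", "<=", ">", ">=")) {
      advance()
      return(list(kind = "cmp", op = t$value, left = left,
                  right = parse_primary()))
    }
    left
  }
  parse_primary <- function() {
    t <- advance()
    if (t$type == "punct" && t$value == "(") {
      e <- parse_expr()
      expect("punct", ")")
      return(e)
    }
    if (t$type %in% c("pname", "iri")) {
      fn <- if (t$type == "iri") t$value else resolve(t$value)
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "punct" && nxt$value == "(") {
        advance()
        args <- list()
        repeat {
          args[[length(args) + 1L]] <- parse_expr()
          nxt <- advance()
          if (nxt$type == "punct" && nxt$value == ")") break
          if (!(nxt$type == "punct" && nxt$value == ",")) {
            stop("sparql parse error in function arguments", call. = FALSE)
          }
        }
        return(list(kind = "call", fn = fn, args = args))
      }
      return(list(kind = "const", value = fn, datatype = NULL, iri = TRUE))
    }
    if (t$type == "var") return(list(kind = "varref", var = t$value))
    if (t$type == "string") return(list(kind = "const", value = t$value,
                                        datatype = xsd_iri("string")))
    if (t$type == "integer") return(list(kind = "const", value = t$value,
                                         datatype = xsd_iri("integer")))
    if (t$type == "decimal") return(list(kind = "const", value = t$value,
                                         datatype = xsd_iri("decimal")))
    stop("sparql parse error: unexpected token in expression", call. = FALSE)
  }

  # prologue
  repeat {
    t <- peek()
    if (!is.null(t) && t$type == "kw" && t$value == "PREFIX") {
      advance()
      p <- expect("pname")
      iri <- expect("iri")
      env$prefixes[sub(":$", "", p$value)] <- iri$value
    } else break
  }
  expect("kw", "SELECT")
  distinct <- FALSE
  if (!is.null(peek()) && peek()$type == "kw" && peek()$value == "DISTINCT") {
    advance(); distinct <- TRUE
  }
  vars <- character(0)
  repeat {
    t <- peek()
    if (!is.null(t) && t$type == "var") { advance(); vars <- c(vars, t$value) }
    else break
  }
  if (length(vars) == 0) stop("sparql parse error: SELECT needs variables",
                              call. = FALSE)
  t <- peek()
  if (!is.null(t) && t$type == "kw" && t$value == "WHERE") advance()
  expect("punct", "{")
  repeat {
    t <- peek()
    if (is.null(t)) stop("sparql parse error: unterminated group", call. = FALSE)
    if (t$type == "punct" && t$value == "}") { advance(); break }
    if (t$type == "kw" && t$value == "FILTER") {
      advance(); expect("punct", "(")
      e <- parse_expr()
      expect("punct", ")")
      env$elements[[length(env$elements) + 1L]] <- list(type = "filter",
                                                        expr = e)
      next
    }
    if (t$type == "kw" && t$value == "BIND") {
      advance(); expect("punct", "(")
      e <- parse_expr()
      expect("kw", "AS")
      v <- expect("var")
      expect("punct", ")")
      env$elements[[length(env$elements) + 1L]] <- list(type = "bind",
                                                        expr = e,
                                                        var = v$value)
      next
    }
    if (t$type == "punct" && t$value == ".") { advance(); next }
    # triples block
    st <- advance()
    subject <- if (st$type == "punct" && st$value == "[") {
      env$anon <- env$anon + 1L
      node <- term_var(paste0(".anon", env$anon))
      parse_po_list(node)
      expect("punct", "]")
      node
    } else parse_term(st)
    parse_po_list(subject)
  }
  structure(list(vars = vars, distinct = distinct, elements = env$elements),
            class = "sparql_query")
}

# --- evaluation ------------------------------------------------------------

#' Evaluate a SPARQL query over a graph
#'
#' @param graph An `rdf_graph`.
#' @param query Query text or a parsed `sparql_query`.
#' @param functions Extension function registry; defaults to
#'   [sparql_functions()]. An unregistered function IRI raises an error
#'   naming it.
#' @return Data frame with one column per selected variable (lexical
#'   values), distinct rows if requested.
#' @export
sparql_query <- function(graph, query, functions = sparql_functions()) {
  if (is.character(query)) query <- sparql_parse(query)
  tr <- graph$triples
  bind <- NULL  # data frame: columns <var> and <var>..dt

  match_pattern <- function(el) {
    keep <- rep(TRUE, nrow(tr))
    if (el$s$kind == "iri") keep <- keep & tr$subject == el$s$value
    if (el$p$kind == "iri") keep <- keep & tr$predicate == el$p$value
    if (el$o$kind == "iri") {
      keep <- keep & tr$object_type == "iri" & tr$object == el$o$value
    } else if (el$o$kind == "literal") {
      keep <- keep & tr$object_type == "literal" & tr$object == el$o$value
    }
    cand <- tr[keep, , drop = FALSE]
    out <- list()
    if (el$s$kind == "var") {
      out[[el$s$value]] <- cand$subject
      out[[paste0(el$s$value, "..dt")]] <- rep(NA_character_, nrow(cand))
    }
    if (el$p$kind == "var") {
      out[[el$p$value]] <- cand$predicate
      out[[paste0(el$p$value, "..dt")]] <- rep(NA_character_, nrow(cand))
    }
    if (el$o$kind == "var") {
      if (el$o$value %in% names(out)) {
        sel <- out[[el$o$value]] == cand$object
        out <- lapply(out, function(column) column[sel])
        cand <- cand[sel, , drop = FALSE]
      } else {
        out[[el$o$value]] <- cand$object
        out[[paste0(el$o$value, "..dt")]] <-
          ifelse(cand$object_type == "literal",
                 ifelse(is.na(cand$datatype), xsd_iri("string"),
                        cand$datatype), NA_character_)
      }
    }
    as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  }

  join <- function(a, b) {
    if (is.null(a)) return(b)
    shared <- intersect(names(a), names(b))
    shared <- shared[!endsWith(shared, "..dt")]
    if (length(shared) == 0) {
      if (nrow(a) == 0 || nrow(b) == 0) {
        return(cbind(a[0, , drop = FALSE], b[0, , drop = FALSE]))
      }
      a_rep <- a[rep(seq_len(nrow(a)), each = nrow(b)), , drop = FALSE]
      b_rep <- b[rep(seq_len(nrow(b)), times = nrow(a)), , drop = FALSE]
      out <- cbind(a_rep, b_rep)
      rownames(out) <- NULL
      return(out)
    }
    merge(a, b, by = intersect(names(a), names(b)), sort = FALSE)
  }

  eval_expr <- function(e, env_df) {
    n <- nrow(env_df)
    switch(e$kind,
      varref = {
        if (!e$var %in% names(env_df)) {
          stop("unbound variable ?", e$var, " in expression", call. = FALSE)
        }
        list(value = env_df[[e$var]],
             datatype = env_df[[paste0(e$var, "..dt")]])
      },
      const = list(value = rep(e$value, n),
                   datatype = rep(e$datatype %||% NA_character_, n)),
      call = {
        fn <- functions[[e$fn]]
        if (is.null(fn)) {
          stop("unbound SPARQL function <", e$fn,
               ">: register it in the `functions` argument", call. = FALSE)
        }
        args <- lapply(e$args, eval_expr, env_df = env_df)
        res <- fn(args)
        list(value = res$value,
             datatype = rep(res$datatype, length.out = n))
      },
      cmp = {
        l <- eval_expr(e$left, env_df)
        r <- eval_expr(e$right, env_df)
        numeric_dts <- c(xsd_iri("integer"), xsd_iri("decimal"),
                         xsd_iri("double"))
        num <- (is.numeric(l$value) | (!is.na(l$datatype) &
                                         l$datatype %in% numeric_dts)) &
               (is.numeric(r$value) | (!is.na(r$datatype) &
                                         r$datatype %in% numeric_dts))
        lv <- l$value; rv <- r$value
        res <- logical(length(lv))
        if (any(num, na.rm = TRUE)) {
          ln <- suppressWarnings(as.numeric(lv))
          rn <- suppressWarnings(as.numeric(rv))
          res_num <- switch(e$op, "=" = ln == rn, "!=" = ln != rn,
                            "<" = ln < rn, "<=" = ln <= rn,
                            ">" = ln > rn, ">=" = ln >= rn)
          res[num] <- res_num[num]
        }
        if (any(!num)) {
          res_str <- switch(e$op, "=" = lv == rv, "!=" = lv != rv,
                            "<" = lv < rv, "<=" = lv <= rv,
                            ">" = lv > rv, ">=" = lv >= rv)
          res[!num] <- res_str[!num]
        }
        list(value = res, datatype = rep(xsd_iri("boolean"), length(res)))
      },
      and = {
        l <- eval_expr(e$left, env_df); r <- eval_expr(e$right, env_df)
        list(value = as.logical(l$value) & as.logical(r$value),
             datatype = rep(xsd_iri("boolean"), n))
      },
      or = {
        l <- eval_expr(e$left, env_df); r <- eval_expr(e$right, env_df)
        list(value = as.logical(l$value) | as.logical(r$value),
             datatype = rep(xsd_iri("boolean"), n))
      },
      stop("unknown expression kind ", e$kind, call. = FALSE))
  }

  for (el in query$elements) {
    if (el$type == "pattern") {
      bind <- join(bind, match_pattern(el))
    } else if (el$type == "bind") {
      if (is.null(bind)) bind <- data.frame(row.names = 1)[, 0, drop = FALSE]
      res <- eval_expr(el$expr, bind)
      bind[[el$var]] <- res$value
      bind[[paste0(el$var, "..dt")]] <- res$datatype
    } else if (el$type == "filter") {
      if (is.null(bind) || nrow(bind) == 0) next
      keep <- eval_expr(el$expr, bind)$value
      keep[is.na(keep)] <- FALSE
      bind <- bind[as.logical(keep), , drop = FALSE]
    }
  }
  if (is.null(bind)) {
    bind <- data.frame(matrix(character(0), nrow = 0,
                              ncol = length(query$vars),
                              dimnames = list(NULL, query$vars)),
                       stringsAsFactors = FALSE)
  }
  missing_vars <- setdiff(query$vars, names(bind))
  for (v in missing_vars) bind[[v]] <- character(0)
  out <- bind[, query$vars, drop = FALSE]
  out[] <- lapply(out, as.character)
  if (query$distinct) out <- unique(out)
  rownames(out) <- NULL
  out
}
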