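# Turtle reader/writer.
#
# A self-contained parser for the Turtle subset used by TML mapping documents,
# serialized R2RML, and materialized graphs: prefix declarations, triples with
# ';'/',' continuations, anonymous blank-node property lists '[...]', short and
# long ("""...""") string literals with ^^datatype or @lang, numeric and
# boolean shorthand, and '#' comments.  RDF collections '( )' are not part of
# the subset and are rejected.

TOK_PUNCT <- c(".", ";", ",", "[", "]")

turtle_tokenize <- function(text) {
  lines <- if (length(text) > 1) text else strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) > 0) lines[1] <- sub("^﻿", "", lines[1])
  toks <- vector("list", 256L)
  nt <- 0L
  push <- function(type, value, ln) {
    nt <<- nt + 1L
    if (nt > length(toks)) length(toks) <<- 2L * nt
    toks[[nt]] <<- list(type = type, value = value, line = ln)
  }
  li <- 1L
  nl <- length(lines)
  while (li <= nl) {
    rest <- lines[li]
    line <- li
    repeat {
      rest <- sub("^[ \t\r]+", "", rest)
      if (nchar(rest) == 0L || startsWith(rest, "#")) break
      ch <- substring(rest, 1L, 1L)
      if (ch %in% c(".", ";", ",", "[", "]")) {
        push("punct", ch, line); rest <- substring(rest, 2L); next
      }
      if (ch %in% c("(", ")")) {
        stop("turtle parse error at line ", line,
             ": RDF collections '( )' are not supported", call. = FALSE)
      }
      if (ch == "<") {
        m <- regmatches(rest, regexpr("^<[^<>\"{}|^`\\\\[:space:]]*>", rest))
        if (length(m) == 0) stop("turtle parse error at line ", line,
                                 ": malformed IRIREF", call. = FALSE)
        push("iri", substring(m, 2L, nchar(m) - 1L), line)
        rest <- substring(rest, nchar(m) + 1L); next
      }
      if (startsWith(rest, "^^")) {
        push("dtype", "^^", line); rest <- substring(rest, 3L); next
      }
      if (ch == "\"") {
        if (startsWith(rest, "\"\"\"")) {
          # long string, possibly spanning lines
          body <- substring(rest, 4L)
          parts <- character(0)
          repeat {
            close <- find_unescaped(body, "\"\"\"")
            if (close > 0L) {
              parts <- c(parts, substring(body, 1L, close - 1L))
              rest <- substring(body, close + 3L)
              break
            }
            parts <- c(parts, body)
            li <- li + 1L
            if (li > nl) stop("turtle parse error at line ", line,
                              ": unterminated string literal", call. = FALSE)
            body <- lines[li]
          }
          push("string", unescape_turtle(paste(parts, collapse = "\n")), line)
          next
        }
        close <- find_unescaped(substring(rest, 2L), "\"")
        if (close == 0L) stop("turtle parse error at line ", line,
                              ": unterminated string literal", call. = FALSE)
        push("string", unescape_turtle(substring(rest, 2L, close)), line)
        rest <- substring(rest, close + 2L); next
      }
      if (ch == "@") {
        m <- regmatches(rest, regexpr("^@[A-Za-z][A-Za-z0-9-]*", rest))
        kw <- substring(m, 2L)
        if (identical(kw, "prefix")) push("atprefix", kw, line)
        else if (identical(kw, "base")) push("atbase", kw, line)
        else push("langtag", kw, line)
        rest <- substring(rest, nchar(m) + 1L); next
      }
      if (ch == "_") {
        m <- regmatches(rest, regexpr("^_:[A-Za-z0-9][A-Za-z0-9_.-]*", rest))
        if (length(m) == 0) stop("turtle parse error at line ", line,
                                 ": malformed blank node label", call. = FALSE)
        push("blank", substring(m, 3L), line)
        rest <- substring(rest, nchar(m) + 1L); next
      }
      m <- regmatches(rest, regexpr("^[+-]?[0-9]+\\.[0-9]+", rest))
      if (length(m) == 1) {
        push("decimal", m, line); rest <- substring(rest, nchar(m) + 1L); next
      }
      m <- regmatches(rest, regexpr("^[+-]?[0-9]+", rest))
      if (length(m) == 1) {
        push("integer", m, line); rest <- substring(rest, nchar(m) + 1L); next
      }
      # keywords, prefixed names, bare prefixes
      m <- regmatches(rest, regexpr(
        "^[A-Za-z][A-Za-z0-9_.-]*(:[A-Za-z0-9_][A-Za-z0-9_.-]*|:)?", rest))
      if (length(m) == 1) {
        if (m %in% c("true", "false")) push("boolean", m, line)
        else if (identical(m, "a")) push("a", "a", line)
        else if (m %in% c("PREFIX", "prefix")) push("atprefix", "prefix", line)
        else if (grepl(":", m, fixed = TRUE)) push("pname", m, line)
        else stop("turtle parse error at line ", line,
                  ": unexpected token '", m, "'", call. = FALSE)
        rest <- substring(rest, nchar(m) + 1L); next
      }
      stop("turtle parse error at line ", line, ": unexpected character '",
           ch, "'", call. = FALSE)
    }
    li <- li + 1L
  }
  toks[seq_len(nt)]
}

# Position of the first occurrence of `what` in `x` not preceded by a
# backslash (counting consecutive backslashes); 0 when absent.
find_unescaped <- function(x, what) {
  start <- 1L
  repeat {
    hit <- regexpr(what, substring(x, start), fixed = TRUE)
    if (hit == -1L) return(0L)
    pos <- start + as.integer(hit) - 1L
    nback <- 0L
    j <- pos - 1L
    while (j >= 1L && substring(x, j, j) == "\\") { nback <- nback + 1L; j <- j - 1L }
    if (nback %% 2L == 0L) return(pos)
    start <- pos + 1L
  }
}

unescape_turtle <- function(x) {
  if (!grepl("\\", x, fixed = TRUE)) return(x)
  out <- character(0)
  parts <- strsplit(x, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(parts)
  while (i <= n) {
    ch <- parts[i]
    if (ch == "\\" && i < n) {
      nxt <- parts[i + 1L]
      rep <- switch(nxt,
        "n" = "\n", "t" = "\t", "r" = "\r", "\"" = "\"", "'" = "'",
        "\\" = "\\", "b" = "\b", "f" = "\f", NULL)
      if (!is.null(rep)) { out <- c(out, rep); i <- i + 2L; next }
      if (nxt == "u" && i + 5L <= n) {
        code <- paste(parts[(i + 2L):(i + 5L)], collapse = "")
        out <- c(out, intToUtf8(strtoi(code, 16L)))
        i <- i + 6L; next
      }
    }
    out <- c(out, ch)
    i <- i + 1L
  }
  paste(out, collapse = "")
}

escape_turtle <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

# Quote a string for Turtle output; long SQL queries keep their layout.
turtle_quote <- function(x) {
  if (grepl("\n", x, fixed = TRUE)) {
    paste0("\"\"\"", gsub("\"\"\"", "\\\"\"\"", x, fixed = TRUE), "\"\"\"")
  } else {
    paste0("\"", escape_turtle(x), "\"")
  }
}

#' Parse a Turtle document
#'
#' Parses the Turtle subset used by this package into a flat triple table in
#' document order, with anonymous blank-node property lists assigned fresh
#' `_:b<n>` identifiers.
#'
#' @param text Turtle document as a single character scalar (or a vector of
#'   lines, which is collapsed).
#' @return A list with `prefixes` (named character vector) and `triples`, a
#'   data frame with columns `subject`, `predicate`, `object`, `object_type`
#'   (`"iri"`, `"blank"` or `"literal"`) and `datatype` (XSD IRI or `NA`).
#' @export
turtle_parse <- function(text) {
  if (length(text) > 1) text <- paste(text, collapse = "\n")
  toks <- turtle_tokenize(text)
  env <- new.env(parent = emptyenv())
  env$prefixes <- character(0)
  env$i <- 1L
  env$blank_n <- 0L
  env$acc <- vector("list", 512L)
  env$nacc <- 0L

  peek <- function() if (env$i <= length(toks)) toks[[env$i]] else NULL
  advance <- function() { t <- peek(); env$i <- env$i + 1L; t }
  expect_punct <- function(p) {
    t <- advance()
    if (is.null(t) || t$type != "punct" || t$value != p) {
      stop("turtle parse error", if (!is.null(t)) paste0(" at line ", t$line),
           ": expected '", p, "'", call. = FALSE)
    }
  }
  emit <- function(s, p, o, type, dt) {
    env$nacc <- env$nacc + 1L
    if (env$nacc > length(env$acc)) length(env$acc) <- 2L * env$nacc
    env$acc[[env$nacc]] <- c(s, p, o, type, if (is.na(dt)) "" else dt)
  }
  resolve <- function(term, line) {
    tryCatch(expand_curie(term, env$prefixes),
             error = function(e) stop(conditionMessage(e), " (line ", line, ")",
                                      call. = FALSE))
  }
  fresh_blank <- function() {
    env$blank_n <- env$blank_n + 1L
    paste0("b", env$blank_n)
  }

  parse_object <- function(subject, predicate) {
    t <- advance()
    if (is.null(t)) stop("turtle parse error: unexpected end of input",
                         call. = FALSE)
    if (t$type == "iri") {
      emit(subject, predicate, t$value, "iri", NA_character_)
    } else if (t$type == "pname") {
      emit(subject, predicate, resolve(t$value, t$line), "iri", NA_character_)
    } else if (t$type == "blank") {
      emit(subject, predicate, t$value, "blank", NA_character_)
    } else if (t$type == "string") {
      dt <- xsd_iri("string")
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "dtype") {
        advance()
        dtok <- advance()
        dt <- if (dtok$type == "iri") dtok$value else resolve(dtok$value, dtok$line)
      } else if (!is.null(nxt) && nxt$type == "langtag") {
        advance()  # language tags are accepted and dropped to plain strings
      }
      emit(subject, predicate, t$value, "literal", dt)
    } else if (t$type == "integer") {
      emit(subject, predicate, t$value, "literal", xsd_iri("integer"))
    } else if (t$type == "decimal") {
      emit(subject, predicate, t$value, "literal", xsd_iri("decimal"))
    } else if (t$type == "boolean") {
      emit(subject, predicate, t$value, "literal", xsd_iri("boolean"))
    } else if (t$type == "punct" && t$value == "[") {
      node <- fresh_blank()
      emit(subject, predicate, node, "blank", NA_character_)
      parse_po_list(node)
      expect_punct("]")
    } else {
      stop("turtle parse error at line ", t$line, ": unexpected ",
           t$type, " '", t$value, "' as object", call. = FALSE)
    }
  }

  parse_po_list <- function(subject) {
    repeat {
      t <- peek()
      if (is.null(t) || (t$type == "punct" && t$value %in% c("]", "."))) return()
      t <- advance()
      predicate <- if (t$type == "a") RDF_TYPE
        else if (t$type == "iri") t$value
        else if (t$type == "pname") resolve(t$value, t$line)
        else stop("turtle parse error at line ", t$line,
                  ": expected predicate, got '", t$value, "'", call. = FALSE)
      repeat {
        parse_object(subject, predicate)
        nxt <- peek()
        if (!is.null(nxt) && nxt$type == "punct" && nxt$value == ",") advance()
        else break
      }
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "punct" && nxt$value == ";") {
        advance()
        next
      }
      return()
    }
  }

  while (!is.null(peek())) {
    t <- peek()
    if (t$type == "atprefix") {
      advance()
      p <- advance()
      if (is.null(p) || p$type != "pname") {
        stop("turtle parse error: malformed @prefix declaration", call. = FALSE)
      }
      pfx <- sub(":$", "", p$value)
      iri <- advance()
      if (is.null(iri) || iri$type != "iri") {
        stop("turtle parse error: @prefix requires an IRIREF", call. = FALSE)
      }
      env$prefixes[pfx] <- iri$value
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "punct" && nxt$value == ".") advance()
      next
    }
    if (t$type == "atbase") {
      stop("turtle parse error at line ", t$line,
           ": @base is not supported; use absolute IRIs", call. = FALSE)
    }
    subject <- {
      s <- advance()
      if (s$type == "iri") s$value
      else if (s$type == "pname") resolve(s$value, s$line)
      else if (s$type == "blank") s$value
      else if (s$type == "punct" && s$value == "[") {
        node <- fresh_blank()
        # subject property list: parse in place, subject is the fresh node
        parse_po_list(node)
        expect_punct("]")
        node
      }
      else stop("turtle parse error at line ", s$line,
                ": expected subject, got '", s$value, "'", call. = FALSE)
    }
    parse_po_list(subject)
    expect_punct(".")
  }

  m <- if (env$nacc == 0) {
    matrix(character(0), ncol = 5)
  } else {
    matrix(unlist(env$acc[seq_len(env$nacc)], use.names = FALSE),
           ncol = 5, byrow = TRUE)
  }
  dt <- m[, 5]
  dt[dt == ""] <- NA_character_
  list(
    prefixes = env$prefixes,
    triples = data.frame(
      subject = m[, 1], predicate = m[, 2], object = m[, 3],
      object_type = m[, 4], datatype = dt,
      stringsAsFactors = FALSE
    )
  )
}
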