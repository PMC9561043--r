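# Graph materialization: execute triples maps against the OMOP database and
# emit the FHIR R4 RDF clinical knowledge graph.
#
# NULL semantics: a predicate-object map referencing a NULL column (or a
# template over a NULL column) emits nothing for that row, and a derived
# child node whose every arc is suppressed is pruned together with the arc
# pointing at it, transitively. Every non-NULL mapped cell contributes at
# least one triple.

# Vectorized IRI-template expansion; rows with any NULL placeholder give NA.
expand_template <- function(template, df, encode = TRUE) {
  tmp <- gsub("\\\\\\{", "\001", template)
  tmp <- gsub("\\\\\\}", "\002", tmp)
  m <- gregexpr("\\{[^{}]*\\}", tmp)[[1]]
  n <- nrow(df)
  if (m[1] == -1) {
    out <- gsub("\002", "}", gsub("\001", "{", tmp, fixed = TRUE), fixed = TRUE)
    return(rep(out, n))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  pieces <- list()
  last <- 1L
  for (k in seq_along(starts)) {
    if (starts[k] > last) {
      pieces[[length(pieces) + 1L]] <- substring(tmp, last, starts[k] - 1L)
    }
    col <- substring(tmp, starts[k] + 1L, starts[k] + lens[k] - 2L)
    pieces[[length(pieces) + 1L]] <- structure(col, placeholder = TRUE)
    last <- starts[k] + lens[k]
  }
  if (last <= nchar(tmp)) {
    pieces[[length(pieces) + 1L]] <- substring(tmp, last)
  }
  out <- rep("", n)
  ok <- rep(TRUE, n)
  for (p in pieces) {
    if (isTRUE(attr(p, "placeholder"))) {
      v <- df[[as.character(p)]]
      if (is.null(v)) stop("template placeholder {", p,
                           "} not in SQL result", call. = FALSE)
      ok <- ok & !is.na(v)
      v <- lexical_form(v)
      if (encode) v <- percent_encode(v)
      v[is.na(v)] <- ""
      out <- paste0(out, v)
    } else {
      out <- paste0(out, p)
    }
  }
  out <- gsub("\001", "{", out, fixed = TRUE)
  out <- gsub("\002", "}", out, fixed = TRUE)
  out[!ok] <- NA_character_
  out
}

percent_encode <- function(x) {
  needs <- grepl("[^A-Za-z0-9._~/:-]", x)
  x[needs] <- vapply(x[needs], function(v) {
    utils::URLencode(v, reserved = TRUE)
  }, character(1), USE.NAMES = FALSE)
  x
}

# Natural lexical form of a column vector (before datatype canonicalization).
lexical_form <- function(v) {
  if (is.integer(v)) return(as.character(v))
  if (is.numeric(v)) {
    whole <- !is.na(v) & v == floor(v) & abs(v) < 1e15
    out <- character(length(v))
    out[whole] <- sprintf("%.0f", v[whole])
    out[!whole] <- canonical_decimal(v[!whole])
    out[is.na(v)] <- NA_character_
    return(out)
  }
  as.character(v)
}

canonical_decimal <- function(v) {
  out <- format(v, digits = 12, scientific = FALSE, trim = TRUE)
  out <- sub("0+$", "", out)
  out <- sub("\\.$", ".0", out)
  out[is.na(v)] <- NA_character_
  out
}

# Canonical literal of a value under an XSD datatype IRI.
canonical_literal <- function(v, datatype) {
  local <- iri_local_name(datatype)
  switch(local,
    integer = {
      out <- sprintf("%.0f", suppressWarnings(as.numeric(v)))
      out[is.na(v)] <- NA_character_
      out
    },
    decimal = {
      num <- suppressWarnings(as.numeric(v))
      out <- ifelse(!is.na(num) & num == floor(num),
                    sprintf("%.1f", num), canonical_decimal(num))
      out[is.na(num)] <- NA_character_
      out
    },
    boolean = ifelse(is.na(v), NA_character_,
                     ifelse(v %in% c("1", "true", "TRUE", TRUE), "true",
                            "false")),
    as.character(v)
  )
}

#' Materialize a FHIR RDF graph from an OMOP database
#'
#' Runs each triples map's SQL query, instantiates subject IRIs from the
#' subject template (values percent-encoded, never failing), emits an
#' `rdf:type` arc for maps declaring a subject class, and one triple per
#' predicate-object map and row unless a referenced column is NULL. After
#' emission, arcs pointing at derived in-namespace nodes that received no
#' arcs of their own are pruned transitively.
#'
#' @param con A `DBIConnection` to the OMOP database.
#' @param maps List of `triples_map` objects (from [compile_tml()] or
#'   [parse_r2rml()]).
#' @param person_filter Optional integer vector of person ids; logical
#'   tables projecting a `person_id` column are restricted to these persons.
#' @param base_iri Instance namespace used for dangling-node pruning.
#' @return An `rdf_graph`.
#' @export
materialize <- function(con, maps, person_filter = NULL,
                        base_iri = ckg_base_iri()) {
  chunks <- list()
  add <- function(s, p, o, type, dt) {
    keep <- !is.na(s) & !is.na(o)
    if (!any(keep)) return()
    chunks[[length(chunks) + 1L]] <<- data.frame(
      subject = s[keep], predicate = p, object = o[keep],
      object_type = type, datatype = dt, stringsAsFactors = FALSE)
  }
  for (m in maps) {
    df <- tryCatch(DBI::dbGetQuery(con, m$logical_table),
                   error = function(e) {
                     stop("materialization error in map <", m$name, ">: ",
                          conditionMessage(e), call. = FALSE)
                   })
    if (!is.null(person_filter) && "person_id" %in% names(df)) {
      df <- df[df$person_id %in% person_filter, , drop = FALSE]
    }
    if (nrow(df) == 0) next
    subjects <- expand_template(m$subject_template, df)
    if (!is.na(m$subject_class)) {
      add(subjects, RDF_TYPE, rep(m$subject_class, nrow(df)), "iri",
          NA_character_)
    }
    for (po in m$poms) {
      obj <- po$object
      if (inherits(obj, "tml_column")) {
        v <- df[[obj$column]]
        if (is.null(v)) stop("materialization error in map <", m$name,
                             ">: column '", obj$column,
                             "' not in SQL result", call. = FALSE)
        if (identical(obj$term_type, "IRI")) {
          add(subjects, po$predicate, as.character(v), "iri", NA_character_)
        } else {
          add(subjects, po$predicate, canonical_literal(v, obj$datatype),
              "literal", obj$datatype)
        }
      } else if (inherits(obj, "tml_template")) {
        vals <- expand_template(obj$template, df,
                                encode = !identical(obj$term_type, "Literal"))
        if (identical(obj$term_type, "Literal")) {
          add(subjects, po$predicate, vals, "literal", xsd_iri("string"))
        } else {
          add(subjects, po$predicate, vals, "iri", NA_character_)
        }
      } else if (inherits(obj, "tml_constant")) {
        n <- nrow(df)
        if (obj$is_iri) {
          add(subjects, po$predicate, rep(obj$value, n), "iri", NA_character_)
        } else {
          add(subjects, po$predicate, rep(obj$value, n), "literal",
              obj$datatype %||% xsd_iri("string"))
        }
      } else {
        stop("internal error: nested object reached the materializer",
             call. = FALSE)
      }
    }
  }
  triples <- if (length(chunks) == 0) empty_triples() else
    unique(do.call(rbind, chunks))
  triples <- prune_dangling(triples, base_iri)
  rdf_graph(triples)
}

# Remove arcs to in-namespace IRI objects that are subjects of nothing,
# repeating until stable (suppression propagates up derived chains).
prune_dangling <- function(triples, base_iri) {
  repeat {
    if (nrow(triples) == 0) return(triples)
    has_arcs <- unique(triples$subject)
    dangling <- triples$object_type == "iri" &
      startsWith(triples$object, base_iri) &
      !(triples$object %in% has_arcs)
    if (!any(dangling)) return(triples)
    triples <- triples[!dangling, , drop = FALSE]
  }
}

#' Materialize directly from a TML document
#'
#' Convenience wrapper: compile then materialize.
#'
#' @inheritParams materialize
#' @param doc A `tml_document`.
#' @return An `rdf_graph`.
#' @export
materialize_tml <- function(con, doc, person_filter = NULL,
                            base_iri = ckg_base_iri()) {
  materialize(con, compile_tml(doc), person_filter = person_filter,
              base_iri = base_iri)
}
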