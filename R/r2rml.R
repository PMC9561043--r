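# TML -> R2RML compilation.
#
# Each nested node at path p under an entry with subject template T becomes
# (a) in the parent triples map, a predicate-object map whose object is the
# derived IRI template T + "/" + p, and (b) a child triples map with the same
# logical table, subject template T + "/" + p, no class, and the node's
# children as its predicate-object maps — applied recursively. Derived
# subjects are IRIs (path-suffixed), never blank nodes, which keeps graphs
# diffable and SPARQL-stable. Duplicate sibling path labels receive 0-based
# ordinal segments; this is a disambiguation, never an error.

triples_map <- function(name, logical_table, subject_template,
                        subject_class = NA_character_, poms = list()) {
  structure(list(name = name, logical_table = logical_table,
                 subject_template = subject_template,
                 subject_class = subject_class, poms = poms),
            class = "triples_map")
}

#' @export
print.triples_map <- function(x, ...) {
  cat("<triples_map> ", x$name, "\n  subject: ", x$subject_template,
      "\n  poms: ", length(x$poms), "\n", sep = "")
  invisible(x)
}

# Disambiguated path labels for one sibling list.
sibling_labels <- function(tree) {
  raw <- vapply(tree, function(po) {
    po$object$path_label %||% iri_local_name(po$predicate)
  }, character(1))
  nested <- vapply(tree, function(po) inherits(po$object, "tml_nested"),
                   logical(1))
  labels <- raw
  dup <- raw %in% raw[nested][duplicated(raw[nested])]
  if (any(dup & nested)) {
    for (lab in unique(raw[dup & nested])) {
      idx <- which(raw == lab & nested)
      labels[idx] <- paste0(lab, "/", seq_along(idx) - 1L)
    }
  }
  labels
}

#' Compile a TML document into flat R2RML-style triples maps
#'
#' @param doc A `tml_document` (validated: [validate_tml()] reports no
#'   error-severity issues).
#' @return List of `triples_map` objects; the count equals the number of
#'   entries plus the number of nested nodes in the document.
#' @export
compile_tml <- function(doc) {
  out <- list()
  emit_map <- function(m) out[[length(out) + 1L]] <<- m
  compile_node <- function(name, logical_table, template, class, tree) {
    poms <- list()
    children <- list()
    labels <- sibling_labels(tree)
    for (i in seq_along(tree)) {
      po <- tree[[i]]
      if (inherits(po$object, "tml_nested")) {
        child_template <- paste0(template, "/", labels[i])
        poms[[length(poms) + 1L]] <- list(
          predicate = po$predicate,
          object = tml_template(child_template, term_type = "IRI"))
        children[[length(children) + 1L]] <- list(
          name = paste0(name, "-", gsub("/", "-", labels[i], fixed = TRUE)),
          template = child_template, tree = po$object$children)
      } else {
        poms[[length(poms) + 1L]] <- po
      }
    }
    emit_map(triples_map(name, logical_table, template, class, poms))
    for (ch in children) {
      compile_node(ch$name, logical_table, ch$template, NA_character_,
                   ch$tree)
    }
  }
  for (e in doc$entries) {
    compile_node(e$name, e$logical_table, e$subject_template,
                 e$subject_class, e$object_tree)
  }
  residual <- any(vapply(out, function(m) {
    any(vapply(m$poms, function(po) inherits(po$object, "tml_nested"),
               logical(1)))
  }, logical(1)))
  if (residual) stop("internal error: residual nesting after compilation",
                     call. = FALSE)
  out
}

#' Serialize triples maps as W3C R2RML
#'
#' Output uses the `rr:` vocabulary (`rr:TriplesMap`, `rr:logicalTable` /
#' `rr:sqlQuery`, `rr:subjectMap`, `rr:predicateObjectMap`, `rr:objectMap`)
#' and re-parses to structurally equal maps; serialization is byte-stable
#' from the second pass.
#'
#' @param maps List of `triples_map` objects.
#' @param prefixes Prefix bindings for the output document.
#' @return Character scalar of Turtle text.
#' @export
serialize_r2rml <- function(maps, prefixes = ckg_namespaces()) {
  pfx <- prefixes[c("rr", "fhir", "rdf", "xsd")]
  out <- c(paste0("@prefix ", names(pfx), ": <", pfx, "> ."), "")
  ser_object_map <- function(obj) {
    if (inherits(obj, "tml_column")) {
      parts <- paste0("rr:column ", turtle_quote(obj$column))
      if (!identical(obj$datatype, xsd_iri("string"))) {
        parts <- c(parts, paste0("rr:datatype ", compact_iri(obj$datatype, pfx)))
      }
      if (identical(obj$term_type, "IRI")) parts <- c(parts, "rr:termType rr:IRI")
    } else if (inherits(obj, "tml_template")) {
      parts <- paste0("rr:template ", turtle_quote(obj$template))
      if (identical(obj$term_type, "Literal")) {
        parts <- c(parts, "rr:termType rr:Literal")
      }
    } else {
      parts <- if (obj$is_iri) {
        paste0("rr:constant ", compact_iri(obj$value, pfx))
      } else {
        paste0("rr:constant ", turtle_quote(obj$value),
               if (!is.null(obj$datatype) && obj$datatype != xsd_iri("string"))
                 paste0("^^", compact_iri(obj$datatype, pfx)) else "")
      }
    }
    paste0("[ ", paste(parts, collapse = " ; "), " ]")
  }
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    lines <- c(
      paste0("<", m$name, "> a rr:TriplesMap ;"),
      paste0("  rr:logicalTable [ rr:sqlQuery ",
             turtle_quote(m$logical_table), " ] ;"),
      paste0("  rr:subjectMap [ rr:template ",
             turtle_quote(m$subject_template),
             if (!is.na(m$subject_class))
               paste0(" ; rr:class ", compact_iri(m$subject_class, pfx))
             else "", " ] ;"),
      vapply(seq_along(m$poms), function(k) {
        po <- m$poms[[k]]
        paste0("  rr:predicateObjectMap [ rr:predicate ",
               compact_iri(po$predicate, pfx), " ; rr:objectMap ",
               ser_object_map(po$object), " ]",
               if (k < length(m$poms)) " ;" else " .")
      }, character(1))
    )
    if (length(m$poms) == 0) {
      lines[length(lines)] <- sub(";$", ".", lines[length(lines)])
    }
    out <- c(out, lines, "")
  }
  paste(out, collapse = "\n")
}

#' Parse an R2RML document into triples maps
#'
#' Reads the flat R2RML dialect emitted by [serialize_r2rml()] (one logical
#' table, subject map and flat predicate-object maps per `rr:TriplesMap`).
#'
#' @param text Turtle text or a file path.
#' @return List of `triples_map` objects.
#' @export
parse_r2rml <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  parsed <- turtle_parse(text)
  tr <- parsed$triples
  by_subject <- split(seq_len(nrow(tr)), tr$subject)
  po_of <- function(node) tr[sort(by_subject[[node]]), , drop = FALSE]
  one <- function(node, pred, what = "literal") {
    po <- po_of(node)
    hit <- po[po$predicate == pred &
                (if (what == "blank") po$object_type == "blank"
                 else if (what == "iri") po$object_type == "iri"
                 else po$object_type == "literal"), , drop = FALSE]
    if (nrow(hit) == 0) NULL else hit$object[1]
  }
  subjects <- unique(tr$subject[tr$predicate == RDF_TYPE &
                                  tr$object == rr_iri("TriplesMap")])
  # preserve document order
  subjects <- subjects[order(match(subjects, tr$subject))]
  lapply(subjects, function(s) {
    lt <- one(s, rr_iri("logicalTable"), "blank")
    sql <- one(lt, rr_iri("sqlQuery"))
    sm <- one(s, rr_iri("subjectMap"), "blank")
    template <- one(sm, rr_iri("template"))
    cls <- one(sm, rr_iri("class"), "iri") %||% NA_character_
    po <- po_of(s)
    pom_nodes <- po$object[po$predicate == rr_iri("predicateObjectMap")]
    poms <- lapply(pom_nodes, function(pn) {
      pred <- one(pn, rr_iri("predicate"), "iri")
      om <- one(pn, rr_iri("objectMap"), "blank")
      col <- one(om, rr_iri("column"))
      tmpl <- one(om, rr_iri("template"))
      tt <- one(om, rr_iri("termType"), "iri")
      tt <- if (is.null(tt)) NULL else iri_local_name(tt)
      obj <- if (!is.null(col)) {
        tml_column(col, datatype = one(om, rr_iri("datatype"), "iri") %||%
                     xsd_iri("string"), term_type = tt %||% "Literal")
      } else if (!is.null(tmpl)) {
        tml_template(tmpl, term_type = tt %||% "IRI")
      } else {
        opo <- po_of(om)
        crow <- opo[opo$predicate == rr_iri("constant"), , drop = FALSE]
        tml_constant(crow$object[1], is_iri = crow$object_type[1] == "iri",
                     datatype = if (crow$object_type[1] == "literal")
                       crow$datatype[1] else NULL)
      }
      list(predicate = pred, object = obj)
    })
    triples_map(s, sql, template, cls, poms)
  })
}
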