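# Independent oracle for compiler equivalence: a direct recursive interpreter
# over TML entries. It never flattens to triples maps — each SQL row is
# walked down the nested object tree, emitting a child node only when its
# subtree yields at least one arc. Shares only the leaf-level lexical
# conventions with the production path.

interpret_tml_direct <- function(con, doc) {
  acc <- list()
  emit <- function(s, p, o, type, dt = NA_character_) {
    acc[[length(acc) + 1L]] <<- data.frame(
      subject = s, predicate = p, object = o, object_type = type,
      datatype = dt, stringsAsFactors = FALSE)
  }
  expand_one <- function(template, row) {
    out <- template
    for (col in template_placeholders(template)) {
      v <- row[[col]]
      if (is.na(v)) return(NA_character_)
      v <- utils::URLencode(fhirckg:::lexical_form(v), reserved = TRUE)
      out <- sub(paste0("{", col, "}"), v, out, fixed = TRUE)
    }
    out
  }
  leaf_triple <- function(subj, pred, obj, row) {
    if (inherits(obj, "tml_column")) {
      v <- row[[obj$column]]
      if (is.na(v)) return(NULL)
      if (identical(obj$term_type, "IRI")) {
        return(list(s = subj, p = pred, o = as.character(v), type = "iri",
                    dt = NA_character_))
      }
      return(list(s = subj, p = pred,
                  o = fhirckg:::canonical_literal(v, obj$datatype),
                  type = "literal", dt = obj$datatype))
    }
    if (inherits(obj, "tml_template")) {
      v <- if (identical(obj$term_type, "Literal")) {
        ex <- obj$template
        for (col in template_placeholders(obj$template)) {
          val <- row[[col]]
          if (is.na(val)) return(NULL)
          ex <- sub(paste0("{", col, "}"), fhirckg:::lexical_form(val),
                    ex, fixed = TRUE)
        }
        return(list(s = subj, p = pred, o = ex, type = "literal",
                    dt = fhirckg:::xsd_iri("string")))
      } else {
        ex <- expand_one(obj$template, row)
        if (is.na(ex)) return(NULL)
        return(list(s = subj, p = pred, o = ex, type = "iri",
                    dt = NA_character_))
      }
    }
    if (obj$is_iri) {
      return(list(s = subj, p = pred, o = obj$value, type = "iri",
                  dt = NA_character_))
    }
    list(s = subj, p = pred, o = obj$value, type = "literal",
         dt = obj$datatype %||% fhirckg:::xsd_iri("string"))
  }
  # returns TRUE when the subtree emitted at least one arc
  walk_tree <- function(subj, tree, row) {
    labels <- fhirckg:::sibling_labels(tree)
    emitted <- FALSE
    for (i in seq_along(tree)) {
      po <- tree[[i]]
      if (inherits(po$object, "tml_nested")) {
        child <- paste0(subj, "/", labels[i])
        # tentatively walk the child; roll back if empty
        mark <- length(acc)
        child_has <- walk_tree(child, po$object$children, row)
        if (child_has) {
          emit(subj, po$predicate, child, "iri")
          emitted <- TRUE
        } else if (length(acc) > mark) {
          acc <<- acc[seq_len(mark)]
        }
      } else {
        tr <- leaf_triple(subj, po$predicate, po$object, row)
        if (!is.null(tr)) {
          emit(tr$s, tr$p, tr$o, tr$type, tr$dt)
          emitted <- TRUE
        }
      }
    }
    emitted
  }
  for (e in doc$entries) {
    df <- DBI::dbGetQuery(con, e$logical_table)
    if (nrow(df) == 0) next
    for (r in seq_len(nrow(df))) {
      row <- df[r, , drop = FALSE]
      subj <- expand_one(e$subject_template, row)
      if (is.na(subj)) next
      if (!is.na(e$subject_class)) {
        emit(subj, fhirckg:::RDF_TYPE, e$subject_class, "iri")
      }
      walk_tree(subj, e$object_tree, row)
    }
  }
  triples <- if (length(acc) == 0) fhirckg:::empty_triples() else
    unique(do.call(rbind, acc))
  rdf_graph(triples)
}
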