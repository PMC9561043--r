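# Turtle Template Mapping Language (TML).
#
# A TML document is a Turtle document of mapping entries. Root constructs
# (rr:logicalTable/rr:sqlQuery, rr:subjectMap/rr:template with optional
# rr:class) and leaf constructs (rr:column, rr:termType, rr:datatype,
# rr:template, rr:constant) behave exactly as in R2RML; the middle of each
# entry is a nested Turtle object tree whose predicates follow the FHIR
# element paths, mirroring the FHIR shape structure directly.

TML_LEAF_KEYS <- c("column", "template", "constant")

#' Parse a TML mapping document
#'
#' @param text Turtle text (scalar or vector of lines), or a file path to a
#'   `.ttl` document.
#' @return An object of class `tml_document`: `prefixes` plus a list of
#'   `entries`, each with `name`, `logical_table` (SQL), `subject_template`,
#'   `subject_class` (IRI or `NA`, inferred from the subject template path
#'   when no `rr:class` is declared) and `object_tree` (ordered
#'   predicate-object list; nested Turtle objects become nested nodes).
#' @export
parse_tml <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  parsed <- turtle_parse(text)
  tr <- parsed$triples
  prefixes <- parsed$prefixes
  entry_subjects <- unique(tr$subject[tr$predicate == rr_iri("logicalTable")])
  entry_subjects <- entry_subjects[!grepl("^b[0-9]+$", entry_subjects) |
                                     !entry_subjects %in%
                                       tr$object[tr$object_type == "blank"]]
  # any non-blank subject with a subjectMap but no logicalTable is malformed
  sm_subjects <- unique(tr$subject[tr$predicate == rr_iri("subjectMap")])
  orphans <- setdiff(sm_subjects, c(entry_subjects,
                                    tr$object[tr$object_type == "blank"]))
  if (length(orphans) > 0) {
    stop("structural error: entry <", orphans[1],
         "> lacks rr:logicalTable", call. = FALSE)
  }

  by_subject <- split(seq_len(nrow(tr)), tr$subject)
  node_po <- function(node) {
    idx <- by_subject[[node]]
    if (is.null(idx)) return(tr[0, , drop = FALSE])
    tr[sort(idx), , drop = FALSE]
  }
  literal_of <- function(node, pred) {
    po <- node_po(node)
    hit <- po[po$predicate == pred & po$object_type == "literal", , drop = FALSE]
    if (nrow(hit) == 0) NULL else hit$object[1]
  }
  iri_of <- function(node, pred) {
    po <- node_po(node)
    hit <- po[po$predicate == pred & po$object_type == "iri", , drop = FALSE]
    if (nrow(hit) == 0) NULL else hit$object[1]
  }
  blank_of <- function(node, pred) {
    po <- node_po(node)
    hit <- po[po$predicate == pred & po$object_type == "blank", , drop = FALSE]
    if (nrow(hit) == 0) NULL else hit$object[1]
  }

  parse_leaf <- function(node) {
    po <- node_po(node)
    col <- literal_of(node, rr_iri("column"))
    tmpl <- literal_of(node, rr_iri("template"))
    term_type <- iri_of(node, rr_iri("termType"))
    term_type <- if (is.null(term_type)) NULL else iri_local_name(term_type)
    dt <- iri_of(node, rr_iri("datatype"))
    if (!is.null(col)) {
      return(tml_column(col, datatype = dt %||% xsd_iri("string"),
                        term_type = term_type %||% "Literal"))
    }
    if (!is.null(tmpl)) {
      return(tml_template(tmpl, term_type = term_type %||% "IRI"))
    }
    const_row <- po[po$predicate == rr_iri("constant"), , drop = FALSE]
    tml_constant(const_row$object[1],
                 is_iri = const_row$object_type[1] == "iri",
                 datatype = if (const_row$object_type[1] == "literal")
                   const_row$datatype[1] else NULL)
  }

  parse_object <- function(row) {
    if (row$object_type == "iri") return(tml_constant(row$object, is_iri = TRUE))
    if (row$object_type == "literal") {
      return(tml_constant(row$object, is_iri = FALSE, datatype = row$datatype))
    }
    node <- row$object
    po <- node_po(node)
    locals <- iri_local_name(po$predicate)
    if (any(locals %in% TML_LEAF_KEYS & startsWith(po$predicate, NS_RR))) {
      return(parse_leaf(node))
    }
    tml_nested(parse_tree(node))
  }

  parse_tree <- function(node) {
    po <- node_po(node)
    lapply(seq_len(nrow(po)), function(i) {
      row <- po[i, , drop = FALSE]
      list(predicate = row$predicate, object = parse_object(row))
    })
  }

  entries <- lapply(entry_subjects, function(s) {
    lt_node <- blank_of(s, rr_iri("logicalTable"))
    sql <- if (!is.null(lt_node)) {
      literal_of(lt_node, rr_iri("sqlQuery")) %||%
        literal_of(lt_node, rr_iri("tableName"))
    }
    if (is.null(sql)) {
      stop("structural error: entry <", s, "> lacks rr:logicalTable/",
           "rr:sqlQuery", call. = FALSE)
    }
    sm_node <- blank_of(s, rr_iri("subjectMap"))
    if (is.null(sm_node)) {
      stop("structural error: entry <", s, "> lacks rr:subjectMap",
           call. = FALSE)
    }
    template <- literal_of(sm_node, rr_iri("template"))
    if (is.null(template)) {
      stop("structural error: entry <", s, "> subject map lacks rr:template",
           call. = FALSE)
    }
    cls <- iri_of(sm_node, rr_iri("class")) %||% infer_subject_class(template)
    pom_node <- blank_of(s, rr_iri("predicateObjectMap"))
    tree <- if (is.null(pom_node)) list() else parse_tree(pom_node)
    entry <- list(name = s, logical_table = sql, subject_template = template,
                  subject_class = cls %||% NA_character_, object_tree = tree)
    check_entry_placeholders(entry)
    entry
  })

  structure(list(prefixes = prefixes, entries = entries),
            class = "tml_document")
}

tml_column <- function(column, datatype = xsd_iri("string"),
                       term_type = "Literal") {
  structure(list(column = column, datatype = datatype,
                 term_type = term_type), class = "tml_column")
}
tml_template <- function(template, term_type = "IRI") {
  structure(list(template = template, term_type = term_type),
            class = "tml_template")
}
tml_constant <- function(value, is_iri, datatype = NULL) {
  structure(list(value = value, is_iri = is_iri,
                 datatype = if (is_iri) NULL else datatype %||% xsd_iri("string")),
            class = "tml_constant")
}
tml_nested <- function(children, path_label = NULL) {
  structure(list(children = children, path_label = path_label),
            class = "tml_nested")
}

#' @export
print.tml_document <- function(x, ...) {
  cat("<tml_document> ", length(x$entries), " entries\n", sep = "")
  for (e in x$entries) {
    cat("  <", e$name, "> -> ",
        if (is.na(e$subject_class)) "(no class)" else e$subject_class, "\n",
        sep = "")
  }
  invisible(x)
}

# Subject class inference: the path segment immediately before the first
# placeholder-bearing segment names the FHIR resource type.
infer_subject_class <- function(template) {
  segs <- strsplit(template, "/", fixed = TRUE)[[1]]
  ph <- grepl("\\{", segs)
  if (!any(ph)) return(NULL)
  before <- segs[which(ph)[1] - 1L]
  if (grepl("^[A-Z][A-Za-z]*$", before)) fhir_iri(before) else NULL
}

#' Extract `{column}` placeholders from an IRI template
#'
#' R2RML-style escaping applies: `\{` and `\}` are literal braces.
#' @param template Template string.
#' @return Character vector of column names.
#' @export
template_placeholders <- function(template) {
  tmp <- gsub("\\\\[{}]", "\001", template)
  m <- regmatches(tmp, gregexpr("\\{([^{}]*)\\}", tmp))[[1]]
  gsub("[{}]", "", m)
}

all_templates <- function(entry) {
  out <- entry$subject_template
  walk <- function(tree) {
    for (po in tree) {
      obj <- po$object
      if (inherits(obj, "tml_template")) out <<- c(out, obj$template)
      if (inherits(obj, "tml_nested")) walk(obj$children)
    }
  }
  walk(entry$object_tree)
  out
}

all_columns <- function(entry) {
  out <- character(0)
  walk <- function(tree) {
    for (po in tree) {
      obj <- po$object
      if (inherits(obj, "tml_column")) out <<- c(out, obj$column)
      if (inherits(obj, "tml_nested")) walk(obj$children)
    }
  }
  walk(entry$object_tree)
  out
}

check_entry_placeholders <- function(entry) {
  if (length(template_placeholders(entry$subject_template)) == 0) {
    stop("structural error: subject template of <", entry$name,
         "> contains no placeholder", call. = FALSE)
  }
  projected <- sql_projected_columns(entry$logical_table)
  if ("*" %in% projected) return(invisible(entry))
  ph <- unique(unlist(lapply(all_templates(entry), template_placeholders)))
  missing <- setdiff(ph, projected)
  if (length(missing) > 0) {
    stop("structural error: placeholder(s) ",
         paste0("{", missing, "}", collapse = ", "),
         " in entry <", entry$name, "> are not projected by its SQL query",
         call. = FALSE)
  }
  invisible(entry)
}

# --- minimal SQL text analysis (projection list and source tables) ----------

# Split on commas at parenthesis depth 0, outside quoted strings.
split_top_level <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  depth <- 0L; in_str <- FALSE
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_str) { if (ch == "'") in_str <- FALSE; next }
    if (ch == "'") { in_str <- TRUE; next }
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") depth <- depth - 1L
    else if (ch == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  trimws(vapply(seq_along(starts), function(k) {
    paste(chars[starts[k]:ends[k]], collapse = "")
  }, character(1)))
}

#' Columns projected by a SELECT statement
#' @param sql SQL text.
#' @return Character vector of output column names (`"*"` when the
#'   projection cannot be enumerated textually).
#' @export
sql_projected_columns <- function(sql) {
  one <- gsub("[\n\t]", " ", sql)
  m <- regmatches(one, regexec("(?i)^\\s*select\\s+(distinct\\s+)?(.*?)\\s+from\\s",
                               one, perl = TRUE))[[1]]
  if (length(m) == 0) return("*")
  items <- split_top_level(m[3])
  vapply(items, function(item) {
    if (item == "*" || grepl("\\.\\*$", item)) return("*")
    al <- regmatches(item, regexec("(?i)\\s+as\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*$",
                                   item, perl = TRUE))[[1]]
    if (length(al) > 0) return(al[2])
    sub("^.*\\.", "", trimws(item))
  }, character(1), USE.NAMES = FALSE)
}

#' Tables referenced by a SQL statement's FROM/JOIN clauses
#' @param sql SQL text.
#' @return Character vector of table names.
#' @export
sql_source_tables <- function(sql) {
  one <- gsub("[\n\t]", " ", sql)
  m <- gregexpr("(?i)(?:\\bfrom\\b|\\bjoin\\b)\\s+([A-Za-z_][A-Za-z0-9_]*)",
                one, perl = TRUE)
  hits <- regmatches(one, m)[[1]]
  unique(sub("(?i)^(from|join)\\s+", "", hits, perl = TRUE))
}

tree_depth <- function(tree) {
  if (length(tree) == 0) return(0L)
  max(vapply(tree, function(po) {
    if (inherits(po$object, "tml_nested")) 1L + tree_depth(po$object$children)
    else 1L
  }, integer(1)))
}

count_nested <- function(tree) {
  sum(vapply(tree, function(po) {
    if (inherits(po$object, "tml_nested")) {
      1L + count_nested(po$object$children)
    } else 0L
  }, integer(1)))
}

count_leaves <- function(tree) {
  sum(vapply(tree, function(po) {
    if (inherits(po$object, "tml_nested")) count_leaves(po$object$children)
    else 1L
  }, integer(1)))
}

#' Validate a TML document against an OMOP schema
#'
#' Checks that every logical table draws from known tables, every template
#' placeholder and column reference is projected by its entry's SQL, every
#' predicate IRI falls in a declared namespace, and nesting depth is at most
#' 6.
#'
#' @param doc A `tml_document`.
#' @param schema An `omop_schema`; defaults to [omop_schema()].
#' @return Data frame of issues (`entry`, `severity`, `message`); zero rows
#'   when the document is clean.
#' @export
validate_tml <- function(doc, schema = omop_schema()) {
  issues <- list()
  add <- function(entry, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      entry = entry, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  known_tables <- c(names(schema$tables), CODING_SYSTEM_TABLE)
  declared_ns <- unname(doc$prefixes)
  for (i in seq_along(doc$entries)) {
    e <- doc$entries[[i]]
    for (tab in sql_source_tables(e$logical_table)) {
      if (!tab %in% known_tables) {
        add(i, "error", paste0("unknown table '", tab, "' in logical table"))
      }
    }
    projected <- sql_projected_columns(e$logical_table)
    if (!"*" %in% projected) {
      ph <- unique(unlist(lapply(all_templates(e), template_placeholders)))
      for (p in setdiff(ph, projected)) {
        add(i, "error", paste0("placeholder {", p, "} not projected"))
      }
      for (colname in setdiff(unique(all_columns(e)), projected)) {
        add(i, "error", paste0("column '", colname, "' not projected"))
      }
    }
    depth <- tree_depth(e$object_tree)
    if (depth > 6) {
      add(i, "error", paste0("object tree depth ", depth, " exceeds 6"))
    }
    preds <- character(0)
    walk <- function(tree) {
      for (po in tree) {
        preds <<- c(preds, po$predicate)
        if (inherits(po$object, "tml_nested")) walk(po$object$children)
      }
    }
    walk(e$object_tree)
    for (p in unique(preds)) {
      if (!any(startsWith(p, declared_ns))) {
        add(i, "error", paste0("predicate <", p,
                               "> not in a declared namespace"))
      }
    }
  }
  if (length(issues) == 0) {
    data.frame(entry = integer(0), severity = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}

#' Serialize a TML document back to Turtle
#'
#' `parse_tml(serialize_tml(doc))` is structurally equal to `doc`; from the
#' second pass the text is byte-stable.
#'
#' @param doc A `tml_document`.
#' @return Character scalar of Turtle text.
#' @export
serialize_tml <- function(doc) {
  pfx <- doc$prefixes
  out <- c(paste0("@prefix ", names(pfx), ": <", pfx, "> ."), "")
  ser_obj <- function(obj, indent) {
    pad <- strrep("  ", indent)
    if (inherits(obj, "tml_constant")) {
      if (obj$is_iri) return(compact_iri(obj$value, pfx))
      return(paste0(turtle_quote(obj$value),
                    if (!is.null(obj$datatype) &&
                        obj$datatype != xsd_iri("string"))
                      paste0("^^", compact_iri(obj$datatype, pfx)) else ""))
    }
    if (inherits(obj, "tml_column")) {
      parts <- paste0("rr:column ", turtle_quote(obj$column))
      if (!identical(obj$datatype, xsd_iri("string"))) {
        parts <- c(parts, paste0("rr:datatype ",
                                 compact_iri(obj$datatype, pfx)))
      }
      if (!identical(obj$term_type, "Literal")) {
        parts <- c(parts, paste0("rr:termType rr:", obj$term_type))
      }
      return(paste0("[ ", paste(parts, collapse = " ; "), " ]"))
    }
    if (inherits(obj, "tml_template")) {
      parts <- paste0("rr:template ", turtle_quote(obj$template))
      if (!identical(obj$term_type, "IRI")) {
        parts <- c(parts, paste0("rr:termType rr:", obj$term_type))
      }
      return(paste0("[ ", paste(parts, collapse = " ; "), " ]"))
    }
    # nested node
    inner <- ser_tree(obj$children, indent + 1L)
    paste0("[\n", inner, "\n", pad, "]")
  }
  ser_tree <- function(tree, indent) {
    pad <- strrep("  ", indent)
    paste(vapply(tree, function(po) {
      paste0(pad, compact_iri(po$predicate, pfx), " ",
             ser_obj(po$object, indent))
    }, character(1)), collapse = " ;\n")
  }
  for (e in doc$entries) {
    lines <- paste0("<", e$name, "> rr:logicalTable [ rr:sqlQuery ",
                    turtle_quote(e$logical_table), " ] ;\n",
                    "  rr:subjectMap [ rr:template ",
                    turtle_quote(e$subject_template),
                    if (!is.na(e$subject_class))
                      paste0(" ; rr:class ",
                             compact_iri(e$subject_class, pfx)) else "",
                    " ] ;\n",
                    "  rr:predicateObjectMap [\n",
                    ser_tree(e$object_tree, 2L),
                    "\n  ] .")
    out <- c(out, lines, "")
  }
  paste(out, collapse = "\n")
}

#' Load the shipped OMOP-to-FHIR mapping set
#'
#' Reads the default TML mapping document covering 11 OMOP tables and 11
#' FHIR resource types, optionally rewriting its configuration points: the
#' encounter class code emitted for inpatient visits (the OMOP convention
#' `"IP"`, or the FHIR-prescribed `"IMP"`), the gender translation CASE, and
#' the instance base IRI.
#'
#' @param path Mapping file; defaults to the packaged
#'   `mappings/omop-fhir.ttl`.
#' @param encounter_code `"IP"` (default, the MIMIC-OMOP convention) or
#'   `"IMP"`.
#' @param gender_map Named character vector concept_id -> code; defaults to
#'   [default_gender_map()].
#' @param base_iri Base IRI for minted instances; defaults to
#'   [ckg_base_iri()].
#' @return A parsed `tml_document`.
#' @export
fhir_mapping <- function(path = default_mapping_path(),
                         encounter_code = c("IP", "IMP"),
                         gender_map = default_gender_map(),
                         base_iri = ckg_base_iri()) {
  encounter_code <- match.arg(encounter_code)
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (encounter_code != "IP") {
    text <- gsub("THEN 'IP' ELSE", paste0("THEN '", encounter_code, "' ELSE"),
                 text, fixed = TRUE)
  }
  if (!identical(gender_map, default_gender_map())) {
    text <- sub(gender_case_sql(default_gender_map()),
                gender_case_sql(gender_map), text, fixed = TRUE)
  }
  if (!identical(base_iri, ckg_base_iri())) {
    text <- gsub(ckg_base_iri(), base_iri, text, fixed = TRUE)
  }
  parse_tml(text)
}

#' @rdname fhir_mapping
#' @export
default_mapping_path <- function() {
  system.file("mappings", "omop-fhir.ttl", package = "fhirckg",
              mustWork = TRUE)
}

# The canonical gender-translation CASE expression embedded in the shipped
# mapping's person query.
gender_case_sql <- function(map = default_gender_map()) {
  paste0("CASE gender_concept_id ",
         paste0("WHEN ", names(map), " THEN '", map, "' ", collapse = ""),
         "ELSE 'unknown' END AS gender_code")
}

#' Coverage audit of a mapping document
#'
#' @param doc A `tml_document`; defaults to the shipped mapping set.
#' @param schema An `omop_schema` used to recognize OMOP tables.
#' @return List with `omop_tables` (distinct OMOP tables used as logical
#'   sources), `resource_types` (distinct FHIR resource classes produced),
#'   `element_mappings` (total leaf-level predicate-object mappings),
#'   `entries` and `nested_nodes` counts.
#' @export
mapping_audit <- function(doc = fhir_mapping(), schema = omop_schema()) {
  tabs <- unique(unlist(lapply(doc$entries,
                               function(e) sql_source_tables(e$logical_table))))
  tabs <- intersect(tabs, names(schema$tables))
  classes <- unique(stats::na.omit(vapply(doc$entries,
                                          function(e) e$subject_class,
                                          character(1))))
  leaves <- sum(vapply(doc$entries,
                       function(e) count_leaves(e$object_tree), integer(1)))
  nested <- sum(vapply(doc$entries,
                       function(e) count_nested(e$object_tree), integer(1)))
  list(omop_tables = sort(tabs), resource_types = sort(classes),
       element_mappings = leaves, entries = length(doc$entries),
       nested_nodes = nested)
}
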