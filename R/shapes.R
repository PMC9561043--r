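# Declarative FHIR structural shape validation.
#
# A deliberately implementable subset of shape checking: per-shape lists of
# (path, min, max, value kind) constraints with nested-shape recursion,
# primitive datatype checks (a primitive node has exactly one fhir:value arc
# of the declared XSD datatype — including the catch-all string rule), and a
# tree-root marker requirement on typed resource roots. Closed-world per
# listed constraint; arcs not mentioned by any constraint are permitted.

#' Load a shape schema
#'
#' The schema format is a YAML document with `prefixes` and `shapes`; each
#' shape has `kind` (`resource`, `node` or `primitive`), resource shapes a
#' `type` IRI, primitive shapes a `datatype`, and `constraints` — a list of
#' `{path, min, max, shape | value}` entries where `shape` names another
#' shape and `value: iri` requires an IRI object.
#'
#' @param path YAML file; defaults to the packaged FHIR R4 subset schema.
#' @return An object of class `shape_schema`.
#' @export
load_shapes <- function(path = default_shapes_path()) {
  raw <- yaml::yaml.load_file(path)
  prefixes <- unlist(raw$prefixes) %||% character(0)
  shapes <- raw$shapes %||% list()
  shapes <- lapply(shapes, function(sh) {
    sh$kind <- sh$kind %||% "node"
    if (!is.null(sh$type)) sh$type <- expand_curie(sh$type, prefixes)
    if (!is.null(sh$datatype)) sh$datatype <- expand_curie(sh$datatype, prefixes)
    sh$constraints <- lapply(sh$constraints %||% list(), function(cst) {
      list(path = expand_curie(cst$path, prefixes),
           min = cst$min %||% 0L,
           max = cst$max %||% "*",
           shape = cst$shape,
           value = cst$value)
    })
    sh
  })
  for (sh in shapes) {
    for (cst in sh$constraints) {
      if (!is.null(cst$shape) && !cst$shape %in% names(shapes)) {
        stop("shape schema load error: dangling shape reference '",
             cst$shape, "'", call. = FALSE)
      }
    }
  }
  structure(list(shapes = shapes, prefixes = prefixes),
            class = "shape_schema")
}

#' @rdname load_shapes
#' @export
default_shapes_path <- function() {
  system.file("shapes", "fhir-r4-subset.yaml", package = "fhirckg",
              mustWork = TRUE)
}

#' @export
print.shape_schema <- function(x, ...) {
  kinds <- vapply(x$shapes, function(s) s$kind, character(1))
  cat("<shape_schema> ", length(x$shapes), " shapes (",
      sum(kinds == "resource"), " resource, ", sum(kinds == "node"),
      " node, ", sum(kinds == "primitive"), " primitive)\n", sep = "")
  invisible(x)
}

#' Validate a graph against a shape schema
#'
#' Every subject carrying `rdf:type` of a shaped resource is checked against
#' its shape, recursing through element arcs into nested shapes. Violations
#' are data, not errors; they are attributed to the resource root under
#' check, so single-arc corruptions are detected with locality.
#'
#' @param graph An `rdf_graph`.
#' @param schema A `shape_schema`.
#' @return An object of class `shape_report`: `per_type` data frame
#'   (`type`, `checked`, `conformant`), `violations` data frame (`node`,
#'   `root`, `type`, `path`, `reason`), and `overall_conformance` (fraction
#'   in [0, 1]; `NA` when nothing was checked).
#' @export
validate_graph <- function(graph, schema) {
  tr <- graph$triples
  by_subject <- split(seq_len(nrow(tr)), tr$subject)
  arcs_of <- function(node) {
    idx <- by_subject[[node]]
    if (is.null(idx)) tr[0, , drop = FALSE] else tr[idx, , drop = FALSE]
  }
  violations <- list()
  flag <- function(node, path, reason) {
    violations[[length(violations) + 1L]] <<- data.frame(
      node = node, path = path, reason = reason, stringsAsFactors = FALSE)
  }

  check_primitive <- function(node, shape) {
    arcs <- arcs_of(node)
    vals <- arcs[arcs$predicate == fhir_iri("value"), , drop = FALSE]
    if (nrow(vals) != 1) {
      flag(node, fhir_iri("value"),
           paste0("primitive node has ", nrow(vals),
                  " fhir:value arc(s); exactly 1 required"))
      return(invisible())
    }
    if (vals$object_type[1] != "literal") {
      flag(node, fhir_iri("value"), "fhir:value must be a literal")
      return(invisible())
    }
    want <- shape$datatype %||% xsd_iri("string")
    got <- vals$datatype[1]
    if (is.na(got)) got <- xsd_iri("string")
    if (!identical(got, want)) {
      flag(node, fhir_iri("value"),
           paste0("literal datatype <", got, "> where <", want,
                  "> required"))
    }
    invisible()
  }

  check_node <- function(node, shape_name) {
    shape <- schema$shapes[[shape_name]]
    if (identical(shape$kind, "primitive")) {
      return(check_primitive(node, shape))
    }
    arcs <- arcs_of(node)
    if (identical(shape$kind, "resource")) {
      marker <- arcs$predicate == fhir_iri("nodeRole") &
        arcs$object == fhir_iri("treeRoot")
      if (!any(marker)) {
        flag(node, fhir_iri("nodeRole"), "missing fhir:treeRoot marker")
      }
    }
    for (cst in shape$constraints) {
      hits <- arcs[arcs$predicate == cst$path, , drop = FALSE]
      k <- nrow(hits)
      if (k < cst$min) {
        flag(node, cst$path, paste0("cardinality ", k, " below minimum ",
                                    cst$min))
        next
      }
      if (!identical(cst$max, "*") && k > as.integer(cst$max)) {
        flag(node, cst$path, paste0("cardinality ", k, " above maximum ",
                                    cst$max))
      }
      if (!is.null(cst$value) && identical(cst$value, "iri")) {
        bad <- hits$object_type != "iri"
        if (any(bad)) flag(node, cst$path, "IRI object required")
        next
      }
      if (!is.null(cst$shape)) {
        for (j in seq_len(k)) {
          if (hits$object_type[j] == "literal") {
            flag(node, cst$path,
                 "literal object where a node is required")
          } else {
            check_node(hits$object[j], cst$shape)
          }
        }
      }
    }
    invisible()
  }

  resource_shapes <- Filter(function(s) identical(s$kind, "resource"),
                            schema$shapes)
  per_type <- list()
  all_viol <- list()
  for (nm in names(resource_shapes)) {
    shape <- resource_shapes[[nm]]
    roots <- unique(tr$subject[tr$predicate == RDF_TYPE &
                                 tr$object == shape$type])
    conformant <- 0L
    for (root in roots) {
      violations <- list()
      check_node(root, nm)
      if (length(violations) == 0) {
        conformant <- conformant + 1L
      } else {
        v <- do.call(rbind, violations)
        v$root <- root
        v$type <- shape$type
        all_viol[[length(all_viol) + 1L]] <- v
      }
    }
    per_type[[length(per_type) + 1L]] <- data.frame(
      type = shape$type, checked = length(roots), conformant = conformant,
      stringsAsFactors = FALSE)
  }
  per_type <- do.call(rbind, per_type) %||%
    data.frame(type = character(0), checked = integer(0),
               conformant = integer(0))
  viol <- if (length(all_viol) > 0) {
    do.call(rbind, all_viol)[, c("node", "root", "type", "path", "reason")]
  } else {
    data.frame(node = character(0), root = character(0), type = character(0),
               path = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  checked <- sum(per_type$checked)
  structure(list(
    per_type = per_type,
    violations = viol,
    overall_conformance = if (checked > 0)
      sum(per_type$conformant) / checked else NA_real_),
    class = "shape_report")
}

#' @export
print.shape_report <- function(x, ...) {
  cat("<shape_report>\n")
  print(x$per_type, row.names = FALSE)
  cat("overall conformance: ",
      if (is.na(x$overall_conformance)) "n/a (nothing checked)"
      else sprintf("%.1f%%", 100 * x$overall_conformance), "\n", sep = "")
  if (nrow(x$violations) > 0) {
    cat(nrow(x$violations), "violation(s); first:\n")
    print(utils::head(x$violations, 3), row.names = FALSE)
  }
  invisible(x)
}
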