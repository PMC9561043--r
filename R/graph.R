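# In-memory RDF graph container with set semantics.

#' Construct an RDF graph
#'
#' @param triples Data frame with columns `subject`, `predicate`, `object`,
#'   `object_type` (`"iri"` or `"literal"`; blank-node rows are permitted when
#'   read from external Turtle) and `datatype` (XSD IRI or `NA` for IRIs).
#'   Duplicate triples are collapsed: a graph is a set.
#' @param namespaces Named character vector of prefix bindings used when
#'   serializing; defaults to [ckg_namespaces()].
#' @return An object of class `rdf_graph`.
#' @export
rdf_graph <- function(triples = empty_triples(), namespaces = ckg_namespaces()) {
  stopifnot(all(c("subject", "predicate", "object", "object_type", "datatype")
                %in% names(triples)))
  triples <- unique(triples[, c("subject", "predicate", "object",
                                "object_type", "datatype")])
  rownames(triples) <- NULL
  structure(list(triples = triples, namespaces = namespaces),
            class = "rdf_graph")
}

empty_triples <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), object_type = character(0),
             datatype = character(0), stringsAsFactors = FALSE)
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat("<rdf_graph> ", nrow(x$triples), " triples, ",
      length(unique(x$triples$subject)), " subjects\n", sep = "")
  invisible(x)
}

#' Number of triples in a graph
#' @param graph An `rdf_graph`.
#' @return Integer count.
#' @export
graph_size <- function(graph) nrow(graph$triples)

#' Per-resource-type instance counts
#'
#' Counts distinct subjects carrying an `rdf:type` arc, keyed by type IRI —
#' the shape of the "instances of FHIR Patient / Condition / ..." report.
#'
#' @param graph An `rdf_graph`.
#' @param types Optional character vector of type IRIs to report (missing
#'   types are reported as 0). Default: all types present.
#' @return Named integer vector, type IRI -> distinct typed subjects.
#' @export
graph_stats <- function(graph, types = NULL) {
  tt <- graph$triples[graph$triples$predicate == RDF_TYPE &
                        graph$triples$object_type == "iri", , drop = FALSE]
  tt <- unique(tt[, c("subject", "object")])
  tab <- table(tt$object)
  counts <- stats::setNames(as.integer(tab), names(tab))
  if (is.null(types)) return(counts)
  out <- stats::setNames(integer(length(types)), types)
  hit <- intersect(types, names(counts))
  out[hit] <- counts[hit]
  out
}

# Canonical sorted key per triple; used for set comparison and stable output.
triple_keys <- function(triples) {
  paste(triples$subject, triples$predicate, triples$object,
        triples$object_type, ifelse(is.na(triples$datatype), "",
                                    triples$datatype), sep = "\r")
}

#' Test two graphs for equality
#'
#' The materializer emits IRIs (never blank nodes), so graph isomorphism
#' reduces to set equality of ground triples. Graphs containing blank nodes
#' are compared up to a canonical relabeling of blank identifiers obtained by
#' sorting each node's outgoing arc signature.
#'
#' @param a,b `rdf_graph` objects.
#' @return Logical scalar.
#' @export
graphs_equal <- function(a, b) {
  ta <- canonicalize_blanks(a$triples)
  tb <- canonicalize_blanks(b$triples)
  setequal(triple_keys(ta), triple_keys(tb))
}

canonicalize_blanks <- function(triples) {
  blanks <- unique(c(triples$subject[triples$object_type != "" &
                                       grepl("^_:", triples$subject)],
                     triples$object[triples$object_type == "blank"]))
  if (length(blanks) == 0) return(triples)
  sig <- vapply(blanks, function(bn) {
    out <- triples[triples$subject == bn, , drop = FALSE]
    inn <- triples[triples$object == bn & triples$object_type == "blank", ,
                   drop = FALSE]
    paste(paste(sort(paste(out$predicate, ifelse(out$object_type == "blank",
                                                 "_", out$object))),
                collapse = "|"),
          paste(sort(inn$predicate), collapse = "|"), sep = "#")
  }, character(1))
  relab <- stats::setNames(paste0("_:c", match(sig, sort(unique(sig)))), blanks)
  triples$subject <- ifelse(triples$subject %in% blanks,
                            relab[triples$subject], triples$subject)
  swap <- triples$object_type == "blank" & triples$object %in% blanks
  triples$object[swap] <- relab[triples$object[swap]]
  triples
}

escape_ntriples <- function(x) escape_turtle(x)

format_term_nt <- function(value, type, datatype) {
  ifelse(type == "iri", paste0("<", value, ">"),
  ifelse(type == "blank", paste0("_:", sub("^_:", "", value)),
         paste0("\"", vapply(value, escape_ntriples, character(1),
                             USE.NAMES = FALSE), "\"",
                ifelse(is.na(datatype) | datatype == xsd_iri("string"), "",
                       paste0("^^<", datatype, ">")))))
}

#' Serialize a graph to disk
#'
#' @param graph An `rdf_graph`.
#' @param path Output file path.
#' @param format `"turtle"` or `"ntriples"`. N-Triples output is sorted
#'   canonically, so equal graphs yield byte-identical files.
#' @return Invisibly, the number of bytes written.
#' @export
write_graph <- function(graph, path, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  tr <- graph$triples
  if (format == "ntriples") {
    lines <- character(0)
    if (nrow(tr) > 0) {
      lines <- paste(
        format_term_nt(tr$subject, ifelse(grepl("^_:", tr$subject), "blank", "iri"), NA),
        paste0("<", tr$predicate, ">"),
        format_term_nt(tr$object, tr$object_type, tr$datatype),
        "."
      )
      lines <- sort(lines, method = "radix")
    }
  } else {
    pfx <- graph$namespaces
    header <- paste0("@prefix ", names(pfx), ": <", pfx, "> .")
    body <- character(0)
    if (nrow(tr) > 0) {
      ord <- order(tr$subject, tr$predicate, tr$object, method = "radix")
      tr <- tr[ord, , drop = FALSE]
      subj <- compact_iri(tr$subject, pfx)
      pred <- compact_iri(tr$predicate, pfx)
      pred[tr$predicate == RDF_TYPE] <- "a"
      obj <- character(nrow(tr))
      is_iri <- tr$object_type == "iri"
      obj[is_iri] <- compact_iri(tr$object[is_iri], pfx)
      lit <- !is_iri
      obj[lit] <- paste0(
        vapply(tr$object[lit], turtle_quote, character(1), USE.NAMES = FALSE),
        ifelse(is.na(tr$datatype[lit]) |
                 tr$datatype[lit] == xsd_iri("string"), "",
               paste0("^^", compact_iri(tr$datatype[lit], pfx))))
      body <- paste(subj, pred, obj, ".")
    }
    lines <- c(header, "", body)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(sum(nchar(lines, type = "bytes")) + length(lines))
}

#' Read a graph from a Turtle or N-Triples file
#'
#' @param path Input path.
#' @return An `rdf_graph`.
#' @export
read_graph <- function(path) {
  parsed <- turtle_parse(readLines(path, warn = FALSE))
  ns <- ckg_namespaces()
  ns[names(parsed$prefixes)] <- parsed$prefixes
  rdf_graph(parsed$triples, namespaces = ns)
}
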