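# File formats: starter FASTA input, consensus FASTA + per-position
# coverage TSV output, and GraphML / XGMML export of assembly graphs.

#' Load starter sequences from a FASTA file
#'
#' Starter ids must be unique and sequences must be over `{A,C,G,T}`
#' (starters containing `N` are rejected: the mapping distance is defined
#' only over the plain alphabet). Very long starters (over 10^4 nt) trigger
#' a warning, as sub-starter generation is quadratic in the number of
#' aligned reads.
#'
#' @param path FASTA file.
#' @return Named character vector of starter sequences.
#' @export
load_starters <- function(path) {
  if (!file.exists(path)) stop(sprintf("starter file '%s' not found", path),
    call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("starter file contains no sequences", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate starter id '%s'", ids[duplicated(ids)][1]),
      call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    sanitize_seq(seqs[i], allow_n = FALSE, what = sprintf("starter '%s'", ids[i]))
  }
  long <- nchar(seqs) > 10000L
  if (any(long)) {
    warning(sprintf(
      "starter(s) %s exceed 10,000 nt; very long starters are discouraged",
      paste(ids[long], collapse = ", ")), call. = FALSE)
  }
  setNames(seqs, ids)
}

#' Write sequence-mode consensus results to FASTA (+ coverage TSV)
#'
#' One record per read-coherent sub-starter; the header carries the starter
#' id, sub-starter index, distance to the starter and min/mean coverage. A
#' parallel tab-separated file (`<path>.cov.tsv`) gives the per-position
#' read coverage of every record.
#'
#' @param results Tibble with columns `starter`, `substarter_index`,
#'   `distance`, `consensus` and list-column `coverage`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(results, path) {
  lines <- character(0)
  cov_lines <- "record\tposition\tcoverage"
  for (i in seq_len(nrow(results))) {
    cov <- results$coverage[[i]]
    rec <- sprintf("%s_sub%d", results$starter[i], results$substarter_index[i])
    hdr <- sprintf(">%s dist=%d min_cov=%g mean_cov=%.2f len=%d",
      rec, results$distance[i], min(cov), mean(cov),
      nchar(results$consensus[i]))
    lines <- c(lines, hdr, results$consensus[i])
    cov_lines <- c(cov_lines,
      sprintf("%s\t%d\t%g", rec, seq_along(cov) - 1L, cov))
  }
  tryCatch({
    writeLines(lines, path)
    writeLines(cov_lines, paste0(path, ".cov.tsv"))
  }, error = function(e) {
    stop(sprintf("failed writing '%s': %s", path, conditionMessage(e)),
      call. = FALSE)
  })
  invisible(path)
}

#' Write an assembly graph to GraphML or XGMML
#'
#' Nodes carry their sequence, length, mean coverage and a root flag; edges
#' are directed.
#'
#' @param graph An `assembly_graph`.
#' @param path Output file.
#' @param dialect `"graphml"` (default) or `"xgmml"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, dialect = c("graphml", "xgmml")) {
  dialect <- match.arg(dialect)
  nd <- graph$nodes
  ed <- graph$edges
  if (dialect == "graphml") {
    doc <- xml2::xml_new_root("graphml",
      xmlns = "http://graphml.graphdrawing.org/xmlns")
    for (key in list(
      c("d_text", "node", "text", "string"),
      c("d_len", "node", "length", "int"),
      c("d_cov", "node", "mean_coverage", "double"),
      c("d_root", "node", "is_root", "boolean"))) {
      xml2::xml_add_child(doc, "key", id = key[1], `for` = key[2],
        attr.name = key[3], attr.type = key[4])
    }
    gx <- xml2::xml_add_child(doc, "graph", id = "assembly", edgedefault = "directed")
    for (i in seq_len(nrow(nd))) {
      nx <- xml2::xml_add_child(gx, "node", id = nd$id[i])
      xml2::xml_add_child(nx, "data", key = "d_text", nd$text[i])
      xml2::xml_add_child(nx, "data", key = "d_len", as.character(nd$length[i]))
      xml2::xml_add_child(nx, "data", key = "d_cov",
        format(nd$mean_coverage[i], digits = 10))
      xml2::xml_add_child(nx, "data", key = "d_root",
        tolower(as.character(nd$is_root[i])))
    }
    for (i in seq_len(nrow(ed))) {
      xml2::xml_add_child(gx, "edge", source = ed$from[i], target = ed$to[i])
    }
    xml2::write_xml(doc, path)
  } else {
    doc <- xml2::xml_new_root("graph",
      xmlns = "http://www.cs.rpi.edu/XGMML",
      label = "assembly", directed = "1")
    for (i in seq_len(nrow(nd))) {
      nx <- xml2::xml_add_child(doc, "node", id = nd$id[i], label = nd$id[i])
      xml2::xml_add_child(nx, "att", name = "text", type = "string",
        value = nd$text[i])
      xml2::xml_add_child(nx, "att", name = "length", type = "integer",
        value = as.character(nd$length[i]))
      xml2::xml_add_child(nx, "att", name = "mean_coverage", type = "real",
        value = format(nd$mean_coverage[i], digits = 10))
      xml2::xml_add_child(nx, "att", name = "is_root", type = "string",
        value = tolower(as.character(nd$is_root[i])))
    }
    for (i in seq_len(nrow(ed))) {
      xml2::xml_add_child(doc, "edge", source = ed$from[i], target = ed$to[i],
        label = paste0(ed$from[i], "-", ed$to[i]))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Read back an assembly graph written by [write_graph_file()]
#'
#' Restores node attributes and topology from either dialect; used for
#' round-trip validation and for loading results into other tools.
#'
#' @param path Graph file.
#' @param dialect `"graphml"` or `"xgmml"` (guessed from the root element
#'   when omitted).
#' @return An `assembly_graph` (node `side` is not stored on disk and comes
#'   back as `NA`).
#' @export
read_graph_file <- function(path, dialect = NULL) {
  doc <- xml2::read_xml(path)
  root_name <- xml2::xml_name(doc)
  if (is.null(dialect)) {
    dialect <- if (root_name == "graphml") "graphml" else "xgmml"
  }
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "x")
  if (dialect == "graphml") {
    nodes <- xml2::xml_find_all(doc, ".//x:graph/x:node", ns)
    get_data <- function(n, key) {
      xml2::xml_text(xml2::xml_find_first(n,
        sprintf("./x:data[@key='%s']", key), ns))
    }
    nd <- dplyr::bind_rows(lapply(nodes, function(n) {
      tibble::tibble(
        id = xml2::xml_attr(n, "id"),
        text = get_data(n, "d_text"),
        length = as.integer(get_data(n, "d_len")),
        mean_coverage = as.numeric(get_data(n, "d_cov")),
        is_root = get_data(n, "d_root") == "true"
      )
    }))
    edges <- xml2::xml_find_all(doc, ".//x:graph/x:edge", ns)
    ed <- tibble::tibble(
      from = xml2::xml_attr(edges, "source"),
      to = xml2::xml_attr(edges, "target")
    )
  } else {
    nodes <- xml2::xml_find_all(doc, "./x:node", ns)
    get_att <- function(n, name) {
      xml2::xml_attr(xml2::xml_find_first(n,
        sprintf("./x:att[@name='%s']", name), ns), "value")
    }
    nd <- dplyr::bind_rows(lapply(nodes, function(n) {
      tibble::tibble(
        id = xml2::xml_attr(n, "id"),
        text = get_att(n, "text"),
        length = as.integer(get_att(n, "length")),
        mean_coverage = as.numeric(get_att(n, "mean_coverage")),
        is_root = get_att(n, "is_root") == "true"
      )
    }))
    edges <- xml2::xml_find_all(doc, "./x:edge", ns)
    ed <- tibble::tibble(
      from = xml2::xml_attr(edges, "source"),
      to = xml2::xml_attr(edges, "target")
    )
  }
  nd$coverage <- lapply(nd$length, function(l) rep(NA_real_, l))
  nd$side <- NA_character_
  structure(list(nodes = nd, edges = ed, root = nd$id[nd$is_root][1]),
    class = "assembly_graph")
}
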