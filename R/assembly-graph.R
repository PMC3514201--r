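# Joining the left and right one-sided extension graphs of a sub-starter
# into one output graph, and extracting a linear consensus in sequence mode.

# Mirror a simplified one-sided graph: reverse-complement texts, reverse
# coverage tracks, reverse edges. Turns the left graph (built on the
# reverse complement of the sub-starter) back into genome orientation.
mirror_graph <- function(g) {
  stopifnot(isTRUE(g$stripped))
  for (nm in names(g$nodes)) {
    nd <- g$nodes[[nm]]
    nd$text <- reverse_complement(nd$text)
    nd$cov <- rev(nd$cov)
    g$nodes[[nm]] <- nd
  }
  g$edges <- data.frame(from = g$edges$to, to = g$edges$from)
  g
}

#' Join the two one-sided graphs of a sub-starter into one output graph
#'
#' The left graph (rooted on the reverse complement of the sub-starter) is
#' mirrored back into genome orientation so its nodes become predecessors of
#' the root; the right graph's nodes are its successors. Both one-sided
#' graphs must be simplified first.
#'
#' @param left,right Simplified one-sided extension graphs sharing the same
#'   sub-starter root.
#' @return An `assembly_graph`: list with `nodes` (tibble: `id`, `text`,
#'   `length`, `coverage` list-column, `mean_coverage`, `is_root`, `side`)
#'   and `edges` (tibble: `from`, `to`), root id `"root"`.
#' @export
join_sides <- function(left, right) {
  stopifnot(isTRUE(left$stripped), isTRUE(right$stripped))
  core <- right$root_core
  left <- mirror_graph(left)
  # the left root (mirrored) ends with the sub-starter core that the right
  # root begins with; splice the left root's extra prefix onto the right root
  lroot <- node_of(left, left$root)
  left_extra_len <- nchar(lroot$text) - core
  root_text <- paste0(substr(lroot$text, 1L, left_extra_len),
    node_of(right, right$root)$text)
  root_cov <- c(head(as.numeric(lroot$cov), left_extra_len),
    as.numeric(node_of(right, right$root)$cov))
  row_of <- function(g, id, side) {
    nd <- node_of(g, id)
    is_root <- id == g$root
    if (is_root) { nd$text <- root_text; nd$cov <- root_cov }
    tibble::tibble(
      id = if (is_root) "root" else paste0(toupper(substr(side, 1, 1)), id),
      text = nd$text,
      length = nchar(nd$text),
      coverage = list(as.numeric(nd$cov)),
      mean_coverage = if (length(nd$cov) > 0) mean(nd$cov) else 0,
      is_root = is_root,
      side = if (is_root) "root" else side
    )
  }
  nodes <- dplyr::bind_rows(
    row_of(right, right$root, "right"),
    dplyr::bind_rows(lapply(setdiff(node_ids(right), right$root),
      function(id) row_of(right, id, "right"))),
    dplyr::bind_rows(lapply(setdiff(node_ids(left), left$root),
      function(id) row_of(left, id, "left")))
  )
  map_id <- function(g, ids, side) {
    if (length(ids) == 0L) return(character(0))
    ifelse(ids == g$root, "root", paste0(toupper(substr(side, 1, 1)), ids))
  }
  edges <- dplyr::bind_rows(
    tibble::tibble(from = map_id(right, right$edges$from, "right"),
                   to = map_id(right, right$edges$to, "right")),
    tibble::tibble(from = map_id(left, left$edges$from, "left"),
                   to = map_id(left, left$edges$to, "left"))
  )
  structure(list(nodes = nodes, edges = edges, root = "root"),
    class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat(sprintf("<assembly_graph> %d nodes, %d edges; root length %d\n",
    nrow(x$nodes), nrow(x$edges), x$nodes$length[x$nodes$is_root]))
  invisible(x)
}

#' Tidy an assembly graph into its node table
#'
#' @param x An `assembly_graph`.
#' @param ... Unused.
#' @return The node tibble (`id`, `text`, `length`, `coverage`,
#'   `mean_coverage`, `is_root`, `side`).
#' @export
tidy.assembly_graph <- function(x, ...) x$nodes

#' One-line summary of an assembly graph
#'
#' @param x An `assembly_graph`.
#' @param ... Unused.
#' @return Tibble with node/edge counts, branch counts on each side of the
#'   root and total spelled length.
#' @export
glance.assembly_graph <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    right_branches = sum(x$edges$from == "root"),
    left_branches = sum(x$edges$to == "root"),
    total_length = sum(x$nodes$length),
    mean_coverage = mean(unlist(x$nodes$coverage))
  )
}

#' Extract the linear consensus of a non-branching assembly graph
#'
#' @param graph An `assembly_graph` whose nodes all have in- and out-degree
#'   at most one (sequence mode).
#' @return List with `consensus` (character scalar) and `coverage`
#'   (numeric per-position counts).
#' @export
linear_consensus <- function(graph) {
  stopifnot(inherits(graph, "assembly_graph"))
  outdeg <- table(factor(graph$edges$from, levels = graph$nodes$id))
  indeg <- table(factor(graph$edges$to, levels = graph$nodes$id))
  if (any(outdeg > 1L) || any(indeg > 1L)) {
    stop("graph has branching nodes; re-run in graph mode to inspect them",
      call. = FALSE)
  }
  start <- graph$nodes$id[indeg[graph$nodes$id] == 0L]
  stopifnot(length(start) == 1L)
  text <- ""
  cov <- numeric(0)
  id <- start
  repeat {
    row <- graph$nodes[graph$nodes$id == id, ]
    text <- paste0(text, row$text)
    cov <- c(cov, row$coverage[[1]])
    nxt <- graph$edges$to[graph$edges$from == id]
    if (length(nxt) == 0L) break
    id <- nxt
  }
  list(consensus = text, coverage = cov)
}

#' Plot an assembly graph
#'
#' Nodes are laid out with igraph's Sugiyama layout; point size encodes mean
#' read coverage and the label shows the node length, mirroring the usual
#' rendering of such graphs.
#'
#' @param object An `assembly_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assembly_graph <- function(object, ...) {
  ig <- igraph::graph_from_data_frame(object$edges, directed = TRUE,
    vertices = object$nodes$id)
  lay <- igraph::layout_with_sugiyama(ig)$layout
  pos <- tibble::tibble(id = igraph::V(ig)$name,
    x = lay[, 2], y = lay[, 1])
  nd <- dplyr::left_join(object$nodes, pos, by = "id")
  ed <- dplyr::left_join(
    dplyr::left_join(object$edges, pos, by = c("from" = "id")),
    dplyr::rename(pos, xend = "x", yend = "y"), by = c("to" = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
        yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey50") +
    ggplot2::geom_point(data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$mean_coverage,
        colour = .data$side)) +
    ggplot2::geom_text(data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$length),
      vjust = -1.2, size = 3) +
    ggplot2::scale_size_continuous(name = "mean coverage") +
    ggplot2::labs(x = NULL, y = NULL, colour = "side") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank())
}
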