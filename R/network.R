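#' Build the signed functional subnetwork of one unbalanced process
#'
#' Restricts a user-supplied functional edge list (STRING-style export) to
#' the member cytokines of a process. Nodes carry the sign of their
#' participation weight — positive and negative members deviate from steady
#' state in opposite directions — and its magnitude; edges keep both
#' endpoints inside the membership, and isolated members remain as nodes.
#' Edges are canonicalized (undirected, endpoints sorted, rows sorted,
#' duplicates merged) so the result does not depend on edge-list order.
#'
#' @param process An [process_membership()] result (membership filled).
#' @param edges Edge list data.frame from [read_edge_list()] (columns
#'   `from`, `to`, optional `score`).
#' @param min_score Optional minimum confidence; edges below it are dropped.
#' @return A `process_subnetwork`: list with `alpha`, `nodes` (data.frame
#'   `id`, `sign`, `weight`) and `edges` (data.frame `from`, `to`[,
#'   `score`]).
#' @export
build_subnetwork <- function(process, edges, min_score = NULL) {
  stopifnot(inherits(process, "unbalanced_process"))
  if (is.null(process$member_ids)) {
    stop("process membership not filled; run process_membership() first",
         call. = FALSE)
  }
  members <- process$member_ids
  nodes <- data.frame(
    id = members,
    sign = ifelse(process$member_weights >= 0, "positive", "negative"),
    weight = abs(process$member_weights),
    stringsAsFactors = FALSE
  )
  rownames(nodes) <- NULL
  has_score <- !is.null(edges$score)
  if (!is.null(min_score) && has_score) {
    edges <- edges[edges$score >= min_score, , drop = FALSE]
  }
  keep <- edges$from %in% members & edges$to %in% members
  ed <- edges[keep, , drop = FALSE]
  if (nrow(ed)) {
    a <- pmin(ed$from, ed$to)
    b <- pmax(ed$from, ed$to)
    ed <- data.frame(from = a, to = b, stringsAsFactors = FALSE)
    if (has_score) ed$score <- edges$score[keep]
    ed <- ed[!duplicated(paste(ed$from, ed$to, sep = "\r")), , drop = FALSE]
    ed <- ed[order(ed$from, ed$to), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(from = character(0), to = character(0),
                     stringsAsFactors = FALSE)
    if (has_score) ed$score <- numeric(0)
  }
  structure(list(alpha = process$alpha, nodes = nodes, edges = ed),
            class = "process_subnetwork")
}

#' @export
print.process_subnetwork <- function(x, ...) {
  cat(sprintf("process %d subnetwork: %d node(s) (%d positive, %d negative), %d edge(s)\n",
              x$alpha, nrow(x$nodes), sum(x$nodes$sign == "positive"),
              sum(x$nodes$sign == "negative"), nrow(x$edges)))
  invisible(x)
}

#' Convert a process subnetwork to an igraph graph
#'
#' @param net A [build_subnetwork()] result.
#' @return An undirected [igraph::igraph] with `sign` and `weight` vertex
#'   attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "process_subnetwork"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Write a process subnetwork to GraphML (plus a tidy edge CSV)
#'
#' @param net A [build_subnetwork()] result.
#' @param path Output `.graphml` path; a sibling `.edges.csv` with the tidy
#'   edge table is written next to it.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  csv <- sub("\\.graphml$", ".edges.csv", path)
  if (identical(csv, path)) csv <- paste0(path, ".edges.csv")
  utils::write.table(net$edges, csv, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
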