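new_network_structure <- function(nodes, amat, provenance = NULL,
                                  score = NA_real_, method = "manual") {
  stopifnot(is.matrix(amat), nrow(amat) == length(nodes))
  dimnames(amat) <- list(nodes, nodes)
  structure(list(nodes = nodes, amat = amat, provenance = provenance,
                 score = score, method = method),
            class = "network_structure")
}

#' Build a network structure from an explicit edge list
#'
#' Mostly useful for tests and worked examples; `edges` is a 2-column
#' matrix or data.frame of (from, to) node names defining a DAG.
#'
#' @param nodes character vector of node names.
#' @param edges 2-column from/to specification (may be empty).
#' @return a `network_structure`.
#' @export
network_structure <- function(nodes, edges = NULL) {
  amat <- matrix(0L, length(nodes), length(nodes))
  dimnames(amat) <- list(nodes, nodes)
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    bad <- !(edges %in% nodes)
    if (any(bad)) stop("unknown node(s): ",
                       paste(unique(edges[bad]), collapse = ", "))
    amat[cbind(match(edges[, 1L], nodes), match(edges[, 2L], nodes))] <- 1L
  }
  if (!is_dag_amat(amat)) stop("edge set contains a directed cycle")
  new_network_structure(nodes, amat)
}

is_dag_amat <- function(amat) {
  g <- amat
  repeat {
    if (nrow(g) == 0L) return(TRUE)
    sinks <- which(rowSums(g) == 0)
    if (length(sinks) == 0L) return(FALSE)
    g <- g[-sinks, -sinks, drop = FALSE]
  }
}

# would adding from -> to create a directed cycle? (i.e. can `to` reach `from`)
creates_cycle <- function(amat, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(amat))
  frontier <- to
  while (length(frontier)) {
    seen[frontier] <- TRUE
    nxt <- which(colSums(amat[frontier, , drop = FALSE]) > 0 & !seen)
    if (from %in% nxt) return(TRUE)
    frontier <- nxt
  }
  seen[from]
}

#' Undirected adjacency matrix of a structure
#'
#' Two nodes are adjacent when an arrow connects them in either direction;
#' adjacency, not orientation, carries the conditional-dependence meaning
#' used by the screen.
#'
#' @param structure a `network_structure`.
#' @return symmetric 0/1 matrix.
#' @export
adjacency_matrix <- function(structure) {
  a <- (structure$amat + t(structure$amat)) > 0
  storage.mode(a) <- "integer"
  a
}

#' Are two nodes adjacent (connected regardless of direction)?
#'
#' @param structure a `network_structure`.
#' @param a,b node names.
#' @return logical.
#' @export
adjacency_query <- function(structure, a, b) {
  ia <- match(a, structure$nodes); ib <- match(b, structure$nodes)
  if (is.na(ia) || is.na(ib))
    stop("unknown node: ", paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
  structure$amat[ia, ib] > 0 || structure$amat[ib, ia] > 0
}

#' Markov blanket of a node
#'
#' Parents, children, and the children's other parents (co-parents) — the
#' minimal set rendering the node conditionally independent of the rest.
#'
#' @param structure a `network_structure`.
#' @param node node name.
#' @return character vector of node names (possibly empty).
#' @export
markov_blanket <- function(structure, node) {
  i <- match(node, structure$nodes)
  if (is.na(i)) stop("unknown node: ", node)
  amat <- structure$amat
  parents <- which(amat[, i] > 0)
  children <- which(amat[i, ] > 0)
  coparents <- integer(0)
  for (ch in children) coparents <- c(coparents, which(amat[, ch] > 0))
  out <- setdiff(sort(unique(c(parents, children, coparents))), i)
  structure$nodes[out]
}

#' @export
print.network_structure <- function(x, ...) {
  ed <- which(x$amat > 0, arr.ind = TRUE)
  cat(sprintf("<network_structure> method=%s, %d nodes, %d edges",
              x$method, length(x$nodes), nrow(ed)))
  if (!is.na(x$score)) cat(sprintf(", score=%.2f", x$score))
  cat("\n")
  if (nrow(ed)) {
    for (k in seq_len(nrow(ed)))
      cat("  ", x$nodes[ed[k, 1L]], "->", x$nodes[ed[k, 2L]], "\n")
  }
  invisible(x)
}

#' Export a structure to DOT or GraphML
#'
#' Deterministic output: nodes in structure order, edges sorted by
#' (from, to). DOT nodes are labeled with the variable names.
#'
#' @param structure a `network_structure`.
#' @param path output file path.
#' @param format `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(structure, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  nodes <- structure$nodes
  ed <- which(structure$amat > 0, arr.ind = TRUE)
  ed <- ed[order(ed[, 1L], ed[, 2L]), , drop = FALSE]
  if (format == "dot") {
    lines <- c("digraph structure {",
               sprintf("  \"%s\";", nodes),
               if (nrow(ed)) sprintf("  \"%s\" -> \"%s\";",
                                     nodes[ed[, 1L]], nodes[ed[, 2L]]),
               "}")
  } else {
    lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
               "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
               "  <graph id=\"structure\" edgedefault=\"directed\">",
               sprintf("    <node id=\"%s\"/>", nodes),
               if (nrow(ed)) sprintf("    <edge source=\"%s\" target=\"%s\"/>",
                                     nodes[ed[, 1L]], nodes[ed[, 2L]]),
               "  </graph>",
               "</graphml>")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the undirected adjacency matrix as CSV
#'
#' @param structure a `network_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(structure, path) {
  a <- adjacency_matrix(structure)
  utils::write.csv(as.data.frame(a), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
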