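## iterative depth-first search over an adjacency list; returns the
## component membership of every node
.dfsComponents <- function(adj, n) {
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- adj[[v]]
      if (length(nb)) stack <- c(stack, nb[comp[nb] == 0L])
    }
  }
  comp
}

#' Build the per-frame molecular interaction graph
#'
#' Molecules are nodes; an undirected edge joins every upper-triangle
#' pair with a classified interaction in the alignment matrix, weighted
#' by the number of contacts in the pair's block and labeled with the
#' winning orientation class and shift. Clusters (molecular aggregates)
#' are the connected components, found by depth-first search.
#'
#' @param am an [AlignmentMatrix-class].
#' @param cm the [ContactMap-class] of the same frame.
#' @return a [ContactGraph-class].
#' @export
contactGraph <- function(am, cm) {
  stopifnot(is(am, "AlignmentMatrix"), is(cm, "ContactMap"))
  nmol <- nrow(am@P)
  if (length(cm@molLengths) != nmol)
    stop("alignment matrix and contact map disagree on molecule count")
  edges <- alignmentTable(am)
  adj <- vector("list", nmol)
  for (e in seq_len(nrow(edges))) {
    p <- edges$p[e]; q <- edges$q[e]
    adj[[p]] <- c(adj[[p]], q)
    adj[[q]] <- c(adj[[q]], p)
  }
  comp <- .dfsComponents(adj, nmol)
  clusters <- unname(split(seq_len(nmol), comp))
  edges <- edges[, c("p", "q", "nContacts", "class", "shift")]
  names(edges)[4] <- "orientation"
  new("ContactGraph", nMol = as.integer(nmol), edges = edges,
      clusters = clusters)
}

#' Majority orientation of each cluster
#'
#' Labels every cluster `"P"` or `"AP"` according to which orientation
#' carries the majority of the contact counts over the cluster's edges
#' (the two antiparallel classes pool into `"AP"`). A tie is reported as
#' `"mixed"`; a cluster without edges (an isolated molecule) as `"none"`.
#'
#' @param graph a [ContactGraph-class].
#' @return character vector, one label per cluster.
#' @export
clusterOrientation <- function(graph) {
  stopifnot(is(graph, "ContactGraph"))
  edges <- graph@edges
  vapply(graph@clusters, function(members) {
    sel <- edges$p %in% members | edges$q %in% members
    if (!any(sel)) return("none")
    par <- sum(edges$nContacts[sel & edges$orientation == "P"])
    anti <- sum(edges$nContacts[sel]) - par
    if (anti > par) "AP" else if (par > anti) "P" else "mixed"
  }, character(1))
}

#' Export a contact graph as a TSV edge list
#'
#' @param graph a [ContactGraph-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGraphTSV <- function(graph, path) {
  stopifnot(is(graph, "ContactGraph"))
  utils::write.table(graph@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
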