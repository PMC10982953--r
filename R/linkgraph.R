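# Mutual-nearest-neighbour link graph over cell-type and spot nodes.

#' K-nearest-neighbour candidate lists in the latent space
#'
#' For every spot: its `k` nearest spots and `k` nearest cell-type nodes (all
#' cell types when there are fewer than `k`). For every cell-type node: its
#' `k` nearest spots. Distances are Euclidean in the latent space, the query
#' node itself is excluded, and distance ties are broken by node index.
#'
#' @param Z a `latent_embedding` (or numeric matrix with `roles` supplied).
#' @param k neighbour count (default 20).
#' @param roles per-row `"celltype"`/`"spot"` flags when `Z` is a bare matrix.
#' @return list with integer-index candidate lists `spot_spot`, `spot_type`,
#'   `type_spot` (indices into the node set) and the full distance matrix `D`.
#' @export
knn_candidates <- function(Z, k = 20L, roles = NULL) {
  if (inherits(Z, "latent_embedding")) {
    roles <- roles %||% Z$node_roles
    Z <- Z$Z
  }
  if (k < 1L) stop("knn_candidates: k must be >= 1")
  if (nrow(Z) < 2L) stop("knn_candidates: need at least two nodes")
  if (is.null(roles)) stop("knn_candidates: node roles required")
  D <- pairwise_dist(Z)
  ct <- which(roles == "celltype")
  sp <- which(roles == "spot")

  top_among <- function(i, cand, kk) {
    cand <- setdiff(cand, i)
    d <- D[i, cand]
    cand[order(d, cand)][seq_len(min(kk, length(cand)))]
  }
  spot_spot <- lapply(sp, top_among, cand = sp, kk = k)
  spot_type <- lapply(sp, function(i) {
    if (length(ct) <= k) ct else top_among(i, ct, k)
  })
  type_spot <- lapply(ct, top_among, cand = sp, kk = k)
  names(spot_spot) <- names(spot_type) <- as.character(sp)
  names(type_spot) <- as.character(ct)
  list(spot_spot = spot_spot, spot_type = spot_type, type_spot = type_spot,
       D = D, celltype_nodes = ct, spot_nodes = sp)
}

#' Build the mutual-nearest-neighbour link graph
#'
#' Connects two nodes only when each is inside the other's role-appropriate
#' top-`k` list. Spot-spot and cell-type-spot subgraphs are computed
#' separately and merged; cell-type pairs are never connected. Retained
#' edges are weighted `w = 1 - d / max(d)` where `max(d)` is taken over the
#' retained edges of the merged graph (set `max_scope = "global"` for the
#' maximum over all pairwise distances).
#'
#' @param Z a `latent_embedding` (or matrix plus `roles`).
#' @param k neighbour count (default 20).
#' @param roles see [knn_candidates()].
#' @param max_scope `"edges"` (default) or `"global"`.
#' @return object of class `link_graph`: symmetric weight matrix `A` with
#'   zero diagonal, edge table `edges` (i, j, dist, weight), `node_roles`, `k`.
#' @export
build_link_graph <- function(Z, k = 20L, roles = NULL, max_scope = "edges") {
  if (inherits(Z, "latent_embedding")) {
    roles <- roles %||% Z$node_roles
    Zm <- Z$Z
  } else Zm <- as.matrix(Z)
  if (!any(roles == "celltype") || !any(roles == "spot"))
    stop("build_link_graph: need at least one cell-type and one spot node")
  cand <- knn_candidates(Zm, k = k, roles = roles)
  D <- cand$D
  a <- nrow(D)

  ei <- integer(0); ej <- integer(0)
  sp <- cand$spot_nodes
  for (s in seq_along(sp)) {
    i <- sp[s]
    for (j in cand$spot_spot[[s]]) {
      if (j > i && i %in% cand$spot_spot[[match(j, sp)]]) {
        ei <- c(ei, i); ej <- c(ej, j)
      }
    }
    for (t in cand$spot_type[[s]]) {
      if (i %in% cand$type_spot[[match(t, cand$celltype_nodes)]]) {
        ei <- c(ei, t); ej <- c(ej, i)
      }
    }
  }

  A <- matrix(0, a, a)
  if (length(ei) == 0L) {
    warning("build_link_graph: graph has no edges")
    edges <- data.frame(i = integer(0), j = integer(0),
                        dist = numeric(0), weight = numeric(0))
  } else {
    d <- D[cbind(ei, ej)]
    maxd <- if (max_scope == "global") max(D) else max(d)
    w <- if (maxd > 0) 1 - d / maxd else rep(1, length(d))
    A[cbind(ei, ej)] <- w
    A[cbind(ej, ei)] <- w
    edges <- data.frame(i = ei, j = ej, dist = d, weight = w)
  }
  rownames(A) <- colnames(A) <- rownames(Zm)
  structure(
    list(A = A, edges = edges, node_roles = roles, k = k,
         max_scope = max_scope),
    class = "link_graph"
  )
}

#' @export
print.link_graph <- function(x, ...) {
  cat(sprintf("link_graph: %d nodes (%d cell types, %d spots), %d edges, k = %d\n",
              nrow(x$A), sum(x$node_roles == "celltype"),
              sum(x$node_roles == "spot"), nrow(x$edges), x$k))
  invisible(x)
}

#' Export a link graph as an edge-list table
#'
#' @param graph a `link_graph`.
#' @param path optional file; when given, the table is written as TSV.
#' @return data.frame with node identifiers, weight and distance (invisibly
#'   when written to file).
#' @export
linkgraph_edge_list <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "link_graph"))
  ids <- rownames(graph$A) %||% as.character(seq_len(nrow(graph$A)))
  out <- data.frame(node_i = ids[graph$edges$i], node_j = ids[graph$edges$j],
                    weight = graph$edges$weight, dist = graph$edges$dist)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
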