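#' Skeleton sets
#'
#' Ground-truth neuron skeletons are trees of nodes in world coordinates (nm).
#' A `skeleton_set` holds a node table `(node_id, skeleton_id, z, y, x)` and
#' an edge table `(from, to)` of node ids within one skeleton. Each skeleton's
#' edges must form a connected acyclic graph; edge length is the Euclidean
#' distance between endpoint positions.
#'
#' @param nodes data.frame with columns `node_id`, `skeleton_id`, `z`, `y`,
#'   `x` (positions in nm).
#' @param edges data.frame with columns `from`, `to` (node ids).
#' @return an object of class `skeleton_set`.
#' @export
skeleton_set <- function(nodes, edges) {
  req <- c("node_id", "skeleton_id", "z", "y", "x")
  if (!all(req %in% names(nodes)))
    stop("`nodes` needs columns: ", paste(req, collapse = ", "))
  if (!all(c("from", "to") %in% names(edges)))
    stop("`edges` needs columns: from, to")
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node ids")
  if (nrow(edges)) {
    sk <- stats::setNames(nodes$skeleton_id, as.character(nodes$node_id))
    miss <- setdiff(c(edges$from, edges$to), nodes$node_id)
    if (length(miss)) stop("edges reference unknown node ids: ",
                           paste(utils::head(miss), collapse = ", "))
    if (any(sk[as.character(edges$from)] != sk[as.character(edges$to)]))
      stop("edge connects nodes of different skeletons")
  }
  # per-skeleton tree check: |E| = |V| - 1 and connected <=> acyclic+connected
  for (s in unique(nodes$skeleton_id)) {
    nid <- nodes$node_id[nodes$skeleton_id == s]
    es <- edges[edges$from %in% nid, , drop = FALSE]
    if (nrow(es) != length(nid) - 1L)
      stop("skeleton ", s, " is not a tree (|E| != |V| - 1)")
    if (length(nid) > 1L) {
      g <- igraph::graph_from_data_frame(
        es, directed = FALSE,
        vertices = data.frame(name = as.character(nid)))
      if (igraph::components(g)$no != 1L)
        stop("skeleton ", s, " is not connected")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "skeleton_set")
}

#' @export
print.skeleton_set <- function(x, ...) {
  cat(sprintf("<skeleton_set> %d skeletons, %d nodes, %d edges, total length %.1f nm\n",
              length(unique(x$nodes$skeleton_id)), nrow(x$nodes),
              nrow(x$edges), sum(skeleton_edge_lengths(x))))
  invisible(x)
}

#' Euclidean length of every skeleton edge (nm)
#' @param skels a [skeleton_set()].
#' @return numeric vector, one length per edge row.
#' @export
skeleton_edge_lengths <- function(skels) {
  if (!nrow(skels$edges)) return(numeric(0))
  pos <- as.matrix(skels$nodes[, c("z", "y", "x")])
  rownames(pos) <- as.character(skels$nodes$node_id)
  a <- pos[as.character(skels$edges$from), , drop = FALSE]
  b <- pos[as.character(skels$edges$to), , drop = FALSE]
  sqrt(rowSums((a - b)^2))
}

#' Total path length per skeleton (nm)
#' @param skels a [skeleton_set()].
#' @return named numeric vector of per-skeleton total edge length.
#' @export
skeleton_lengths <- function(skels) {
  len <- skeleton_edge_lengths(skels)
  sk <- stats::setNames(skels$nodes$skeleton_id,
                        as.character(skels$nodes$node_id))
  esk <- sk[as.character(skels$edges$from)]
  out <- tapply(len, esk, sum)
  ids <- unique(skels$nodes$skeleton_id)
  res <- stats::setNames(numeric(length(ids)), ids)
  res[names(out)] <- out
  res
}

#' Read skeletons from SWC or CSV
#'
#' SWC rows are `id type x y z radius parent` with positions in nm and parent
#' `-1` at roots; each root-connected tree becomes one skeleton, numbered in
#' order of appearance of its root. The CSV dialect has a header
#' `node_id, skeleton_id, z, y, x, parent_id` (positions nm, parent `-1` at
#' roots). Cycles, cross-skeleton edges and unknown parent ids are format
#' errors.
#'
#' @param path file path.
#' @param dialect `"swc"` or `"csv"`.
#' @return a [skeleton_set()].
#' @export
read_skeletons <- function(path, dialect = c("swc", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "swc") {
    tab <- utils::read.table(path, comment.char = "#",
                             col.names = c("id", "type", "x", "y", "z",
                                           "radius", "parent"))
    nodes <- data.frame(node_id = tab$id, skeleton_id = NA_integer_,
                        z = tab$z, y = tab$y, x = tab$x)
    parent <- tab$parent
  } else {
    tab <- utils::read.csv(path)
    req <- c("node_id", "skeleton_id", "z", "y", "x", "parent_id")
    if (!all(req %in% names(tab)))
      stop("CSV skeleton file needs columns: ", paste(req, collapse = ", "))
    nodes <- tab[, c("node_id", "skeleton_id", "z", "y", "x")]
    parent <- tab$parent_id
  }
  has_parent <- parent != -1
  if (any(has_parent & !(parent %in% nodes$node_id)))
    stop("skeleton format error: unknown parent node id")
  edges <- data.frame(from = parent[has_parent],
                      to = nodes$node_id[has_parent])
  # assign skeleton ids from root-connected components (SWC) / validate (CSV)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node_id)))
  comp <- igraph::components(g)$membership
  comp <- comp[as.character(nodes$node_id)]
  if (dialect == "swc") {
    nodes$skeleton_id <- as.integer(factor(comp, levels = unique(comp)))
  } else if (any(tapply(nodes$skeleton_id, comp, function(s)
    length(unique(s))) > 1L)) {
    stop("skeleton format error: edge connects different skeleton_ids")
  }
  skeleton_set(nodes, edges)   # tree/acyclicity enforced here
}

#' Write skeletons in the CSV dialect
#'
#' Inverse of [read_skeletons()] for `dialect = "csv"`; each node row carries
#' its parent within the tree (roots get `-1`).
#'
#' @param skels a [skeleton_set()].
#' @param path output file.
#' @return `invisible(NULL)`.
#' @export
write_skeletons_csv <- function(skels, path) {
  parent <- stats::setNames(rep(-1, nrow(skels$nodes)),
                            as.character(skels$nodes$node_id))
  # orient edges away from the first node of each skeleton (simple BFS on
  # the undirected adjacency)
  if (nrow(skels$edges)) {
    adj <- split(c(skels$edges$to, skels$edges$from),
                 as.character(c(skels$edges$from, skels$edges$to)))
    for (s in unique(skels$nodes$skeleton_id)) {
      nid <- skels$nodes$node_id[skels$nodes$skeleton_id == s]
      if (length(nid) < 2L) next
      visited <- stats::setNames(logical(length(nid)), as.character(nid))
      queue <- nid[1]
      visited[as.character(nid[1])] <- TRUE
      while (length(queue)) {
        cur <- queue[1]
        queue <- queue[-1]
        for (nb in adj[[as.character(cur)]]) {
          if (!visited[as.character(nb)]) {
            visited[as.character(nb)] <- TRUE
            parent[as.character(nb)] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  out <- data.frame(node_id = skels$nodes$node_id,
                    skeleton_id = skels$nodes$skeleton_id,
                    z = skels$nodes$z, y = skels$nodes$y, x = skels$nodes$x,
                    parent_id = parent[as.character(skels$nodes$node_id)])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Crop skeletons to a volume's region of interest
#'
#' Nodes outside the ROI are dropped together with their incident edges, and
#' the remaining connected components are relabeled as new skeletons (a
#' skeleton crossing the ROI boundary becomes several shorter skeletons).
#' This is the cropping convention under which run-length metrics are
#' evaluated on sub-volumes.
#'
#' @param skels a [skeleton_set()].
#' @param vol an [annotated_volume()] defining the ROI.
#' @return a [skeleton_set()] with relabeled `skeleton_id`s.
#' @export
crop_skeletons <- function(skels, vol) {
  lo <- vol$offset
  hi <- vol$offset + vol_shape(vol) * vol$voxel_size
  pos <- as.matrix(skels$nodes[, c("z", "y", "x")])
  keep <- pos[, 1] >= lo[1] & pos[, 1] < hi[1] &
    pos[, 2] >= lo[2] & pos[, 2] < hi[2] &
    pos[, 3] >= lo[3] & pos[, 3] < hi[3]
  nodes <- skels$nodes[keep, , drop = FALSE]
  edges <- skels$edges[skels$edges$from %in% nodes$node_id &
                         skels$edges$to %in% nodes$node_id, , drop = FALSE]
  if (!nrow(nodes)) return(skeleton_set(nodes, edges))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node_id)))
  comp <- igraph::components(g)$membership[as.character(nodes$node_id)]
  nodes$skeleton_id <- as.integer(factor(comp, levels = unique(comp)))
  skeleton_set(nodes, edges)
}
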