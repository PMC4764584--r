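#' Skeletonize a tubular mask into an attributed network graph
#'
#' Thins the mask to a one-voxel curve skeleton (sequential simple-point
#' deletion ordered by the distance transform, preserving curve end points),
#' then traces the skeleton into a graph: nodes are end points (degree 1)
#' and junctions (clusters of skeleton voxels with more than two
#' neighbours); edges carry their centerline polyline, length and mean
#' radius (distance-transform value along the centerline). Short terminal
#' spurs (shorter than twice the local radius) are pruned.
#'
#' @param mask logical 3D array of a tubular structure.
#' @param spacing voxel size (µm), scalar or length 3.
#' @param prune prune terminal spurs shorter than \code{pruneFactor} x local
#'   radius.
#' @param pruneFactor spur-length multiple of the junction radius.
#' @return a \linkS4class{NetworkGraph}; empty mask gives an empty graph.
#' @export
skeletonizeToGraph <- function(mask, spacing = c(1, 1, 1), prune = TRUE,
                               pruneFactor = 2) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  emptyGraph <- function() new("NetworkGraph",
    nodes = data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                       z = numeric(0), radius = numeric(0),
                       degree = integer(0)),
    edges = data.frame(from = integer(0), to = integer(0),
                       length = numeric(0), meanRadius = numeric(0)),
    polylines = list(), graph = igraph::make_empty_graph(directed = FALSE))
  if (!any(mask)) return(emptyGraph())
  d <- dim3(mask)
  ed <- edtSq(!mask, spacing)
  skel <- array(.thin3d(as.logical(mask), d, as.numeric(ed)), d)
  idx <- which(skel)
  if (!length(idx)) return(emptyGraph())
  radius <- sqrt(ed[idx])
  co <- arrayInd(idx, d)
  # adjacency among skeleton voxels (26-neighbourhood)
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  adj <- vector("list", length(idx))
  for (o in seq_len(nrow(offs))) {
    nc <- sweep(co, 2, offs[o, ], "+")
    ok <- nc[, 1] >= 1 & nc[, 1] <= d[1] & nc[, 2] >= 1 & nc[, 2] <= d[2] &
      nc[, 3] >= 1 & nc[, 3] <= d[3]
    ni <- rep(0L, length(idx))
    ni[ok] <- pos[nc[ok, 1] + d[1] * (nc[ok, 2] - 1L) +
                    d[1] * d[2] * (nc[ok, 3] - 1L)]
    hit <- which(ni > 0L)
    for (h in hit) adj[[h]] <- c(adj[[h]], ni[h])
  }
  deg <- lengths(adj)
  g <- buildSkelGraph(co, radius, adj, deg, spacing)
  if (prune && nrow(g$edges)) g <- pruneSpurs(g, pruneFactor)
  ig <- if (nrow(g$edges))
    igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                  directed = FALSE,
                                  vertices = data.frame(name = g$nodes$id))
  else igraph::make_empty_graph(directed = FALSE)
  new("NetworkGraph", nodes = g$nodes, edges = g$edges,
      polylines = g$polylines, graph = ig)
}

# trace voxel chains between node voxels (degree != 2 or junction clusters)
buildSkelGraph <- function(co, radius, adj, deg, spacing) {
  nV <- nrow(co)
  isNode <- deg != 2L
  # cluster adjacent node voxels into single nodes
  nodeId <- integer(nV)
  nNodes <- 0L
  for (v in which(isNode)) {
    if (nodeId[v]) next
    nNodes <- nNodes + 1L
    stack <- v
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (nodeId[cur]) next
      nodeId[cur] <- nNodes
      nb <- adj[[cur]]
      stack <- c(stack, nb[isNode[nb] & nodeId[nb] == 0L])
    }
  }
  # an isolated cycle has no node voxel: promote one voxel per cycle
  visited <- logical(nV)
  markChain <- function(start) {
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (visited[cur]) next
      visited[cur] <<- TRUE
      stack <- c(stack, adj[[cur]][!visited[adj[[cur]]]])
    }
  }
  for (v in which(isNode)) markChain(v)
  while (any(!visited)) {
    v <- which(!visited)[1]
    nNodes <- nNodes + 1L
    nodeId[v] <- nNodes
    isNode[v] <- TRUE
    markChain(v)
  }
  umCoord <- function(i) (co[i, , drop = FALSE] - 1) * rep(spacing,
                                                           each = length(i))
  # node table
  nodes <- data.frame(id = seq_len(nNodes), x = 0, y = 0, z = 0,
                      radius = 0, degree = 0L)
  for (k in seq_len(nNodes)) {
    mem <- which(nodeId == k)
    cc <- colMeans(umCoord(mem))
    nodes$x[k] <- cc[1]; nodes$y[k] <- cc[2]; nodes$z[k] <- cc[3]
    nodes$radius[k] <- mean(radius[mem])
  }
  # walk edges
  edges <- list(); polylines <- list()
  used <- new.env(hash = TRUE)
  stepLen <- function(a, b) sqrt(sum(((co[a, ] - co[b, ]) * spacing)^2))
  for (v in which(isNode)) {
    for (nb in adj[[v]]) {
      key <- paste0(min(v, nb), "_", max(v, nb))
      if (!is.null(used[[key]])) next
      # walk from v through nb until the next node voxel
      path <- c(v, nb)
      used[[key]] <- TRUE
      prev <- v; cur <- nb
      while (!isNode[cur]) {
        nxt <- setdiff(adj[[cur]], prev)
        if (!length(nxt)) break              # dead end (shouldn't happen)
        nxt <- nxt[1]
        k2 <- paste0(min(cur, nxt), "_", max(cur, nxt))
        if (!is.null(used[[k2]])) break
        used[[k2]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      if (!isNode[cur]) next
      a <- nodeId[v]; b <- nodeId[cur]
      len <- sum(vapply(seq_len(length(path) - 1L),
                        function(i) stepLen(path[i], path[i + 1L]), 0))
      edges[[length(edges) + 1L]] <- data.frame(
        from = a, to = b, length = len, meanRadius = mean(radius[path]))
      polylines[[length(polylines) + 1L]] <- umCoord(path)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = integer(0), to = integer(0),
                           length = numeric(0), meanRadius = numeric(0))
  # node degrees from edge incidence
  nodes$degree <- vapply(nodes$id, function(k)
    sum(edges$from == k) + sum(edges$to == k), 0L)
  list(nodes = nodes, edges = edges, polylines = polylines)
}

pruneSpurs <- function(g, pruneFactor) {
  repeat {
    degree <- vapply(g$nodes$id, function(k)
      sum(g$edges$from == k) + sum(g$edges$to == k), 0L)
    leafEnd <- function(i) {
      a <- g$edges$from[i]; b <- g$edges$to[i]
      da <- degree[match(a, g$nodes$id)]; db <- degree[match(b, g$nodes$id)]
      if (da == 1L && db > 1L) return(b)
      if (db == 1L && da > 1L) return(a)
      NA_integer_
    }
    drop <- integer(0)
    for (i in seq_len(nrow(g$edges))) {
      j <- leafEnd(i)
      if (is.na(j)) next
      rj <- g$nodes$radius[match(j, g$nodes$id)]
      if (g$edges$length[i] < pruneFactor * rj) drop <- c(drop, i)
    }
    if (!length(drop)) break
    g$edges <- g$edges[-drop, , drop = FALSE]
    g$polylines <- g$polylines[-drop]
    keep <- unique(c(g$edges$from, g$edges$to))
    g$nodes <- g$nodes[g$nodes$id %in% keep, , drop = FALSE]
  }
  # merge pass-through nodes (degree 2 after pruning)
  g <- mergeDegree2(g)
  g
}

mergeDegree2 <- function(g) {
  repeat {
    degree <- vapply(g$nodes$id, function(k)
      sum(g$edges$from == k) + sum(g$edges$to == k), 0L)
    cand <- g$nodes$id[degree == 2L]
    merged <- FALSE
    for (k in cand) {
      inc <- which(g$edges$from == k | g$edges$to == k)
      if (length(inc) != 2L) next
      e1 <- g$edges[inc[1], ]; e2 <- g$edges[inc[2], ]
      o1 <- if (e1$from == k) e1$to else e1$from
      o2 <- if (e2$from == k) e2$to else e2$from
      if (o1 == k || o2 == k) next            # self loop, keep
      # orient p1 to run o1 -> k and p2 to run k -> o2
      p1 <- orientPolyline(g$polylines[[inc[1]]], g$nodes, o1, k)
      p2 <- orientPolyline(g$polylines[[inc[2]]], g$nodes, k, o2)
      L <- e1$length + e2$length
      mr <- (e1$meanRadius * e1$length + e2$meanRadius * e2$length) / L
      g$edges <- g$edges[-inc, , drop = FALSE]
      g$polylines <- g$polylines[-inc]
      g$edges <- rbind(g$edges, data.frame(from = o1, to = o2, length = L,
                                           meanRadius = mr))
      g$polylines[[length(g$polylines) + 1L]] <- rbind(p1, p2[-1, ,
                                                              drop = FALSE])
      g$nodes <- g$nodes[g$nodes$id != k, , drop = FALSE]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  g
}

orientPolyline <- function(p, nodes, fromId, toId) {
  a <- as.numeric(nodes[match(fromId, nodes$id), c("x", "y", "z")])
  dStart <- sum((p[1, ] - a)^2)
  dEnd <- sum((p[nrow(p), ] - a)^2)
  if (dEnd < dStart) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

#' @rdname accessors
#' @export
setMethod("graphNodes", "NetworkGraph", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("graphEdges", "NetworkGraph", function(x) x@edges)
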