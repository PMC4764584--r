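# Internal triangle-mesh helpers.

# unit icosphere via icosahedron subdivision; returns vertices (unit radius,
# centred at origin) and 1-based triangles, outward orientation
icosphere <- function(subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edgeKey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    mids <- new.env()
    nv <- nrow(v)
    newV <- list()
    midpoint <- function(a, b) {
      k <- edgeKey(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      newV[[length(newV) + 1L]] <<- p
      id <- nv + length(newV)
      mids[[k]] <- id
      id
    }
    newF <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[4 * i - 3, ] <- c(a, ab, ca)
      newF[4 * i - 2, ] <- c(b, bc, ab)
      newF[4 * i - 1, ] <- c(cc, ca, bc)
      newF[4 * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newV))
    f <- newF
  }
  list(vertices = v, triangles = f)
}

# directed edge list (both directions) of a triangle matrix
meshEdgesDirected <- function(tri) {
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  rbind(e, e[, 2:1])
}

# per-vertex neighbour mean (uniform Laplacian smoothing target)
neighborMean <- function(V, edges) {
  .neighbor_mean(V, as.integer(edges[, 1]), as.integer(edges[, 2]))
}

# outward vertex normals (area-weighted average of face normals)
vertexNormals <- function(V, tri) {
  .vertex_normals(V, tri)
}

# signed volume (positive for outward-oriented closed meshes)
signedMeshVolume <- function(V, tri) {
  p1 <- V[tri[, 1], , drop = FALSE]
  p2 <- V[tri[, 2], , drop = FALSE]
  p3 <- V[tri[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

triangleAreas <- function(V, tri) {
  u <- V[tri[, 2], , drop = FALSE] - V[tri[, 1], , drop = FALSE]
  w <- V[tri[, 3], , drop = FALSE] - V[tri[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# voxelize a mesh (µm vertices) into a logical array of given dim/spacing;
# winding-number fill tolerates locally interpenetrating tuned surfaces
meshToMask <- function(mesh, dim, spacing, signedFill = TRUE) {
  vox <- sweep(mesh@vertices, 2, spacing, "/")
  array(.voxelize_mesh(vox, mesh@triangles, as.integer(dim), signedFill),
        dim = dim)
}

# voxel index ranges (with margin) of every positive label, in one pass
objectBBoxes <- function(lab, margin = 2L) {
  d <- dim(lab)
  idx <- which(lab > 0L)
  co <- arrayInd(idx, d)
  l <- lab[idx]
  out <- vector("list", max(lab))
  for (ax in 1:3) {
    lo <- tapply(co[, ax], l, min)
    hi <- tapply(co[, ax], l, max)
    for (k in seq_along(lo)) {
      i <- as.integer(names(lo)[k])
      out[[i]]$lo[ax] <- max(1L, lo[k] - margin)
      out[[i]]$hi[ax] <- min(d[ax], hi[k] + margin)
    }
  }
  out
}

# mesh the single component of a cropped mask, vertices in global µm
meshFromCrop <- function(sub, lo, spacing, smoothIters = 2L) {
  mt <- .march_tets(sub * 1.0, dim3(sub), 0.5)
  if (!nrow(mt$vertices)) return(NULL)
  verts <- sweep(sweep(mt$vertices, 2, lo - 1L, "+"), 2, spacing, "*")
  m <- new("TriangleMesh", vertices = verts, triangles = mt$triangles,
           flags = list())
  if (smoothIters > 0L) m <- smoothMesh(m, iters = smoothIters, lambda = 0.4)
  m
}

# voxelize a mesh into the bbox crop only; returns logical array of crop dim
meshToCrop <- function(mesh, lo, hi, spacing) {
  cd <- hi - lo + 1L
  vox <- sweep(sweep(mesh@vertices, 2, spacing, "/"), 2, lo - 1L)
  array(.voxelize_mesh(vox, mesh@triangles, as.integer(cd), TRUE), dim = cd)
}
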