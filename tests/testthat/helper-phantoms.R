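# Geometric phantoms shared across the suite.

ts <- asNamespace("tissuescope3d")

solidSphere <- function(dim = c(41, 41, 41), centre = (dim + 1) / 2,
                        radius = 10) {
  co <- as.matrix(expand.grid(seq_len(dim[1]), seq_len(dim[2]),
                              seq_len(dim[3])))
  d <- sqrt((co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2 +
            (co[, 3] - centre[3])^2)
  array(d <= radius, dim)
}

solidCylinderX <- function(len = 100, radius = 4, pad = 8) {
  d <- c(len + 2 * pad, 2 * ceiling(radius) + 2 * pad + 1,
         2 * ceiling(radius) + 2 * pad + 1)
  cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  co <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  m <- co[, 1] > pad & co[, 1] <= pad + len &
    ((co[, 2] - cy)^2 + (co[, 3] - cz)^2) <= radius^2
  array(m, d)
}

solidTorus <- function(dim = c(41, 41, 41), R = 10, r = 4) {
  c0 <- (dim + 1) / 2
  co <- as.matrix(expand.grid(seq_len(dim[1]), seq_len(dim[2]),
                              seq_len(dim[3])))
  d <- sqrt((sqrt((co[, 1] - c0[1])^2 + (co[, 2] - c0[2])^2) - R)^2 +
            (co[, 3] - c0[3])^2)
  array(d <= r, dim)
}

# slab occupying z in [z1, z2] with optional per-column bending of both
# surfaces (bend: matrix of offsets) and embedded empty spheres
bentSlab <- function(nx = 48, ny = 48, nz = 80, z1 = 20, z2 = 60,
                     bend = NULL, holes = NULL, fg = 100, bg = 0) {
  a <- array(bg, c(nx, ny, nz))
  if (is.null(bend)) bend <- matrix(0, nx, ny)
  zi <- array(rep(seq_len(nz), each = nx * ny), c(nx, ny, nz))
  top <- array(rep(z1 + bend, nz), c(nx, ny, nz))
  bot <- array(rep(z2 + bend, nz), c(nx, ny, nz))
  a[zi >= top & zi <= bot] <- fg
  if (!is.null(holes)) {
    co <- as.matrix(expand.grid(seq_len(nx), seq_len(ny), seq_len(nz)))
    for (h in holes) {
      dd <- sqrt((co[, 1] - h[1])^2 + (co[, 2] - h[2])^2 +
                 (co[, 3] - h[3])^2)
      a[dd <= h[4]] <- bg
    }
  }
  a
}

meshOfSphere <- function(radius = 10, dim = c(41, 41, 41), spacing = 1) {
  meshFromMask(solidSphere(dim, radius = radius), spacing)[[1]]
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
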