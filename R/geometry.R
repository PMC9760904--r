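#' Build a hexagonal subcellular-element cell
#'
#' Constructs the rest configuration of a model cell as a centered hexagonal
#' (triangular-lattice) patch of subcellular elements. A patch with `n_rings`
#' rings around the central element contains `N = 1 + 3 n (n + 1)` elements,
#' and every nearest-neighbor pair is connected by a Kelvin-Voigt bond with
#' rest length `L_cell / sqrt(N)`, so that the patch diameter is close to the
#' nominal cell diameter `L_cell` (model length unit: 10 um).
#'
#' One lattice direction is aligned with the x axis so the rightmost element
#' is unique; that element is marked as the activator (the element that
#' receives chemical stimuli). Ties are broken by largest x, then largest y.
#'
#' @param n_rings Number of rings around the central element (>= 1). 5 rings
#'   give the standard small cell (N = 91), 7 rings the large cell (N = 169).
#' @param L_cell Nominal cell diameter in model units (default 1, i.e. 10 um).
#' @return A `cell_mesh` object: a list with `positions` (N x 2 matrix),
#'   `bonds` (E x 2 integer matrix, 1-based, i < j), `rest_length` (length-E
#'   vector of bond rest lengths), `triangles` (F x 3 integer matrix of
#'   counter-clockwise oriented unit triangles), `activator` (element index),
#'   `L_cell`, and `shape = "hexagonal"`.
#' @examples
#' mesh <- build_hexagonal_cell(5)
#' nrow(mesh$positions)  # 91
#' nrow(mesh$bonds)      # 240
#' @seealso [build_circular_cell()], [triangle_areas()]
#' @export
build_hexagonal_cell <- function(n_rings, L_cell = 1) {
  stopifnot(length(n_rings) == 1L, n_rings >= 1, n_rings == round(n_rings),
            length(L_cell) == 1L, L_cell > 0)
  n <- as.integer(n_rings)
  N <- 1L + 3L * n * (n + 1L)
  s <- L_cell / sqrt(N)

  # axial coordinates (q, r) with hex distance <= n
  qs <- integer(0); rs <- integer(0)
  for (q in -n:n) for (r in max(-n, -q - n):min(n, -q + n)) {
    qs <- c(qs, q); rs <- c(rs, r)
  }
  x <- s * (qs + rs / 2)
  y <- s * rs * (sqrt(3) / 2)
  key <- paste(qs, rs)
  idx <- seq_along(key)
  names(idx) <- key

  # unit triangles keyed by the lattice cell (q,r): "up" = (q,r),(q+1,r),(q,r+1)
  # and "down" = (q+1,r),(q+1,r+1),(q,r+1). The base cell of a down triangle
  # may itself lie outside the patch, so scan an extended base grid.
  qb <- rep(-(n + 1L):n, times = 2L * n + 2L)
  rb <- rep(-(n + 1L):n, each = 2L * n + 2L)
  tri <- matrix(0L, 0L, 3L)
  up <- cbind(paste(qb, rb), paste(qb + 1L, rb), paste(qb, rb + 1L))
  dn <- cbind(paste(qb + 1L, rb), paste(qb + 1L, rb + 1L), paste(qb, rb + 1L))
  for (m in list(up, dn)) {
    ok <- m[, 1] %in% key & m[, 2] %in% key & m[, 3] %in% key
    tri <- rbind(tri, cbind(idx[m[ok, 1]], idx[m[ok, 2]], idx[m[ok, 3]]))
  }
  dimnames(tri) <- NULL

  mesh <- new_cell_mesh(cbind(x, y), tri, L_cell, shape = "hexagonal")
  mesh$rest_length <- rep(s, nrow(mesh$bonds))
  mesh$n_rings <- n
  mesh
}

#' Build an approximately circular subcellular-element cell
#'
#' Places elements on concentric rings at spacing close to
#' `L_cell / sqrt(target_N)` and triangulates adjacent rings with a
#' structured annulus stitching (advancing by polar angle), which cannot
#' produce crossing edges and yields counter-clockwise triangles. Each bond's
#' rest length is set to the as-built element distance, so the circular cell
#' is stress-free at its initial configuration.
#'
#' The number of rings is chosen so the element count is as close as possible
#' to `target_N`; the achieved `N` is typically within +-10% of the target.
#'
#' @param target_N Desired number of elements (>= 7).
#' @param L_cell Cell diameter in model units.
#' @return A `cell_mesh` (see [build_hexagonal_cell()]) with
#'   `shape = "circular"` and an extra field `ell0`, the mean bond length
#'   `L_bond / N_bond`.
#' @export
build_circular_cell <- function(target_N, L_cell = 1) {
  stopifnot(target_N >= 7, L_cell > 0)
  # elements per ring m: round(2*pi*m); pick ring count with N nearest target
  count_for <- function(M) 1L + sum(as.integer(round(2 * pi * seq_len(M))))
  M <- 1L
  while (count_for(M + 1L) <= target_N) M <- M + 1L
  if (abs(count_for(M + 1L) - target_N) < abs(count_for(M) - target_N))
    M <- M + 1L
  dr <- (L_cell / 2) / M

  rings <- vector("list", M + 1L)
  rings[[1]] <- matrix(c(0, 0), 1L, 2L)
  for (m in seq_len(M)) {
    nm <- as.integer(round(2 * pi * m))
    th <- 2 * pi * (seq_len(nm) - 1L) / nm
    rings[[m + 1L]] <- cbind(m * dr * cos(th), m * dr * sin(th))
  }
  pos <- do.call(rbind, rings)
  ring_id <- rep(seq_along(rings), vapply(rings, nrow, 1L))

  tri <- matrix(0L, 0L, 3L)
  offset <- cumsum(c(0L, vapply(rings, nrow, 1L)))
  # center fan
  n1 <- nrow(rings[[2]])
  for (j in seq_len(n1))
    tri <- rbind(tri, c(1L, offset[2] + j, offset[2] + j %% n1 + 1L))
  # stitch consecutive rings by advancing the pointer with the smaller angle
  if (M >= 2) for (m in 2:M) {
    tri <- rbind(tri, stitch_rings(offset[m] + seq_len(nrow(rings[[m]])),
                                   offset[m + 1] + seq_len(nrow(rings[[m + 1]])),
                                   pos))
  }

  mesh <- new_cell_mesh(pos, tri, L_cell, shape = "circular")
  d <- mesh$positions[mesh$bonds[, 1], , drop = FALSE] -
       mesh$positions[mesh$bonds[, 2], , drop = FALSE]
  mesh$rest_length <- sqrt(rowSums(d^2))
  mesh$ell0 <- sum(mesh$rest_length) / length(mesh$rest_length)
  mesh$ring_id <- ring_id
  mesh
}

# Triangulate the annulus between an inner ring (indices `a`) and an outer
# ring (`b`), both ordered by increasing polar angle starting near 0.
stitch_rings <- function(a, b, pos) {
  ang <- function(i) atan2(pos[i, 2], pos[i, 1]) %% (2 * pi)
  aa <- ang(a); bb <- ang(b)
  na <- length(a); nb <- length(b)
  # cumulative angle of the *next* vertex (handles the wrap once)
  nextang <- function(v, k) if (k < length(v)) v[k + 1L] else v[1L] + 2 * pi
  i <- 1L; j <- 1L; ci <- 0L; cj <- 0L
  tri <- matrix(0L, na + nb, 3L)
  t <- 0L
  while (ci < na || cj < nb) {
    adv_a <- if (ci >= na) FALSE
             else if (cj >= nb) TRUE
             else nextang(aa, i) <= nextang(bb, j)
    t <- t + 1L
    if (adv_a) {
      iN <- i %% na + 1L
      tri[t, ] <- c(a[i], b[j], a[iN])
      i <- iN; ci <- ci + 1L
    } else {
      jN <- j %% nb + 1L
      tri[t, ] <- c(a[i], b[j], b[jN])
      j <- jN; cj <- cj + 1L
    }
  }
  tri[seq_len(t), , drop = FALSE]
}

# Common constructor: derive bonds from triangle edges, orient triangles CCW,
# mark the rightmost element as the activator.
new_cell_mesh <- function(positions, triangles, L_cell, shape) {
  positions <- unname(as.matrix(positions))
  storage.mode(triangles) <- "integer"
  # enforce counter-clockwise orientation
  s <- signed_area(positions, triangles)
  flip <- s < 0
  if (any(flip)) triangles[flip, c(2, 3)] <- triangles[flip, c(3, 2)]
  s <- signed_area(positions, triangles)
  if (any(s <= 0))
    stop("degenerate triangle(s) in mesh construction: ",
         paste(which(s <= 0), collapse = ", "))
  edges <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  if (any(edges[, 1] == edges[, 2])) stop("self-bond produced")
  act <- order(-positions[, 1], -positions[, 2])[1L]
  structure(list(positions = positions,
                 bonds = edges,
                 rest_length = NULL,
                 triangles = triangles,
                 activator = act,
                 L_cell = L_cell,
                 shape = shape),
            class = "cell_mesh")
}

#' Signed areas of mesh triangles
#'
#' @param positions N x 2 coordinate matrix (defaults to the mesh rest
#'   positions when a `cell_mesh` is given).
#' @param triangles F x 3 integer matrix of vertex indices, or a `cell_mesh`.
#' @return Vector of signed triangle areas `S_ijk`; positive for
#'   counter-clockwise orientation.
#' @export
triangle_areas <- function(triangles, positions = NULL) {
  if (inherits(triangles, "cell_mesh")) {
    if (is.null(positions)) positions <- triangles$positions
    triangles <- triangles$triangles
  }
  signed_area(positions, triangles)
}

signed_area <- function(pos, tri) {
  ax <- pos[tri[, 1], 1]; ay <- pos[tri[, 1], 2]
  bx <- pos[tri[, 2], 1]; by <- pos[tri[, 2], 2]
  cx <- pos[tri[, 3], 1]; cy <- pos[tri[, 3], 2]
  ((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
}

#' Mean bond length of a mesh
#' @param mesh A `cell_mesh`.
#' @return `L_bond / N_bond`, the mean rest bond length.
#' @export
mean_bond_length <- function(mesh) {
  stopifnot(inherits(mesh, "cell_mesh"))
  mean(mesh$rest_length)
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("cell_mesh (%s): N = %d elements, %d bonds, %d triangles\n",
              x$shape, nrow(x$positions), nrow(x$bonds), nrow(x$triangles)))
  cat(sprintf("  L_cell = %g, mean bond length = %.6g, activator = element %d\n",
              x$L_cell, mean(x$rest_length), x$activator))
  invisible(x)
}

#' @export
plot.cell_mesh <- function(x, ...) {
  plot(x$positions, asp = 1, pch = 19, cex = 0.6,
       xlab = "x", ylab = "y", ...)
  segments(x$positions[x$bonds[, 1], 1], x$positions[x$bonds[, 1], 2],
           x$positions[x$bonds[, 2], 1], x$positions[x$bonds[, 2], 2],
           col = "grey70")
  points(x$positions[x$activator, 1], x$positions[x$activator, 2],
         pch = 8, col = "red", cex = 1.4)
  invisible(x)
}

#' Write / read a cell mesh as plain-text tables
#'
#' Serializes a mesh to three CSV tables (`<prefix>_elements.csv`,
#' `<prefix>_bonds.csv`, `<prefix>_triangles.csv`) with 1-based element
#' indices and full double precision, so that a write/read cycle is lossless.
#'
#' @param mesh A `cell_mesh`.
#' @param prefix Path prefix for the three CSV files.
#' @return `write_cell_mesh` returns the three file paths invisibly;
#'   `read_cell_mesh` returns the reconstructed `cell_mesh`.
#' @export
write_cell_mesh <- function(mesh, prefix) {
  stopifnot(inherits(mesh, "cell_mesh"))
  fmt <- function(v) sprintf("%.17g", v)
  el <- data.frame(id = seq_len(nrow(mesh$positions)),
                   x = fmt(mesh$positions[, 1]), y = fmt(mesh$positions[, 2]),
                   activator = as.integer(seq_len(nrow(mesh$positions)) == mesh$activator))
  bd <- data.frame(i = mesh$bonds[, 1], j = mesh$bonds[, 2],
                   rest_length = fmt(mesh$rest_length))
  tr <- data.frame(i = mesh$triangles[, 1], j = mesh$triangles[, 2],
                   k = mesh$triangles[, 3])
  paths <- paste0(prefix, c("_elements.csv", "_bonds.csv", "_triangles.csv"))
  utils::write.csv(el, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(bd, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(tr, paths[3], row.names = FALSE, quote = FALSE)
  cat(sprintf("L_cell,shape\n%.17g,%s\n", mesh$L_cell, mesh$shape),
      file = paste0(prefix, "_meta.csv"))
  invisible(paths)
}

#' @rdname write_cell_mesh
#' @export
read_cell_mesh <- function(prefix) {
  el <- utils::read.csv(paste0(prefix, "_elements.csv"))
  bd <- utils::read.csv(paste0(prefix, "_bonds.csv"))
  tr <- utils::read.csv(paste0(prefix, "_triangles.csv"))
  meta <- utils::read.csv(paste0(prefix, "_meta.csv"))
  mesh <- structure(list(positions = cbind(el$x, el$y),
                         bonds = cbind(as.integer(bd$i), as.integer(bd$j)),
                         rest_length = bd$rest_length,
                         triangles = cbind(as.integer(tr$i), as.integer(tr$j),
                                           as.integer(tr$k)),
                         activator = which(el$activator == 1L),
                         L_cell = as.numeric(meta$L_cell),
                         shape = as.character(meta$shape)),
                    class = "cell_mesh")
  mesh
}
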