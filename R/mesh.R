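#' Build a synthetic cortical surface mesh
#'
#' Constructs a small stand-in for a cortical hemisphere mesh: a set of
#' vertices with coordinates, a symmetric neighbourhood graph, strictly
#' positive per-vertex midthickness areas (mm^2) and an analysis mask
#' (all `TRUE` on construction; callers may mask out low-quality vertices
#' later, e.g. from a tSNR map).
#'
#' Two geometries are available:
#' * `"grid"` — a rectangular lattice with 1 mm spacing and 4-neighbour
#'   connectivity; interior vertices have exactly 4 neighbours.
#' * `"sphere"` — a Fibonacci lattice on a sphere whose radius is chosen so
#'   the mean per-vertex area is about 1 mm^2, with a symmetrized
#'   k-nearest-neighbour graph (k = 6), mimicking a closed cortical surface.
#'
#' Per-vertex areas are proportional to the local mean squared neighbour
#' distance (a Voronoi-like weight) and normalised so they sum to the total
#' surface area, giving realistic spatial variation in vertex area.
#'
#' @param n_vertices Number of vertices V (>= 16).
#' @param kind `"grid"` or `"sphere"`.
#' @param seed Integer seed; for `"sphere"` it jitters the lattice slightly,
#'   for `"grid"` it is unused but kept so every generator has the same
#'   signature. Same arguments + seed always give the identical mesh.
#' @return An object of class `surface_mesh`: a list with `n_vertices`,
#'   `coords` (V x 3), `adjacency` (sparse symmetric 0/1 Matrix),
#'   `vertex_area` (length-V, mm^2), `analysis_mask` (length-V logical),
#'   `edge_length` (mean edge length, mm) and `kind`.
#' @examples
#' mesh <- make_mesh(100, kind = "grid")
#' sum(mesh$vertex_area)
#' @export
make_mesh <- function(n_vertices, kind = c("grid", "sphere"), seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(n_vertices) || length(n_vertices) != 1L || n_vertices < 16)
    stop("`n_vertices` must be a single number >= 16", call. = FALSE)
  n_vertices <- as.integer(n_vertices)

  if (kind == "grid") {
    mesh <- make_grid_mesh(n_vertices)
  } else {
    mesh <- withr::with_seed(as.integer(seed), make_sphere_mesh(n_vertices))
  }
  mesh$kind <- kind
  class(mesh) <- "surface_mesh"
  validate_mesh(mesh)
  mesh
}

# r x c lattice with r the largest divisor of n not exceeding sqrt(n)
make_grid_mesh <- function(n) {
  r <- floor(sqrt(n))
  while (r > 1 && n %% r != 0) r <- r - 1L
  cc <- n %/% r
  ij <- expand.grid(row = seq_len(r), col = seq_len(cc))
  coords <- cbind(ij$col - 1, ij$row - 1, 0)
  idx <- matrix(seq_len(n), nrow = r)
  from <- integer(0); to <- integer(0)
  if (cc > 1) { from <- c(from, idx[, -cc]); to <- c(to, idx[, -1]) }
  if (r > 1)  { from <- c(from, idx[-r, ]);  to <- c(to, idx[-1, ]) }
  adj <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                              dims = c(n, n))
  list(n_vertices = n, coords = coords, adjacency = adj,
       vertex_area = rep(1, n), analysis_mask = rep(TRUE, n),
       edge_length = 1)
}

make_sphere_mesh <- function(n) {
  radius <- sqrt(n / (4 * pi)) # mean vertex area ~ 1 mm^2
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * i + stats::runif(1, 0, 2 * pi) # seeded rotation jitter
  coords <- radius * cbind(rho * cos(theta), rho * sin(theta), z)

  k <- 6L
  d2 <- as.matrix(stats::dist(coords))^2
  from <- integer(0); to <- integer(0)
  for (v in seq_len(n)) {
    nb <- order(d2[v, ])[2:(k + 1L)]
    from <- c(from, rep.int(v, k)); to <- c(to, nb)
  }
  adj <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                              dims = c(n, n))
  adj@x[] <- 1 # symmetrize duplicates to unit weight
  adj <- Matrix::drop0(adj)
  Matrix::diag(adj) <- 0
  adj <- Matrix::drop0(adj)

  # Voronoi-like areas: local mean squared neighbour distance, normalized
  w <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] != 0)
    mean(d2[v, nb])
  }, numeric(1))
  area <- w / sum(w) * 4 * pi * radius^2
  el <- mean(sqrt(d2[as.matrix(Matrix::summary(adj))[, 1:2]]))
  list(n_vertices = n, coords = coords, adjacency = adj,
       vertex_area = area, analysis_mask = rep(TRUE, n),
       edge_length = el)
}

validate_mesh <- function(mesh) {
  adj <- mesh$adjacency
  stopifnot(isTRUE(Matrix::isSymmetric(adj)), all(Matrix::diag(adj) == 0),
            all(mesh$vertex_area > 0))
  if (!graph_connected(adj, which(mesh$analysis_mask)))
    stop("mesh analysis mask is not connected", call. = FALSE)
  invisible(mesh)
}

# BFS connectivity of the induced subgraph on `verts`
graph_connected <- function(adj, verts) {
  if (length(verts) <= 1L) return(TRUE)
  inset <- logical(nrow(adj)); inset[verts] <- TRUE
  seen <- logical(nrow(adj))
  queue <- verts[1L]; seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- which(adj[v, ] != 0)
    nb <- nb[inset[nb] & !seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen[verts])
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s, %d vertices, %d edges, total area %.1f mm^2\n",
              x$kind, x$n_vertices, Matrix::nnzero(x$adjacency) / 2,
              sum(x$vertex_area)))
  cat(sprintf("  analysis mask: %d/%d vertices\n",
              sum(x$analysis_mask), x$n_vertices))
  invisible(x)
}

#' Geodesic-style distance from mesh vertices to a source vertex
#'
#' Grid meshes use planar Euclidean distance; spherical meshes use
#' great-circle distance. Used by the synthetic generator to place smooth
#' network blobs.
#'
#' @param mesh A `surface_mesh`.
#' @param from Source vertex index.
#' @return Numeric vector of length V, distances in mm.
#' @keywords internal
mesh_distance <- function(mesh, from) {
  p <- mesh$coords
  if (identical(mesh$kind, "sphere")) {
    radius <- sqrt(sum(p[from, ]^2))
    cosang <- pmin(1, pmax(-1, (p %*% p[from, ]) / (radius^2)))
    radius * acos(drop(cosang))
  } else {
    sqrt(rowSums((p - matrix(p[from, ], nrow(p), 3, byrow = TRUE))^2))
  }
}

#' Smooth a vertex map on the surface with an approximate geodesic Gaussian
#'
#' Applies iterated graph-Laplacian diffusion calibrated so the effective
#' kernel approximates a 2D geodesic Gaussian of the requested FWHM
#' (sigma = fwhm / sqrt(8 ln 2)). The combinatorial Laplacian conserves the
#' map sum exactly on a closed mesh, and disconnected components of the
#' supplied mask are smoothed independently (diffusion cannot cross a
#' missing edge).
#'
#' The explicit Euler step `x <- x - tau * L x` adds kernel variance
#' `2 * tau * h^2` per iteration (h = mean edge length), so the number of
#' iterations is `sigma^2 / (2 h^2 tau)` with `tau` capped for stability.
#' A FWHM below one edge length cannot be represented on the graph and
#' returns the input unchanged.
#'
#' @param x Numeric vector of per-vertex values (length V).
#' @param mesh A `surface_mesh`.
#' @param fwhm_mm Kernel full width at half maximum, mm (> 0).
#' @param mask Logical length-V mask; vertices outside it are untouched and
#'   do not exchange mass. Defaults to the mesh analysis mask.
#' @return Smoothed numeric vector, length V.
#' @export
smooth_surface <- function(x, mesh, fwhm_mm, mask = mesh$analysis_mask) {
  stopifnot(inherits(mesh, "surface_mesh"), length(x) == mesh$n_vertices)
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop("`fwhm_mm` must be a single positive number", call. = FALSE)
  h <- mesh$edge_length
  if (fwhm_mm < h) return(x)
  sigma2 <- (fwhm_mm / sqrt(8 * log(2)))^2

  sub <- which(mask)
  adj <- mesh$adjacency[sub, sub, drop = FALSE]
  deg <- Matrix::rowSums(adj)
  tau_max <- 0.9 / max(deg, 1) # explicit-Euler stability
  n_iter <- max(1L, ceiling(sigma2 / (2 * h^2 * tau_max)))
  tau <- sigma2 / (2 * h^2 * n_iter)

  y <- x[sub]
  for (i in seq_len(n_iter)) {
    y <- y - tau * (deg * y - drop(adj %*% y))
  }
  out <- x
  out[sub] <- y
  out
}
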