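#' Clipping plane
#'
#' A half-space used to delineate the aneurysm sac, the parent-artery band,
#' or any other region of a lumen surface. A vertex x is kept when
#' `side * dot(normal, x - origin) >= 0`.
#'
#' @param origin 3-vector, a point on the plane (mm).
#' @param normal 3-vector; normalized internally, must be nonzero.
#' @param side +1 or -1, which side of the plane to keep.
#' @return an object of class `clip_plane`.
#' @export
clip_plane <- function(origin, normal, side = 1) {
  origin <- as.double(origin)
  normal <- as.double(normal)
  stopifnot(length(origin) == 3L, length(normal) == 3L)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("plane normal must be nonzero")
  normal <- normal / nn
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-9) stop("normal normalization failed")
  side <- as.double(side)
  if (!side %in% c(-1, 1)) stop("side must be +1 or -1")
  structure(list(origin = origin, normal = normal, side = side),
            class = "clip_plane")
}

# signed "keep" coordinate of points w.r.t. a clip plane
.plane_signed <- function(points, plane) {
  d <- sweep(points, 2L, plane$origin)
  plane$side * as.vector(d %*% plane$normal)
}

# characteristic length used for relative tolerances
.mesh_diameter <- function(points) {
  r <- apply(points, 2L, range)
  sqrt(sum((r[2L, ] - r[1L, ])^2))
}

# triangle mask of the connected component containing the vertex nearest seed.
# Frontier expansion, vectorized over triangles.
.component_triangles <- function(points, triangles, seed) {
  n <- nrow(points)
  d2 <- rowSums(sweep(points, 2L, seed)^2)
  d2[-unique(as.vector(triangles))] <- Inf  # only vertices used by triangles
  start <- which.min(d2)
  incomp <- logical(n)
  incomp_used <- logical(nrow(triangles))
  incomp <- incomp
  incomp[start] <- TRUE
  repeat {
    touch <- !incomp_used &
      (incomp[triangles[, 1L]] | incomp[triangles[, 2L]] | incomp[triangles[, 3L]])
    if (!any(touch)) break
    incomp_used[touch] <- TRUE
    incomp[triangles[touch, , drop = FALSE]] <- TRUE
  }
  incomp_used
}

# clip a mesh by one plane with exact triangle splitting (Sutherland-Hodgman
# per triangle); fields are interpolated linearly onto new edge vertices.
.clip_one_plane <- function(mesh, plane, eps_rel = 1e-12) {
  p <- mesh$points
  tr <- mesh$triangles
  fields <- mesh$fields
  eps <- eps_rel * max(.mesh_diameter(p), 1)
  s <- .plane_signed(p, plane)
  s[abs(s) < eps] <- 0

  sv <- cbind(s[tr[, 1L]], s[tr[, 2L]], s[tr[, 3L]])
  n_neg <- rowSums(sv < 0)
  n_pos <- rowSums(sv > 0)
  keep_whole <- n_neg == 0L
  drop_whole <- n_pos == 0L & n_neg > 0L
  mixed <- which(!keep_whole & !drop_whole)

  # registry of edge-intersection vertices, keyed on the (sorted) mesh edge
  edge_key <- character(0)
  edge_i <- integer(0)
  edge_j <- integer(0)
  edge_t <- numeric(0)
  edge_idx <- new.env(parent = emptyenv())
  n_orig <- nrow(p)
  get_edge_vertex <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    key <- paste0(a, ":", b)
    idx <- edge_idx[[key]]
    if (!is.null(idx)) return(idx)
    t <- s[a] / (s[a] - s[b])  # fraction from a to b where s = 0
    edge_i[[length(edge_i) + 1L]] <<- a
    edge_j[[length(edge_j) + 1L]] <<- b
    edge_t[[length(edge_t) + 1L]] <<- t
    idx <- n_orig + length(edge_t)
    edge_idx[[key]] <- idx
    idx
  }

  new_tris <- list()
  for (ti in mixed) {
    v <- tr[ti, ]
    poly <- integer(0)
    for (k in 1:3) {
      a <- v[k]
      b <- v[if (k == 3L) 1L else k + 1L]
      if (s[a] >= 0) poly <- c(poly, a)
      if ((s[a] > 0 && s[b] < 0) || (s[a] < 0 && s[b] > 0))
        poly <- c(poly, get_edge_vertex(a, b))
    }
    # drop consecutive duplicates (on-plane vertices can coincide)
    if (length(poly) > 1L)
      poly <- poly[c(TRUE, poly[-1L] != poly[-length(poly)])]
    if (length(poly) > 1L && poly[1L] == poly[length(poly)])
      poly <- poly[-length(poly)]
    if (length(poly) >= 3L)
      for (k in 2:(length(poly) - 1L))
        new_tris[[length(new_tris) + 1L]] <- poly[c(1L, k, k + 1L)]
  }

  if (length(edge_t)) {
    ei <- unlist(edge_i); ej <- unlist(edge_j); et <- unlist(edge_t)
    newp <- p[ei, , drop = FALSE] * (1 - et) + p[ej, , drop = FALSE] * et
    p <- rbind(p, newp)
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (is.matrix(f)) {
        fields[[nm]] <- rbind(f, f[ei, , drop = FALSE] * (1 - et) +
                                   f[ej, , drop = FALSE] * et)
      } else {
        fields[[nm]] <- c(f, f[ei] * (1 - et) + f[ej] * et)
      }
    }
  }

  tr_out <- rbind(tr[keep_whole, , drop = FALSE],
                  if (length(new_tris)) do.call(rbind, new_tris))
  list(points = p, triangles = tr_out, fields = fields)
}

# drop vertices not referenced by any triangle, remapping indices
.prune_vertices <- function(points, triangles, fields) {
  used <- sort(unique(as.vector(triangles)))
  remap <- integer(nrow(points))
  remap[used] <- seq_along(used)
  tr <- matrix(remap[triangles], ncol = 3L)
  fields <- lapply(fields, function(f)
    if (is.matrix(f)) f[used, , drop = FALSE] else f[used])
  list(points = points[used, , drop = FALSE], triangles = tr, fields = fields)
}

#' Clip a surface mesh by a set of planes
#'
#' Keeps the region on the kept side of every plane. Triangles crossing a
#' plane are split exactly along it, so region areas carry no whole-triangle
#' resolution bias; vertex fields are interpolated linearly onto the new cut
#' vertices. By default the result is restricted to the connected component
#' containing the kept vertex nearest `seed` (region definitions place the
#' seed inside the target region, e.g. the sac dome).
#'
#' @param mesh a [surface_mesh()].
#' @param planes a single [clip_plane()] or a list of them.
#' @param seed 3-vector inside the target region (mm); must lie on the kept
#'   side of all planes. May be `NULL` when `component = FALSE`.
#' @param component if `FALSE`, return the whole kept region without
#'   connected-component selection (no seed needed).
#' @return the clipped [surface_mesh()].
#' @export
clip_by_planes <- function(mesh, planes, seed = NULL, component = TRUE) {
  if (inherits(planes, "clip_plane")) planes <- list(planes)
  stopifnot(length(planes) >= 1L)
  if (component) {
    if (is.null(seed)) stop("a seed point is required for component selection")
    seed <- as.double(seed)
    eps <- 1e-9 * max(.mesh_diameter(mesh$points), 1)
    for (pl in planes)
      if (.plane_signed(matrix(seed, 1L), pl) < -eps)
        stop("seed lies on the discarded side of a clip plane")
  }
  cur <- list(points = mesh$points, triangles = mesh$triangles,
              fields = mesh$fields)
  for (pl in planes) {
    cur <- .clip_one_plane(
      surface_mesh(cur$points, cur$triangles, cur$fields), pl)
    if (is.null(cur$triangles) || nrow(cur$triangles) == 0L)
      stop("clipping produced an empty region")
  }
  if (component) {
    keep <- .component_triangles(cur$points, cur$triangles, seed)
    cur$triangles <- cur$triangles[keep, , drop = FALSE]
    if (nrow(cur$triangles) == 0L) stop("clipping produced an empty region")
  }
  cur <- .prune_vertices(cur$points, cur$triangles, cur$fields)
  surface_mesh(cur$points, cur$triangles, cur$fields)
}
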