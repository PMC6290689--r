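#' Planar cross-section patch
#'
#' A planar triangulated lumen cut carrying per-vertex velocity data, from
#' which lumen area and mean through-plane velocity are integrated. Most
#' submissions carry velocity vectors; a minority provide magnitudes only,
#' which are handled by an explicit magnitude mode (flagged on the result).
#'
#' @param points n x 3 coordinates in mm, all lying within the planarity
#'   tolerance of one plane.
#' @param triangles m x 3 integer matrix, 1-based.
#' @param velocity n x 3 per-vertex velocity vectors in cm/s, or `NULL`.
#' @param velocity_magnitude length-n per-vertex speeds in cm/s, or `NULL`.
#'   Exactly one of `velocity` / `velocity_magnitude` must be given.
#' @param normal optional unit 3-vector (oriented downstream). When `NULL`
#'   the plane is fitted to the points by least squares and, when velocity
#'   vectors are present, the sign is chosen so that the mean of `v . n` is
#'   nonnegative; for magnitude-only patches the fitted sign is kept and the
#'   caller is expected to orient via the region definition.
#' @param planarity_tol maximum point-to-plane distance, relative to the
#'   patch diameter (default 1e-6).
#' @return an object of class `cross_section`.
#' @export
cross_section <- function(points, triangles, velocity = NULL,
                          velocity_magnitude = NULL, normal = NULL,
                          planarity_tol = 1e-6) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  n <- nrow(points)
  has_vec <- !is.null(velocity)
  has_mag <- !is.null(velocity_magnitude)
  if (has_vec == has_mag)
    stop("exactly one of velocity / velocity_magnitude must be provided")
  if (has_vec) {
    velocity <- as.matrix(velocity)
    storage.mode(velocity) <- "double"
    if (nrow(velocity) != n || ncol(velocity) != 3L)
      stop("velocity must be n x 3")
  } else {
    velocity_magnitude <- as.double(velocity_magnitude)
    if (length(velocity_magnitude) != n)
      stop("velocity_magnitude must have one value per vertex")
  }

  ctr <- colMeans(points)
  centered <- sweep(points, 2L, ctr)
  if (is.null(normal)) {
    sv <- svd(centered, nu = 0L, nv = 3L)
    normal <- sv$v[, 3L]
  }
  normal <- as.double(normal)
  normal <- normal / sqrt(sum(normal^2))
  if (abs(sqrt(sum(normal^2)) - 1) > 1e-9) stop("invalid patch normal")

  diam <- .mesh_diameter(points)
  dev <- max(abs(centered %*% normal))
  if (dev > planarity_tol * diam)
    stop(sprintf(paste0("patch is not planar: max point-to-plane distance ",
                        "%.3g exceeds tolerance %.3g"),
                 dev, planarity_tol * diam))

  if (has_vec) {
    mean_dot <- mean(velocity %*% normal)
    if (mean_dot < 0) normal <- -normal
  }
  structure(list(points = points, triangles = triangles,
                 normal = normal, velocity = velocity,
                 velocity_magnitude = velocity_magnitude,
                 is_magnitude_only = has_mag),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("cross_section: %d vertices, %d triangles, %s velocity\n",
              nrow(x$points), nrow(x$triangles),
              if (x$is_magnitude_only) "magnitude-only" else "vector"))
  invisible(x)
}

#' Patch area
#'
#' @param patch a [cross_section()].
#' @return area in mm^2.
#' @export
patch_area <- function(patch) {
  sum(triangle_areas(list(points = patch$points, triangles = patch$triangles)))
}

#' Mean through-plane velocity of a cross-section patch
#'
#' Vector mode integrates the through-plane component,
#' `(1/A) * integral of v . n dA`; magnitude mode integrates the provided
#' speeds, `(1/A) * integral of |v| dA`. Both use linear (per-triangle
#' vertex-average) quadrature. The returned value carries the integration
#' mode as attribute `velocity_mode` (`"vector"` or `"magnitude"`).
#'
#' @param patch a [cross_section()].
#' @return mean velocity in cm/s, with attribute `velocity_mode`.
#' @export
mean_velocity <- function(patch) {
  ta <- triangle_areas(list(points = patch$points, triangles = patch$triangles))
  A <- sum(ta)
  if (A <= 0) stop("degenerate patch: zero area")
  tr <- patch$triangles
  if (patch$is_magnitude_only) {
    f <- patch$velocity_magnitude
    mode <- "magnitude"
  } else {
    f <- as.vector(patch$velocity %*% patch$normal)
    mode <- "vector"
  }
  tri_mean <- (f[tr[, 1L]] + f[tr[, 2L]] + f[tr[, 3L]]) / 3
  structure(sum(tri_mean * ta) / A, velocity_mode = mode)
}

#' Volumetric flow rate from area and mean velocity
#'
#' `Q = area x velocity`, with the exact unit conversion
#' mm^2 * cm/s = 1e-2 mL/s.
#'
#' @param area lumen area in mm^2 (> 0).
#' @param velocity mean through-plane velocity in cm/s.
#' @return flow rate in mL/s.
#' @export
flow_rate <- function(area, velocity) {
  stopifnot(area > 0)
  0.01 * area * as.numeric(velocity)
}

#' Cross-section of a surface mesh by a plane
#'
#' Intersects the mesh with the plane, chains the per-triangle intersection
#' segments into closed loops, selects as the lumen contour the loop whose
#' centroid is nearest the plane origin, and measures its area by the planar
#' shoelace formula in an orthonormal in-plane basis.
#'
#' @param mesh a [surface_mesh()].
#' @param plane a list or [clip_plane()] with `origin` and `normal`.
#' @return an object of class `section_geometry`: `area` (mm^2),
#'   `effective_diameter` (`2*sqrt(area/pi)`, mm), `loops` (list of closed
#'   polylines), `lumen_loop` (index of the selected loop).
#' @export
plane_section <- function(mesh, plane) {
  p <- mesh$points
  tr <- mesh$triangles
  o <- as.double(plane$origin)
  nrm <- as.double(plane$normal)
  nrm <- nrm / sqrt(sum(nrm^2))
  s <- as.vector(sweep(p, 2L, o) %*% nrm)
  tol <- 1e-12 * max(.mesh_diameter(p), 1)
  s[abs(s) < tol] <- tol  # nudge on-plane vertices to the positive side

  sv <- cbind(s[tr[, 1L]], s[tr[, 2L]], s[tr[, 3L]])
  cut <- which(rowSums(sv > 0) %in% 1:2)
  if (length(cut) == 0L) stop("plane does not intersect the mesh")

  # one segment per cut triangle, endpoints keyed by the crossed mesh edge
  seg_a <- character(length(cut))
  seg_b <- character(length(cut))
  pt_of <- new.env(parent = emptyenv())
  edge_point <- function(i, j) {
    a <- min(i, j); b <- max(i, j)
    key <- paste0(a, ":", b)
    if (is.null(pt_of[[key]])) {
      t <- s[a] / (s[a] - s[b])
      pt_of[[key]] <- p[a, ] * (1 - t) + p[b, ] * t
    }
    key
  }
  for (k in seq_along(cut)) {
    v <- tr[cut[k], ]
    keys <- character(0)
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      i <- v[e[1L]]; j <- v[e[2L]]
      if ((s[i] > 0) != (s[j] > 0)) keys <- c(keys, edge_point(i, j))
    }
    if (length(keys) != 2L) stop("inconsistent triangle/plane intersection")
    seg_a[k] <- keys[1L]
    seg_b[k] <- keys[2L]
  }

  # chain segments into loops: every edge key must join exactly two segments
  nodes <- unique(c(seg_a, seg_b))
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  for (k in seq_along(seg_a)) {
    adj[[seg_a[k]]] <- c(adj[[seg_a[k]]], k)
    adj[[seg_b[k]]] <- c(adj[[seg_b[k]]], k)
  }
  deg <- lengths(adj)
  if (any(deg != 2L))
    stop(sprintf("open section contour: %d intersection point(s) with %s",
                 sum(deg != 2L),
                 paste(unique(deg[deg != 2L]), collapse = "/")))
  used <- logical(length(seg_a))
  loops <- list()
  for (k0 in seq_along(seg_a)) {
    if (used[k0]) next
    loop_keys <- seg_a[k0]
    cur_key <- seg_b[k0]
    used[k0] <- TRUE
    repeat {
      loop_keys <- c(loop_keys, cur_key)
      nxt <- adj[[cur_key]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) break
      k <- nxt[1L]
      used[k] <- TRUE
      cur_key <- if (seg_a[k] == cur_key) seg_b[k] else seg_a[k]
    }
    if (loop_keys[1L] != loop_keys[length(loop_keys)])
      stop("open section contour: loop failed to close")
    loop_keys <- loop_keys[-length(loop_keys)]
    loops[[length(loops) + 1L]] <-
      do.call(rbind, lapply(loop_keys, function(kk) pt_of[[kk]]))
  }

  centroids <- t(vapply(loops, colMeans, numeric(3L)))
  d2 <- rowSums(sweep(centroids, 2L, o)^2)
  sel <- which.min(d2)

  # orthonormal in-plane basis
  ref <- if (abs(nrm[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2L] * e1[3L] - nrm[3L] * e1[2L],
          nrm[3L] * e1[1L] - nrm[1L] * e1[3L],
          nrm[1L] * e1[2L] - nrm[2L] * e1[1L])
  lp <- sweep(loops[[sel]], 2L, o)
  u <- as.vector(lp %*% e1)
  v <- as.vector(lp %*% e2)
  j <- c(seq_len(length(u))[-1L], 1L)
  area <- abs(sum(u * v[j] - u[j] * v)) / 2
  if (area <= 0) stop("section produced zero area")

  structure(list(area = area,
                 effective_diameter = 2 * sqrt(area / pi),
                 loops = loops, lumen_loop = sel),
            class = "section_geometry")
}

#' @export
print.section_geometry <- function(x, ...) {
  cat(sprintf("section_geometry: area %.4g mm^2, D %.4g mm, %d loop(s)\n",
              x$area, x$effective_diameter, length(x$loops)))
  invisible(x)
}

#' Average area, velocity, diameter and flow rate over transverse slices
#'
#' The parent-artery characterization averages lumen area and mean
#' through-plane velocity over up to five transverse slices; the effective
#' diameter and the flow rate are then derived from the averaged area and
#' velocity.
#'
#' @param slices list of `list(geometry = , velocity = )` pairs, where
#'   `geometry` is a [plane_section()] result (or a bare area in mm^2) and
#'   `velocity` a mean through-plane velocity in cm/s. Length 1 to 5.
#' @return list with `area` (mm^2), `velocity` (cm/s), `diameter` (mm) and
#'   `flow_rate` (mL/s).
#' @export
multi_slice_average <- function(slices) {
  if (length(slices) < 1L || length(slices) > 5L)
    stop("between 1 and 5 slices are required")
  areas <- vapply(slices, function(s) {
    g <- s$geometry
    if (inherits(g, "section_geometry")) g$area else as.numeric(g)
  }, numeric(1L))
  vels <- vapply(slices, function(s) as.numeric(s$velocity), numeric(1L))
  area <- mean(areas)
  velocity <- mean(vels)
  list(area = area, velocity = velocity,
       diameter = 2 * sqrt(area / pi),
       flow_rate = flow_rate(area, velocity))
}

#' Read a cross-section patch
#'
#' Reads a VTK legacy ASCII polydata patch with either a per-vertex vector
#' field `velocity` or a scalar field `velocity_magnitude` (both cm/s).
#' Planarity is verified; the plane is fitted by least squares and oriented
#' downstream when vectors are present.
#'
#' @param path file path.
#' @param planarity_tol relative planarity tolerance (see [cross_section()]).
#' @return a [cross_section()].
#' @export
read_section <- function(path, planarity_tol = 1e-6) {
  raw <- read_vtk_polydata(path)
  sizes <- lengths(raw$polygons)
  if (any(sizes != 3L)) stop("unsupported cell: non-triangle polygon")
  tr <- do.call(rbind, raw$polygons)
  vel <- raw$point_data[["velocity"]]
  mag <- raw$point_data[["velocity_magnitude"]]
  if (!is.null(vel) && !is.null(mag))
    stop("ambiguous patch: both velocity and velocity_magnitude present")
  if (is.null(vel) && is.null(mag))
    stop("patch has neither velocity nor velocity_magnitude")
  cross_section(raw$points, tr, velocity = vel, velocity_magnitude = mag,
                planarity_tol = planarity_tol)
}

#' Write a cross-section patch
#'
#' @param patch a [cross_section()].
#' @param path output path (VTK legacy ASCII polydata).
#' @return `path`, invisibly.
#' @export
write_section <- function(patch, path) {
  pd <- if (patch$is_magnitude_only)
    list(velocity_magnitude = patch$velocity_magnitude)
  else list(velocity = patch$velocity)
  write_vtk_polydata(patch$points, patch$triangles, pd, path,
                     title = "wssvar cross-section")
}
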