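#' Triangulated lumen surface mesh
#'
#' Container for a triangulated surface with named per-vertex fields, the
#' unit of exchange for all geometry and hemodynamics operations. Coordinates
#' are in mm; the WSS field, when present, is named `"wss"` and is in Pa.
#'
#' @param points numeric matrix, n x 3, vertex coordinates in mm.
#' @param triangles integer matrix, m x 3, 1-based vertex indices. A triangle
#'   may not repeat a vertex index (geometrically degenerate triangles with
#'   distinct indices are allowed and contribute zero area).
#' @param fields named list of per-vertex data: numeric vectors of length n
#'   (scalar fields) or n x 3 matrices (vector fields).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(points, triangles, fields = list()) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(points) <- NULL
  dimnames(triangles) <- NULL
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  n <- nrow(points)
  if (nrow(triangles) > 0L) {
    if (min(triangles) < 1L || max(triangles) > n)
      stop("triangle index out of range")
    if (any(triangles[, 1L] == triangles[, 2L] |
            triangles[, 1L] == triangles[, 3L] |
            triangles[, 2L] == triangles[, 3L]))
      stop("triangle repeats a vertex index")
  }
  if (length(fields)) {
    if (is.null(names(fields)) || any(!nzchar(names(fields))))
      stop("all fields must be named")
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (is.matrix(f)) {
        if (nrow(f) != n || ncol(f) != 3L)
          stop(sprintf("vector field '%s' must be n x 3", nm))
        storage.mode(f) <- "double"
      } else {
        if (length(f) != n)
          stop(sprintf("field '%s' must have one value per vertex", nm))
        f <- as.double(f)
      }
      fields[[nm]] <- f
    }
  }
  structure(list(points = points, triangles = triangles, fields = fields),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, fields: %s\n",
              nrow(x$points), nrow(x$triangles),
              if (length(x$fields)) paste(names(x$fields), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Per-triangle areas of a surface mesh
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of triangle areas (mm^2); degenerate triangles
#'   contribute 0.
#' @export
triangle_areas <- function(mesh) {
  p <- mesh$points
  tr <- mesh$triangles
  a <- p[tr[, 2L], , drop = FALSE] - p[tr[, 1L], , drop = FALSE]
  b <- p[tr[, 3L], , drop = FALSE] - p[tr[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  0.5 * sqrt(cx * cx + cy * cy + cz * cz)
}

#' Total surface area
#'
#' @param mesh a `surface_mesh`.
#' @return total area in mm^2.
#' @export
surface_area <- function(mesh) sum(triangle_areas(mesh))

#' Vertex-lumped areas
#'
#' Each vertex receives one third of the area of every incident triangle, the
#' standard lumped weighting for area-weighted surface averages. The vertex
#' areas sum to the total surface area exactly (up to summation order).
#'
#' @param mesh a `surface_mesh`.
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh) / 3
  n <- nrow(mesh$points)
  va <- numeric(n)
  for (k in 1:3) {
    s <- rowsum(ta, group = mesh$triangles[, k])
    idx <- as.integer(rownames(s))
    va[idx] <- va[idx] + s[, 1L]
  }
  va
}

#' Signed volume enclosed by a surface
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for a
#' closed surface with outward-oriented triangle winding.
#'
#' @param mesh a `surface_mesh` (meaningful for closed surfaces).
#' @return signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  p <- mesh$points
  tr <- mesh$triangles
  a <- p[tr[, 1L], , drop = FALSE]
  b <- p[tr[, 2L], , drop = FALSE]
  c_ <- p[tr[, 3L], , drop = FALSE]
  det <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
         a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
         a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  sum(det) / 6
}

#' Mirror a mesh across a coordinate plane
#'
#' Flips one coordinate axis and reverses triangle winding so that outward
#' orientation is preserved. Mirroring twice is the identity; triangle areas
#' are preserved exactly.
#'
#' @param mesh a `surface_mesh`.
#' @param axis 1, 2 or 3: the coordinate to negate.
#' @return the mirrored `surface_mesh`.
#' @export
mirror_mesh <- function(mesh, axis = 1L) {
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  p <- mesh$points
  p[, axis] <- -p[, axis]
  tr <- mesh$triangles[, c(1L, 3L, 2L), drop = FALSE]
  surface_mesh(p, tr, mesh$fields)
}

#' Area-weighted mean of a scalar vertex field
#'
#' Vertex-lumped (one-third incident area) weights.
#'
#' @param mesh a `surface_mesh`.
#' @param field field name (default `"wss"`).
#' @return scalar area-weighted mean.
#' @export
field_area_mean <- function(mesh, field = "wss") {
  f <- mesh$fields[[field]]
  if (is.null(f)) stop(sprintf("mesh has no field '%s'", field))
  if (is.matrix(f)) stop("field_area_mean expects a scalar field")
  va <- vertex_areas(mesh)
  tot <- sum(va)
  if (tot <= 0) stop("mesh has zero surface area")
  sum(f * va) / tot
}

#' Surface area below a scalar-field threshold
#'
#' Area of the region where a linearly interpolated vertex field is below a
#' threshold. Triangles straddling the isocontour are split exactly along it
#' (linear interpolation along edges), so the result is the exact area of the
#' sub-threshold region of the piecewise-linear field. A vertex-lumped
#' estimate (sum of vertex areas with value below threshold) is available as
#' a cross-check via `method = "lumped"`.
#'
#' @param mesh a `surface_mesh`.
#' @param threshold scalar threshold.
#' @param field field name (default `"wss"`).
#' @param method `"exact"` (isocontour splitting) or `"lumped"`.
#' @return area in mm^2 of the region with field value < threshold.
#' @export
area_below_threshold <- function(mesh, threshold, field = "wss",
                                 method = c("exact", "lumped")) {
  method <- match.arg(method)
  f <- mesh$fields[[field]]
  if (is.null(f)) stop(sprintf("mesh has no field '%s'", field))
  if (method == "lumped") {
    va <- vertex_areas(mesh)
    return(sum(va[f < threshold]))
  }
  tr <- mesh$triangles
  ta <- triangle_areas(mesh)
  v <- cbind(f[tr[, 1L]], f[tr[, 2L]], f[tr[, 3L]])
  below <- v < threshold
  nb <- rowSums(below)
  out <- numeric(nrow(tr))
  out[nb == 3L] <- ta[nb == 3L]
  # mixed triangles: fraction of area below from linear interpolation.
  mix <- which(nb == 1L | nb == 2L)
  for (i in mix) {
    vi <- v[i, ]
    bi <- below[i, ]
    if (sum(bi) == 1L) {
      j <- which(bi)
      others <- setdiff(1:3, j)
      t1 <- (threshold - vi[j]) / (vi[others[1L]] - vi[j])
      t2 <- (threshold - vi[j]) / (vi[others[2L]] - vi[j])
      out[i] <- ta[i] * t1 * t2
    } else {
      j <- which(!bi)
      others <- setdiff(1:3, j)
      t1 <- (threshold - vi[j]) / (vi[others[1L]] - vi[j])
      t2 <- (threshold - vi[j]) / (vi[others[2L]] - vi[j])
      out[i] <- ta[i] * (1 - t1 * t2)
    }
  }
  sum(out)
}
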