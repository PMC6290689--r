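#' @name vtk_io
#' @title VTK legacy polydata input/output
#'
#' @description
#' The pipeline's canonical on-disk mesh format is VTK legacy polydata v3.0,
#' ASCII (`DATASET POLYDATA` with `POINTS`, `POLYGONS` and optional
#' `POINT_DATA` `SCALARS`/`VECTORS` blocks) — the de facto exchange format
#' for CFD surface post-processing. Only triangle cells are accepted;
#' anything else raises an error rather than being skipped silently.
NULL

# tokenize the numeric body of a block spread over an unknown number of lines
.vtk_scan <- function(lines, start, count) {
  vals <- numeric(0)
  i <- start
  while (length(vals) < count && i <= length(lines)) {
    v <- scan(text = lines[i], what = double(), quiet = TRUE)
    vals <- c(vals, v)
    i <- i + 1L
  }
  if (length(vals) < count) stop("unexpected end of VTK file")
  list(values = vals[seq_len(count)], next_line = i)
}

#' Read a VTK legacy ASCII polydata file
#'
#' @param path file path.
#' @return a list with `points` (n x 3), `polygons` (list of integer vectors,
#'   1-based) and `point_data` (named list of vectors / n x 3 matrices).
#' @keywords internal
read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  up <- toupper(trimws(lines))
  if (!any(grepl("^ASCII", up))) stop("only ASCII VTK legacy files are supported")
  if (!any(grepl("^DATASET\\s+POLYDATA", up))) stop("not a POLYDATA dataset")

  ip <- grep("^POINTS\\b", up)
  if (length(ip) != 1L) stop("expected exactly one POINTS block")
  n_pts <- as.integer(strsplit(trimws(lines[ip]), "\\s+")[[1L]][2L])
  sc <- .vtk_scan(lines, ip + 1L, 3L * n_pts)
  points <- matrix(sc$values, ncol = 3L, byrow = TRUE)

  for (kw in c("LINES", "VERTICES", "TRIANGLE_STRIPS"))
    if (any(grepl(paste0("^", kw, "\\b"), up)))
      stop(sprintf("unsupported cell block '%s': only triangle POLYGONS are handled", kw))

  polygons <- list()
  ig <- grep("^POLYGONS\\b", up)
  if (length(ig) == 1L) {
    hdr <- as.numeric(strsplit(trimws(lines[ig]), "\\s+")[[1L]][2:3])
    sc <- .vtk_scan(lines, ig + 1L, hdr[2L])
    vals <- as.integer(sc$values)
    polygons <- vector("list", hdr[1L])
    pos <- 1L
    for (k in seq_len(hdr[1L])) {
      sz <- vals[pos]
      polygons[[k]] <- vals[(pos + 1L):(pos + sz)] + 1L
      pos <- pos + sz + 1L
    }
  } else if (length(ig) > 1L) stop("multiple POLYGONS blocks")

  point_data <- list()
  ipd <- grep("^POINT_DATA\\b", up)
  if (length(ipd) == 1L) {
    n_pd <- as.integer(strsplit(trimws(lines[ipd]), "\\s+")[[1L]][2L])
    if (n_pd != n_pts) stop("POINT_DATA count does not match POINTS")
    i <- ipd + 1L
    while (i <= length(lines)) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      if (length(tok) == 0L || !nzchar(tok[1L])) { i <- i + 1L; next }
      key <- toupper(tok[1L])
      if (key == "SCALARS") {
        nm <- tok[2L]
        ncomp <- if (length(tok) >= 4L) as.integer(tok[4L]) else 1L
        if (is.na(ncomp)) ncomp <- 1L
        if (ncomp != 1L) stop("only 1-component SCALARS are supported")
        i <- i + 1L
        if (grepl("^LOOKUP_TABLE", toupper(trimws(lines[i])))) i <- i + 1L
        sc <- .vtk_scan(lines, i, n_pts)
        point_data[[nm]] <- sc$values
        i <- sc$next_line
      } else if (key == "VECTORS") {
        nm <- tok[2L]
        sc <- .vtk_scan(lines, i + 1L, 3L * n_pts)
        point_data[[nm]] <- matrix(sc$values, ncol = 3L, byrow = TRUE)
        i <- sc$next_line
      } else if (key %in% c("CELL_DATA", "FIELD")) {
        break
      } else {
        i <- i + 1L
      }
    }
  }
  list(points = points, polygons = polygons, point_data = point_data)
}

#' Write a VTK legacy ASCII polydata file
#'
#' @param points n x 3 matrix (mm).
#' @param triangles m x 3 integer matrix, 1-based.
#' @param point_data named list of scalar vectors or n x 3 matrices.
#' @param path output path.
#' @param title dataset title line.
#' @keywords internal
write_vtk_polydata <- function(points, triangles, point_data = list(),
                               path, title = "wssvar surface") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(points))), con)
  writeLines(apply(points, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = " ")), con)
  m <- nrow(triangles)
  writeLines(sprintf("POLYGONS %d %d", m, 4L * m), con)
  if (m > 0L)
    writeLines(paste(3L, triangles[, 1L] - 1L, triangles[, 2L] - 1L,
                     triangles[, 3L] - 1L), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(points)), con)
    for (nm in names(point_data)) {
      f <- point_data[[nm]]
      if (is.matrix(f)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(f, 1L, function(r)
          paste(formatC(r, digits = 17, format = "g"), collapse = " ")), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(formatC(f, digits = 17, format = "g"), con)
      }
    }
  }
  invisible(path)
}

#' Read a lumen surface mesh
#'
#' Reads a VTK legacy ASCII polydata surface, rescaling coordinates to mm
#' and optionally mirroring. Mirroring reverses triangle winding so outward
#' orientation is preserved.
#'
#' @param path VTK legacy polydata (ASCII) file with triangle cells.
#' @param scale_factor multiplicative factor applied to coordinates (e.g.
#'   1000 for a mesh stored in metres); must be > 0.
#' @param mirror_axis `NULL` (no mirroring) or 1/2/3, the axis to flip.
#' @param require_wss error if the per-vertex `"wss"` field (Pa) is absent.
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path, scale_factor = 1, mirror_axis = NULL,
                         require_wss = FALSE) {
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L,
            scale_factor > 0)
  raw <- read_vtk_polydata(path)
  sizes <- lengths(raw$polygons)
  if (any(sizes != 3L))
    stop(sprintf("unsupported cell: %d non-triangle polygon(s)",
                 sum(sizes != 3L)))
  tr <- do.call(rbind, raw$polygons)
  if (is.null(tr)) tr <- matrix(integer(0), ncol = 3L)
  if (require_wss && is.null(raw$point_data[["wss"]]))
    stop("required per-vertex field 'wss' is missing")
  mesh <- surface_mesh(raw$points * scale_factor, tr, raw$point_data)
  if (!is.null(mirror_axis)) mesh <- mirror_mesh(mesh, mirror_axis)
  mesh
}

#' Write a lumen surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path output path (VTK legacy ASCII polydata).
#' @param title dataset title line.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, title = "wssvar surface") {
  write_vtk_polydata(mesh$points, mesh$triangles, mesh$fields, path, title)
}
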