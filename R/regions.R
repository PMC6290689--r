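#' Region definitions for one submission
#'
#' The set of clipping planes and slice planes that delineate, for one
#' registered submission, the aneurysm sac, the parent-artery (MCA) band,
#' the transverse inflow slices and the outlet slices. The same region
#' definitions are applied to every team's co-registered surface for a given
#' case. Seeds are points known to lie inside the sac / on the parent band,
#' used to pick the right connected component after clipping.
#'
#' @param sac_planes list of [clip_plane()] isolating the sac (>= 1).
#' @param parent_band_planes list of [clip_plane()] delineating the MCA
#'   band (>= 1).
#' @param slice_planes list of 1 to 5 planes (`origin`, `normal`) for the
#'   transverse inflow slices.
#' @param outlet_slices named list of planes, one per outlet label.
#' @param dominant_outlet label of the dominant outflow branch; must be one
#'   of the outlet labels.
#' @param sac_seed,parent_seed 3-vectors (mm) inside the respective regions.
#' @return an object of class `region_set`.
#' @export
region_set <- function(sac_planes, parent_band_planes, slice_planes,
                       outlet_slices = list(), dominant_outlet = NULL,
                       sac_seed = NULL, parent_seed = NULL) {
  as_plane_list <- function(x) {
    if (inherits(x, "clip_plane")) x <- list(x)
    lapply(x, function(pl)
      if (inherits(pl, "clip_plane")) pl
      else clip_plane(pl$origin, pl$normal, if (is.null(pl$side)) 1 else pl$side))
  }
  sac_planes <- as_plane_list(sac_planes)
  parent_band_planes <- as_plane_list(parent_band_planes)
  if (length(sac_planes) < 1L) stop("at least one sac plane is required")
  if (length(parent_band_planes) < 1L)
    stop("at least one parent-band plane is required")
  if (length(slice_planes) < 1L || length(slice_planes) > 5L)
    stop("slice count must be between 1 and 5")
  slice_planes <- lapply(slice_planes, function(pl)
    list(origin = as.double(pl$origin),
         normal = as.double(pl$normal) / sqrt(sum(as.double(pl$normal)^2))))
  if (length(outlet_slices)) {
    if (is.null(names(outlet_slices)) || any(!nzchar(names(outlet_slices))))
      stop("outlet slices must be named by outlet label")
    if (is.null(dominant_outlet) ||
        !dominant_outlet %in% names(outlet_slices))
      stop("dominant_outlet must be one of the outlet labels")
    outlet_slices <- lapply(outlet_slices, function(pl)
      list(origin = as.double(pl$origin),
           normal = as.double(pl$normal) / sqrt(sum(as.double(pl$normal)^2))))
  }
  structure(list(sac_planes = sac_planes,
                 parent_band_planes = parent_band_planes,
                 slice_planes = slice_planes,
                 outlet_slices = outlet_slices,
                 dominant_outlet = dominant_outlet,
                 sac_seed = if (!is.null(sac_seed)) as.double(sac_seed),
                 parent_seed = if (!is.null(parent_seed)) as.double(parent_seed)),
            class = "region_set")
}

.plane_to_list <- function(pl) {
  out <- list(origin = as.numeric(pl$origin), normal = as.numeric(pl$normal))
  if (!is.null(pl$side)) out$side <- as.numeric(pl$side)
  out
}

#' Write a region set to YAML
#'
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_set <- function(regions, path) {
  obj <- list(
    sac_planes = lapply(regions$sac_planes, .plane_to_list),
    parent_band_planes = lapply(regions$parent_band_planes, .plane_to_list),
    slice_planes = lapply(regions$slice_planes, .plane_to_list),
    outlet_slices = lapply(regions$outlet_slices, .plane_to_list),
    dominant_outlet = regions$dominant_outlet,
    sac_seed = as.numeric(regions$sac_seed),
    parent_seed = as.numeric(regions$parent_seed))
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' Read a region set from YAML
#'
#' @param path YAML file written by [write_region_set()].
#' @return a [region_set()].
#' @export
read_region_set <- function(path) {
  obj <- yaml::read_yaml(path)
  region_set(
    sac_planes = obj$sac_planes,
    parent_band_planes = obj$parent_band_planes,
    slice_planes = obj$slice_planes,
    outlet_slices = obj$outlet_slices,
    dominant_outlet = obj$dominant_outlet,
    sac_seed = obj$sac_seed,
    parent_seed = obj$parent_seed)
}

#' Team metadata record
#'
#' The questionnaire-derived characteristics used for stratified statistics:
#' self-assessed experience (high: > 100 aneurysm cases; medium: 11-100;
#' low: 10 or fewer), temporal scheme, inlet location, the inflow scaling
#' exponent n of the power law Q ~ D^n (or `"other"`), and blood properties.
#'
#' @param team_id team identifier string.
#' @param experience `"high"`, `"medium"` or `"low"`.
#' @param temporal_scheme `"steady"` or `"pulsatile"`.
#' @param inlet_location `"MCA"` or `"ICA"`.
#' @param inflow_scaling_exponent integer 0-3 or `"other"`.
#' @param viscosity dynamic viscosity in cP.
#' @param density density in g/cm^3.
#' @return an object of class `team_meta`.
#' @export
team_meta <- function(team_id, experience = c("high", "medium", "low"),
                      temporal_scheme = c("steady", "pulsatile"),
                      inlet_location = c("MCA", "ICA"),
                      inflow_scaling_exponent = 2,
                      viscosity = 3.7, density = 1.06) {
  experience <- match.arg(experience)
  temporal_scheme <- match.arg(temporal_scheme)
  inlet_location <- match.arg(inlet_location)
  if (!identical(inflow_scaling_exponent, "other")) {
    inflow_scaling_exponent <- as.numeric(inflow_scaling_exponent)
    stopifnot(is.finite(inflow_scaling_exponent))
  }
  structure(list(team_id = as.character(team_id), experience = experience,
                 temporal_scheme = temporal_scheme,
                 inlet_location = inlet_location,
                 inflow_scaling_exponent = inflow_scaling_exponent,
                 viscosity = viscosity, density = density),
            class = "team_meta")
}
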