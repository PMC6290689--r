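#' Blood properties
#'
#' @param density blood density in g/cm^3. Values outside (0.9, 1.2) trigger
#'   a warning (overridable sanity bound).
#' @param viscosity dynamic viscosity in cP. Values outside (1, 10) trigger
#'   a warning.
#' @return an object of class `blood_properties`.
#' @export
blood_properties <- function(density = 1.06, viscosity = 3.7) {
  stopifnot(density > 0, viscosity > 0)
  if (density <= 0.9 || density >= 1.2)
    warning(sprintf("density %.3g g/cm^3 outside the usual (0.9, 1.2) range",
                    density))
  if (viscosity <= 1 || viscosity >= 10)
    warning(sprintf("viscosity %.3g cP outside the usual (1, 10) range",
                    viscosity))
  structure(list(density = density, viscosity = viscosity),
            class = "blood_properties")
}

#' Reynolds number
#'
#' `Re = rho * V * D / mu` evaluated in SI units from the pipeline's working
#' units: velocity in cm/s, diameter in mm, density in g/cm^3, viscosity in
#' cP. The exact conversion collapses to `Re = 10 * V * D * rho / mu`.
#'
#' @param velocity mean velocity in cm/s.
#' @param diameter vessel diameter in mm.
#' @param props a [blood_properties()].
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(velocity, diameter, props) {
  stopifnot(velocity >= 0, diameter > 0)
  10 * velocity * diameter * props$density / props$viscosity
}

#' Poiseuille wall shear stress
#'
#' WSS of fully developed laminar flow in a straight circular tube,
#' `tau = 32 * mu * Q / (pi * D^3)`. With viscosity in cP, flow in mL/s and
#' diameter in mm, the SI conversion factors cancel exactly, so the formula
#' is evaluated directly in working units and returns Pa.
#'
#' @param viscosity dynamic viscosity in cP.
#' @param flow flow rate in mL/s.
#' @param diameter diameter in mm.
#' @return wall shear stress in Pa.
#' @export
poiseuille_wss <- function(viscosity, flow, diameter) {
  stopifnot(viscosity > 0, flow >= 0, diameter > 0)
  32 * viscosity * flow / (pi * diameter^3)
}

#' Calculated parent-artery WSS
#'
#' Area-weighted (vertex-lumped) mean of the WSS magnitude over the clipped
#' parent-artery (MCA) band, i.e. a circumferential and longitudinal average
#' of the submitted CFD field over a consistent segment.
#'
#' @param band a [surface_mesh()] carrying the `"wss"` field, the clipped
#'   parent-artery band.
#' @return mean WSS in Pa.
#' @export
parent_calculated_wss <- function(band) {
  if (nrow(band$triangles) < 1L) stop("parent band has no triangles")
  field_area_mean(band, "wss")
}

#' Aneurysm-sac WSS metrics
#'
#' Computes the standard trio of sac parameters and their parent-normalized
#' variants from an isolated sac surface:
#' \itemize{
#'   \item AWSS: area-weighted mean WSS magnitude (Pa);
#'   \item MWSS: maximum vertex WSS magnitude (Pa), no percentile capping;
#'   \item LSA: fraction of sac area with WSS below `tau_low` (default
#'     0.4 Pa), measured on exactly split sub-triangles at the threshold
#'     isocontour;
#'   \item AWSS* = AWSS / parent WSS, MWSS* = MWSS / parent WSS;
#'   \item LSA*: as LSA but with the relative threshold
#'     `kappa * parent_wss` (default `kappa` = 0.1).
#' }
#'
#' @param sac a [surface_mesh()] with a `"wss"` field.
#' @param parent_wss parent-artery mean WSS in Pa (> 0).
#' @param tau_low absolute low-shear threshold in Pa.
#' @param kappa relative low-shear threshold as a fraction of `parent_wss`.
#' @param lsa_method `"exact"` (isocontour splitting, default) or
#'   `"lumped"` (vertex-lumped cross-check).
#' @return list with `awss`, `mwss`, `lsa`, `awss_star`, `mwss_star`,
#'   `lsa_star`, plus the thresholds used.
#' @export
sac_metrics <- function(sac, parent_wss, tau_low = 0.4, kappa = 0.1,
                        lsa_method = c("exact", "lumped")) {
  lsa_method <- match.arg(lsa_method)
  if (!is.finite(parent_wss) || parent_wss <= 0)
    stop("parent_wss must be positive for normalization")
  if (is.null(sac$fields[["wss"]])) stop("sac mesh has no 'wss' field")
  if (nrow(sac$triangles) < 1L) stop("sac mesh is empty")
  total <- surface_area(sac)
  awss <- field_area_mean(sac, "wss")
  mwss <- max(sac$fields[["wss"]])
  lsa <- area_below_threshold(sac, tau_low, "wss", method = lsa_method) / total
  lsa_star <- area_below_threshold(sac, kappa * parent_wss, "wss",
                                   method = lsa_method) / total
  list(awss = awss, mwss = mwss, lsa = lsa,
       awss_star = awss / parent_wss,
       mwss_star = mwss / parent_wss,
       lsa_star = lsa_star,
       tau_low = tau_low, kappa = kappa)
}

#' Outflow division
#'
#' Fraction of the total outlet flow carried by the dominant daughter branch.
#'
#' @param outlet_flows named numeric vector of outlet flow rates (mL/s),
#'   all nonnegative, at least two outlets, positive total.
#' @param dominant label of the dominant outlet.
#' @return fraction in \[0, 1\].
#' @export
outflow_division <- function(outlet_flows, dominant) {
  if (length(outlet_flows) < 2L) stop("at least two outlets are required")
  if (any(outlet_flows < 0)) stop("outlet flows must be nonnegative")
  tot <- sum(outlet_flows)
  if (tot <= 0) stop("total outlet flow must be positive")
  if (!dominant %in% names(outlet_flows))
    stop(sprintf("dominant outlet '%s' is not among the outlet labels",
                 dominant))
  unname(outlet_flows[[dominant]] / tot)
}

#' Compute all hemodynamic parameters for one submission
#'
#' Orchestrates the per-(team, case) analysis: transverse slices through the
#' parent artery give area, mean velocity, effective diameter and flow rate
#' (averaged over the slices); from these, Reynolds number and Poiseuille WSS
#' follow. The parent band clipped from the WSS field gives the calculated
#' parent WSS and the WSS ratio; outlet patches give the outflow division;
#' and the clipped sac gives AWSS/MWSS/LSA and their normalized variants.
#' Steady and time-averaged pulsatile WSS fields are treated identically.
#' If the sac region is absent the sac metrics are returned as `NA` while
#' the parent metrics are still produced.
#'
#' @param mesh a [surface_mesh()] with a `"wss"` field.
#' @param sections list of [cross_section()] patches matching
#'   `regions$slice_planes` (one per slice, same order).
#' @param regions a [region_set()].
#' @param props a [blood_properties()].
#' @param outlet_patches named list of [cross_section()] patches, one per
#'   outlet label in `regions$outlet_slices`.
#' @param tau_low,kappa low-shear thresholds passed to [sac_metrics()].
#' @return list with elements `parent` (diameter, flow_rate, velocity,
#'   reynolds, poiseuille_wss, calculated_wss, wss_ratio, flow_division) and
#'   `sac` (see [sac_metrics()]; `NA` values when the sac region is missing).
#' @export
compute_submission <- function(mesh, sections, regions, props,
                               outlet_patches = NULL,
                               tau_low = 0.4, kappa = 0.1) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n_slices <- length(regions$slice_planes)
  if (length(sections) != n_slices)
    stop("one cross-section patch per slice plane is required")

  slices <- vector("list", n_slices)
  for (k in seq_len(n_slices)) {
    geom <- plane_section(mesh, regions$slice_planes[[k]])
    vel <- mean_velocity(sections[[k]])
    slices[[k]] <- list(geometry = geom, velocity = vel)
  }
  avg <- multi_slice_average(slices)

  re <- reynolds(avg$velocity, avg$diameter, props)
  tau_p <- poiseuille_wss(props$viscosity, avg$flow_rate, avg$diameter)

  band <- clip_by_planes(mesh, regions$parent_band_planes,
                         seed = regions$parent_seed)
  tau_c <- parent_calculated_wss(band)

  division <- NA_real_
  if (!is.null(outlet_patches) && length(regions$outlet_slices)) {
    flows <- vapply(names(regions$outlet_slices), function(lbl) {
      patch <- outlet_patches[[lbl]]
      if (is.null(patch)) return(NA_real_)
      flow_rate(patch_area(patch), mean_velocity(patch))
    }, numeric(1L))
    if (!anyNA(flows))
      division <- outflow_division(flows, regions$dominant_outlet)
  }

  sac <- NULL
  sacm <- list(awss = NA_real_, mwss = NA_real_, lsa = NA_real_,
               awss_star = NA_real_, mwss_star = NA_real_,
               lsa_star = NA_real_, tau_low = tau_low, kappa = kappa)
  if (length(regions$sac_planes)) {
    sac <- tryCatch(
      clip_by_planes(mesh, regions$sac_planes, seed = regions$sac_seed),
      error = function(e) NULL)
    if (!is.null(sac))
      sacm <- sac_metrics(sac, tau_c, tau_low = tau_low, kappa = kappa)
  }

  list(parent = list(diameter = avg$diameter,
                     flow_rate = avg$flow_rate,
                     velocity = avg$velocity,
                     reynolds = re,
                     poiseuille_wss = tau_p,
                     calculated_wss = tau_c,
                     wss_ratio = tau_c / tau_p,
                     flow_division = division),
       sac = sacm)
}
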