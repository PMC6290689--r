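#' @name synthetic_cohort
#' @title Synthetic virtual-challenge cohort with closed-form ground truth
#'
#' @description
#' A virtual multi-team challenge: an idealized reference geometry (straight
#' parent tube, spherical aneurysm sac, two daughter branches) whose every
#' hemodynamic parameter has a closed form, plus a perturbation model that
#' emulates the documented inter-team variation (segmentation-driven
#' diameter scatter, inflow scaling laws Q ~ D^n, viscosity and density
#' menus, WSS-profile shape scatter). The closed forms make the whole mesh
#' pipeline testable without any external data.
#'
#' The sac WSS profile is an axisymmetric linear function of the cosine of
#' the polar angle from the dome apex: with u = cos(theta) and the neck at
#' u = u_n, `wss(u) = tau_c * (a_f + (n_f - a_f) * (1 - u)/(1 - u_n))`,
#' where `tau_c` is the parent WSS, `a_f` the apex fraction and `n_f` the
#' neck fraction. Because the spherical area element is uniform in u, the
#' closed forms are elementary: sac area `2 pi a^2 (1 - u_n)`,
#' `AWSS = tau_c (a_f + n_f)/2`, `MWSS = tau_c n_f`, and
#' `LSA(tau) = clamp(((tau/tau_c) - a_f)/(n_f - a_f), 0, 1)`.
NULL

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.unit <- function(v) v / sqrt(sum(v^2))

# open cylindrical tube from p0 along dir
.tube_mesh <- function(p0, dir, len, radius, n_theta, n_axial) {
  dir <- .unit(dir)
  ref <- if (abs(dir[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(ref - sum(ref * dir) * dir)
  e2 <- .cross3(dir, e1)
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  circ <- radius * (outer(cos(th), e1) + outer(sin(th), e2))
  ts <- seq(0, len, length.out = n_axial + 1L)
  pts <- do.call(rbind, lapply(ts, function(t)
    sweep(circ, 2L, p0 + t * dir, "+")))
  j <- seq_len(n_theta)
  j2 <- c(j[-1L], 1L)
  tris <- do.call(rbind, lapply(seq_len(n_axial), function(k) {
    a <- (k - 1L) * n_theta + j
    b <- (k - 1L) * n_theta + j2
    cc <- k * n_theta + j2
    d <- k * n_theta + j
    rbind(cbind(a, b, cc), cbind(a, cc, d))
  }))
  list(points = pts, triangles = tris)
}

# UV sphere; returns points/triangles plus the per-vertex u = cos(polar angle)
.sphere_mesh <- function(center, radius, n_theta, n_phi) {
  phi <- pi * seq_len(n_phi - 1L) / n_phi
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  rows <- lapply(phi, function(ph)
    cbind(radius * sin(ph) * cos(th),
          radius * sin(ph) * sin(th),
          radius * cos(ph)))
  pts <- rbind(c(0, 0, radius), do.call(rbind, rows), c(0, 0, -radius))
  pts <- sweep(pts, 2L, center, "+")
  np <- nrow(pts)
  j <- seq_len(n_theta)
  j2 <- c(j[-1L], 1L)
  row_start <- function(i) 1L + (i - 1L) * n_theta  # offset of ring i (1-based rings)
  tris <- list()
  tris[[1L]] <- cbind(1L, 1L + j, 1L + j2)                    # north fan
  for (i in seq_len(n_phi - 2L)) {
    a <- 1L + (i - 1L) * n_theta + j
    b <- 1L + (i - 1L) * n_theta + j2
    cc <- 1L + i * n_theta + j2
    d <- 1L + i * n_theta + j
    tris[[length(tris) + 1L]] <- rbind(cbind(a, cc, b), cbind(a, d, cc))
  }
  last <- 1L + (n_phi - 2L) * n_theta
  tris[[length(tris) + 1L]] <- cbind(np, last + j2, last + j)  # south fan
  list(points = pts, triangles = do.call(rbind, tris))
}

# planar disc patch; returns points/triangles plus per-vertex radial distance
.disc_mesh <- function(center, normal, radius, n_r, n_theta) {
  normal <- .unit(normal)
  ref <- if (abs(normal[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .unit(ref - sum(ref * normal) * normal)
  e2 <- .cross3(normal, e1)
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  pts <- matrix(center, nrow = 1L)
  rho <- 0
  for (k in seq_len(n_r)) {
    r <- radius * k / n_r
    ring <- sweep(r * (outer(cos(th), e1) + outer(sin(th), e2)), 2L, center, "+")
    pts <- rbind(pts, ring)
    rho <- c(rho, rep(r, n_theta))
  }
  j <- seq_len(n_theta)
  j2 <- c(j[-1L], 1L)
  tris <- list(cbind(1L, 1L + j, 1L + j2))
  for (k in seq_len(n_r - 1L)) {
    a <- 1L + (k - 1L) * n_theta + j
    b <- 1L + (k - 1L) * n_theta + j2
    cc <- 1L + k * n_theta + j2
    d <- 1L + k * n_theta + j
    tris[[length(tris) + 1L]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  }
  list(points = pts, triangles = do.call(rbind, tris),
       rho = rho, normal = normal)
}

.merge_meshes <- function(parts) {
  offs <- cumsum(c(0L, vapply(parts, function(p) nrow(p$points), integer(1L))))
  pts <- do.call(rbind, lapply(parts, `[[`, "points"))
  tris <- do.call(rbind, lapply(seq_along(parts), function(i)
    parts[[i]]$triangles + offs[i]))
  list(points = pts, triangles = tris, offsets = offs)
}

#' Reference virtual-case description
#'
#' Parameters of one idealized middle-cerebral-artery bifurcation aneurysm:
#' a straight parent tube (diameter ~ 2.45 mm, the cohort median), a
#' spherical sac of ~ 8 mm diameter, two daughter branches whose cubed
#' diameters give the outflow split, and an analytic sac WSS profile (see
#' [synthetic_cohort]). All dimensions in mm, flow in mL/s.
#'
#' @param parent_diameter parent-artery diameter D0 (mm).
#' @param parent_length parent tube length (mm).
#' @param sac_diameter sac (sphere) diameter (mm).
#' @param sac_center_height height of the sphere centre above the tube axis
#'   (mm).
#' @param sac_neck_cos cosine of the polar angle of the neck plane, u_n.
#' @param sac_apex_frac,sac_neck_frac sac WSS at apex / neck as fractions of
#'   the parent WSS.
#' @param branch_diameters two daughter-branch diameters (mm); the outflow
#'   split follows their cubes (Murray's law).
#' @param branch_length daughter branch length (mm).
#' @param flow parent flow rate Q0 (mL/s).
#' @param viscosity,density blood properties (cP, g/cm^3).
#' @param wss_shape_factor ratio of the tube's WSS field to the Poiseuille
#'   value (1 = fully developed flow; ~ 1.5 emulates the non-developed
#'   profiles seen in real parent arteries).
#' @param n_slices number of transverse inflow slices (1-5).
#' @param resolution mesh resolution multiplier (1 = default density).
#' @return a list of class `reference_case`.
#' @export
reference_case <- function(parent_diameter = 2.45,
                           parent_length = 12,
                           sac_diameter = 8,
                           sac_center_height = 2.0,
                           sac_neck_cos = 0.5,
                           sac_apex_frac = 0.01,
                           sac_neck_frac = 1.11,
                           branch_diameters = c(2.1, 1.7),
                           branch_length = 6,
                           flow = 2.43,
                           viscosity = 3.7,
                           density = 1.06,
                           wss_shape_factor = 1,
                           n_slices = 5,
                           resolution = 1) {
  stopifnot(parent_diameter > 0, parent_length > 0, sac_diameter > 0,
            length(branch_diameters) == 2L, all(branch_diameters > 0),
            flow > 0, viscosity > 0, density > 0, wss_shape_factor > 0,
            sac_neck_cos > 0, sac_neck_cos < 1,
            sac_neck_frac > sac_apex_frac, sac_apex_frac >= 0,
            n_slices >= 1, n_slices <= 5)
  structure(as.list(environment()), class = "reference_case")
}

# uniformly rescale all linear dimensions of a case (segmentation-error model)
.scale_case <- function(case, eps) {
  for (nm in c("parent_diameter", "parent_length", "sac_diameter",
               "sac_center_height", "branch_diameters", "branch_length"))
    case[[nm]] <- case[[nm]] * eps
  case
}

#' Closed-form hemodynamic parameters of a virtual case
#'
#' Evaluates every pipeline output analytically from the case description —
#' no mesh involved — for use as the independent oracle.
#'
#' @param case a [reference_case()].
#' @param tau_low,kappa low-shear thresholds (Pa; fraction of parent WSS).
#' @return list with the parent and sac parameters (same names as
#'   [compute_submission()] output).
#' @export
oracle_metrics <- function(case, tau_low = 0.4, kappa = 0.1) {
  D <- case$parent_diameter
  A <- pi * D^2 / 4
  Q <- case$flow
  V <- 100 * Q / A
  tau_p <- poiseuille_wss(case$viscosity, Q, D)
  tau_c <- case$wss_shape_factor * tau_p
  d3 <- case$branch_diameters^3
  split <- max(d3) / sum(d3)
  af <- case$sac_apex_frac
  nf <- case$sac_neck_frac
  lsa_at <- function(tau_frac)
    min(max((tau_frac - af) / (nf - af), 0), 1)
  list(parent = list(
         diameter = D, flow_rate = Q, velocity = V,
         reynolds = 10 * V * D * case$density / case$viscosity,
         poiseuille_wss = tau_p, calculated_wss = tau_c,
         wss_ratio = case$wss_shape_factor, flow_division = split),
       sac = list(
         awss = tau_c * (af + nf) / 2,
         mwss = tau_c * nf,
         lsa = lsa_at(tau_low / tau_c),
         awss_star = (af + nf) / 2,
         mwss_star = nf,
         lsa_star = lsa_at(kappa),
         area = 2 * pi * (case$sac_diameter / 2)^2 * (1 - case$sac_neck_cos),
         tau_low = tau_low, kappa = kappa))
}

#' Build the virtual submission for a case
#'
#' Generates the triangulated surface (parent tube along the x axis ending
#' at the origin, spherical sac above it, two daughter branches fanning
#' downstream), the per-vertex WSS field (`wss_shape_factor` times the
#' Poiseuille WSS on the vessels; the analytic polar profile on the sac),
#' the transverse-slice and outlet cross-section patches carrying the
#' parabolic velocity profile `v(rho) = 2 V (1 - (2 rho / D)^2)`, the region
#' definitions, and the closed-form ground-truth record.
#'
#' The tube, sac and branch surfaces are separate connected components that
#' overlap at the junctions rather than being stitched watertight: every
#' region the pipeline analyses (sac cap, parent band, slices) is delineated
#' by planes away from the junctions and selected per connected component,
#' so the junction geometry never enters any metric and each region keeps
#' its closed form.
#'
#' @param case a [reference_case()].
#' @param velocity_as_magnitude emit the slice patches with speed magnitudes
#'   instead of vectors (emulating magnitude-only submissions).
#' @return an object of class `virtual_submission`: list with `mesh`,
#'   `sections`, `outlet_patches`, `regions`, `case`, `truth`.
#' @export
make_reference <- function(case = reference_case(),
                           velocity_as_magnitude = FALSE) {
  res <- case$resolution
  R0 <- case$parent_diameter / 2
  a <- case$sac_diameter / 2
  cz <- case$sac_center_height
  z_neck <- cz + a * case$sac_neck_cos
  if (z_neck <= R0)
    stop("sac/tube intersection failure: neck plane cuts the parent tube")

  n_theta <- max(16L, as.integer(round(64 * res)))
  L <- case$parent_length
  n_ax <- max(8L, as.integer(ceiling(4 * L * res)))
  n_phi <- max(12L, as.integer(round(64 * res)))

  truth <- oracle_metrics(case)
  tau_c <- truth$parent$calculated_wss

  tube <- .tube_mesh(c(-L, 0, 0), c(1, 0, 0), L, R0, n_theta, n_ax)
  sac_center <- c(0, 0, cz)
  sph <- .sphere_mesh(sac_center, a, n_theta, n_phi)

  ang <- 40 * pi / 180
  dirs <- list(c(cos(ang), sin(ang), 0), c(cos(ang), -sin(ang), 0))
  rb <- case$branch_diameters / 2
  n_axb <- max(4L, as.integer(ceiling(4 * case$branch_length * res)))
  br <- lapply(1:2, function(i)
    .tube_mesh(c(0, 0, 0), dirs[[i]], case$branch_length, rb[i],
               n_theta, n_axb))

  merged <- .merge_meshes(c(list(tube, sph), br))

  # WSS field: shape-factor * Poiseuille on the vessels, polar profile on sac
  d3 <- case$branch_diameters^3
  qb <- case$flow * d3 / sum(d3)
  tau_br <- case$wss_shape_factor *
    poiseuille_wss(case$viscosity, qb, case$branch_diameters)
  wss <- numeric(nrow(merged$points))
  n_tube <- nrow(tube$points)
  n_sph <- nrow(sph$points)
  wss[seq_len(n_tube)] <- tau_c
  u_sph <- (sph$points[, 3L] - cz) / a
  t_sph <- (1 - u_sph) / (1 - case$sac_neck_cos)
  af <- case$sac_apex_frac
  nf <- case$sac_neck_frac
  wss[n_tube + seq_len(n_sph)] <- tau_c * (af + (nf - af) * t_sph)
  off <- n_tube + n_sph
  for (i in 1:2) {
    nb <- nrow(br[[i]]$points)
    wss[off + seq_len(nb)] <- tau_br[i]
    off <- off + nb
  }
  mesh <- surface_mesh(merged$points, merged$triangles, list(wss = wss))

  # transverse inflow slices through the parent segment
  slice_fracs <- if (case$n_slices == 1L) 0.75 else
    seq(0.75, 0.45, length.out = case$n_slices)
  slice_xs <- -slice_fracs * L
  A <- pi * R0^2
  vbar <- 100 * case$flow / A  # cm/s
  n_r <- max(8L, as.integer(round(20 * res)))
  make_slice <- function(x0, radius, vmean, direction) {
    d <- .disc_mesh(c(x0, 0, 0), direction, radius, n_r, n_theta)
    v_axial <- 2 * vmean * (1 - (d$rho / radius)^2)
    if (velocity_as_magnitude)
      cross_section(d$points, d$triangles,
                    velocity_magnitude = abs(v_axial), normal = d$normal)
    else
      cross_section(d$points, d$triangles,
                    velocity = outer(v_axial, direction), normal = d$normal)
  }
  sections <- lapply(slice_xs, make_slice, radius = R0, vmean = vbar,
                     direction = c(1, 0, 0))

  # outlet patches near the branch ends
  vb <- 100 * qb / (pi * rb^2)
  outlet_patches <- list()
  outlet_slices <- list()
  for (i in 1:2) {
    ctr <- dirs[[i]] * 0.8 * case$branch_length
    d <- .disc_mesh(ctr, dirs[[i]], rb[i], n_r, n_theta)
    v_axial <- 2 * vb[i] * (1 - (d$rho / rb[i])^2)
    lbl <- paste0("branch", i)
    outlet_patches[[lbl]] <- cross_section(
      d$points, d$triangles, velocity = outer(v_axial, dirs[[i]]),
      normal = d$normal)
    outlet_slices[[lbl]] <- list(origin = ctr, normal = dirs[[i]])
  }
  dominant <- paste0("branch", which.max(d3))

  band_lo <- -0.375 * L
  band_hi <- -0.208 * L
  regions <- region_set(
    sac_planes = list(clip_plane(c(0, 0, z_neck), c(0, 0, 1), side = 1)),
    parent_band_planes = list(
      clip_plane(c(band_lo, 0, 0), c(1, 0, 0), side = 1),
      clip_plane(c(band_hi, 0, 0), c(1, 0, 0), side = -1)),
    slice_planes = lapply(slice_xs, function(x0)
      list(origin = c(x0, 0, 0), normal = c(1, 0, 0))),
    outlet_slices = outlet_slices,
    dominant_outlet = dominant,
    sac_seed = c(0, 0, cz + a),
    parent_seed = c((band_lo + band_hi) / 2, 0, -R0))

  structure(list(mesh = mesh, sections = sections,
                 outlet_patches = outlet_patches, regions = regions,
                 case = case, truth = truth),
            class = "virtual_submission")
}

#' @export
print.virtual_submission <- function(x, ...) {
  cat(sprintf(
    "virtual_submission: D %.3g mm, Q %.3g mL/s, mu %.3g cP, %d triangles\n",
    x$case$parent_diameter, x$case$flow, x$case$viscosity,
    nrow(x$mesh$triangles)))
  invisible(x)
}

#' Perturbation model for the virtual cohort
#'
#' The menus and scatter magnitudes that emulate the documented inter-team
#' variation: a lognormal per-dataset diameter scale (segmentation error),
#' the inflow scaling-law menu Q ~ D^n with n in \{0, 1, 2, 3, other\} at the
#' challenge's observed frequencies (6, 2, 10, 4, 4 of 26), the viscosity
#' menu \{3.5, 3.7, 4.0\} cP at frequencies \{12, 2, 12\}, the density menu
#' (typical 1.05-1.06 g/cm^3 for 22 of 26, otherwise 1.0-1.05), experience
#' levels (5 high / 13 medium / 8 low), and a lognormal WSS-profile shape
#' factor capturing non-developed parent velocity profiles.
#'
#' @param sigma_d lognormal sdlog of the per-dataset diameter scale.
#' @param scaling_exponents named probabilities for n in
#'   `c("0","1","2","3","other")`; `"other"` draws a continuous exponent
#'   uniformly on \[0, 3\].
#' @param viscosities named probabilities for the viscosity menu (names are
#'   the cP values).
#' @param p_density_typical probability of the typical density.
#' @param density_typical typical density value (g/cm^3).
#' @param density_other_range range of the atypical densities.
#' @param experience named probabilities for experience levels.
#' @param temporal named probabilities for steady/pulsatile labelling.
#' @param inlet named probabilities for MCA/ICA inlet labelling.
#' @param wss_ratio_median,wss_ratio_sdlog lognormal parameters of the
#'   calculated:Poiseuille WSS shape factor (median 1.5 emulates the
#'   non-developed profiles observed in parent arteries; set median 1 and
#'   sdlog 0 for an ideal fully developed cohort).
#' @return a list of class `perturbation_config`.
#' @export
perturbation_config <- function(
    sigma_d = 0.034,
    scaling_exponents = c(`0` = 6, `1` = 2, `2` = 10, `3` = 4, other = 4) / 26,
    viscosities = c(`3.5` = 12, `3.7` = 2, `4.0` = 12) / 26,
    p_density_typical = 22 / 26,
    density_typical = 1.055,
    density_other_range = c(1.00, 1.05),
    experience = c(high = 5, medium = 13, low = 8) / 26,
    temporal = c(steady = 15, pulsatile = 11) / 26,
    inlet = c(MCA = 17, ICA = 9) / 26,
    wss_ratio_median = 1.5,
    wss_ratio_sdlog = 0.16) {
  stopifnot(sigma_d >= 0, wss_ratio_sdlog >= 0, wss_ratio_median > 0,
            abs(sum(scaling_exponents) - 1) < 1e-9,
            abs(sum(viscosities) - 1) < 1e-9,
            abs(sum(experience) - 1) < 1e-9,
            p_density_typical >= 0, p_density_typical <= 1)
  structure(as.list(environment()), class = "perturbation_config")
}

# draw one team's strategy (menus held fixed across that team's cases)
.draw_team <- function(pert) {
  n_lab <- sample(names(pert$scaling_exponents), 1L,
                  prob = pert$scaling_exponents)
  exponent <- if (n_lab == "other") stats::runif(1L, 0, 3) else as.numeric(n_lab)
  list(
    exponent_label = n_lab,
    exponent = exponent,
    viscosity = as.numeric(sample(names(pert$viscosities), 1L,
                                  prob = pert$viscosities)),
    density = if (stats::runif(1L) < pert$p_density_typical)
      pert$density_typical
    else stats::runif(1L, pert$density_other_range[1L],
                      pert$density_other_range[2L]),
    experience = sample(names(pert$experience), 1L, prob = pert$experience),
    temporal = sample(names(pert$temporal), 1L, prob = pert$temporal),
    inlet = sample(names(pert$inlet), 1L, prob = pert$inlet),
    wss_shape = stats::rlnorm(1L, meanlog = log(pert$wss_ratio_median),
                              sdlog = pert$wss_ratio_sdlog))
}

#' Sample a virtual challenge cohort
#'
#' Draws per-team strategies (scaling law, viscosity, density, WSS shape
#' factor, experience labels) and per-dataset-per-case diameter factors
#' `eps ~ lognormal(0, sigma_d)`, then builds every virtual submission with
#' its own consistently regenerated geometry, flow and fields. A team with
#' scaling law n assigns the flow `Q = Q_ref * (D / D_ref)^n` to the case it
#' segmented with parent diameter `D` (so n = 0 is "same flow rate", n = 2
#' "same velocity", n = 3 "same WSS"). Optionally, some teams contribute two
#' datasets from independent diameter draws (paired a/b submissions sharing
#' one strategy), mirroring repeat-segmentation submissions. Fully
#' reproducible for a given seed.
#'
#' @param cases named list of [reference_case()] objects (default
#'   [make_case_set()]).
#' @param pert a [perturbation_config()].
#' @param n_teams number of teams (>= 3).
#' @param paired_teams integer indices of teams contributing two datasets.
#' @param seed integer RNG seed.
#' @param resolution mesh resolution multiplier applied to every case.
#' @param flow_ref,diameter_ref anchors of the scaling law (mL/s, mm).
#' @param build_meshes if `FALSE`, skip geometry construction and return
#'   only metadata and closed-form truth records (fast; used for large
#'   parameter-recovery studies).
#' @return list of class `virtual_cohort`: `datasets` (each with
#'   `dataset_id`, `team_id`, `meta`, `submissions` — one per case, or
#'   `truths` when `build_meshes = FALSE`), `cases`, `pert`, `seed`.
#' @export
sample_cohort <- function(cases = make_case_set(), pert = perturbation_config(),
                          n_teams = 26, paired_teams = c(19, 26),
                          seed = 1, resolution = 1,
                          flow_ref = 2.43, diameter_ref = 2.45,
                          build_meshes = TRUE) {
  seed <- as.integer(seed)  # force now, before the RNG state is captured
  stopifnot(n_teams >= 3)
  if (is.null(names(cases)))
    names(cases) <- paste0("case", seq_along(cases))
  paired_teams <- paired_teams[paired_teams <= n_teams]
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  datasets <- list()
  for (ti in seq_len(n_teams)) {
    strat <- .draw_team(pert)
    reps <- if (ti %in% paired_teams) c("a", "b") else ""
    for (rep_tag in reps) {
      dataset_id <- sprintf("T%02d%s", ti, rep_tag)
      meta <- team_meta(
        team_id = sprintf("T%02d", ti),
        experience = strat$experience,
        temporal_scheme = strat$temporal,
        inlet_location = strat$inlet,
        inflow_scaling_exponent = if (strat$exponent_label == "other")
          "other" else strat$exponent,
        viscosity = strat$viscosity, density = strat$density)
      subs <- list()
      truths <- list()
      for (cs in names(cases)) {
        eps <- stats::rlnorm(1L, meanlog = 0, sdlog = pert$sigma_d)
        ccase <- .scale_case(cases[[cs]], eps)
        ccase$resolution <- cases[[cs]]$resolution * resolution
        ccase$viscosity <- strat$viscosity
        ccase$density <- strat$density
        ccase$wss_shape_factor <- strat$wss_shape
        ccase$flow <- flow_ref *
          (ccase$parent_diameter / diameter_ref)^strat$exponent
        truths[[cs]] <- c(oracle_metrics(ccase), list(eps = eps))
        if (build_meshes) {
          sub <- make_reference(ccase)
          sub$dataset_id <- dataset_id
          sub$case_id <- cs
          subs[[cs]] <- sub
        }
      }
      datasets[[dataset_id]] <- list(dataset_id = dataset_id,
                                     team_id = sprintf("T%02d", ti),
                                     meta = meta,
                                     strategy = strat,
                                     truths = truths,
                                     submissions = if (build_meshes) subs)
    }
  }
  structure(list(datasets = datasets, cases = cases, pert = pert,
                 seed = seed), class = "virtual_cohort")
}

#' Default set of five virtual aneurysm cases
#'
#' Five idealized bifurcation-aneurysm cases of similar (~ 8 mm) sac size
#' but distinct parent diameters, outflow splits and sac WSS profiles, so
#' that case rank-orderings are nontrivial. One case uses a single inflow
#' slice (the others five), mirroring a case whose short parent segment
#' admits only one slice.
#'
#' @param resolution mesh resolution multiplier stored on each case.
#' @return named list of [reference_case()] objects.
#' @export
make_case_set <- function(resolution = 1) {
  list(
    case1 = reference_case(parent_diameter = 2.55, sac_diameter = 8.4,
                           sac_apex_frac = 0.30, sac_neck_frac = 1.60,
                           branch_diameters = c(2.15, 1.75),
                           flow = 2.43, resolution = resolution),
    case2 = reference_case(parent_diameter = 2.45, sac_diameter = 8.0,
                           sac_apex_frac = 0.04, sac_neck_frac = 1.10,
                           branch_diameters = c(2.10, 1.70),
                           flow = 2.43, resolution = resolution),
    case3 = reference_case(parent_diameter = 2.50, sac_diameter = 8.2,
                           sac_apex_frac = 0.02, sac_neck_frac = 0.90,
                           branch_diameters = c(2.25, 1.55),
                           flow = 2.43, resolution = resolution),
    case4 = reference_case(parent_diameter = 2.30, sac_diameter = 7.6,
                           sac_apex_frac = 0.03, sac_neck_frac = 1.80,
                           branch_diameters = c(1.95, 1.80),
                           flow = 2.43, n_slices = 1, resolution = resolution),
    case5 = reference_case(parent_diameter = 2.40, sac_diameter = 8.1,
                           sac_apex_frac = 0.25, sac_neck_frac = 1.45,
                           branch_diameters = c(2.05, 1.70),
                           flow = 2.43, resolution = resolution))
}
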