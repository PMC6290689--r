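# Small programmatic fixtures shared across test files.

# open cylinder along +x starting at x0, using the package's generator
cylinder_fixture <- function(radius = 1.225, x0 = -10, len = 10,
                             n_theta = 64, n_axial = 40, wss = NULL) {
  tm <- wssvar:::.tube_mesh(c(x0, 0, 0), c(1, 0, 0), len, radius,
                            n_theta, n_axial)
  fields <- if (!is.null(wss)) list(wss = rep(wss, nrow(tm$points))) else list()
  surface_mesh(tm$points, tm$triangles, fields)
}

# asymmetric closed tetrahedron with outward winding
tetra_fixture <- function() {
  p <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(0, 0, 3))
  tr <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  surface_mesh(p, tr)
}

# flat disc cross-section with a chosen velocity profile
disc_patch_fixture <- function(radius = 1.225, center = c(0, 0, 0),
                               normal = c(1, 0, 0), n_r = 20, n_theta = 48,
                               profile = function(rho) rep(50, length(rho)),
                               magnitude_only = FALSE,
                               extra_inplane = NULL) {
  d <- wssvar:::.disc_mesh(center, normal, radius, n_r, n_theta)
  v <- profile(d$rho)
  if (magnitude_only)
    return(cross_section(d$points, d$triangles, velocity_magnitude = abs(v),
                         normal = d$normal))
  vel <- outer(v, d$normal)
  if (!is.null(extra_inplane)) vel <- vel + extra_inplane(d)
  cross_section(d$points, d$triangles, velocity = vel, normal = d$normal)
}

expected_parameter_names <- function() {
  c("diameter", "flow_rate", "velocity", "reynolds", "poiseuille_wss",
    "calculated_wss", "wss_ratio", "flow_division",
    "awss", "mwss", "lsa", "awss_star", "mwss_star", "lsa_star")
}

# relative error helper
relerr <- function(got, want) abs(got - want) / abs(want)
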