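test_that("closed-form sac metrics agree with numeric quadrature", {
  case <- reference_case(sac_apex_frac = 0.07, sac_neck_frac = 1.3,
                         sac_neck_cos = 0.4, wss_shape_factor = 1.4)
  tr <- oracle_metrics(case, tau_low = 0.4, kappa = 0.1)
  tau_c <- tr$parent$calculated_wss
  un <- case$sac_neck_cos
  a <- case$sac_diameter / 2
  prof <- function(u) tau_c * (case$sac_apex_frac +
    (case$sac_neck_frac - case$sac_apex_frac) * (1 - u) / (1 - un))
  # area element on the sphere is uniform in u = cos(theta)
  area <- 2 * pi * a^2 * (1 - un)
  awss_num <- stats::integrate(prof, un, 1, rel.tol = 1e-10)$value *
    2 * pi * a^2 / area
  expect_lt(relerr(tr$sac$awss, awss_num), 1e-9)
  expect_equal(tr$sac$mwss, prof(un))
  lsa_num <- stats::integrate(function(u) as.numeric(prof(u) < 0.4), un, 1,
                              subdivisions = 2000L,
                              rel.tol = 1e-8)$value / (1 - un)
  expect_lt(abs(tr$sac$lsa - lsa_num), 1e-6)
  expect_equal(tr$sac$area, area)
})

test_that("oracle metrics scale as expected with flow", {
  case <- reference_case()
  tr <- oracle_metrics(case)
  case2 <- case
  case2$flow <- 2 * case$flow
  tr2 <- oracle_metrics(case2)
  expect_equal(tr2$parent$poiseuille_wss, 2 * tr$parent$poiseuille_wss)
  expect_equal(tr2$sac$awss, 2 * tr$sac$awss)
  expect_equal(tr2$sac$awss_star, tr$sac$awss_star)
  expect_equal(tr2$sac$lsa_star, tr$sac$lsa_star)
})

test_that("the pipeline recovers the reference case within tolerance", {
  sub <- make_reference(reference_case(resolution = 0.6))
  props <- blood_properties(sub$case$density, sub$case$viscosity)
  r <- compute_submission(sub$mesh, sub$sections, sub$regions, props,
                          sub$outlet_patches)
  tr <- sub$truth
  expect_lt(relerr(r$parent$diameter, tr$parent$diameter), 0.005)
  expect_lt(relerr(r$parent$flow_rate, tr$parent$flow_rate), 0.01)
  expect_lt(relerr(r$parent$calculated_wss, tr$parent$calculated_wss), 1e-9)
  expect_lt(relerr(r$sac$awss, tr$sac$awss), 0.02)
  expect_equal(r$sac$mwss, tr$sac$mwss, tolerance = 1e-9)
  expect_lt(relerr(r$parent$flow_division, tr$parent$flow_division), 0.01)
})

test_that("extreme sac placement raises a geometry error", {
  expect_error(make_reference(reference_case(sac_center_height = -6)),
               "intersection failure")
})

test_that("cohorts are byte-identical for a fixed seed", {
  c1 <- sample_cohort(n_teams = 4, paired_teams = integer(0), seed = 77,
                      resolution = 0.3)
  c2 <- sample_cohort(n_teams = 4, paired_teams = integer(0), seed = 77,
                      resolution = 0.3)
  expect_identical(c1, c2)
  c3 <- sample_cohort(n_teams = 4, paired_teams = integer(0), seed = 78,
                      resolution = 0.3)
  expect_false(identical(c1$datasets[[1]]$truths, c3$datasets[[1]]$truths))
})

test_that("a degenerate perturbation config collapses the cohort", {
  pert <- perturbation_config(
    sigma_d = 0,
    scaling_exponents = c(`0` = 0, `1` = 0, `2` = 1, `3` = 0, other = 0),
    viscosities = c(`3.5` = 1, `3.7` = 0, `4.0` = 0),
    p_density_typical = 1,
    wss_ratio_sdlog = 0)
  coh <- sample_cohort(cases = make_case_set()["case2"], pert = pert,
                       n_teams = 5, paired_teams = integer(0), seed = 5,
                       resolution = 0.3)
  m <- cohort_metrics(coh)
  s <- summarize_cohort(m)
  expect_true(all(abs(s$cod[is.finite(s$cod)]) < 1e-12))
  # all teams produced identical values
  v <- as.data.frame(m)
  spread <- tapply(v$value, v$parameter, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
})

test_that("normalized metrics ignore flow magnitude and viscosity", {
  base <- reference_case(resolution = 0.4)
  variants <- list(
    base,
    utils::modifyList(base, list(flow = 2 * base$flow)),
    utils::modifyList(base, list(viscosity = 4.0)),
    utils::modifyList(base, list(flow = 0.6 * base$flow, viscosity = 3.5)))
  stars <- lapply(variants, function(cs) {
    sub <- make_reference(cs)
    r <- compute_submission(sub$mesh, sub$sections, sub$regions,
                            blood_properties(cs$density, cs$viscosity),
                            sub$outlet_patches)
    unlist(r$sac[c("awss_star", "mwss_star", "lsa_star")])
  })
  for (k in 2:4)
    expect_equal(stars[[k]], stars[[1]], tolerance = 1e-9)
})

test_that("sampled strategies follow the configured menus", {
  coh <- sample_cohort(n_teams = 200, paired_teams = integer(0), seed = 31,
                       build_meshes = FALSE,
                       cases = make_case_set()["case2"])
  visc <- vapply(coh$datasets, function(d) d$meta$viscosity, numeric(1))
  expect_true(all(visc %in% c(3.5, 3.7, 4.0)))
  expect_gt(mean(visc == 3.5), 0.3)  # expected 12/26
  expect_lt(mean(visc == 3.7), 0.25)  # expected 2/26
  expo <- vapply(coh$datasets, function(d)
    as.character(d$meta$inflow_scaling_exponent), character(1))
  expect_true(all(expo %in% c("0", "1", "2", "3", "other")))
  eps <- vapply(coh$datasets, function(d) d$truths[[1]]$eps, numeric(1))
  expect_lt(abs(sd(log(eps)) - 0.034), 0.01)
  # n = 0 teams share one flow rate; n = 2 teams scale with diameter^2
  q <- vapply(coh$datasets, function(d) d$truths[[1]]$parent$flow_rate,
              numeric(1))
  d <- vapply(coh$datasets, function(d) d$truths[[1]]$parent$diameter,
              numeric(1))
  n0 <- expo == "0"
  expect_lt(diff(range(q[n0])), 1e-12)
  n2 <- expo == "2"
  expect_equal(q[n2], 2.43 * (d[n2] / 2.45)^2, tolerance = 1e-12)
})
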