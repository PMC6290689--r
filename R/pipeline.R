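#' @name pipeline
#' @title Cohort-level orchestration
#'
#' @description
#' Drivers that run the per-submission analysis over a whole (virtual or
#' real) cohort, assemble the long metrics table, summarize it with the
#' dispersion statistics, and compare paired intra-team submissions —
#' mirroring a centralized multi-team challenge analysis. Failures are
#' contained per submission (logged and skipped), since real cohorts
#' contain incomplete datasets.
NULL

.parent_params <- c("diameter", "flow_rate", "velocity", "reynolds",
                    "poiseuille_wss", "calculated_wss", "wss_ratio",
                    "flow_division")
.sac_params <- c("awss", "mwss", "lsa", "awss_star", "mwss_star", "lsa_star")

#' All pipeline parameter names
#' @return character vector of the 14 per-submission parameters.
#' @export
pipeline_parameters <- function() c(.parent_params, .sac_params)

.metric_rows <- function(dataset_id, case_id, meta, parent, sac) {
  vals <- c(unlist(parent[.parent_params]), unlist(sac[.sac_params]))
  data.frame(team = dataset_id, case = case_id,
             parameter = c(.parent_params, .sac_params),
             value = as.numeric(vals),
             base_team = meta$team_id,
             experience = meta$experience,
             temporal_scheme = meta$temporal_scheme,
             inlet_location = meta$inlet_location,
             inflow_scaling_exponent = as.character(meta$inflow_scaling_exponent),
             viscosity = meta$viscosity,
             density = meta$density,
             stringsAsFactors = FALSE)
}

#' Run the hemodynamics pipeline over a virtual cohort
#'
#' Applies [compute_submission()] to every (dataset, case) submission and
#' returns the long [metrics_table()]. Per-submission failures are logged
#' (attribute `"failures"`, a data frame) and the run continues.
#'
#' @param cohort a `virtual_cohort` from [sample_cohort()] (built with
#'   meshes).
#' @param tau_low,kappa low-shear thresholds (see [sac_metrics()]).
#' @return a [metrics_table()] with team-metadata columns; rows for every
#'   successfully processed submission. The `team` column holds the dataset
#'   id (paired a/b submissions count as independent datasets), `base_team`
#'   the contributing team.
#' @export
cohort_metrics <- function(cohort, tau_low = 0.4, kappa = 0.1) {
  rows <- list()
  failures <- data.frame(dataset = character(0), case = character(0),
                         error = character(0), stringsAsFactors = FALSE)
  for (ds in cohort$datasets) {
    if (is.null(ds$submissions))
      stop("cohort was sampled with build_meshes = FALSE")
    for (cs in names(ds$submissions)) {
      sub <- ds$submissions[[cs]]
      res <- tryCatch(
        compute_submission(sub$mesh, sub$sections, sub$regions,
                           blood_properties(ds$meta$density,
                                            ds$meta$viscosity),
                           sub$outlet_patches,
                           tau_low = tau_low, kappa = kappa),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- rbind(failures, data.frame(
          dataset = ds$dataset_id, case = cs,
          error = conditionMessage(res), stringsAsFactors = FALSE))
        next
      }
      rows[[length(rows) + 1L]] <-
        .metric_rows(ds$dataset_id, cs, ds$meta, res$parent, res$sac)
    }
  }
  out <- metrics_table(do.call(rbind, rows))
  attr(out, "failures") <- failures
  out
}

#' Closed-form metrics table for a virtual cohort
#'
#' Same shape as [cohort_metrics()] but evaluated from the ground-truth
#' records (no mesh computation) — the independent oracle for
#' parameter-recovery tests.
#'
#' @param cohort a `virtual_cohort` (meshes not required). The stored truth
#'   records use the thresholds in force when the cohort was sampled
#'   (defaults 0.4 Pa and 0.1).
#' @return a [metrics_table()].
#' @export
oracle_cohort_metrics <- function(cohort) {
  rows <- list()
  for (ds in cohort$datasets) {
    for (cs in names(ds$truths)) {
      tr <- ds$truths[[cs]]
      rows[[length(rows) + 1L]] <-
        .metric_rows(ds$dataset_id, cs, ds$meta, tr$parent, tr$sac)
    }
  }
  metrics_table(do.call(rbind, rows))
}

#' Dispersion summaries for every parameter and grouping
#'
#' For every parameter, produces per-case and case-average summaries
#' (median, IQR, CoD, 10th/90th percentiles) for the whole cohort and
#' stratified by experience level. Case-average rows follow the
#' missing-data rule of [case_average()]. CoD and the derived percent
#' columns are reported both raw and rounded to integer percent (the
#' convention of the challenge's summary tables); raw values are always
#' retained.
#'
#' @param metrics a [metrics_table()] with an `experience` column.
#' @param parameters parameters to summarize (default all present).
#' @param quantile_type quantile estimator (see [summary_stats()]).
#' @return data frame with columns `parameter`, `scope` (case label or
#'   `"case_average"`), `group` (`"All"` or an experience level), `n`,
#'   `median`, `q1`, `q3`, `cod`, `cod_pct`, `p10`, `p90`.
#' @export
summarize_cohort <- function(metrics, parameters = NULL, quantile_type = 6L) {
  metrics <- as.data.frame(metrics)
  if (is.null(parameters)) parameters <- unique(metrics$parameter)
  cases <- sort(unique(metrics$case))
  exp_of <- tapply(metrics$experience, metrics$team, `[`, 1L)
  groups <- c("All", "high", "medium", "low")
  out <- list()
  add_row <- function(parameter, scope, group, values) {
    values <- values[is.finite(values)]
    if (length(values) < 3L) return()
    s <- summary_stats(values, quantile_type = quantile_type)
    out[[length(out) + 1L]] <<- data.frame(
      parameter = parameter, scope = scope, group = group, n = s$n,
      median = s$median, q1 = s$q1, q3 = s$q3,
      cod = as.numeric(s$cod),
      cod_pct = round(100 * as.numeric(s$cod)),
      p10 = s$p10, p90 = s$p90, stringsAsFactors = FALSE)
  }
  for (par in parameters) {
    sub <- metrics[metrics$parameter == par, ]
    ca <- case_average(sub, par, cases = cases)
    for (grp in groups) {
      pick_team <- if (grp == "All") names(exp_of) else
        names(exp_of)[exp_of == grp]
      for (cs in cases) {
        v <- sub$value[sub$case == cs & sub$team %in% pick_team]
        add_row(par, cs, grp, v)
      }
      add_row(par, "case_average", grp, ca[names(ca) %in% pick_team])
    }
  }
  do.call(rbind, out)
}

#' Intra-team percent differences between paired submissions
#'
#' For teams that contributed two datasets (ids suffixed `a`/`b`), compares
#' the case-average value of every parameter between the two datasets with
#' the symmetric [percent_diff()].
#'
#' @param metrics a [metrics_table()] whose `team` column contains paired
#'   ids like `"T19a"`/`"T19b"`.
#' @return data frame with columns `team`, `parameter`, `value_a`,
#'   `value_b`, `pct_diff`, `pct_diff_int` (integer-rounded, the reporting
#'   convention).
#' @export
intra_team_diff <- function(metrics) {
  metrics <- as.data.frame(metrics)
  ids <- unique(metrics$team)
  pair_base <- sub("[ab]$", "", ids[grepl("[ab]$", ids)])
  pairs <- unique(pair_base[duplicated(pair_base)])
  out <- list()
  for (pb in pairs) {
    a <- metrics[metrics$team == paste0(pb, "a"), ]
    b <- metrics[metrics$team == paste0(pb, "b"), ]
    for (par in unique(a$parameter)) {
      ca <- case_average(a, par)
      cb <- case_average(b, par)
      if (length(ca) != 1L || length(cb) != 1L) next
      pd <- percent_diff(ca[[1L]], cb[[1L]])
      out[[length(out) + 1L]] <- data.frame(
        team = pb, parameter = par, value_a = ca[[1L]], value_b = cb[[1L]],
        pct_diff = pd, pct_diff_int = round(pd), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(team = character(0),
                                      parameter = character(0),
                                      value_a = numeric(0),
                                      value_b = numeric(0),
                                      pct_diff = numeric(0),
                                      pct_diff_int = numeric(0)))
  do.call(rbind, out)
}

#' Hypothesis tests across cases and experience levels
#'
#' Kruskal-Wallis with Dunn's post hoc comparisons for differences in each
#' parameter across aneurysm cases (per-case values) and across experience
#' levels (case-average values), plus D'Agostino-Pearson normality tests of
#' the case-average distributions. Significance is assessed at alpha
#' (default 0.05).
#'
#' @param metrics a [metrics_table()] with an `experience` column.
#' @param parameters parameters to test (default all present).
#' @param alpha significance level.
#' @return nested list, one entry per parameter, with `across_cases`,
#'   `across_experience` (each: `h`, `p`, `significant`, `pairwise`) and
#'   `normality` (`k2`, `p`) where sample sizes allow.
#' @export
cohort_tests <- function(metrics, parameters = NULL, alpha = 0.05) {
  metrics <- as.data.frame(metrics)
  if (is.null(parameters)) parameters <- unique(metrics$parameter)
  exp_of <- tapply(metrics$experience, metrics$team, `[`, 1L)
  out <- list()
  for (par in parameters) {
    sub <- metrics[metrics$parameter == par & is.finite(metrics$value), ]
    entry <- list()
    by_case <- split(sub$value, sub$case)
    by_case <- by_case[lengths(by_case) >= 1L]
    if (length(by_case) >= 2L && sum(lengths(by_case)) >= 5L) {
      kw <- kruskal_wallis_dunn(by_case)
      entry$across_cases <- list(h = kw$h, p = kw$p,
                                 significant = kw$p < alpha,
                                 pairwise = kw$pairwise)
    }
    ca <- case_average(sub, par)
    if (length(ca) >= 8L)
      entry$normality <- dagostino_pearson(ca)[c("k2", "p")]
    grp <- split(unname(ca), exp_of[names(ca)])
    grp <- grp[lengths(grp) >= 1L]
    if (length(grp) >= 2L && sum(lengths(grp)) >= 5L) {
      kw <- kruskal_wallis_dunn(grp)
      entry$across_experience <- list(h = kw$h, p = kw$p,
                                      significant = kw$p < alpha,
                                      pairwise = kw$pairwise)
    }
    out[[par]] <- entry
  }
  out
}

#' Multiply the WSS field of a submission by a constant
#'
#' Utility for invariance studies: rescales the per-vertex WSS field of a
#' virtual submission (the normalized sac parameters are unaffected because
#' the parent WSS is recomputed from the same scaled field).
#'
#' @param submission a `virtual_submission`.
#' @param factor positive scale factor.
#' @return the submission with `wss` multiplied by `factor`.
#' @export
scale_wss <- function(submission, factor) {
  stopifnot(factor > 0)
  submission$mesh$fields$wss <- submission$mesh$fields$wss * factor
  submission
}

#' Write a virtual cohort to a directory
#'
#' One subdirectory per (dataset, case) holding the surface mesh (VTK legacy
#' ASCII), the slice and outlet patches (VTK), and the region definitions
#' (YAML); a cohort-level `manifest.yaml` records the seed, the
#' perturbation configuration and every ground-truth record, so a cohort
#' directory is self-describing and reruns are verifiable.
#'
#' @param cohort a `virtual_cohort` built with meshes.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cohort$seed,
                   pert = lapply(unclass(cohort$pert), function(x)
                     if (is.numeric(x)) as.list(x) else x),
                   datasets = list())
  for (ds in cohort$datasets) {
    for (cs in names(ds$submissions)) {
      sub <- ds$submissions[[cs]]
      d <- file.path(dir, ds$dataset_id, cs)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_surface(sub$mesh, file.path(d, "surface.vtk"))
      for (k in seq_along(sub$sections))
        write_section(sub$sections[[k]], file.path(d, sprintf("slice%02d.vtk", k)))
      for (lbl in names(sub$outlet_patches))
        write_section(sub$outlet_patches[[lbl]],
                      file.path(d, paste0("outlet_", lbl, ".vtk")))
      write_region_set(sub$regions, file.path(d, "regions.yaml"))
    }
    manifest$datasets[[ds$dataset_id]] <- list(
      team = ds$team_id,
      meta = unclass(ds$meta),
      truths = lapply(ds$truths, function(tr)
        list(parent = tr$parent, sac = tr$sac, eps = tr$eps)))
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"), precision = 17L)
  invisible(dir)
}

#' Read a cohort directory back into submissions
#'
#' @param dir directory written by [write_cohort()].
#' @return list with `manifest` and `datasets`; each dataset carries
#'   re-read `submissions` (mesh, sections, outlet patches, regions).
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  datasets <- list()
  for (ds_id in names(manifest$datasets)) {
    md <- manifest$datasets[[ds_id]]$meta
    meta <- team_meta(md$team_id, md$experience, md$temporal_scheme,
                      md$inlet_location, md$inflow_scaling_exponent,
                      md$viscosity, md$density)
    case_dirs <- list.dirs(file.path(dir, ds_id), recursive = FALSE)
    subs <- list()
    for (cd in case_dirs) {
      cs <- basename(cd)
      slices <- sort(list.files(cd, pattern = "^slice[0-9]+\\.vtk$",
                                full.names = TRUE))
      outs <- list.files(cd, pattern = "^outlet_.*\\.vtk$", full.names = TRUE)
      outlet_patches <- lapply(outs, read_section)
      names(outlet_patches) <- sub("^outlet_(.*)\\.vtk$", "\\1",
                                   basename(outs))
      subs[[cs]] <- list(
        mesh = read_surface(file.path(cd, "surface.vtk"), require_wss = TRUE),
        sections = lapply(slices, read_section),
        outlet_patches = outlet_patches,
        regions = read_region_set(file.path(cd, "regions.yaml")),
        dataset_id = ds_id, case_id = cs)
    }
    datasets[[ds_id]] <- list(dataset_id = ds_id,
                              team_id = manifest$datasets[[ds_id]]$team,
                              meta = meta, submissions = subs)
  }
  list(manifest = manifest, datasets = datasets)
}
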