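#!/usr/bin/env Rscript
# Cohort statistics: per-case and case-average dispersion summaries
# (median, IQR, CoD, 10th/90th percentiles) for every hemodynamic parameter,
# stratified All/high/medium/low experience; Kruskal-Wallis + Dunn tests
# across cases and experience levels; rank-order consensus; and intra-team
# percent differences for the paired (two-segmentation) datasets.

suppressPackageStartupMessages(library(wssvar))

metrics <- read_metrics_table("results/metrics.csv")

summary_tab <- summarize_cohort(metrics)
utils::write.csv(summary_tab, "results/summary.csv", row.names = FALSE)
message("wrote results/summary.csv (", nrow(summary_tab), " rows)")

ca_all <- summary_tab[summary_tab$scope == "case_average" &
                        summary_tab$group == "All", ]
message("case-average CoD (%), whole cohort:")
for (k in seq_len(nrow(ca_all)))
  message(sprintf("  %-15s %3d", ca_all$parameter[k], ca_all$cod_pct[k]))

# rank-order consensus per parameter
cons_rows <- list()
for (par in pipeline_parameters()) {
  rk <- rank_cases(metrics, par)
  if (is.null(rk) || !nrow(rk)) next
  rc <- rank_consensus(rk)
  for (rank in colnames(rc$counts))
    for (cs in rownames(rc$counts))
      cons_rows[[length(cons_rows) + 1L]] <- data.frame(
        parameter = par, case = cs, rank = as.integer(rank),
        n_teams = rc$counts[cs, rank],
        majority = identical(rc$majority[[rank]], cs))
}
consensus <- do.call(rbind, cons_rows)
utils::write.csv(consensus, "results/rank_consensus.csv", row.names = FALSE)
maj <- consensus[consensus$majority, ]
message("strict-majority consensus cells: ", nrow(maj))

# hypothesis tests
tests <- cohort_tests(metrics)
jsonlite::write_json(tests, "results/tests.json", auto_unbox = TRUE,
                     digits = 10, force = TRUE)
message("wrote results/tests.json")

# intra-team variability (paired a/b datasets)
it <- intra_team_diff(metrics)
utils::write.csv(it, "results/intra_team.csv", row.names = FALSE)
message("intra-team case-average %diff range: ",
        paste(range(it$pct_diff_int), collapse = " to "))
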