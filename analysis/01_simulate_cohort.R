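#!/usr/bin/env Rscript
# Simulate the virtual challenge cohort: 26 teams, two of which contribute a
# second segmentation (28 datasets), across the five idealized MCA-aneurysm
# cases, with strategy menus at the challenge's observed frequencies.
# Writes the closed-form ground-truth metric table to results/ and caches the
# full cohort (meshes included) under scratch/ for the downstream steps.

suppressPackageStartupMessages(library(wssvar))

seed <- 2015
resolution <- 0.5  # cohort-scale mesh density (~5k triangles per surface)
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

message("sampling cohort (seed ", seed, ", resolution ", resolution, ") ...")
cohort <- sample_cohort(cases = make_case_set(resolution = resolution),
                        n_teams = 26, paired_teams = c(19, 26), seed = seed)
message(length(cohort$datasets), " datasets x ",
        length(cohort$cases), " cases")

truth <- oracle_cohort_metrics(cohort)
write_metrics_table(truth, "results/ground_truth_metrics.csv")
message("wrote results/ground_truth_metrics.csv (",
        nrow(truth), " rows of closed-form values)")

# one example submission in the exchange formats, to show the on-disk layout
example <- cohort
example$datasets <- cohort$datasets[1]
example$datasets[[1]]$submissions <-
  example$datasets[[1]]$submissions["case1"]
write_cohort(example, "scratch/cohort_example")
message("wrote one example submission under scratch/cohort_example/")

saveRDS(cohort, "scratch/cohort.rds")
message("cached full cohort at scratch/cohort.rds")
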