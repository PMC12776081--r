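#!/usr/bin/env Rscript

# Stage 2: de novo discovery of trajectory subsets.
#
# QC-filter the cohort, scan for recurrently altered loci under the
# genomic mask, build the event catalog (recurrent SCNA regions + driver
# SNVs at >= 3% prevalence + WGD), order every sample's events across 25
# randomized iterations, choose the number of trajectories by lowest
# median BIC over K = 1..5, and consolidate the per-iteration mixture
# fits into one assignment.

library(pltraj)

sim <- readRDS("scratch/sim.rds")
seed <- 11

cohort <- qc_filter(sim$cohort)
scan <- scan_recurrent_scnas(cohort)
catalog <- build_catalog(cohort, scan$regions)
cat("Catalog:", nrow(catalog), "events (",
    sum(catalog$kind == "GAIN"), "gains,", sum(catalog$kind == "LOH"),
    "LOH,", sum(catalog$kind == "HD"), "HD,",
    sum(catalog$kind == "SNV"), "driver SNVs, plus WGD ).\n")

rankings <- order_cohort(cohort, catalog, n_iterations = 25, seed = seed)
cat(length(rankings$unclassifiable),
    "sample(s) carried no catalog event and were set aside.\n")

selection <- select_k(rankings, k_max = 5, n_restarts = 2, seed = seed)
cat("Median BIC by K:\n")
print(round(selection$median_bic, 1))
cat("Selected K =", selection$selected_k, "\n")

assignment <- consolidate_assignments(selection$fits,
                                      rankings$unclassifiable)

truth <- sim$truth$samples
confusion <- table(truth = truth$archetype[match(names(assignment$labels),
                                                 truth$sample_id)],
                   assigned = assignment$labels)
cat("Assignment vs planted archetypes:\n")
print(confusion)

utils::write.table(catalog, "results/02_catalog.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(K = seq_along(selection$median_bic),
             median_bic = unname(selection$median_bic)),
  "results/02_median_bic.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(sample_id = names(assignment$labels),
             label = unname(assignment$labels)),
  "results/02_assignment.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(as.data.frame(confusion), "results/02_confusion.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(cohort = cohort, catalog = catalog, rankings = rankings,
             selection = selection, assignment = assignment),
        "scratch/state.rds")
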