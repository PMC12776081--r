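#!/usr/bin/env Rscript

# Stage 3: per-trajectory re-discovery and aggregate orderings.
#
# Within each discovered subset the recurrence scan and catalog are re-run
# so subset-specific events can enter, events are re-ordered, and the
# aggregate ordering (median rank with a 95% interval across iterations)
# summarises the trajectory. Pre-WGD event proportions and per-event
# clonality preferences are compared between subsets.

library(pltraj)

state <- readRDS("scratch/state.rds")
seed <- 11
labels <- state$assignment$labels

subsets <- list()
for (lab in setdiff(sort(unique(labels)), "UNCLASSIFIABLE")) {
  ids <- names(labels)[labels == lab]
  sub <- subset_cohort(state$cohort, ids)
  scan <- scan_recurrent_scnas(sub)
  catalog <- build_catalog(sub, scan$regions)
  rk <- order_cohort(sub, catalog, n_iterations = 25,
                     seed = seed + match(lab, sort(unique(labels))))
  agg <- aggregate_ordering(rk, ids)
  subsets[[lab]] <- list(ids = ids, catalog = catalog, rankings = rk,
                         aggregate = agg)
  utils::write.table(agg, sprintf("results/03_aggregate_%s.tsv", lab),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s (n=%d): %d events; earliest five: %s\n", lab,
              length(ids), nrow(agg),
              paste(utils::head(agg$event_id, 5), collapse = ", ")))
}

# proportion of events ordered before WGD, per WGD sample, between the two
# WGD-richest subsets
wgd_ids <- state$cohort$samples$sample_id[state$cohort$samples$wgd]
by_lab <- vapply(split(names(labels), labels)[names(subsets)],
                 function(ids) mean(ids %in% wgd_ids), numeric(1))
two <- names(sort(by_lab, decreasing = TRUE))[1:2]
pre <- prewgd_proportion_test(state$rankings, labels, wgd_ids, two)
cat(sprintf("Pre-WGD proportion, %s vs %s: Wilcoxon p = %.3g\n",
            two[1], two[2], pre$p))
utils::write.table(pre$per_sample, "results/03_prewgd_proportions.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# clonality preference within each subset
for (lab in names(subsets)) {
  occ <- do.call(rbind, lapply(subsets[[lab]]$ids, function(sid) {
    p <- state$rankings$presence[[sid]]
    if (nrow(p)) p[c("event_id", "clonality")]
  }))
  res <- clonality_preference(occ)
  utils::write.table(res, sprintf("results/03_clonality_%s.tsv", lab),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- res$item[res$flagged & res$odds_ratio > 1]
  cat(sprintf("%s: %d events preferentially clonal (e.g. %s)\n", lab,
              length(hits), paste(utils::head(hits, 3), collapse = ", ")))
}

saveRDS(subsets, "scratch/subsets.rds")
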