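#' Default pipeline configuration
#'
#' Parameters mirror the full-scale analysis (1000 ordering iterations,
#' K up to 5, 1 Mb bins, FDR 0.05, 3 percent SNV prevalence); desk-scale
#' runs lower `n_iterations` to ~25.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_nrpcc = 10, min_purity = 0.30, bin_size = 1e6,
              alpha = 0.05, min_snv_prev = 0.03, min_overlap_frac = 0.5,
              clonal_band = 0.9, n_iterations = 1000, k_max = 5,
              n_restarts = 5, tol = 1e-6, max_iter = 500,
              prior_pseudocount = 0.1, acceleration = 1, seed = 1)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the trajectory-discovery pipeline end to end
#'
#' Stages: QC filter, recurrent-SCNA scan and catalog build, randomized
#' within-sample ordering, mixture-size selection by lowest median BIC,
#' per-iteration mixture fits consolidated into a trajectory assignment,
#' per-subset re-discovery (catalog rebuilt within each subset, events
#' re-ordered) and aggregate orderings. Deterministic given the seed.
#'
#' @param cohort a `pl_cohort`.
#' @param config list from [pipeline_config()].
#' @param mask filter mask; default [default_mask()] on the cohort genome.
#' @param stages character vector of stages to run after the catalog;
#'   subsets of `c("order", "select_k", "assign", "rediscover")` (each
#'   later stage needs the earlier ones).
#' @return list: `cohort` (post-QC), `catalog`, `regions`, `rankings`,
#'   `selection`, `assignment`, `subsets` (per-trajectory re-discovered
#'   catalog, rankings and aggregate ordering), `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), mask = NULL,
                         stages = c("order", "select_k", "assign",
                                    "rediscover")) {
  if (is.null(mask)) mask <- default_mask(cohort$genome)
  out <- list(config = config)
  cohort <- qc_filter(cohort, config$min_nrpcc, config$min_purity)
  out$cohort <- cohort
  scan <- scan_recurrent_scnas(cohort, mask, config$bin_size, config$alpha)
  out$regions <- scan$regions
  out$catalog <- build_catalog(cohort, scan$regions,
                               min_snv_prev = config$min_snv_prev,
                               min_overlap_frac = config$min_overlap_frac)
  if (!"order" %in% stages) return(out)
  out$rankings <- order_cohort(cohort, out$catalog, config$n_iterations,
                               config$seed, config$min_overlap_frac,
                               config$clonal_band)
  if (!"select_k" %in% stages) return(out)
  out$selection <- select_k(out$rankings, config$k_max, config$n_restarts,
                            config$seed, config$tol, config$max_iter,
                            config$prior_pseudocount)
  if (!"assign" %in% stages) return(out)
  out$assignment <- consolidate_assignments(out$selection$fits,
                                            out$rankings$unclassifiable)
  if (!"rediscover" %in% stages) return(out)
  labels <- out$assignment$labels
  out$subsets <- list()
  for (lab in setdiff(sort(unique(labels)), "UNCLASSIFIABLE")) {
    ids <- names(labels)[labels == lab]
    sub <- subset_cohort(cohort, ids)
    sub_scan <- scan_recurrent_scnas(sub, mask, config$bin_size,
                                     config$alpha)
    sub_catalog <- build_catalog(sub, sub_scan$regions,
                                 min_snv_prev = config$min_snv_prev,
                                 min_overlap_frac = config$min_overlap_frac)
    sub_rankings <- order_cohort(sub, sub_catalog, config$n_iterations,
                                 mix_seed(config$seed, lab),
                                 config$min_overlap_frac,
                                 config$clonal_band)
    out$subsets[[lab]] <- list(
      sample_ids = ids, catalog = sub_catalog, rankings = sub_rankings,
      aggregate = aggregate_ordering(
        sub_rankings, ids,
        prior_pseudocount = config$prior_pseudocount))
  }
  out
}

#' Smoking-by-SBS4-by-trajectory path counts
#'
#' The count table behind a Sankey-style diagram: how tumours flow from
#' smoking status through SBS4 status into the discovered trajectories.
#' Row sums over a smoking/SBS4 stratum equal its cohort size.
#'
#' @param cohort a `pl_cohort`.
#' @param labels named trajectory labels.
#' @return data.frame of `smoking`, `sbs4`, `trajectory`, `n`.
#' @export
report_sankey <- function(cohort, labels) {
  smp <- cohort$samples[cohort$samples$sample_id %in% names(labels), ]
  tab <- table(smoking = smp$smoking,
               sbs4 = ifelse(smp$sbs4, "SBS4+", "SBS4-"),
               trajectory = labels[smp$sample_id])
  out <- as.data.frame(tab, responseName = "n")
  out[out$n >= 0, ]
}

#' Volcano-plot export of enrichment results
#' @param enrichment data.frame from [event_enrichment()].
#' @return data.frame with `item`, `log2_or`, `neg_log10_fdr`, `flagged`.
#' @export
report_volcano <- function(enrichment) {
  data.frame(item = enrichment$item,
             log2_or = log2(enrichment$odds_ratio),
             neg_log10_fdr = -log10(pmax(enrichment$fdr, 1e-300)),
             flagged = enrichment$flagged)
}

#' Write pipeline outputs as TSV files with a run manifest
#' @param result list from [run_pipeline()].
#' @param out_dir output directory.
#' @return invisibly, the output directory.
#' @export
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wr(result$catalog, "catalog.tsv")
  if (!is.null(result$assignment)) {
    wr(data.frame(sample_id = names(result$assignment$labels),
                  label = unname(result$assignment$labels)),
       "assignment.tsv")
    wr(as.data.frame(result$assignment$votes), "votes.tsv")
  }
  if (!is.null(result$selection))
    wr(data.frame(K = seq_along(result$selection$median_bic),
                  median_bic = unname(result$selection$median_bic)),
       "median_bic.tsv")
  for (lab in names(result$subsets))
    wr(result$subsets[[lab]]$aggregate,
       sprintf("aggregate_ordering_%s.tsv", lab))
  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("pltraj"))),
    sprintf("seed: %s", result$config$seed),
    sprintf("n_iterations: %s", result$config$n_iterations),
    sprintf("n_samples: %s", nrow(result$cohort$samples)),
    sprintf("selected_k: %s",
            if (is.null(result$selection)) NA else
              result$selection$selected_k))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
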