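#!/usr/bin/env Rscript

# Stage 4: contingency statistics over the discovered trajectories.
#
# Event enrichment between the smoking-like subset and the rest (volcano
# export), demographic comparisons under their stratum filters, the
# driver-gene count contrast, pairwise event co-occurrence / mutual
# exclusivity, and mutational-signature presence tests.

library(pltraj)

state <- readRDS("scratch/state.rds")
labels <- state$assignment$labels
classified <- labels[labels != "UNCLASSIFIABLE"]

# the smoking-like subset is the one richest in ever-smokers
smoking <- stats::setNames(state$cohort$samples$smoking,
                           state$cohort$samples$sample_id)
ever_rate <- vapply(split(names(classified), classified),
                    function(ids) mean(smoking[ids] == "ever"), numeric(1))
sd_lab <- names(which.max(ever_rate))
nsd_labs <- setdiff(names(ever_rate), sd_lab)
cat("Smoking-like subset:", sd_lab, "( ever-smoker fraction",
    round(max(ever_rate), 2), ")\n")

pres <- presence_matrix(state$cohort, state$catalog)
pres <- pres[names(classified), , drop = FALSE]

enr <- event_enrichment(pres, classified, list(sd_lab, nsd_labs))
utils::write.table(enr, "results/04_enrichment_SD_vs_NSD.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(report_volcano(enr), "results/04_volcano_SD_vs_NSD.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sum(enr$flagged), "events substantially associated with", sd_lab,
    "or the combined others (OR > 3/2 or < 2/3, FDR < 0.05).\n")
if (length(nsd_labs) == 2) {
  enr2 <- event_enrichment(pres, classified,
                           list(nsd_labs[1], nsd_labs[2]))
  utils::write.table(enr2, "results/04_enrichment_NSD_pair.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

demo <- rbind(
  demographic_comparison(state$cohort, labels, "smoking", sd_lab,
                         c("ever", "never"))$result,
  demographic_comparison(state$cohort, labels, "sbs4", sd_lab,
                         c("positive", "negative"),
                         subset_filter = function(s)
                           s$smoking == "never")$result,
  demographic_comparison(state$cohort, labels, "ancestry", sd_lab,
                         c("EUR", "EAS"),
                         subset_filter = function(s)
                           s$smoking == "never")$result,
  demographic_comparison(state$cohort, labels, "sex", sd_lab,
                         c("M", "F"))$result)
demo$fdr <- bh_fdr(demo$p)
utils::write.table(demo, "results/04_demographics.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Demographic comparisons (risk ratio toward", sd_lab, "):\n")
print(demo[c("item", "risk_ratio", "p", "fdr")], row.names = FALSE)

# driver genes with SNVs in >= 3% of each subset
subset_genes <- lapply(split(names(classified), classified), function(ids) {
  snv <- state$cohort$snvs[state$cohort$snvs$sample_id %in% ids, ]
  tab <- table(unique(snv[c("sample_id", "gene")])$gene)
  names(tab)[tab >= 0.03 * length(ids)]
})
dct <- driver_count_test(subset_genes, universe_size = 72)
utils::write.table(dct, "results/04_driver_counts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(dct, row.names = FALSE)

cooc <- cooccurrence(pres)
sig <- cooc[cooc$fdr_greater < 0.05 | cooc$fdr_less < 0.05, ]
utils::write.table(sig, "results/04_cooccurrence_significant.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(nrow(sig), "event pairs show significant co-occurrence or mutual",
    "exclusivity.\n")

sigs <- state$cohort$signatures
sig_res <- suppressWarnings(
  signature_presence_test(sigs, classified, list(sd_lab, nsd_labs)))
utils::write.table(sig_res, "results/04_signature_presence.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Signatures enriched in", sd_lab, ":",
    paste(sig_res$item[sig_res$flagged & sig_res$odds_ratio > 1],
          collapse = ", "), "\n")
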