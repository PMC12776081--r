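#!/usr/bin/env Rscript

# Stage 5: genome-wide state metrics and the instability regression.
#
# Mean weighted copy-number tracks with per-locus Wilcoxon tests between
# two subsets, amplification magnitude at the recurrent chr12 gain locus,
# per-sample burden metrics (PGA, ploidy, latency, ...), copy-number
# deviation, and the multivariate regression of aberrant copy-number
# signature activity with VIF diagnostics.

library(pltraj)

state <- readRDS("scratch/state.rds")
labels <- state$assignment$labels
classified <- labels[labels != "UNCLASSIFIABLE"]
groups <- split(names(classified), classified)

# per-locus comparison between the two largest subsets
two <- names(sort(lengths(groups), decreasing = TRUE))[1:2]
prof <- union_profiles(state$cohort, groups[two])
locus_tests <- per_locus_tests(prof, groups[two])
sig <- locus_tests[locus_tests$supported & !is.na(locus_tests$fdr) &
                     locus_tests$fdr < 0.05, ]
utils::write.table(sig, "results/05_locus_tests_significant.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(nrow(sig), "union segments x statistics differ between", two[1],
    "and", two[2], "at FDR < 0.05.\n")
for (lab in two) {
  track <- cbind(prof$segments, prof$means[[lab]])
  utils::write.table(track, sprintf("results/05_mean_track_%s.tsv", lab),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

# amplification magnitude at the recurrent chr12 gain (an MDM2-like locus)
locus <- list(chrom = "chr12", start = 62e6, end = 64e6)
mag <- vapply(names(classified), function(sid)
  amplification_magnitude(state$cohort, sid, locus), numeric(1))
mag_tab <- data.frame(sample_id = names(mag), label = classified,
                      magnitude = mag)
utils::write.table(mag_tab[!is.na(mag_tab$magnitude), ],
                   "results/05_amplification_chr12.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
med <- tapply(mag_tab$magnitude, mag_tab$label, stats::median, na.rm = TRUE)
cat("Median chr12 amplification magnitude by subset:",
    paste(names(med), round(med, 2), collapse = ", "), "\n")

# burden metrics and deviation
mask <- default_mask(state$cohort$genome)
burden <- do.call(rbind, lapply(names(classified), function(sid)
  burden_metrics(state$cohort, sid, mask)))
burden$label <- classified[burden$sample_id]
burden$cn_deviation <- vapply(burden$sample_id, function(sid)
  cn_deviation(state$cohort, sid, mask), numeric(1))
utils::write.table(burden, "results/05_burden.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Median PGA by subset:\n")
print(round(tapply(burden$pga, burden$label, stats::median), 3))

# pairwise burden comparisons with BH within each pair
metrics <- c("snv_count", "pga", "ploidy", "sv_count", "kataegis",
             "latency_years", "cn_deviation")
pairs <- utils::combn(names(groups), 2, simplify = FALSE)
cmp <- do.call(rbind, lapply(pairs, function(p) {
  ps <- vapply(metrics, function(mtr) {
    x <- burden[[mtr]][burden$label == p[1]]
    y <- burden[[mtr]][burden$label == p[2]]
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, numeric(1))
  data.frame(contrast = paste(p, collapse = "_vs_"), metric = metrics,
             p = ps, fdr = bh_fdr(ps))
}))
utils::write.table(cmp, "results/05_burden_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# instability regression: aberrant CN-signature proportion on drivers,
# WGD, purity, smoking, ancestry, sex
sigs <- state$cohort$signatures
rownames(sigs) <- sigs$sample_id
smp <- state$cohort$samples
smp <- smp[smp$sample_id %in% names(classified), ]
cn_cols <- grep("^CN", names(sigs), value = TRUE)
aberr <- vapply(smp$sample_id, function(sid)
  aberrant_signature_proportion(unlist(sigs[sid, cn_cols]),
                                smp$wgd[smp$sample_id == sid]),
  numeric(1))
drivers <- c("TP53", "EGFR", "KRAS", "STK11", "KEAP1")
dmat <- sapply(drivers, function(g)
  as.integer(smp$sample_id %in%
               state$cohort$snvs$sample_id[state$cohort$snvs$gene == g]))
df <- data.frame(aberrant = aberr, dmat,
                 wgd = as.integer(smp$wgd), purity = smp$purity,
                 smoking = as.integer(smp$smoking == "ever"),
                 eur = as.integer(smp$ancestry == "EUR"),
                 male = as.integer(smp$sex == "M"))
fit <- instability_regression(df, response = "aberrant")
utils::write.table(fit$coefficients, "results/05_instability_coefs.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(predictor = names(fit$vif), vif = unname(fit$vif)),
  "results/05_instability_vif.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(round(fit$correlation, 3),
                   "results/05_predictor_correlation.tsv", sep = "\t",
                   quote = FALSE)
cat("Largest VIF:", names(which.max(fit$vif)),
    round(max(fit$vif), 2), "\n")
cat("Largest absolute predictor correlation:",
    round(max(abs(fit$correlation[upper.tri(fit$correlation)])), 3), "\n")
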