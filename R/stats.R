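as_table2x2 <- function(table) {
  tab <- as.matrix(table)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0), sum(tab) > 0)
  storage.mode(tab) <- "double"
  tab
}

#' Two-tailed Fisher exact p-value for a 2x2 table
#'
#' Exact two-sided p by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more likely than the observed one.
#'
#' @param table 2x2 matrix `rbind(c(a, b), c(c, d))`; rows = condition,
#'   columns = outcome.
#' @return the p-value.
#' @export
fisher_two_tailed <- function(table) {
  tab <- as_table2x2(table)
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[2, 1]          # first-column margin
  n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]          # first-row margin
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  min(1, sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)]))
}

#' Odds ratio of a 2x2 table
#'
#' `(a*d)/(b*c)`, with the Haldane-Anscombe correction (0.5 added to every
#' cell) when any cell is zero so rare events still yield a finite ratio.
#'
#' @param table 2x2 count matrix.
#' @return the (possibly corrected) odds ratio.
#' @export
odds_ratio <- function(table) {
  tab <- as_table2x2(table)
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Risk ratio of a 2x2 table
#'
#' `(a/(a+b)) / (c/(c+d))`. An empty row leaves the ratio undefined and
#' returns `NA` with a warning.
#'
#' @param table 2x2 count matrix.
#' @return the risk ratio, or `NA` when a row is empty.
#' @export
risk_ratio <- function(table) {
  tab <- as_table2x2(table)
  if (any(rowSums(tab) == 0)) {
    warning("risk ratio undefined for an empty row", call. = FALSE)
    return(NA_real_)
  }
  (tab[1, 1] / sum(tab[1, ])) / (tab[2, 1] / sum(tab[2, ]))
}

#' Benjamini-Hochberg false discovery rates
#' @param p_values numeric vector of p-values in `[0,1]`.
#' @return adjusted values, order-preserving to the input.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

enrich_row <- function(item, a, b, c, d) {
  tab <- rbind(c(a, b), c(c, d))
  data.frame(item = item, a = a, b = b, c = c, d = d,
             odds_ratio = odds_ratio(tab),
             risk_ratio = suppressWarnings(risk_ratio(tab)),
             p = fisher_two_tailed(tab))
}

finish_enrichment <- function(res, or_hi = 3 / 2, or_lo = 2 / 3,
                              fdr_cut = 0.05) {
  res$fdr <- bh_fdr(res$p)
  res$flagged <- (res$odds_ratio > or_hi | res$odds_ratio < or_lo) &
    res$fdr < fdr_cut
  rownames(res) <- NULL
  res
}

#' Event enrichment between trajectory groups
#'
#' For each catalog event, a 2x2 of presence by group under a binary
#' contrast (e.g. SD vs both NSD trajectories combined), a two-tailed
#' Fisher test, odds and risk ratios, and BH FDRs across events. Hits are
#' flagged "substantial" when the odds ratio exceeds 3/2 (or falls below
#' 2/3) at FDR < 0.05.
#'
#' @param presence logical samples x events matrix.
#' @param group_labels named trajectory labels for the samples.
#' @param contrast list of two character vectors of labels,
#'   `list(case = ..., control = ...)`.
#' @return data.frame of per-event enrichment results.
#' @export
event_enrichment <- function(presence, group_labels, contrast) {
  labels <- group_labels[rownames(presence)]
  case <- labels %in% contrast[[1]]
  control <- labels %in% contrast[[2]]
  if (!any(case) || !any(control))
    stop("a contrast group has no samples", call. = FALSE)
  res <- do.call(rbind, lapply(colnames(presence), function(ev) {
    x <- presence[, ev]
    enrich_row(ev, sum(x & case), sum(!x & case),
               sum(x & control), sum(!x & control))
  }))
  finish_enrichment(res)
}

#' Demographic association with the trajectories
#'
#' Builds the 2x2 of a binary demographic factor against SD-versus-NSD
#' trajectory membership, optionally within a filtered stratum (e.g. the
#' ancestry comparison runs on never-smokers, EUR vs EAS only), and
#' returns Fisher p, odds and risk ratios plus the stacked per-level
#' trajectory proportions.
#'
#' @param cohort a `pl_cohort`.
#' @param labels named trajectory labels.
#' @param factor one of `"smoking"`, `"ancestry"`, `"sex"`, `"sbs4"`.
#' @param sd_labels labels counted as the smoker-dominant side.
#' @param levels the two factor levels compared, first = exposed row.
#' @param subset_filter optional predicate on the sample sheet rows.
#' @return list: `result` (one enrichment row), `proportions` (level x
#'   trajectory fraction matrix).
#' @export
demographic_comparison <- function(cohort, labels, factor,
                                   sd_labels, levels = NULL,
                                   subset_filter = NULL) {
  stopifnot(factor %in% c("smoking", "ancestry", "sex", "sbs4"))
  smp <- cohort$samples
  smp <- smp[smp$sample_id %in% names(labels)[labels != "UNCLASSIFIABLE"], ]
  if (!is.null(subset_filter)) smp <- smp[subset_filter(smp), , drop = FALSE]
  val <- smp[[factor]]
  if (is.logical(val)) val <- ifelse(val, "positive", "negative")
  if (is.null(levels)) levels <- unique(val)
  if (!all(levels %in% val))
    stop("factor level absent after filtering: ",
         paste(setdiff(levels, val), collapse = ", "), call. = FALSE)
  smp <- smp[val %in% levels, , drop = FALSE]
  val <- val[val %in% levels]
  lab <- labels[smp$sample_id]
  in_sd <- lab %in% sd_labels
  a <- sum(val == levels[1] & in_sd)
  b <- sum(val == levels[1] & !in_sd)
  c_ <- sum(val == levels[2] & in_sd)
  d <- sum(val == levels[2] & !in_sd)
  res <- enrich_row(paste0(factor, ":", levels[1], "-vs-", levels[2]),
                    a, b, c_, d)
  props <- prop.table(table(val, lab), margin = 1)
  list(result = res, proportions = props)
}

#' Per-trajectory driver-gene count test
#'
#' For each trajectory, a Fisher test on the 2x2 of (driver genes with SNVs
#' in >= 3 percent of the subset's samples vs the rest of the 72-gene
#' universe) against the other two subsets pooled. The primary pooling
#' counts genes at >= 3 percent in either other subset against one
#' universe; `pooling = "additive"` instead adds the two subsets' counts
#' over a doubled universe.
#'
#' @param subset_genes named list of character vectors: the genes >= 3
#'   percent per trajectory.
#' @param universe_size driver-universe size (default 72).
#' @param pooling `"union"` (primary) or `"additive"`.
#' @return data.frame, one row per trajectory, with Fisher p and BH FDR.
#' @export
driver_count_test <- function(subset_genes, universe_size = 72,
                              pooling = c("union", "additive")) {
  pooling <- match.arg(pooling)
  stopifnot(universe_size >= max(lengths(subset_genes)))
  res <- do.call(rbind, lapply(names(subset_genes), function(lab) {
    own <- length(subset_genes[[lab]])
    others <- subset_genes[names(subset_genes) != lab]
    if (pooling == "union") {
      oth <- length(unique(unlist(others)))
      tab <- rbind(c(own, universe_size - own),
                   c(oth, universe_size - oth))
    } else {
      oth <- sum(lengths(others))
      tab <- rbind(c(own, universe_size - own),
                   c(oth, 2 * universe_size - oth))
    }
    data.frame(trajectory = lab, n_genes = own, n_genes_other = oth,
               p = fisher_two_tailed(tab), odds_ratio = odds_ratio(tab))
  }))
  res$fdr <- bh_fdr(res$p)
  rownames(res) <- NULL
  res
}

#' Pairwise event co-occurrence and mutual exclusivity
#'
#' For every event pair with marginal counts `nA`, `nB` and overlap `j`
#' among `N` samples, exact hypergeometric tails: `p_greater = P(X >= j)`
#' (co-occurrence) and `p_less = P(X <= j)` (exclusivity). BH correction is
#' applied separately within the positive and the negative sets.
#'
#' @param presence logical samples x events matrix (>= 2 events).
#' @return data.frame per unordered pair: counts, expected overlap,
#'   `effect` (observed minus expected), both tails and both FDRs.
#' @export
cooccurrence <- function(presence) {
  events <- colnames(presence)
  stopifnot(length(events) >= 2)
  N <- nrow(presence)
  pairs <- utils::combn(events, 2)
  res <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    A <- pairs[1, i]; B <- pairs[2, i]
    nA <- sum(presence[, A]); nB <- sum(presence[, B])
    j <- sum(presence[, A] & presence[, B])
    expected <- nA * nB / N
    data.frame(event_a = A, event_b = B, n_a = nA, n_b = nB, overlap = j,
               expected = expected, effect = j - expected,
               p_greater = stats::phyper(j - 1, nA, N - nA, nB,
                                         lower.tail = FALSE),
               p_less = stats::phyper(j, nA, N - nA, nB))
  }))
  res$fdr_greater <- bh_fdr(res$p_greater)
  res$fdr_less <- bh_fdr(res$p_less)
  rownames(res) <- NULL
  res
}

#' Clonal-versus-subclonal preference of events within a trajectory
#'
#' Per event: a 2x2 of the event's clonal and subclonal occurrence counts
#' against those of all other events in the subset; Fisher test with BH
#' within the subset. An odds ratio above 1 marks a clonal preference.
#'
#' @param clonality data.frame with `event_id` and `clonality`
#'   (`"CLONAL"`/`"SUBCLONAL"`), one row per event occurrence in the
#'   subset's samples.
#' @return data.frame of per-event results.
#' @export
clonality_preference <- function(clonality) {
  events <- unique(clonality$event_id)
  stopifnot(length(events) >= 2)
  is_clonal <- clonality$clonality == "CLONAL"
  res <- do.call(rbind, lapply(events, function(ev) {
    own <- clonality$event_id == ev
    enrich_row(ev, sum(own & is_clonal), sum(own & !is_clonal),
               sum(!own & is_clonal), sum(!own & !is_clonal))
  }))
  finish_enrichment(res)
}

#' Proportion of events before WGD, compared between trajectories
#'
#' For every WGD sample the fraction of its ordered events ranked before
#' the WGD event (iteration 1; the fraction is fixed by the timing strata,
#' not by the within-stratum shuffle), then a two-sided Wilcoxon rank-sum
#' test between two trajectories.
#'
#' @param rankings a `pl_rankings` object.
#' @param labels named trajectory labels.
#' @param wgd_samples sample ids with WGD.
#' @param groups character(2): the two trajectory labels to compare.
#' @return list: `per_sample` (sample, label, proportion), `p` (Wilcoxon),
#'   or `p = NA` when a group has no WGD samples.
#' @export
prewgd_proportion_test <- function(rankings, labels, wgd_samples, groups) {
  rk1 <- rankings$iterations[[1]]
  ids <- intersect(names(rk1), wgd_samples)
  ids <- ids[vapply(rk1[ids], function(r) "WGD" %in% r && length(r) > 1,
                    logical(1))]
  # fraction of the sample's non-WGD events ranked before the WGD event
  prop <- vapply(ids, function(sid) {
    r <- rk1[[sid]]
    (which(r == "WGD") - 1) / (length(r) - 1)
  }, numeric(1))
  per_sample <- data.frame(sample_id = ids, label = labels[ids],
                           proportion = prop)
  x <- per_sample$proportion[per_sample$label == groups[1]]
  y <- per_sample$proportion[per_sample$label == groups[2]]
  if (!length(x) || !length(y))
    return(list(per_sample = per_sample, p = NA_real_))
  exact <- length(x) <= 25 && length(y) <= 25 &&
    !any(duplicated(c(x, y)))
  p <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  list(per_sample = per_sample, p = p)
}

#' Mutational-signature presence enrichment between trajectory groups
#'
#' A signature is "present" in a sample when its activity exceeds zero;
#' per signature a 2x2 against the contrast with Fisher and BH. Signatures
#' present in no sample are skipped with a warning.
#'
#' @param signatures wide activity data.frame (`sample_id` + signatures).
#' @param group_labels named trajectory labels.
#' @param contrast list of two label vectors, as in [event_enrichment()].
#' @return data.frame of per-signature enrichment results.
#' @export
signature_presence_test <- function(signatures, group_labels, contrast) {
  sig_cols <- setdiff(names(signatures), "sample_id")
  act <- as.matrix(signatures[sig_cols])
  stopifnot(all(act >= 0))
  rownames(act) <- signatures$sample_id
  keep <- colSums(act > 0) > 0
  if (any(!keep))
    warning("skipping all-zero signature(s): ",
            paste(sig_cols[!keep], collapse = ", "), call. = FALSE)
  event_enrichment(act[, keep, drop = FALSE] > 0, group_labels, contrast)
}
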