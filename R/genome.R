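#' CCF-weighted copy number of segments
#'
#' The expected major/minor copy number of each segment under its cellular
#' states, weighted by state fraction; clonal segments return their own
#' copy numbers.
#'
#' @param segments segment data.frame (rows from a cohort's `segments`).
#' @return data.frame with `major`, `minor`, `total` per input row.
#' @export
weighted_cn <- function(segments) {
  two <- !is.na(segments$frac2)
  major <- segments$major1 * segments$frac1 +
    ifelse(two, segments$major2 * segments$frac2, 0)
  minor <- segments$minor1 * segments$frac1 +
    ifelse(two, segments$minor2 * segments$frac2, 0)
  data.frame(major = major, minor = minor, total = major + minor)
}

unmasked_autosomes <- function(genome, mask) {
  auto <- genome[!grepl("chr[XY]$", genome$chrom), , drop = FALSE]
  territory <- GenomicRanges::GRanges(
    auto$chrom, IRanges::IRanges(1, auto$length),
    seqlengths = stats::setNames(genome$length, genome$chrom))
  GenomicRanges::setdiff(territory, mask, ignore.strand = TRUE)
}

#' Union segmentation and per-sample weighted copy-number matrix
#'
#' Breaks the genome at every breakpoint of every involved sample and
#' reports, per union sub-segment and sample, the CCF-weighted major,
#' minor and total copy number (NA where a sample has no covering
#' segment), plus per-subset mean tracks.
#'
#' @param cohort a `pl_cohort`.
#' @param subsets named list of sample-id vectors.
#' @return list: `segments` (chrom/start/end of the union pieces),
#'   `major`/`minor`/`total` (piece x sample matrices) and `means` (a
#'   per-subset list of piece x 3 mean-track matrices).
#' @export
union_profiles <- function(cohort, subsets) {
  ids <- unique(unlist(subsets))
  stopifnot(length(ids) >= 1)
  seg <- cohort$segments[cohort$segments$sample_id %in% ids, , drop = FALSE]
  gr <- segments_to_granges(seg)
  pieces <- GenomicRanges::disjoin(GenomicRanges::granges(gr))
  wcn <- weighted_cn(seg)
  mk <- function() matrix(NA_real_, length(pieces), length(ids),
                          dimnames = list(NULL, ids))
  major <- mk(); minor <- mk(); total <- mk()
  hits <- GenomicRanges::findOverlaps(pieces, gr, type = "within")
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  idx <- cbind(qi, match(seg$sample_id[si], ids))
  major[idx] <- wcn$major[si]
  minor[idx] <- wcn$minor[si]
  total[idx] <- wcn$total[si]
  means <- lapply(subsets, function(s) cbind(
    major = rowMeans(major[, s, drop = FALSE], na.rm = TRUE),
    minor = rowMeans(minor[, s, drop = FALSE], na.rm = TRUE),
    total = rowMeans(total[, s, drop = FALSE], na.rm = TRUE)))
  list(segments = data.frame(
         chrom = as.character(GenomeInfoDb::seqnames(pieces)),
         start = GenomicRanges::start(pieces) - 1,
         end = GenomicRanges::end(pieces)),
       major = major, minor = minor, total = total, means = means)
}

#' Per-locus copy-number comparison between two subsets
#'
#' At every union sub-segment and for each of the major, minor and total
#' statistics, a two-sided Wilcoxon rank-sum test between the two subsets'
#' weighted copy numbers, BH-adjusted across segments within each
#' statistic, with the mean difference as effect. Segments covered by
#' fewer than `support_frac` of the samples in either subset are masked
#' (`supported = FALSE`) and excluded from the adjustment.
#'
#' @param profiles output of [union_profiles()].
#' @param subsets named list of exactly two sample-id vectors.
#' @param support_frac minimum covered-sample fraction per subset (0.25).
#' @return data.frame, one row per segment x statistic.
#' @export
per_locus_tests <- function(profiles, subsets, support_frac = 0.25) {
  stopifnot(length(subsets) == 2)
  g1 <- subsets[[1]]; g2 <- subsets[[2]]
  out <- list()
  for (stat in c("major", "minor", "total")) {
    mat <- profiles[[stat]]
    res <- lapply(seq_len(nrow(mat)), function(i) {
      x <- mat[i, g1]; y <- mat[i, g2]
      sup <- mean(!is.na(x)) >= support_frac &&
        mean(!is.na(y)) >= support_frac
      p <- if (sup && length(unique(stats::na.omit(c(x, y)))) > 1)
        suppressWarnings(stats::wilcox.test(x, y)$p.value) else
          if (sup) 1 else NA_real_
      data.frame(segment = i, statistic = stat, supported = sup,
                 effect = mean(x, na.rm = TRUE) - mean(y, na.rm = TRUE),
                 p = p)
    })
    res <- do.call(rbind, res)
    res$fdr <- NA_real_
    res$fdr[res$supported] <- bh_fdr(res$p[res$supported])
    out[[stat]] <- res
  }
  res <- cbind(profiles$segments[rep(seq_len(nrow(profiles$segments)), 3), ],
               do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Amplification magnitude of a gene locus
#'
#' Sums, over the gained segments overlapping the locus, the weighted major
#' copy number times the overlap length (the gain length capped at the
#' gene), divided by the gene length. Samples with no overlapping gain
#' return `NA` and are excluded from comparisons.
#'
#' @param cohort a `pl_cohort`.
#' @param sample_id one sample.
#' @param locus list or data.frame row with `chrom`, `start`, `end`.
#' @return the magnitude, or `NA` when no gain overlaps the locus.
#' @export
amplification_magnitude <- function(cohort, sample_id, locus) {
  smp <- cohort$samples[cohort$samples$sample_id == sample_id, ]
  seg <- sample_segments(cohort, sample_id)
  if (!nrow(seg)) return(NA_real_)
  cls <- segment_classes(seg, stats::setNames(smp$wgd, sample_id))
  gained <- (cls$state1 == "GAIN" |
               (!is.na(cls$state2) & cls$state2 == "GAIN")) &
    seg$chrom == locus$chrom & seg$start < locus$end & seg$end > locus$start
  if (!any(gained)) return(NA_real_)
  wcn <- weighted_cn(seg[gained, , drop = FALSE])
  ov <- pmin(seg$end[gained], locus$end) - pmax(seg$start[gained], locus$start)
  gene_len <- locus$end - locus$start
  sum(wcn$major * pmin(ov, gene_len) / gene_len)
}

sample_weighted_track <- function(cohort, sample_id, unmasked) {
  seg <- sample_segments(cohort, sample_id)
  if (!nrow(seg))
    return(data.frame(width = numeric(), major = numeric(),
                      minor = numeric()))
  gr <- GenomicRanges::GRanges(seg$chrom,
                               IRanges::IRanges(seg$start + 1, seg$end))
  wcn <- weighted_cn(seg)
  hits <- GenomicRanges::findOverlaps(gr, unmasked)
  qi <- S4Vectors::queryHits(hits)
  inter <- IRanges::pintersect(gr[qi], unmasked[S4Vectors::subjectHits(hits)])
  data.frame(width = IRanges::width(inter),
             major = wcn$major[qi], minor = wcn$minor[qi])
}

#' Copy-number deviation from the baseline state
#'
#' The length-weighted mean, over unmasked autosomal territory, of the
#' absolute deviation of the weighted major and minor copy numbers from
#' the baseline (1+1 in non-WGD samples, 2+2 after WGD). A non-WGD sample
#' whose length-weighted average major is 1.5 (via gains) and minor 0.5
#' (via LOH) scores 1 (0.5 major + 0.5 minor deviation). Territory not
#' covered by any segment is taken as baseline.
#'
#' @param cohort a `pl_cohort`.
#' @param sample_id one sample.
#' @param mask excluded territory; default [default_mask()].
#' @return non-negative deviation score.
#' @export
cn_deviation <- function(cohort, sample_id, mask = NULL) {
  if (is.null(mask)) mask <- default_mask(cohort$genome)
  unmasked <- unmasked_autosomes(cohort$genome, mask)
  total_w <- sum(IRanges::width(unmasked))
  smp <- cohort$samples[cohort$samples$sample_id == sample_id, ]
  base <- if (smp$wgd) 2 else 1
  tr <- sample_weighted_track(cohort, sample_id, unmasked)
  if (!nrow(tr)) return(0)
  sum(tr$width * (abs(tr$major - base) + abs(tr$minor - base))) / total_w
}

#' Latency between the most recent common ancestor and diagnosis
#'
#' Under a constant per-year mutation rate (optionally accelerated by `a`
#' during clonal growth), the years separating the emergence of the MRCA
#' from diagnosis: `L = age_dx * m_post / (a * m_truncal + m_post)` where
#' `m_truncal` counts clonal-cluster mutations and `m_post` the mutations
#' accrued after the MRCA.
#'
#' @param m_truncal clonal (truncal) mutation count.
#' @param m_post post-MRCA mutation count.
#' @param age_dx age at diagnosis, years.
#' @param acceleration mutation-rate acceleration factor `a > 0` (1 = none).
#' @return latency in years (0 when `m_post` is 0).
#' @export
latency <- function(m_truncal, m_post, age_dx, acceleration = 1) {
  stopifnot(m_truncal + m_post > 0, acceleration > 0)
  if (m_post == 0) return(0)
  age_dx * m_post / (acceleration * m_truncal + m_post)
}

# post-MRCA mutation count: in the first enumerated tree, the subclonal
# root-to-leaf path with the largest summed CCF
m_post_mutations <- function(clusters) {
  if (nrow(clusters) < 2) return(0)
  tree <- enumerate_trees(clusters)[[1]]
  ccf <- stats::setNames(clusters$ccf, as.character(clusters$cluster_id))
  nm <- stats::setNames(clusters$n_mutations,
                        as.character(clusters$cluster_id))
  leaves <- setdiff(names(tree), tree)
  best_m <- 0; best_ccf <- -Inf
  for (leaf in leaves) {
    path <- character(0); node <- leaf
    while (!is.na(tree[[node]])) { path <- c(path, node); node <- tree[[node]] }
    if (!length(path)) next
    if (sum(ccf[path]) > best_ccf) {
      best_ccf <- sum(ccf[path])
      best_m <- sum(nm[path])
    }
  }
  best_m
}

#' Per-sample burden metrics
#'
#' Percent genome altered (fraction of unmasked territory whose rounded
#' weighted state differs from 1+1 — the baseline stays diploid, so WGD
#' itself counts as altered), length-weighted ploidy, SNV/SV/kataegis
#' counts passed through, and latency.
#'
#' @param cohort a `pl_cohort`.
#' @param sample_id one sample.
#' @param mask excluded territory; default [default_mask()].
#' @param acceleration latency acceleration factor.
#' @return one-row data.frame: `sample_id`, `snv_count`, `pga`, `ploidy`,
#'   `sv_count`, `kataegis`, `latency_years`.
#' @export
burden_metrics <- function(cohort, sample_id, mask = NULL,
                           acceleration = 1) {
  if (is.null(mask)) mask <- default_mask(cohort$genome)
  unmasked <- unmasked_autosomes(cohort$genome, mask)
  total_w <- sum(IRanges::width(unmasked))
  smp <- cohort$samples[cohort$samples$sample_id == sample_id, ]
  tr <- sample_weighted_track(cohort, sample_id, unmasked)
  altered <- round(tr$major) != 1 | round(tr$minor) != 1
  pga <- sum(tr$width[altered]) / total_w
  ploidy <- if (nrow(tr)) sum(tr$width * (tr$major + tr$minor)) /
    sum(tr$width) else 2
  clus <- cohort$clusters[cohort$clusters$sample_id == sample_id, ]
  lat <- if (nrow(clus)) {
    m_truncal <- clus$n_mutations[which.max(clus$ccf)]
    latency(m_truncal, m_post_mutations(clus), smp$age_dx, acceleration)
  } else NA_real_
  data.frame(sample_id = sample_id, snv_count = smp$snv_total, pga = pga,
             ploidy = ploidy, sv_count = smp$sv_count,
             kataegis = smp$kataegis, latency_years = lat)
}

#' Proportion of aberrant copy-number signature activity
#'
#' CN1 is the baseline signature in non-WGD samples and CN2 after WGD; all
#' other activity is aberrant. Returns `1 - baseline / total`, or `NA`
#' when every activity is zero.
#'
#' @param activities named non-negative numeric vector of CN-signature
#'   activities.
#' @param wgd logical WGD status.
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
aberrant_signature_proportion <- function(activities, wgd) {
  stopifnot(all(activities >= 0))
  total <- sum(activities)
  if (total == 0) return(NA_real_)
  baseline <- if (wgd) "CN2" else "CN1"
  base_act <- if (baseline %in% names(activities)) activities[[baseline]] else 0
  1 - base_act / total
}

#' Genomic-instability multivariate regression with VIF diagnostics
#'
#' Ordinary least squares of the aberrant copy-number signature proportion
#' on driver-gene/WGD indicators, purity, smoking, ancestry and sex (all
#' numeric or 0/1), with per-coefficient 95 percent confidence intervals,
#' variance inflation factors (`1 / (1 - R^2_j)` from regressing each
#' predictor on the others) and the full predictor correlation matrix.
#'
#' @param data data.frame holding the response and predictors.
#' @param response name of the response column.
#' @param predictors names of predictor columns (default: all others).
#' @return list of class `instability_fit`: `coefficients` (term,
#'   estimate, ci_low, ci_high, p), `vif` (named), `correlation`, `model`.
#' @export
instability_regression <- function(data, response = "aberrant",
                                   predictors = NULL) {
  if (is.null(predictors)) predictors <- setdiff(names(data), response)
  stopifnot(nrow(data) > length(predictors) + 1)
  X <- as.matrix(data[predictors])
  storage.mode(X) <- "double"
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    aliased <- predictors[qrX$pivot[seq(qrX$rank + 1,
                                        ncol(X) + 1)] - 1]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(sprintf("`%s`", predictors),
                            response = sprintf("`%s`", response))
  fit <- stats::lm(fml, data = data)
  ci <- stats::confint(fit)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      ci_low = ci[, 1], ci_high = ci[, 2], p = sm[, 4])
  rownames(coefs) <- NULL
  coefs$term <- gsub("`", "", coefs$term)
  vif <- vapply(seq_along(predictors), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  names(vif) <- predictors
  structure(list(coefficients = coefs, vif = vif,
                 correlation = stats::cor(X), model = fit),
            class = "instability_fit")
}
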