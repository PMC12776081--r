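test_that("weighted copy number is the state-fraction expectation", {
  seg <- seg_row("s", "chr1", 0, 10, 2, 1, 0.5, 1, 1, 0.5)
  expect_equal(weighted_cn(seg), data.frame(major = 1.5, minor = 1,
                                            total = 2.5))
  clonal <- seg_row("s", "chr1", 0, 10, 3, 2)
  expect_equal(weighted_cn(clonal)$total, 5)
  seg2 <- seg_row("s", "chr1", 0, 10, 3, 1, 0.3, 1, 1, 0.7)
  expect_equal(weighted_cn(seg2)$total, 0.3 * 4 + 0.7 * 2,
               tolerance = 1e-12)
})

test_that("union profiles tile breakpoints and average subsets", {
  cohort <- two_half_cohort(list(
    a = list(major = c(2, 2), minor = c(1, 1)),
    b = list(major = c(1, 1), minor = c(1, 1))))
  # give sample b one extra breakpoint on chr1
  cohort$segments <- rbind(
    cohort$segments[!(cohort$segments$sample_id == "b" &
                        cohort$segments$chrom == "chr1"), ],
    seg_row("b", "chr1", 0, 30e6, 1, 1),
    seg_row("b", "chr1", 30e6, 50e6, 1, 1),
    seg_row("b", "chr1", 50e6, 100e6, 1, 1))
  prof <- union_profiles(cohort, list(all = c("a", "b")))
  chr1 <- prof$segments$chrom == "chr1"
  expect_identical(sum(chr1), 3L)      # breakpoints at 30, 50 Mb
  expect_equal(unname(prof$means$all[chr1, "major"]), rep(1.5, 3))
  # union pieces tile each chromosome exactly once
  by_chr <- split(prof$segments, prof$segments$chrom)
  for (tab in by_chr)
    expect_equal(sum(tab$end - tab$start), 1e8)
  # identical subsets give identical mean tracks
  prof2 <- union_profiles(cohort, list(x = c("a", "b"), y = c("a", "b")))
  expect_equal(prof2$means$x, prof2$means$y)
  # an all-diploid subset is (1,1,2) everywhere
  prof3 <- union_profiles(cohort, list(d = "b"))
  expect_true(all(prof3$means$d[, "total"] == 2))
})

test_that("per-locus tests mask weak support and detect planted shifts", {
  spec <- c(lapply(sprintf("g1_%02d", 1:8), function(x)
              list(major = c(3, 1), minor = c(1, 1))),
            lapply(sprintf("g2_%02d", 1:8), function(x)
              list(major = c(1, 1), minor = c(1, 1))))
  names(spec) <- c(sprintf("g1_%02d", 1:8), sprintf("g2_%02d", 1:8))
  cohort <- two_half_cohort(spec)
  prof <- union_profiles(cohort, list(g1 = names(spec)[1:8],
                                      g2 = names(spec)[9:16]))
  res <- per_locus_tests(prof, list(g1 = names(spec)[1:8],
                                    g2 = names(spec)[9:16]))
  first_half_major <- res$statistic == "major" & res$start == 0 &
    res$chrom == "chr1"
  expect_equal(res$effect[first_half_major], 2)
  expect_lt(res$fdr[first_half_major], 0.05)
  second_half <- res$statistic == "major" & res$start == 5e7 &
    res$chrom == "chr1"
  expect_gt(res$p[second_half], 0.99)   # identical halves
  # support below 25% in one class is masked
  prof$major[1, names(spec)[1:6]] <- NA  # 2/8 = 25% minus one sample
  prof$major[1, names(spec)[1:7][7]] <- NA
  res2 <- per_locus_tests(prof, list(g1 = names(spec)[1:8],
                                     g2 = names(spec)[9:16]))
  masked <- res2$segment == 1 & res2$statistic == "major"
  expect_false(res2$supported[masked])
  expect_true(is.na(res2$fdr[masked]))
})

test_that("amplification magnitude follows the capped-overlap formula", {
  locus <- list(chrom = "chr1", start = 40e6, end = 60e6)
  base <- flat_sample("s", c(1, 1), c(1, 1))
  cohort <- function(segs) new_cohort(
    base$sample, segs,
    data.frame(sample_id = character(), gene = character(),
               cluster_id = character(), multiplicity = integer()),
    data.frame(sample_id = "s", cluster_id = "C1", ccf = 0.99,
               n_mutations = 10), driver_universe())
  # gain spanning the whole gene at major 6
  segs <- rbind(seg_row("s", "chr1", 0, 100e6, 6, 1),
                base$segments[base$segments$chrom != "chr1", ])
  expect_equal(amplification_magnitude(cohort(segs), "s", locus), 6)
  # gain covering half the gene
  segs <- rbind(seg_row("s", "chr1", 0, 50e6, 6, 1),
                seg_row("s", "chr1", 50e6, 100e6, 1, 1),
                base$segments[base$segments$chrom != "chr1", ])
  expect_equal(amplification_magnitude(cohort(segs), "s", locus), 3)
  # no gain at the locus -> missing
  expect_true(is.na(amplification_magnitude(
    cohort(base$segments), "s", locus)))
})

test_that("copy-number deviation matches its worked example", {
  # half the genome gained 2+1, half 1+0 LOH: 0.5 + 0.5 = 1
  cohort <- two_half_cohort(list(
    s = list(major = c(2, 1), minor = c(1, 0))))
  expect_equal(cn_deviation(cohort, "s"), 1, tolerance = 1e-9)
  # fully baseline profiles score 0, for both WGD states
  flat <- two_half_cohort(list(s = list(major = c(1, 1), minor = c(1, 1))))
  expect_equal(cn_deviation(flat, "s"), 0)
  wgd <- two_half_cohort(list(
    s = list(major = c(2, 2), minor = c(2, 2), wgd = TRUE)))
  expect_equal(cn_deviation(wgd, "s"), 0)
  # invariant to re-splitting a segment into identical halves
  quarter <- two_half_cohort(list(
    s = list(major = c(2, 1), minor = c(1, 0))))
  seg <- quarter$segments
  one <- seg[seg$chrom == "chr1" & seg$start == 0, ]
  split2 <- rbind(transform(one, end = 25e6),
                  transform(one, start = 25e6))
  quarter$segments <- rbind(seg[!(seg$chrom == "chr1" & seg$start == 0), ],
                            split2)
  expect_equal(cn_deviation(quarter, "s"), cn_deviation(cohort, "s"),
               tolerance = 1e-12)
})

test_that("burden metrics: PGA keeps the diploid baseline under WGD", {
  dip <- two_half_cohort(list(s = list(major = c(1, 1), minor = c(1, 1))))
  b <- burden_metrics(dip, "s")
  expect_equal(b$pga, 0)
  expect_equal(b$ploidy, 2)
  half <- two_half_cohort(list(s = list(major = c(2, 1), minor = c(1, 1))))
  b <- burden_metrics(half, "s")
  expect_gt(b$pga, 0.4); expect_lt(b$pga, 0.6)  # ~half the genome gained
  # one extra copy over exactly the altered fraction of the genome
  expect_equal(b$ploidy, 2 + b$pga, tolerance = 1e-9)
  wgd <- two_half_cohort(list(
    s = list(major = c(2, 2), minor = c(2, 2), wgd = TRUE)))
  b <- burden_metrics(wgd, "s")
  expect_equal(b$pga, 1)
  expect_equal(b$ploidy, 4)
})

test_that("latency follows the constant-rate closed form", {
  expect_equal(latency(80, 20, 60, 1), 12)
  expect_equal(latency(80, 0, 60, 1), 0)
  expect_lt(latency(80, 20, 60, 1000), 0.02)   # acceleration kills latency
  expect_gte(latency(10, 1000, 60), 0)
  expect_lte(latency(10, 1000, 60), 60)        # bounded by age at diagnosis
})

test_that("aberrant signature proportion keys the baseline on WGD", {
  expect_equal(aberrant_signature_proportion(c(CN1 = 80, CN9 = 20), FALSE),
               0.2)
  expect_equal(aberrant_signature_proportion(c(CN2 = 100), TRUE), 0)
  expect_equal(aberrant_signature_proportion(c(CN2 = 50, CN1 = 50), FALSE),
               0.5)
  expect_true(is.na(aberrant_signature_proportion(c(CN1 = 0, CN2 = 0),
                                                  TRUE)))
})

test_that("instability regression: VIFs, rank deficiency, recovery", {
  # orthogonal predictors have VIF exactly 1
  X <- expand.grid(a = c(0, 1), b = c(0, 1), c = c(0, 1))
  X$y <- rnorm(8)
  fit <- instability_regression(X, response = "y")
  expect_equal(unname(fit$vif), rep(1, 3), tolerance = 1e-12)
  expect_true(all(diag(fit$correlation) == 1))
  expect_equal(fit$correlation, t(fit$correlation))
  # duplicated predictor columns abort with the offender named
  X$b2 <- X$b
  expect_error(instability_regression(X, response = "y"),
               "collinear")
  # planted +0.2 effect at n = 400 lands inside its own 95% CI
  set.seed(14)
  n <- 400
  df <- data.frame(G = rbinom(n, 1, 0.4), wgd = rbinom(n, 1, 0.5),
                   purity = runif(n, 0.3, 0.9), smoking = rbinom(n, 1, 0.3))
  df$aberrant <- 0.1 + 0.2 * df$G + 0.05 * df$wgd + rnorm(n, 0, 0.1)
  fit <- instability_regression(df, response = "aberrant")
  g <- fit$coefficients[fit$coefficients$term == "G", ]
  expect_lt(g$ci_low, 0.2)
  expect_gt(g$ci_high, 0.2)
  expect_true(all(fit$vif >= 1))
  # independent route: car's VIF on the same model
  expect_equal(unname(fit$vif),
               unname(car::vif(fit$model)), tolerance = 1e-8)
})
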