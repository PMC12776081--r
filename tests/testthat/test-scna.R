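test_that("SCNA classes are conditioned on WGD and mutually exclusive", {
  expect_identical(classify_scna(2, 1, FALSE), "GAIN")
  expect_identical(classify_scna(2, 1, TRUE), "NON_LOH_LOSS")
  expect_identical(classify_scna(0, 0, FALSE), "HD")
  expect_identical(classify_scna(0, 0, TRUE), "HD")
  expect_identical(classify_scna(1, 1, FALSE), "NONE")
  expect_identical(classify_scna(1, 0, FALSE), "LOH")
  expect_identical(classify_scna(3, 0, FALSE), "LOH")   # LOH beats total
  expect_identical(classify_scna(3, 1, TRUE), "NONE")   # at WGD baseline
  # total and deterministic over a grid: exactly one class each
  grid <- expand.grid(major = 0:6, minor = 0:6, wgd = c(TRUE, FALSE))
  grid <- grid[grid$minor <= grid$major, ]
  cls <- classify_scna(grid$major, grid$minor, grid$wgd)
  expect_true(all(cls %in% c("GAIN", "LOH", "NON_LOH_LOSS", "HD", "NONE")))
  expect_identical(cls, classify_scna(grid$major, grid$minor, grid$wgd))
  expect_error(classify_scna(-1, 0, FALSE), "negative")
})

test_that("WGD timing by parsimony matches the exhaustive-history oracle", {
  for (M in 0:6) for (m in 0:M) {
    if (M == 1 && m == 1) next     # diploid state carries no SCNA to time
    expect_identical(classify_wgd_timing(M, m), oracle_wgd_timing(M, m),
                     label = sprintf("state (%d,%d)", M, m))
  }
  expect_identical(classify_wgd_timing(2, 1), "LATE_CLONAL")
  expect_identical(classify_wgd_timing(2, 0), "EARLY_CLONAL")
  expect_identical(classify_wgd_timing(4, 2), "EARLY_CLONAL")
  expect_identical(classify_wgd_timing(3, 2), "LATE_CLONAL")
  expect_identical(classify_wgd_timing(1, 0), "EARLY_CLONAL")
  expect_error(classify_wgd_timing(2, 1, wgd = FALSE), "WGD")
})

test_that("filter masks drop HLA / sex-chromosome bins, keep clean bins", {
  mask <- default_mask()
  bins <- GenomicRanges::GRanges(
    c("chr6", "chrX", "chr1"),
    IRanges::IRanges(c(12.0e6, 5e6, 60e6) + 1, c(12.5e6, 6e6, 61e6)))
  kept <- apply_filters(bins, mask, "drop")
  expect_identical(as.character(GenomeInfoDb::seqnames(kept)), "chr1")
  # intersect mode trims segments to unmasked territory
  seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10e6))
  trimmed <- apply_filters(seg, mask, "intersect")
  expect_equal(GenomicRanges::start(trimmed), 5e6 + 1)  # telomere clipped
})

test_that("a BED file can replace the built-in mask", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t5000000", "1\t7000000\t8000000",
               "chrX\t0\t100000000"), path)
  mask <- read_mask_bed(path)
  expect_length(mask, 3L)   # "1" normalised to "chr1", kept separate
  bin <- GenomicRanges::GRanges("chr1", IRanges::IRanges(7.2e6, 7.4e6))
  expect_length(apply_filters(bin, mask, "drop"), 0L)
})

test_that("binomial recurrence tail matches direct summation", {
  expect_equal(binomial_recurrence_p(0, 100, 0.05), 1.0)
  expect_equal(binomial_recurrence_p(20, 20, 0.5), 0.5^20, tolerance = 1e-15)
  expect_equal(binomial_recurrence_p(20, 100, 0.05),
               oracle_binom_upper(20, 100, 0.05), tolerance = 1e-12)
  for (k in c(1, 3, 7)) {
    expect_equal(binomial_recurrence_p(k, 30, 0.2),
                 oracle_binom_upper(k, 30, 0.2), tolerance = 1e-12)
  }
  expect_error(binomial_recurrence_p(1, 10, 1.2), "p_bar")
})

make_scan_fixture <- function(n = 100, n_gain = 60) {
  # n samples on the mini genome; n_gain share an identical 10 Mb gain on
  # chr1, everyone has a small scattered gain elsewhere as background
  genome <- mini_genome()
  rows <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("P%03d", i)
    for (ci in seq_len(nrow(genome))) {
      chrom <- genome$chrom[ci]; L <- genome$length[ci]
      segs <- data.frame(start = 0, end = L, major1 = 1, minor1 = 1)
      if (chrom == "chr1" && i <= n_gain) {
        segs <- data.frame(start = c(0, 60e6, 70e6), end = c(60e6, 70e6, L),
                           major1 = c(1, 2, 1), minor1 = c(1, 1, 1))
      }
      if (chrom == "chr2") {        # per-sample background gain, ~2 Mb
        s0 <- 10e6 + (i %% 37) * 2e6
        segs <- data.frame(start = c(0, s0, s0 + 2e6), end = c(s0, s0 + 2e6, L),
                           major1 = c(1, 2, 1), minor1 = c(1, 1, 1))
      }
      segs$sample_id <- sid; segs$chrom <- chrom
      segs$frac1 <- 1; segs$major2 <- NA_real_; segs$minor2 <- NA_real_
      segs$frac2 <- NA_real_
      rows[[length(rows) + 1L]] <- segs
    }
  }
  samples <- data.frame(
    sample_id = sprintf("P%03d", seq_len(n)), purity = 0.7, nrpcc = 20,
    wgd = FALSE, smoking = "never", ancestry = "EUR", sex = "F",
    age_dx = 60, sbs4 = FALSE, sv_count = 0L, kataegis = 0L,
    snv_total = 1000, survival_weeks = NA_real_)
  new_cohort(samples, do.call(rbind, rows),
             data.frame(sample_id = character(), gene = character(),
                        cluster_id = character(), multiplicity = integer()),
             data.frame(sample_id = samples$sample_id, cluster_id = "C1",
                        ccf = 0.99, n_mutations = 1000),
             driver_universe())
}

test_that("recurrence scan finds a shared gain against a low background", {
  cohort <- make_scan_fixture()
  scan <- scan_recurrent_scnas(cohort)
  gains <- scan$regions[scan$regions$class == "GAIN"]
  locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(60e6 + 1, 70e6))
  expect_true(any(IRanges::overlapsAny(gains, locus)))
  # scattered 2 Mb background gains on chr2 are not called
  expect_false(any(as.character(GenomeInfoDb::seqnames(scan$regions)) ==
                     "chr2"))
  # regions never overlap the mask
  expect_false(any(IRanges::overlapsAny(scan$regions,
                                        default_mask(cohort$genome))))
  # invariant to sample order
  perm <- subset_cohort(cohort, rev(cohort$samples$sample_id))
  scan2 <- scan_recurrent_scnas(perm)
  expect_identical(as.data.frame(scan$regions), as.data.frame(scan2$regions))
})

test_that("scan of a class-free cohort returns nothing", {
  cohort <- make_scan_fixture(n = 10, n_gain = 0)
  cohort$segments$major1 <- 1   # erase even the background gains
  scan <- scan_recurrent_scnas(cohort)
  expect_identical(length(scan$regions), 0L)
})

test_that("scan recovers planted SCNA loci on the synthetic cohort", {
  sim <- shared_sim()
  scan <- scan_recurrent_scnas(sim$cohort)
  planted <- default_archetypes()[[1]]$events
  planted <- planted[planted$kind %in% c("GAIN", "LOH", "HD"), ]
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    locus <- GenomicRanges::GRanges(
      planted$chrom[i], IRanges::IRanges(planted$start[i] + 1, planted$end[i]))
    same <- scan$regions[scan$regions$class == planted$kind[i]]
    any(IRanges::overlapsAny(same, locus))
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("catalog applies the inclusive 3% SNV prevalence rule", {
  cohort <- make_scan_fixture(n = 100, n_gain = 0)
  # plant SNVs: geneA in 2 samples (2%), geneB in 3 samples (3%)
  cohort$snvs <- data.frame(
    sample_id = sprintf("P%03d", 1:5),
    gene = c("TP53", "TP53", "KRAS", "KRAS", "KRAS"),
    cluster_id = "C1", multiplicity = 1L)
  catalog <- build_catalog(cohort, GenomicRanges::GRanges(),
                           min_snv_prev = 0.03)
  expect_false("SNV_TP53" %in% catalog$event_id)
  expect_true("SNV_KRAS" %in% catalog$event_id)
  expect_true("WGD" %in% catalog$event_id)
})

test_that("event presence reports clonality, timing and cluster links", {
  cohort <- tiny_cohort()
  catalog <- data.frame(
    event_id = c("LOH_chr2", "SNV_TP53", "SNV_KRAS", "GAIN_chr1", "WGD"),
    kind = c("LOH", "SNV", "SNV", "GAIN", "WGD"),
    chrom = c("chr2", NA, NA, "chr1", NA),
    start = c(10e6, NA, NA, 10e6, NA), end = c(90e6, NA, NA, 90e6, NA),
    gene = c(NA, "TP53", "KRAS", NA, NA), prevalence = NA_real_)
  # S1 (WGD): chr2 is clonal 4+2 -> GAIN, not LOH; chr1 2+2 -> NONE
  p1 <- event_presence(cohort, "S1", catalog)
  expect_setequal(p1$event_id, c("SNV_TP53", "WGD"))
  expect_identical(p1$timing[p1$event_id == "SNV_TP53"], "EARLY_CLONAL")
  # S2 (non-WGD): chr1 has subclonal 2+1 gain at CCF 0.6 -> cluster S1
  p2 <- event_presence(cohort, "S2", catalog)
  gain <- p2[p2$event_id == "GAIN_chr1", ]
  expect_identical(gain$clonality, "SUBCLONAL")
  expect_identical(gain$cluster_id, "S1")
  snv <- p2[p2$event_id == "SNV_KRAS", ]
  expect_identical(snv$clonality, "SUBCLONAL")  # CCF 0.6 < clonal band
  # a sample carrying nothing yields an empty set
  none <- catalog[catalog$event_id == "LOH_chr2", ]
  expect_identical(nrow(event_presence(cohort, "S1", none)), 0L)
})

test_that("clonal early LOH in a WGD sample is timed early", {
  cohort <- tiny_cohort()
  cohort$segments[1, c("major1", "minor1")] <- c(2, 0)  # chr1 of S1
  catalog <- data.frame(event_id = "LOH_chr1", kind = "LOH", chrom = "chr1",
                        start = 10e6, end = 90e6, gene = NA_character_,
                        prevalence = NA_real_)
  p <- event_presence(cohort, "S1", catalog, min_overlap_frac = 0.5)
  expect_identical(p$clonality, "CLONAL")
  expect_identical(p$timing, "EARLY_CLONAL")
})
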