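test_that("two-tailed Fisher matches hypergeometric enumeration", {
  expect_equal(fisher_two_tailed(rbind(c(1, 1), c(1, 1))), 1.0)
  expect_equal(fisher_two_tailed(rbind(c(5, 0), c(0, 5))), 1 / 126,
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    p <- fisher_two_tailed(tab)
    expect_equal(p, oracle_fisher_two_tailed(tab), tolerance = 1e-12)
    expect_equal(p, fisher_two_tailed(t(tab)), tolerance = 1e-12)
    # independent route: R's own exact test
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("odds and risk ratios reproduce the SBS4 worked example", {
  tab <- rbind(c(9, 8), c(65, 324))   # SBS4+/- vs SD/NSD among NS tumours
  expect_equal(risk_ratio(tab), (9 / 17) / (65 / 389), tolerance = 1e-12)
  expect_equal(round(risk_ratio(tab), 2), 3.17)
  expect_equal(odds_ratio(rbind(c(1, 1), c(1, 1))), 1)
  expect_equal(risk_ratio(rbind(c(1, 1), c(1, 1))), 1)
  # Haldane correction keeps zero-cell tables finite
  expect_equal(odds_ratio(rbind(c(5, 0), c(2, 3))),
               (5.5 * 3.5) / (0.5 * 2.5))
  expect_warning(rr <- risk_ratio(rbind(c(0, 0), c(2, 3))), "undefined")
  expect_true(is.na(rr))
})

test_that("BH adjustment matches the reference step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  step_up <- function(p) {           # reference implementation
    n <- length(p); o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(n / (n:1) * p[o]))
    adj[order(o)]
  }
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_fdr(p), step_up(p), tolerance = 1e-12)
    expect_true(all(diff(bh_fdr(sort(p))) >= -1e-15))
  }
})

test_that("event enrichment flags substantial trajectory-specific events", {
  set.seed(21)
  n <- 120
  labels <- stats::setNames(rep(c("SD", "NSD_L", "NSD_G"), each = n / 3),
                            sprintf("s%03d", 1:n))
  pres <- cbind(
    sd_only = c(rep(TRUE, 40), rep(FALSE, 80)),
    balanced = stats::runif(n) < 0.5)
  rownames(pres) <- names(labels)
  res <- event_enrichment(pres, labels,
                          list("SD", c("NSD_L", "NSD_G")))
  sd_row <- res[res$item == "sd_only", ]
  expect_true(sd_row$flagged)
  expect_gt(sd_row$odds_ratio, 3 / 2)
  expect_false(res$flagged[res$item == "balanced"])
  expect_error(event_enrichment(pres, labels, list("SD", "absent")),
               "no samples")
})

test_that("driver-count test reproduces the 45 vs 13/16 contrast", {
  genes <- driver_universe()
  subset_genes <- list(SD = genes[1:45], NSD_L = genes[1:13],
                       NSD_G = genes[1:16])
  res <- driver_count_test(subset_genes, universe_size = 72)
  expect_lt(res$fdr[res$trajectory == "SD"], 0.05)
  # equal counts give a null result
  eq <- driver_count_test(list(A = genes[1:20], B = genes[1:20],
                               C = genes[1:20]), 72)
  expect_equal(eq$p, rep(1, 3), tolerance = 1e-12)
  add <- driver_count_test(subset_genes, 72, pooling = "additive")
  expect_lt(add$fdr[add$trajectory == "SD"], 0.05)
})

test_that("co-occurrence tails are exact hypergeometric sums", {
  pres <- matrix(FALSE, 10, 2, dimnames = list(NULL, c("A", "B")))
  pres[1:5, "A"] <- TRUE; pres[1:5, "B"] <- TRUE
  res <- cooccurrence(pres)
  expect_equal(res$p_greater, 1 / 252, tolerance = 1e-12)
  expect_equal(res$p_greater, oracle_hyper_upper(5, 5, 5, 10),
               tolerance = 1e-12)
  set.seed(3)
  for (i in 1:10) {
    N <- 30; nA <- sample(5:20, 1); nB <- sample(5:20, 1)
    m <- matrix(FALSE, N, 2, dimnames = list(NULL, c("A", "B")))
    m[sample(N, nA), 1] <- TRUE; m[sample(N, nB), 2] <- TRUE
    j <- sum(m[, 1] & m[, 2])
    r <- cooccurrence(m)
    expect_equal(r$p_greater, oracle_hyper_upper(j, nA, nB, N),
                 tolerance = 1e-12)
    expect_equal(r$p_less, oracle_hyper_lower(j, nA, nB, N),
                 tolerance = 1e-12)
  }
  # overlap at its expectation leaves both tails above one half
  pres <- matrix(FALSE, 20, 2, dimnames = list(NULL, c("A", "B")))
  pres[1:10, "A"] <- TRUE; pres[c(1:5, 11:15), "B"] <- TRUE  # j = E[X] = 5
  r <- cooccurrence(pres)
  expect_gte(r$p_greater, 0.5)
  expect_gte(r$p_less, 0.5)
})

test_that("clonality preference flags an always-clonal event", {
  clon <- rbind(
    data.frame(event_id = "E", clonality = rep("CLONAL", 30)),
    data.frame(event_id = paste0("o", 1:4),
               clonality = rep(c("CLONAL", "SUBCLONAL"), each = 2 * 30)))
  res <- clonality_preference(clon)
  e_row <- res[res$item == "E", ]
  expect_gt(e_row$odds_ratio, 1)
  expect_lt(e_row$fdr, 0.05)
  # uniform clonality rates stay null
  null <- data.frame(event_id = rep(c("A", "B"), each = 40),
                     clonality = rep(c("CLONAL", "SUBCLONAL"), 40))
  expect_true(all(clonality_preference(null)$fdr > 0.9))
})

test_that("pre-WGD proportions and their Wilcoxon comparison behave", {
  rks <- list(
    w1 = c("a", "b", "WGD", "c"), w2 = c("WGD", "a", "b", "c"),
    w3 = c("a", "b", "c", "WGD", "d"), w4 = c("a", "WGD", "b", "c"))
  fake <- structure(list(iterations = list(rks)), class = "pl_rankings")
  labels <- c(w1 = "T1", w2 = "T1", w3 = "T2", w4 = "T2")
  res <- prewgd_proportion_test(fake, labels, names(rks), c("T1", "T2"))
  expect_equal(res$per_sample$proportion,
               c(2 / 3, 0, 3 / 4, 1 / 3), tolerance = 1e-12)
  expect_true(res$p > 0 && res$p <= 1)
  # identical distributions give p near 1; Wilcoxon agrees with an exact
  # permutation oracle on small samples
  x <- c(0.1, 0.4, 0.7); y <- c(0.2, 0.5, 0.8)
  w <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  perm_p <- {
    pool <- c(x, y); stat <- sum(rank(pool)[1:3])
    combs <- utils::combn(6, 3)
    stats_all <- apply(combs, 2, function(ix) sum(rank(pool)[ix]))
    mean(abs(stats_all - mean(stats_all)) >= abs(stat - mean(stats_all)))
  }
  expect_equal(w, perm_p, tolerance = 1e-12)
  none <- prewgd_proportion_test(fake, labels, character(0), c("T1", "T2"))
  expect_true(is.na(none$p))
})

test_that("signature presence enrichment recovers a planted signature", {
  sig <- data.frame(sample_id = sprintf("s%02d", 1:40),
                    SV5 = c(runif(20, 10, 50), rep(0, 20)),
                    CN1 = runif(40, 10, 50), DEAD = 0)
  labels <- stats::setNames(rep(c("SD", "NSD"), each = 20), sig$sample_id)
  expect_warning(res <- signature_presence_test(sig, labels,
                                                list("SD", "NSD")),
                 "all-zero")
  expect_true(res$flagged[res$item == "SV5"])
  expect_false("DEAD" %in% res$item)
})

test_that("demographic comparison applies stratum filters", {
  sim <- shared_sim()
  labels <- stats::setNames(
    ifelse(sim$truth$samples$archetype == "ASD", "T3",
           ifelse(sim$truth$samples$archetype == "ALoss", "T1", "T2")),
    sim$truth$samples$sample_id)
  out <- demographic_comparison(sim$cohort, labels, "smoking",
                                sd_labels = "T3",
                                levels = c("ever", "never"))
  expect_gt(out$result$risk_ratio, 1)   # smokers enriched on the SD-like arm
  expect_equal(sum(out$proportions["ever", ]), 1, tolerance = 1e-12)
  # ancestry comparison restricted to never-smokers
  out2 <- demographic_comparison(
    sim$cohort, labels, "ancestry", sd_labels = "T3",
    levels = c("EUR", "EAS"),
    subset_filter = function(s) s$smoking == "never")
  expect_s3_class(out2$result, "data.frame")
  expect_error(demographic_comparison(
    sim$cohort, labels, "ancestry", sd_labels = "T3",
    levels = c("EUR", "MARTIAN")), "absent")
})
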