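test_that("single-ranking log-likelihood has its closed forms", {
  expect_equal(pl_loglik(c("A", "B"), c(A = 0.5, B = 0.5)), log(0.5))
  expect_equal(pl_loglik(c("A", "B", "C"),
                         c(A = 0.5, B = 0.25, C = 0.25)), log(0.25))
  expect_equal(pl_loglik("A", c(A = 1)), 0)
  expect_error(pl_loglik(c("A", "B"), c(A = 1)), "worth")
  expect_error(pl_loglik("A", c(A = -1)), "positive")
})

test_that("MM fit recovers the paired-comparison MLE and symmetries", {
  rks <- c(rep(list(c("A", "B")), 3), list(c("B", "A")))
  fit <- fit_pl(rks, prior_pseudocount = 0)
  expect_equal(unname(fit$worths[c("A", "B")]), c(0.75, 0.25),
               tolerance = 1e-6)
  # symmetric data -> uniform worths
  sym <- list(c("A", "B", "C"), c("B", "C", "A"), c("C", "A", "B"),
              c("C", "B", "A"), c("B", "A", "C"), c("A", "C", "B"))
  fit <- fit_pl(sym, prior_pseudocount = 0)
  expect_equal(unname(fit$worths), rep(1 / 3, 3), tolerance = 1e-6)
  # the recorded objective never decreases
  expect_true(all(diff(fit$trace) >= -1e-10))
})

test_that("MM log-likelihood matches a simplex pattern search", {
  set.seed(42)
  for (m in 3:5) {
    items <- LETTERS[seq_len(m)]
    true_w <- stats::setNames(exp(-0.5 * seq_len(m)), items)
    rks <- replicate(8, {
      sub <- sample(items, sample(2:m, 1))
      # draw a full order of the subset by sequential worth sampling
      out <- character(0)
      w <- true_w[sub]
      while (length(w)) {
        pick <- sample(seq_along(w), 1, prob = w)
        out <- c(out, names(w)[pick]); w <- w[-pick]
      }
      out
    }, simplify = FALSE)
    rks <- rks[lengths(rks) > 1]
    fit <- suppressWarnings(fit_pl(rks, prior_pseudocount = 0, tol = 1e-10))
    oracle <- oracle_pl_gridsearch(rks, fit$items)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-3,
                 label = sprintf("m=%d fit loglik", m))
    expect_gte(fit$loglik, oracle$loglik - 1e-4)
  }
})

test_that("disconnected comparison data demand a pseudocount", {
  rks <- list(c("A", "B"), c("A", "B"), c("C", "D"))
  expect_error(fit_pl(rks, prior_pseudocount = 0), "pseudocount")
  fit <- fit_pl(rks, prior_pseudocount = 0.1)
  expect_true(all(fit$worths > 0))
  expect_equal(sum(fit$worths), 1, tolerance = 1e-9)
})

test_that("mixture with K = 1 reduces exactly to the plain fit", {
  sim <- shared_sim()
  catalog <- build_catalog(sim$cohort,
                           scan_recurrent_scnas(sim$cohort)$regions)
  rk <- order_cohort(sim$cohort, catalog, n_iterations = 1, seed = 2)
  rankings <- rk$iterations[[1]]
  plain <- fit_pl(rankings)
  mix <- fit_pl_mixture(rankings, K = 1)
  expect_equal(mix$loglik, plain$loglik, tolerance = 1e-9)
  m <- length(plain$items)
  expect_equal(mix$bic, -2 * plain$loglik + (m - 1) * log(length(rankings)),
               tolerance = 1e-9)
})

test_that("mixture separates two well-separated ranking populations", {
  set.seed(11)
  items <- LETTERS[1:8]
  w1 <- stats::setNames(exp(-1.2 * (1:8)), items)
  w2 <- stats::setNames(rev(w1), items)
  draw <- function(w) {
    out <- character(0)
    while (length(w)) {
      pick <- sample(seq_along(w), 1, prob = w)
      out <- c(out, names(w)[pick]); w <- w[-pick]
    }
    out
  }
  rks <- c(replicate(40, draw(w1), simplify = FALSE),
           replicate(40, draw(w2), simplify = FALSE))
  names(rks) <- sprintf("r%02d", seq_along(rks))
  fit <- fit_pl_mixture(rks, K = 2, n_restarts = 3, seed = 4)
  top <- apply(fit$responsibilities, 1, max)
  expect_gte(mean(top >= 0.95), 0.95)
  # MAP assignment separates the two populations
  map <- max.col(fit$responsibilities)
  expect_true(all(map[1:40] == map[1]), info = "population 1 coherent")
  expect_true(all(map[41:80] == map[41]))
  expect_false(map[1] == map[41])
  # label-swap invariance: permuting components leaves the loglik unchanged
  ll <- function(weights, comps) {
    sum(vapply(rks, function(r) {
      lks <- vapply(comps, function(w) pl_loglik(r, w), numeric(1))
      mx <- max(lks + log(weights))
      mx + log(sum(exp(lks + log(weights) - mx)))
    }, numeric(1)))
  }
  expect_equal(ll(fit$weights, fit$components),
               ll(rev(fit$weights), rev(fit$components)), tolerance = 1e-9)
  # EM objective trace is monotone
  expect_true(all(diff(fit$trace) >= -1e-8))
})

test_that("BIC selection finds one component in single-archetype data", {
  arch <- default_archetypes()[2]
  sim <- simulate_cohort(arch, n_per_archetype = 50, seed = 31, noise = 0.1)
  catalog <- build_catalog(sim$cohort,
                           scan_recurrent_scnas(sim$cohort)$regions)
  rk <- order_cohort(sim$cohort, catalog, n_iterations = 4, seed = 13)
  sel <- select_k(rk, k_max = 3, n_restarts = 2, seed = 17)
  expect_identical(sel$selected_k, 1L)
})

test_that("consolidation is idempotent and label-permutation invariant", {
  resp <- matrix(c(0.9, 0.1, 0.8, 0.2, 0.1, 0.9), ncol = 2, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), NULL))
  fit <- list(K = 2L, responsibilities = resp)
  out1 <- consolidate_assignments(list(fit, fit, fit))
  expect_identical(unname(out1$labels), c("T1", "T1", "T2"))
  # permuting another iteration's labels changes nothing after alignment
  fit_sw <- list(K = 2L, responsibilities = resp[, 2:1])
  out2 <- consolidate_assignments(list(fit, fit_sw, fit))
  expect_identical(out1$labels, out2$labels)
  out3 <- consolidate_assignments(list(fit), unclassifiable = "z")
  expect_identical(unname(out3$labels["z"]), "UNCLASSIFIABLE")
})

test_that("aggregate ordering summarises a deterministic subset", {
  # every sample ranks A first, then B/C in mixed order
  rks <- list(s1 = c("A", "B", "C"), s2 = c("A", "C", "B"),
              s3 = c("A", "B", "C"), s4 = c("A", "B"))
  fake <- structure(list(items = c("A", "B", "C"),
                         sample_ids = names(rks),
                         unclassifiable = character(0),
                         iterations = list(rks, rks, rks)),
                    class = "pl_rankings")
  agg <- aggregate_ordering(fake, names(rks))
  expect_identical(agg$event_id[1], "A")
  expect_equal(agg$median_rank[1], 1)
  expect_equal(agg$ci_low[1], 1)
  expect_equal(agg$ci_high[1], 1)
  expect_equal(agg$prevalence[agg$event_id == "C"], 0.75)
  expect_error(aggregate_ordering(fake, "s1"), "at least 2")
})
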