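# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: timing is checked by exhaustive enumeration of event
# histories, exact tests by direct probability summation, and the
# Plackett-Luce MLE by a refining pattern search on the worth simplex.

# --- exhaustive WGD-timing oracle ---------------------------------------
# Shortest event histories by exhaustive relaxation over the full state
# space (allele pair, doubled yet, any step taken before doubling): steps
# are +/-1 on a single allele (never regained from 0, cost 1) and one
# doubling (an event, cost 0). Returns the minimal step count over
# histories whose first step precedes the doubling and over histories
# with no pre-doubling step.
oracle_wgd_counts <- function(major, minor, amax = 14L) {
  target <- sort(c(major, minor))
  # dist[a+1, b+1, doubled+1, pre+1]
  dist <- array(Inf, dim = c(amax + 1, amax + 1, 2, 2))
  dist[2, 2, 1, 1] <- 0                     # (1,1), not doubled, no pre step
  repeat {
    prev <- dist
    for (a in 0:amax) for (b in 0:amax) for (dd in 0:1) for (pre in 0:1) {
      d <- dist[a + 1, b + 1, dd + 1, pre + 1]
      if (!is.finite(d)) next
      relax <- function(a2, b2, dd2, pre2, cost) {
        i <- c(a2 + 1, b2 + 1, dd2 + 1, pre2 + 1)
        if (d + cost < dist[i[1], i[2], i[3], i[4]])
          dist[i[1], i[2], i[3], i[4]] <<- d + cost
      }
      if (dd == 0 && 2 * a <= amax && 2 * b <= amax)
        relax(2 * a, 2 * b, 1, pre, 0)
      for (mv in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        a2 <- a + mv[1]; b2 <- b + mv[2]
        if (a2 < 0 || b2 < 0 || a2 > amax || b2 > amax) next
        if ((mv[1] == 1 && a == 0) || (mv[2] == 1 && b == 0)) next
        relax(a2, b2, dd, if (dd == 0) 1 else pre, 1)
      }
    }
    if (identical(prev, dist)) break
  }
  at <- function(pre) min(dist[target[2] + 1, target[1] + 1, 2, pre + 1],
                          dist[target[1] + 1, target[2] + 1, 2, pre + 1])
  c(early = at(1), late = at(0))
}

oracle_wgd_timing <- function(major, minor) {
  cnt <- oracle_wgd_counts(major, minor)
  if (cnt[["early"]] <= cnt[["late"]]) "EARLY_CLONAL" else "LATE_CLONAL"
}

# --- exact tail-sum oracles ---------------------------------------------
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

oracle_hyper_pmf <- function(j, nA, nB, N) {
  choose(nA, j) * choose(N - nA, nB - j) / choose(N, nB)
}

oracle_hyper_upper <- function(j, nA, nB, N) {
  hi <- min(nA, nB)
  if (j > hi) return(0)
  sum(vapply(j:hi, oracle_hyper_pmf, numeric(1), nA = nA, nB = nB, N = N))
}

oracle_hyper_lower <- function(j, nA, nB, N) {
  lo <- max(0, nA + nB - N)
  if (j < lo) return(0)
  sum(vapply(lo:j, oracle_hyper_pmf, numeric(1), nA = nA, nB = nB, N = N))
}

# two-sided Fisher by enumerating all tables with the observed margins
oracle_fisher_two_tailed <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_; n <- b + d; k <- a + b; N <- m + n
  support <- max(0, k - n):min(k, m)
  pmf <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(N, k), numeric(1))
  obs <- pmf[match(a, support)]
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# --- independent Plackett-Luce log-likelihood and MLE search ------------
oracle_pl_loglik <- function(rankings, worths) {
  total <- 0
  for (r in rankings) {
    w <- unname(worths[r])
    for (j in seq_along(w))
      total <- total + log(w[j] / sum(w[j:length(w)]))
  }
  total
}

# refining pattern search over the worth simplex: coarse grid, then local
# grids shrinking around the incumbent
oracle_pl_gridsearch <- function(rankings, items, steps = 6) {
  m <- length(items)
  best_w <- rep(1 / m, m)
  names(best_w) <- items
  best_ll <- oracle_pl_loglik(rankings, best_w)
  delta <- 0.2
  for (s in seq_len(steps)) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_len(m)) for (sign in c(-1, 1)) {
        w <- best_w
        w[i] <- max(w[i] + sign * delta, 1e-6)
        w <- w / sum(w)
        ll <- oracle_pl_loglik(rankings, w)
        if (ll > best_ll + 1e-12) {
          best_ll <- ll; best_w <- w; improved <- TRUE
        }
      }
    }
    delta <- delta / 4
  }
  list(worths = best_w, loglik = best_ll)
}

# --- small fixtures ------------------------------------------------------
# a hand-built two-sample cohort over the miniature genome
tiny_cohort <- function() {
  samples <- data.frame(
    sample_id = c("S1", "S2"), purity = c(0.8, 0.5), nrpcc = c(20, 15),
    wgd = c(TRUE, FALSE), smoking = c("never", "ever"),
    ancestry = c("EUR", "EAS"), sex = c("F", "M"), age_dx = c(60, 70),
    sbs4 = c(FALSE, TRUE), sv_count = c(10L, 5L), kataegis = c(1L, 0L),
    snv_total = c(5000, 8000), survival_weeks = c(200, NA))
  segments <- data.frame(
    sample_id = c("S1", "S1", "S2"),
    chrom = c("chr1", "chr2", "chr1"),
    start = c(0, 0, 0), end = c(1e8, 1e8, 1e8),
    major1 = c(2, 4, 2), minor1 = c(2, 2, 1), frac1 = c(1, 1, 0.6),
    major2 = c(NA, NA, 1), minor2 = c(NA, NA, 1), frac2 = c(NA, NA, 0.4))
  clusters <- data.frame(
    sample_id = c("S1", "S2", "S2"), cluster_id = c("C1", "C1", "S1"),
    ccf = c(0.98, 0.97, 0.6), n_mutations = c(4000, 6000, 2000))
  snvs <- data.frame(
    sample_id = c("S1", "S2"), gene = c("TP53", "KRAS"),
    cluster_id = c("C1", "S1"), multiplicity = c(2L, 1L))
  new_cohort(samples, segments, snvs, clusters, driver_universe())
}

# cached medium synthetic cohort shared by several test files
sim_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(sim_cache$sim))
    sim_cache$sim <- simulate_cohort(default_archetypes(),
                                     n_per_archetype = 30, seed = 202,
                                     noise = 0.1)
  sim_cache$sim
}

# --- flat-profile cohort builders (used by genome & acceptance tests) ---
seg_row <- function(sid, chrom, start, end, M1, m1, f1 = 1,
                    M2 = NA, m2 = NA, f2 = NA)
  data.frame(sample_id = sid, chrom = chrom, start = start, end = end,
             major1 = M1, minor1 = m1, frac1 = f1,
             major2 = M2, minor2 = m2, frac2 = f2)

flat_sample <- function(sid, major_by_half, minor_by_half, wgd = FALSE) {
  genome <- mini_genome()
  segs <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    rbind(seg_row(sid, genome$chrom[i], 0, L / 2,
                  major_by_half[1], minor_by_half[1]),
          seg_row(sid, genome$chrom[i], L / 2, L,
                  major_by_half[2], minor_by_half[2]))
  }))
  list(sample = data.frame(
         sample_id = sid, purity = 0.8, nrpcc = 20, wgd = wgd,
         smoking = "never", ancestry = "EUR", sex = "F", age_dx = 60,
         sbs4 = FALSE, sv_count = 0L, kataegis = 0L, snv_total = 1000,
         survival_weeks = NA_real_),
       segments = segs)
}

two_half_cohort <- function(spec) {
  parts <- lapply(names(spec), function(sid)
    flat_sample(sid, spec[[sid]]$major, spec[[sid]]$minor,
                isTRUE(spec[[sid]]$wgd)))
  new_cohort(do.call(rbind, lapply(parts, `[[`, "sample")),
             do.call(rbind, lapply(parts, `[[`, "segments")),
             data.frame(sample_id = character(), gene = character(),
                        cluster_id = character(), multiplicity = integer()),
             data.frame(sample_id = names(spec), cluster_id = "C1",
                        ccf = 0.99, n_mutations = 1000),
             driver_universe())
}

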