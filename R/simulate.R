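#' Candidate driver-gene universe used by the synthetic cohort
#'
#' 72 lung-adenocarcinoma-plausible driver genes; the first few are the
#' ones the archetypes actively mutate.
#'
#' @return character vector of 72 gene symbols.
#' @export
driver_universe <- function() {
  c("TP53", "EGFR", "KRAS", "STK11", "KEAP1", "RBM10", "SMARCA4",
    "BRAF", "MET", "ERBB2", "PIK3CA", "CTNNB1", "NF1", "RB1", "CDKN2A",
    "ARID1A", "ARID1B", "ARID2", "SETD2", "BAP1", "ATM", "NRAS", "MGA",
    "U2AF1", "RIT1", "CDK4", "CCND1", "MDM2", "MYC", "TERT", "PTEN",
    "APC", "FGFR1", "FGFR4", "PDGFRB", "ALK", "ROS1", "RET", "ERBB4",
    "AKT1", "MAP2K1", "SOS1", "HRAS", "JAK2", "KIT", "DDR2", "NTRK1",
    "NTRK3", "FBXW7", "SMAD4", "STAG2", "KMT2C", "KMT2D", "CREBBP",
    "EP300", "NCOA6", "ZFHX3", "FAT1", "NOTCH1", "NOTCH2", "BCOR",
    "BCORL1", "CHEK2", "PALB2", "BRCA2", "MSH2", "POLE", "RAD51B",
    "TGFBR1", "TGFBR2", "ROBO2", "PSIP1")
}

scna_pool <- function() {
  loh_chr <- c(17, 8, 13, 9, 19, 3, 6, 15, 21, 10)
  gain_chr <- c(1, 7, 16, 2, 5, 12, 14, 20, 22, 11)
  hd_chr <- c(4, 18)
  mk <- function(kind, chr) data.frame(
    event_id = sprintf("%s_chr%d_60.0Mb", kind, chr), kind = kind,
    chrom = paste0("chr", chr), start = 60e6, end = 68e6,
    gene = NA_character_)
  rbind(mk("LOH", loh_chr), mk("GAIN", gain_chr), mk("HD", hd_chr))
}

snv_pool <- function(n_snv) {
  genes <- driver_universe()[seq_len(n_snv)]
  data.frame(event_id = paste0("SNV_", genes), kind = "SNV",
             chrom = NA_character_, start = NA_real_, end = NA_real_,
             gene = genes)
}

wgd_row <- function() data.frame(
  event_id = "WGD", kind = "WGD", chrom = NA_character_,
  start = NA_real_, end = NA_real_, gene = NA_character_)

# deterministic canonical orders for the three archetypes; each is a
# permutation of the shared event pool
canonical_orders <- function(events) {
  id <- events$event_id
  loh <- id[events$kind == "LOH"]
  gain <- id[events$kind == "GAIN"]
  hd <- id[events$kind == "HD"]
  snv <- function(g) paste0("SNV_", g)
  # loss-dominant, WGD-early archetype: few driver SNVs and three losses
  # precede an early WGD; remaining losses next, gains late
  a_loss <- c(snv(c("TP53", "RBM10", "EGFR")), loh[1:3], "WGD",
              loh[4:10], hd, snv(c("ERBB2", "KRAS", "SMARCA4", "STK11",
                                   "KEAP1")), gain)
  # gain-dominant archetype: early driver SNVs then frequent gains from a
  # diploid base; WGD, when present, comes late; losses last
  a_gain <- c(snv(c("EGFR", "TP53", "ERBB2")), gain[1:6], "WGD",
              gain[7:10], snv(c("KRAS", "RBM10", "SMARCA4")), rev(hd),
              snv(c("STK11", "KEAP1")), rev(loh))
  # smoking-like archetype: many driver SNVs first, its own losses before
  # an early-ish WGD, gains and the remaining losses late
  a_sd <- c(snv(c("TP53", "KRAS", "STK11", "KEAP1", "SMARCA4")),
            loh[c(5, 1, 6)], "WGD", loh[c(8, 9, 10, 7, 4, 3, 2)],
            rev(hd), snv(c("RBM10", "EGFR", "ERBB2")), rev(gain))
  list(ALoss = a_loss, AGain = a_gain, ASD = a_sd)
}

#' Default planted trajectory archetypes
#'
#' Three archetypes over a shared pool of `n_events` events (driver SNVs,
#' LOH/gain/HD regions on the miniature genome, and WGD): a loss-dominant
#' archetype with WGD in 87 percent of samples and early losses, a
#' gain-dominant archetype with early gains and rare, late WGD, and a
#' smoking-like archetype led by driver SNVs with pre-WGD losses. The
#' canonical orders are pairwise dissimilar (Kendall tau < 0.5) and the
#' per-event worths decay geometrically along each order.
#'
#' @param n_events total catalog size (>= 10; default 30 = 7 SNVs, 22
#'   SCNA regions, WGD).
#' @param seed integer seed (jitters prevalences deterministically).
#' @return list of three `pl_archetype` lists: `label`, `events`,
#'   `canonical_order`, `worths`, `prevalence`, `wgd_rate`, `wgd_rank`,
#'   `demographic_bias`, `burden`.
#' @export
default_archetypes <- function(n_events = 30, seed = 1) {
  stopifnot(n_events >= 10)
  n_snv <- max(3, min(7, n_events - 23))
  n_scna <- n_events - n_snv - 1
  events <- rbind(scna_pool()[seq_len(n_scna), ], snv_pool(n_snv), wgd_row())
  orders <- canonical_orders(events)
  orders <- lapply(orders, function(o) o[o %in% events$event_id])
  wgd_rates <- c(ALoss = 0.87, AGain = 0.31, ASD = 0.60)
  demo <- list(
    ALoss = list(smoking_never = 0.95, sbs4_if_never = 0.02,
                 sbs4_if_ever = 0.90, eur = 0.45, eas = 0.45, male = 0.40),
    AGain = list(smoking_never = 0.95, sbs4_if_never = 0.02,
                 sbs4_if_ever = 0.90, eur = 0.45, eas = 0.45, male = 0.40),
    ASD = list(smoking_never = 0.35, sbs4_if_never = 0.12,
               sbs4_if_ever = 0.90, eur = 0.75, eas = 0.15, male = 0.60))
  # rare_driver_rate: per-gene chance of a background SNV in each driver
  # gene outside the archetype's canonical ones — the smoking-like
  # archetype accrues many more rare drivers, as expected from its
  # higher mutation burden
  burden <- list(
    ALoss = list(snv_meanlog = log(6000), snv_sdlog = 0.4, sv_mu = 40,
                 kataegis_mu = 3, sv5_rate = 0.05,
                 rare_driver_rate = 0.005),
    AGain = list(snv_meanlog = log(6000), snv_sdlog = 0.4, sv_mu = 25,
                 kataegis_mu = 2, sv5_rate = 0.05,
                 rare_driver_rate = 0.005),
    ASD = list(snv_meanlog = log(20000), snv_sdlog = 0.5, sv_mu = 60,
               kataegis_mu = 6, sv5_rate = 0.60,
               rare_driver_rate = 0.02))
  out <- lapply(names(orders), function(lab) {
    ord <- orders[[lab]]
    m <- length(ord)
    worths <- stats::setNames(exp(-0.22 * (seq_len(m) - 1)), ord)
    worths <- worths / sum(worths)
    set.seed(mix_seed(seed, lab, 11L))
    prev <- 0.92 * exp(-1.4 * (seq_len(m) - 1) / (m - 1)) + 0.06 +
      stats::runif(m, -0.03, 0.03)
    prev <- stats::setNames(pmin(pmax(prev, 0.05), 0.98), ord)
    structure(list(label = lab, events = events, canonical_order = ord,
                   worths = worths, prevalence = prev,
                   wgd_rate = wgd_rates[[lab]],
                   wgd_rank = match("WGD", ord),
                   demographic_bias = demo[[lab]],
                   burden = burden[[lab]]),
              class = "pl_archetype")
  })
  names(out) <- names(orders)
  out
}

# sequential Plackett-Luce sample without replacement; `temper` in [0,1]
# flattens the worths towards uniform (1 = uniform)
pl_sample <- function(worths, temper = 0) {
  lw <- (1 - temper) * log(worths)
  w <- exp(lw - max(lw))
  ids <- names(worths)
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    pick <- sample(seq_along(ids), 1, prob = w)
    out[i] <- ids[pick]
    ids <- ids[-pick]; w <- w[-pick]
  }
  out
}

# copy-number states realising each event class; WGD samples keep LOH and
# HD pre-doubling so that parsimony timing round-trips to the truth
event_state <- function(kind, wgd, timing) {
  if (!wgd) {
    switch(kind, GAIN = c(2, 1), LOH = c(1, 0), HD = c(0, 0))
  } else {
    switch(kind,
           GAIN = if (identical(timing, "EARLY_CLONAL")) c(4, 2) else c(3, 2),
           LOH = c(2, 0), HD = c(0, 0))
  }
}

simulate_sample <- function(arch, sid, seed, noise, a_idx, i) {
  set.seed(mix_seed(seed, a_idx, i, 3L))
  bias <- arch$demographic_bias
  wgd <- stats::runif(1) < arch$wgd_rate
  ev_ids <- setdiff(arch$canonical_order, "WGD")
  carried <- character(0)
  for (try in 1:10) {
    carried <- ev_ids[stats::runif(length(ev_ids)) < arch$prevalence[ev_ids]]
    if (length(carried) >= 2) break
  }
  if (length(carried) < 2) carried <- ev_ids[1:2]
  items <- c(carried, if (wgd) "WGD")
  draw <- pl_sample(arch$worths[items], temper = noise)

  # stratify: leading block clonal, the rest subclonal
  L <- length(draw)
  n_clonal <- max(1, min(L, ceiling(stats::runif(1, 0.55, 0.8) * L)))
  if (wgd) n_clonal <- max(n_clonal, which(draw == "WGD"))
  clonal <- draw[seq_len(n_clonal)]
  subclonal <- setdiff(draw, clonal)
  kinds <- stats::setNames(arch$events$kind, arch$events$event_id)
  timing <- stats::setNames(rep(NA_character_, L), draw)
  if (wgd) {
    wpos <- which(clonal == "WGD")
    timing[clonal] <- ifelse(seq_along(clonal) < wpos,
                             "EARLY_CLONAL", "LATE_CLONAL")
    timing["WGD"] <- "WGD"
    # full-allele losses after a doubling are indistinguishable from
    # pre-WGD losses, so clonal LOH/HD are realised (and recorded) early
    move <- clonal[timing[clonal] == "LATE_CLONAL" &
                     kinds[clonal] %in% c("LOH", "HD")]
    if (length(move)) {
      timing[move] <- "EARLY_CLONAL"
      clonal <- c(setdiff(clonal[seq_len(wpos - 1)], "WGD"), move, "WGD",
                  setdiff(clonal[seq(wpos, length(clonal))],
                          c(move, "WGD")))
    }
  }

  # subclone tree: contiguous blocks of the subclonal tail, chain or star
  n_sub <- if (length(subclonal)) min(1 + stats::rbinom(1, 2, 0.35),
                                      length(subclonal)) else 0
  sub_assign <- if (n_sub > 0)
    stats::setNames(sort(rep_len(seq_len(n_sub), length(subclonal))),
                    subclonal) else integer(0)
  star <- n_sub >= 2 && stats::runif(1) < 0.4
  ccfs <- numeric(0)
  if (n_sub > 0) {
    if (star) {
      c1 <- stats::runif(1, 0.35, 0.55)
      rest <- if (n_sub > 1)
        stats::runif(n_sub - 1, 0.10, min(c1 - 0.05, 1 - c1) /
                       max(1, n_sub - 1)) else numeric(0)
      ccfs <- c(c1, sort(rest, decreasing = TRUE))
    } else {
      ccfs <- stats::runif(1, 0.45, 0.85)
      while (length(ccfs) < n_sub)
        ccfs <- c(ccfs, stats::runif(1, 0.08, 0.9) * ccfs[length(ccfs)])
    }
    ccfs <- round(pmax(ccfs, 0.05), 4)
    ccfs <- ccfs - seq(0, by = 1e-4, length.out = n_sub)  # force distinct
  }
  clonal_ccf <- round(stats::runif(1, 0.95, 1), 4)
  cluster_ids <- c("C1", if (n_sub > 0) paste0("S", seq_len(n_sub)))
  cluster_ccf <- c(clonal_ccf, ccfs)
  parent <- c(NA_character_,
              if (n_sub > 0) {
                if (star) c("C1", rep("C1", n_sub - 1))
                else c("C1", if (n_sub > 1) paste0("S", seq_len(n_sub - 1)))
              })
  names(parent) <- cluster_ids

  snv_total <- round(stats::rlnorm(1, arch$burden$snv_meanlog,
                                   arch$burden$snv_sdlog))
  n_mut <- round(snv_total * c(stats::runif(1, 0.5, 0.8),
                               if (n_sub > 0) rep(NA, n_sub)))
  if (n_sub > 0) {
    rem <- snv_total - n_mut[1]
    split <- rdirichlet1(n_sub)
    n_mut[-1] <- pmax(1, round(rem * split))
  }
  clusters <- data.frame(sample_id = sid, cluster_id = cluster_ids,
                         ccf = cluster_ccf, n_mutations = n_mut)

  ev_cluster <- stats::setNames(rep("C1", L), draw)
  if (n_sub > 0) ev_cluster[names(sub_assign)] <- paste0("S", sub_assign)

  # realise segments chromosome by chromosome
  base <- if (wgd) c(2, 2) else c(1, 1)
  seg_rows <- list()
  ev_tab <- arch$events[match(setdiff(draw, "WGD"), arch$events$event_id), ]
  scna <- ev_tab[ev_tab$kind %in% c("GAIN", "LOH", "HD"), , drop = FALSE]
  genome <- mini_genome()
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$chrom[ci]; Lc <- genome$length[ci]
    here <- scna[scna$chrom == chrom, , drop = FALSE]
    here <- here[order(here$start), , drop = FALSE]
    pos <- 0
    add <- function(s, e, M1, m1, f1, M2 = NA, m2 = NA, f2 = NA)
      seg_rows[[length(seg_rows) + 1L]] <<- data.frame(
        sample_id = sid, chrom = chrom, start = s, end = e,
        major1 = M1, minor1 = m1, frac1 = f1,
        major2 = M2, minor2 = m2, frac2 = f2)
    for (k in seq_len(nrow(here))) {
      ev <- here[k, ]
      if (ev$start > pos) add(pos, ev$start, base[1], base[2], 1)
      is_clonal <- ev$event_id %in% clonal
      st <- event_state(ev$kind, wgd,
                        if (is_clonal) timing[[ev$event_id]] else NA)
      if (is_clonal) {
        add(ev$start, ev$end, st[1], st[2], 1)
      } else {
        ccf <- cluster_ccf[match(ev_cluster[[ev$event_id]], cluster_ids)]
        add(ev$start, ev$end, st[1], st[2], ccf,
            base[1], base[2], 1 - ccf)
      }
      pos <- ev$end
    }
    if (pos < Lc) add(pos, Lc, base[1], base[2], 1)
  }
  segments <- do.call(rbind, seg_rows)

  snv_ev <- ev_tab[ev_tab$kind == "SNV", , drop = FALSE]
  snvs <- if (nrow(snv_ev)) data.frame(
    sample_id = sid, gene = snv_ev$gene,
    cluster_id = ev_cluster[snv_ev$event_id],
    multiplicity = ifelse(
      wgd & snv_ev$event_id %in% clonal &
        timing[snv_ev$event_id] == "EARLY_CLONAL", 2L, 1L)) else
    data.frame(sample_id = character(), gene = character(),
               cluster_id = character(), multiplicity = integer())

  # background SNVs in drivers outside the trajectory: kept below the 3%
  # cohort prevalence that would admit them to the catalog, but frequent
  # enough in the smoking-like archetype to separate per-subset driver
  # counts
  rare_pool <- setdiff(driver_universe(), snv_pool(7)$gene)
  rare_hit <- rare_pool[stats::runif(length(rare_pool)) <
                          arch$burden$rare_driver_rate]
  if (length(rare_hit))
    snvs <- rbind(snvs, data.frame(sample_id = sid, gene = rare_hit,
                                   cluster_id = "C1", multiplicity = 1L))

  smoking <- if (stats::runif(1) < bias$smoking_never) "never" else "ever"
  sbs4 <- stats::runif(1) < if (smoking == "never") bias$sbs4_if_never else
    bias$sbs4_if_ever
  anc_p <- stats::runif(1)
  ancestry <- if (anc_p < bias$eur) "EUR" else
    if (anc_p < bias$eur + bias$eas) "EAS" else "OTHER"
  sex <- if (stats::runif(1) < bias$male) "M" else "F"
  age_dx <- round(min(90, max(30, stats::rnorm(1, 65, 8))))
  sample_row <- data.frame(
    sample_id = sid, purity = round(stats::runif(1, 0.35, 0.95), 3),
    nrpcc = round(stats::runif(1, 12, 40), 1), wgd = wgd,
    smoking = smoking, ancestry = ancestry, sex = sex, age_dx = age_dx,
    sbs4 = sbs4, sv_count = stats::rnbinom(1, mu = arch$burden$sv_mu,
                                           size = 4),
    kataegis = stats::rpois(1, arch$burden$kataegis_mu),
    snv_total = snv_total,
    survival_weeks = if (stats::runif(1) < 0.9)
      round(stats::rexp(1, 1 / 200)) else NA_real_)

  aberr <- if (arch$label == "ASD") stats::runif(1, 0.15, 0.5) else
    stats::runif(1, 0.02, 0.25)
  base_act <- stats::runif(1, 40, 80)
  sig_row <- data.frame(
    sample_id = sid,
    CN1 = if (wgd) stats::runif(1, 0, 2) else base_act,
    CN2 = if (wgd) base_act else stats::runif(1, 0, 2),
    CN9 = base_act * aberr * stats::runif(1, 0.5, 1.5),
    SBS4 = if (sbs4) stats::runif(1, 50, 500) else 0,
    SV5 = if (stats::runif(1) < arch$burden$sv5_rate)
      stats::runif(1, 10, 100) else 0)

  truth_events <- data.frame(
    sample_id = sid, event_id = draw,
    clonality = ifelse(draw %in% clonal, "CLONAL", "SUBCLONAL"),
    timing = unname(timing[draw]), cluster_id = unname(ev_cluster[draw]),
    order = seq_along(draw))
  truth_events <- truth_events[match(c(clonal, subclonal),
                                     truth_events$event_id), ]
  truth_events$order <- seq_len(nrow(truth_events))
  list(sample = sample_row, segments = segments, snvs = snvs,
       clusters = clusters, signatures = sig_row,
       truth = list(sample_id = sid, archetype = arch$label,
                    tree = parent, events = truth_events))
}

#' Simulate a cohort with planted trajectory archetypes
#'
#' Each sample carries a Bernoulli subset of its archetype's events, whose
#' within-sample order is a (tempered) Plackett-Luce draw from the
#' archetype worths; the leading block is clonal (WGD inside it when
#' present), the tail is split over a pigeonhole-valid subclone tree with
#' stick-breaking CCFs. SCNA events are realised as segments whose states
#' are consistent with WGD status and intended timing (so classification
#' and parsimony timing round-trip to the truth), driver SNVs get
#' multiplicity 2 when pre-WGD in a WGD sample, and demographics, burden
#' fields and signature activities follow archetype-specific
#' distributions.
#'
#' @param archetypes list from [default_archetypes()].
#' @param n_per_archetype samples per archetype.
#' @param seed integer seed.
#' @param noise ordering temperature in `[0,1]` (0 = faithful Plackett-
#'   Luce draws, 1 = uniform shuffles).
#' @param inject_unclassifiable add one sample carrying no catalog event.
#' @return list: `cohort` (a `pl_cohort`) and `truth` (list with
#'   `samples` data.frame of planted labels, `events` per-sample truth
#'   table, `trees`).
#' @export
simulate_cohort <- function(archetypes, n_per_archetype = 100, seed = 1,
                            noise = 0.1, inject_unclassifiable = FALSE) {
  stopifnot(n_per_archetype >= 1, noise >= 0, noise <= 1)
  parts <- list()
  for (a_idx in seq_along(archetypes)) {
    arch <- archetypes[[a_idx]]
    for (i in seq_len(n_per_archetype)) {
      sid <- sprintf("%s_%03d", arch$label, i)
      parts[[length(parts) + 1L]] <-
        simulate_sample(arch, sid, seed, noise, a_idx, i)
    }
  }
  if (inject_unclassifiable) {
    set.seed(mix_seed(seed, 99L))
    sid <- "UNCLASS_001"
    genome <- mini_genome()
    segments <- data.frame(
      sample_id = sid, chrom = genome$chrom, start = 0,
      end = genome$length, major1 = 1, minor1 = 1, frac1 = 1,
      major2 = NA_real_, minor2 = NA_real_, frac2 = NA_real_)
    parts[[length(parts) + 1L]] <- list(
      sample = data.frame(sample_id = sid, purity = 0.5, nrpcc = 20,
                          wgd = FALSE, smoking = "never", ancestry = "EUR",
                          sex = "F", age_dx = 60, sbs4 = FALSE,
                          sv_count = 5L, kataegis = 0L, snv_total = 3000,
                          survival_weeks = 250),
      segments = segments,
      snvs = data.frame(sample_id = character(), gene = character(),
                        cluster_id = character(), multiplicity = integer()),
      clusters = data.frame(sample_id = sid, cluster_id = "C1",
                            ccf = 0.98, n_mutations = 3000),
      signatures = data.frame(sample_id = sid, CN1 = 60, CN2 = 0.5,
                              CN9 = 2, SBS4 = 0, SV5 = 0),
      truth = list(sample_id = sid, archetype = "UNCLASSIFIABLE",
                   tree = c(C1 = NA_character_),
                   events = data.frame()))
  }
  bind <- function(what) do.call(rbind, lapply(parts, `[[`, what))
  cohort <- new_cohort(bind("sample"), bind("segments"), bind("snvs"),
                       bind("clusters"), driver_universe(), mini_genome(),
                       signatures = bind("signatures"),
                       provenance = list(generator = "simulate_cohort",
                                         seed = seed, noise = noise,
                                         n_per_archetype = n_per_archetype))
  truths <- lapply(parts, `[[`, "truth")
  truth <- list(
    samples = data.frame(
      sample_id = vapply(truths, `[[`, character(1), "sample_id"),
      archetype = vapply(truths, `[[`, character(1), "archetype")),
    events = do.call(rbind, lapply(truths, `[[`, "events")),
    trees = stats::setNames(lapply(truths, `[[`, "tree"),
                            vapply(truths, `[[`, character(1), "sample_id")))
  list(cohort = cohort, truth = truth)
}

#' Stress-perturb a cohort's subclonal structure
#'
#' Swaps the event assignments of adjacent subclone generations (each
#' parent/child pair independently with probability `swap_rate`),
#' reassigning SNV cluster links and subclonal segment fractions while
#' leaving every CCF — and therefore the pigeonhole structure — untouched.
#'
#' @param cohort a `pl_cohort`.
#' @param swap_rate probability of swapping each adjacent cluster pair.
#' @param seed integer seed.
#' @return the perturbed `pl_cohort`.
#' @export
perturb_orderings <- function(cohort, swap_rate, seed = 1) {
  stopifnot(swap_rate >= 0, swap_rate <= 1)
  out <- cohort
  for (sid in cohort$samples$sample_id) {
    clus <- cohort$clusters[cohort$clusters$sample_id == sid, ]
    subs <- clus[order(-clus$ccf), ][-1, , drop = FALSE]   # drop clonal
    if (nrow(subs) < 2) next
    set.seed(mix_seed(seed, sid, 5L))
    for (i in seq_len(nrow(subs) - 1)) {
      if (stats::runif(1) >= swap_rate) next
      a <- subs$cluster_id[i]; b <- subs$cluster_id[i + 1]
      ccf_a <- subs$ccf[i]; ccf_b <- subs$ccf[i + 1]
      sn <- out$snvs$sample_id == sid
      cl <- out$snvs$cluster_id
      out$snvs$cluster_id[sn & cl == a] <- "..tmp.."
      out$snvs$cluster_id[sn & cl == b] <- a
      out$snvs$cluster_id[sn & out$snvs$cluster_id == "..tmp.."] <- b
      sg <- out$segments$sample_id == sid & !is.na(out$segments$frac2)
      fa <- sg & abs(out$segments$frac1 - ccf_a) < 1e-9
      fb <- sg & abs(out$segments$frac1 - ccf_b) < 1e-9
      out$segments$frac1[fa] <- ccf_b
      out$segments$frac2[fa] <- 1 - ccf_b
      out$segments$frac1[fb] <- ccf_a
      out$segments$frac2[fb] <- 1 - ccf_a
    }
  }
  validate_cohort(out)
  out
}
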