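# deterministic 31-bit stream key so per-(sample, iteration) draws are
# reproducible and independent of execution order
mix_seed <- function(...) {
  x <- 0
  for (v in c(...)) {
    v <- if (is.character(v)) sum(utf8ToInt(v) * seq_along(utf8ToInt(v))) else v
    x <- (x * 1000003 + as.numeric(v)) %% 2147483647
  }
  as.integer(x)
}

#' Enumerate phylogenetic trees compatible with a sample's cluster CCFs
#'
#' Every rooted tree over the mutation clusters in which (i) the clonal
#' cluster (highest CCF, treated as CCF 1) is the root, (ii) each
#' subclone's parent has CCF >= its own, and (iii) the pigeonhole principle
#' holds: the CCFs of any node's direct children sum to no more than the
#' node's own CCF. Enumeration order is deterministic (clusters considered
#' in decreasing CCF, parents in decreasing CCF).
#'
#' @param clusters data.frame with `cluster_id` and `ccf` for one sample.
#' @param max_subclones guard on the enumeration (default 8).
#' @return list of trees; each tree is a named character vector mapping
#'   `cluster_id` to its parent's `cluster_id` (`NA` for the root).
#' @export
enumerate_trees <- function(clusters, max_subclones = 8) {
  stopifnot(nrow(clusters) >= 1)
  ord <- order(-clusters$ccf)
  ids <- as.character(clusters$cluster_id)[ord]
  ccf <- clusters$ccf[ord]
  ccf[1] <- 1.0   # clonal cluster anchors the root
  k <- length(ids) - 1
  if (k > max_subclones)
    stop("more than ", max_subclones,
         " subclones; merge clusters before tree enumeration", call. = FALSE)
  trees <- list()
  parent <- rep(NA_character_, length(ids))
  names(parent) <- ids
  child_sum <- stats::setNames(rep(0, length(ids)), ids)
  recurse <- function(i) {
    if (i > length(ids)) {
      trees[[length(trees) + 1L]] <<- parent
      return(invisible())
    }
    for (j in seq_len(i - 1)) {
      if (ccf[j] < ccf[i]) next
      if (child_sum[ids[j]] + ccf[i] > ccf[j] + 1e-9) next
      parent[ids[i]] <<- ids[j]
      child_sum[ids[j]] <<- child_sum[ids[j]] + ccf[i]
      recurse(i + 1)
      child_sum[ids[j]] <<- child_sum[ids[j]] - ccf[i]
      parent[ids[i]] <<- NA_character_
    }
  }
  if (k == 0) trees[[1]] <- parent else recurse(2)
  trees
}

# one random linear emission of clusters respecting ancestry: repeatedly
# pick, uniformly, a cluster whose parent has already been emitted
random_topological_order <- function(tree) {
  ids <- names(tree)
  emitted <- character(0)
  avail <- ids[is.na(tree)]
  while (length(avail)) {
    pick <- if (length(avail) == 1) avail else sample(avail, 1)
    emitted <- c(emitted, pick)
    avail <- setdiff(ids[is.na(tree) | tree %in% emitted], emitted)
  }
  emitted
}

#' Randomly order one sample's present events under its constraints
#'
#' Builds one total order: in WGD samples early-clonal events, then WGD,
#' then late-clonal events, then subclonal events (non-WGD samples: clonal
#' then subclonal). Events within a clonal stratum are shuffled uniformly;
#' subclonal events follow a phylogenetic tree drawn uniformly from
#' [enumerate_trees()], clusters being emitted by a random topological
#' traversal with a uniform shuffle inside each cluster. Uses R's RNG
#' state; seed the caller for reproducibility.
#'
#' @param present presence table from [event_presence()].
#' @param clusters the sample's cluster table.
#' @param wgd logical, the sample's WGD status.
#' @param trees optionally, the pre-enumerated tree list.
#' @return character vector of event ids, earliest first.
#' @export
order_sample <- function(present, clusters, wgd, trees = NULL) {
  stopifnot(nrow(present) >= 1)
  shuffle <- function(x) if (length(x) > 1) sample(x) else x
  clonal <- present[present$clonality == "CLONAL", , drop = FALSE]
  sub <- present[present$clonality == "SUBCLONAL", , drop = FALSE]
  if (wgd && "WGD" %in% clonal$event_id) {
    head_ids <- c(
      shuffle(clonal$event_id[!is.na(clonal$timing) &
                                clonal$timing == "EARLY_CLONAL"]),
      "WGD",
      shuffle(clonal$event_id[clonal$event_id != "WGD" &
                                (is.na(clonal$timing) |
                                   clonal$timing != "EARLY_CLONAL")]))
  } else {
    head_ids <- shuffle(clonal$event_id)
  }
  tail_ids <- character(0)
  if (nrow(sub)) {
    if (is.null(trees)) trees <- enumerate_trees(clusters)
    tree <- trees[[if (length(trees) > 1) sample(length(trees), 1) else 1]]
    for (cl in random_topological_order(tree)) {
      here <- sub$event_id[!is.na(sub$cluster_id) & sub$cluster_id == cl]
      tail_ids <- c(tail_ids, shuffle(here))
    }
    # events whose matched cluster is absent from the tree go last, shuffled
    stray <- setdiff(sub$event_id, tail_ids)
    tail_ids <- c(tail_ids, shuffle(stray))
  }
  c(head_ids, tail_ids)
}

#' Randomized event orderings for a whole cohort
#'
#' For every sample with at least one present catalog event, draws
#' `n_iterations` randomized total orders honouring the sample's
#' constraints; samples carrying nothing are flagged unclassifiable and
#' excluded. RNG streams are keyed by (seed, sample, iteration), so results
#' are reproducible and independent of evaluation order.
#'
#' @param cohort a `pl_cohort`.
#' @param catalog event catalog from [build_catalog()].
#' @param n_iterations number of randomized orderings per sample (the
#'   full-scale analysis uses 1000; desk runs use ~25).
#' @param seed integer seed.
#' @param min_overlap_frac,clonal_band see [event_presence()].
#' @return object of class `pl_rankings`: list with `items` (catalog event
#'   ids), `sample_ids`, `unclassifiable`, `presence` (per-sample presence
#'   tables) and `iterations` — a list of length `n_iterations`, each a
#'   named list of event-id vectors.
#' @export
order_cohort <- function(cohort, catalog, n_iterations = 1000, seed = 1,
                         min_overlap_frac = 0.5, clonal_band = 0.9) {
  stopifnot(n_iterations >= 1)
  ids <- cohort$samples$sample_id
  presence <- lapply(stats::setNames(ids, ids), function(sid)
    event_presence(cohort, sid, catalog, min_overlap_frac, clonal_band))
  n_ev <- vapply(presence, nrow, integer(1))
  unclassifiable <- ids[n_ev == 0]
  keep <- ids[n_ev > 0]
  trees <- lapply(stats::setNames(keep, keep), function(sid)
    enumerate_trees(cohort$clusters[cohort$clusters$sample_id == sid, ,
                                    drop = FALSE]))
  wgd <- stats::setNames(cohort$samples$wgd, ids)
  iterations <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    rk <- vector("list", length(keep))
    names(rk) <- keep
    for (si in seq_along(keep)) {
      sid <- keep[si]
      set.seed(mix_seed(seed, si, it))
      rk[[sid]] <- order_sample(presence[[sid]],
                                cohort$clusters[
                                  cohort$clusters$sample_id == sid, ,
                                  drop = FALSE],
                                wgd[[sid]], trees[[sid]])
    }
    iterations[[it]] <- rk
  }
  structure(list(items = catalog$event_id, sample_ids = keep,
                 unclassifiable = unclassifiable, presence = presence,
                 iterations = iterations, seed = seed),
            class = "pl_rankings")
}

#' @export
print.pl_rankings <- function(x, ...) {
  cat(sprintf("pl_rankings: %d samples x %d iterations over %d events (%d unclassifiable)\n",
              length(x$sample_ids), length(x$iterations), length(x$items),
              length(x$unclassifiable)))
  invisible(x)
}

#' Flatten rankings to a long table
#' @param rankings a `pl_rankings`.
#' @return data.frame with `sample_id`, `iteration`, `rank`, `event_id`.
#' @export
ranking_table <- function(rankings) {
  out <- list()
  for (it in seq_along(rankings$iterations)) {
    rk <- rankings$iterations[[it]]
    lens <- lengths(rk)
    out[[it]] <- data.frame(
      sample_id = rep(names(rk), lens), iteration = it,
      rank = unlist(lapply(lens, seq_len), use.names = FALSE),
      event_id = unlist(rk, use.names = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
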