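# ---- flat representation of rankings-of-subsets -------------------------
#
# Rankings are total orders over each sample's own item subset. For speed
# every fit works on a flattened form: `ord` concatenates the item indices
# of all rankings, `rid` labels the ranking each position belongs to, and
# grouped (reverse) cumulative sums give every stagewise denominator in one
# vectorised pass.

flatten_rankings <- function(idx_list) {
  len <- lengths(idx_list)
  ord <- unlist(idx_list, use.names = FALSE)
  n <- length(ord)
  rid <- rep(seq_along(idx_list), len)
  ends <- cumsum(len)
  starts <- ends - len + 1L
  last <- logical(n); last[ends] <- TRUE
  end_at <- rep(ends, len)
  start_at <- rep(starts, len)
  list(ord = ord, rid = rid, len = len, n = n,
       last = last, end_at = end_at, start_at = start_at)
}

grev_cumsum <- function(v, fl) {           # sum_{j >= p} within ranking
  cs <- cumsum(v)
  v + cs[fl$end_at] - cs
}

g_cumsum <- function(v, fl) {              # sum_{j <= p} within ranking
  cs <- cumsum(v)
  cs - (cs[fl$start_at] - v[fl$start_at])
}

# per-ranking log-likelihood under worths w (unnormalised is fine: the
# stagewise ratios are scale-free)
flat_loglik <- function(w, fl) {
  wv <- w[fl$ord]
  term <- log(wv) - log(grev_cumsum(wv, fl))
  as.vector(rowsum(term, fl$rid))
}

ghost_prior <- function(w, eps, wg) {
  if (eps <= 0) return(0)
  eps * sum(log(w) + log(wg) - 2 * log(w + wg))
}

# strong connectivity of the "beats" graph; required for a finite MLE when
# no pseudocount regularises the boundary
beats_connected <- function(fl, m) {
  adj <- matrix(FALSE, m, m)
  # i beats j whenever i precedes j in some ranking; consecutive pairs are
  # enough to generate the same reachability closure
  not_last <- which(!fl$last)
  adj[cbind(fl$ord[not_last], fl$ord[not_last + 1L])] <- TRUE
  reach <- adj | diag(TRUE, m)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  all(reach)
}

# Hunter-style MM for rankings of subsets with a ghost-opponent prior:
# each item also plays `eps` wins and `eps` losses against a ghost of fixed
# worth wg, which regularises disconnected data. Each update maximises a
# minorisation of the penalised log-likelihood, so the recorded objective
# trace is non-decreasing.
mm_core <- function(fl, m, weights, eps, w, tol, max_iter) {
  wg <- 1 / m
  u_pos <- weights[fl$rid]
  win_w <- u_pos; win_w[fl$last] <- 0
  W <- numeric(m)
  tmp <- rowsum(win_w, fl$ord)
  W[as.integer(rownames(tmp))] <- tmp
  obj <- sum(weights * flat_loglik(w, fl)) + ghost_prior(w, eps, wg)
  trace <- obj
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    wv <- w[fl$ord]
    inv <- u_pos / grev_cumsum(wv, fl)
    inv[fl$last] <- 0
    s <- g_cumsum(inv, fl)
    C <- numeric(m)
    tmp <- rowsum(s, fl$ord)
    C[as.integer(rownames(tmp))] <- tmp
    w_new <- (W + eps) / (C + if (eps > 0) 2 * eps / (w + wg) else 0)
    if (eps <= 0) w_new <- w_new / sum(w_new)
    w <- w_new
    obj_new <- sum(weights * flat_loglik(w, fl)) + ghost_prior(w, eps, wg)
    trace <- c(trace, obj_new)
    if (abs(obj_new - obj) < tol * (abs(obj) + 1e-12)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  list(w = w, objective = obj, trace = trace, iterations = iter,
       converged = converged)
}

index_rankings <- function(rankings, items) {
  lapply(rankings, function(r) {
    idx <- match(r, items)
    if (anyNA(idx))
      stop("ranking contains items outside the item universe: ",
           paste(r[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
  })
}

# ---- exported operations ------------------------------------------------

#' Plackett-Luce log-likelihood of one ranking
#'
#' The ranking is read as a sequence of choices over the sample's own item
#' subset: the probability of the item at position j is its worth divided
#' by the summed worths of the items not yet placed.
#'
#' @param ranking character vector of item ids, earliest first.
#' @param worths named positive numeric vector covering every ranked item.
#' @return the log-likelihood (0 for a single-item ranking).
#' @export
pl_loglik <- function(ranking, worths) {
  w <- worths[ranking]
  if (anyNA(w)) stop("ranked item without a worth", call. = FALSE)
  if (any(w <= 0)) stop("worths must be positive", call. = FALSE)
  sum(log(w) - log(rev(cumsum(rev(w)))))
}

#' Maximum-likelihood Plackett-Luce fit by MM
#'
#' Fits item worths to a set of rankings of item subsets with Hunter's
#' minorise-maximise updates. A Dirichlet-style ghost-opponent pseudocount
#' (default 0.1 wins and losses per item against a fixed ghost) keeps the
#' maximiser off the boundary when the comparison graph is disconnected;
#' with `prior_pseudocount = 0` the fit is the plain MLE and disconnected
#' data raise an error. The recorded `trace` is the penalised objective,
#' which is non-decreasing at every update.
#'
#' @param rankings list of character vectors (each a ranking).
#' @param items item universe; defaults to the union of ranked items. Items
#'   never ranked are dropped with a warning.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum MM updates.
#' @param prior_pseudocount ghost pseudocount per item.
#' @param weights optional per-ranking non-negative weights.
#' @return list of class `pl_fit`: `worths` (named, normalised to sum 1),
#'   `loglik` (data log-likelihood at the fit), `trace`, `iterations`,
#'   `converged`, `items`.
#' @export
fit_pl <- function(rankings, items = NULL, tol = 1e-6, max_iter = 500,
                   prior_pseudocount = 0.1, weights = NULL) {
  ranked <- unique(unlist(rankings, use.names = FALSE))
  if (is.null(items)) items <- ranked
  absent <- setdiff(items, ranked)
  if (length(absent)) {
    warning("dropping item(s) never ranked: ",
            paste(absent, collapse = ", "), call. = FALSE)
    items <- setdiff(items, absent)
  }
  m <- length(items)
  if (m < 2) stop("need at least two distinct items", call. = FALSE)
  fl <- flatten_rankings(index_rankings(rankings, items))
  if (prior_pseudocount <= 0 && !beats_connected(fl, m))
    stop("comparison graph is not strongly connected; ",
         "refit with prior_pseudocount > 0", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(rankings))
  fit <- mm_core(fl, m, weights, prior_pseudocount,
                 w = rep(1 / m, m), tol = tol, max_iter = max_iter)
  worths <- fit$w / sum(fit$w)
  names(worths) <- items
  structure(list(worths = worths,
                 loglik = sum(weights * flat_loglik(fit$w, fl)),
                 trace = fit$trace, iterations = fit$iterations,
                 converged = fit$converged, items = items),
            class = "pl_fit")
}

rdirichlet1 <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

#' Plackett-Luce mixture fit by EM
#'
#' Clusters rankings into `K` latent trajectories, each with its own worth
#' vector. E-step: responsibilities proportional to mixture weight times
#' the component likelihood of each ranking. M-step: weight update plus one
#' responsibility-weighted MM step per component (a generalised EM, so the
#' penalised objective recorded in `trace` never decreases). The best of
#' `n_restarts` random initialisations by data log-likelihood is returned;
#' `K = 1` runs the plain [fit_pl()] path and matches its log-likelihood
#' exactly.
#'
#' @param rankings list of character-vector rankings.
#' @param K number of mixture components (>= 1).
#' @param n_restarts random restarts (default 5).
#' @param seed integer seed controlling the restarts.
#' @param tol,max_iter,prior_pseudocount,items as in [fit_pl()].
#' @return list of class `pl_mixture`: `K`, `weights`, `components` (list
#'   of named worth vectors), `responsibilities` (rankings x K), `loglik`
#'   (data mixture log-likelihood), `bic`, `trace`, `converged`.
#' @export
fit_pl_mixture <- function(rankings, K, n_restarts = 5, seed = 1,
                           tol = 1e-6, max_iter = 500,
                           prior_pseudocount = 0.1, items = NULL) {
  N <- length(rankings)
  stopifnot(K >= 1, N >= K)
  ranked <- unique(unlist(rankings, use.names = FALSE))
  if (is.null(items)) items <- ranked else items <- intersect(items, ranked)
  m <- length(items)
  n_par <- (K - 1) + K * (m - 1)
  if (K == 1) {
    fit <- fit_pl(rankings, items = items, tol = tol, max_iter = max_iter,
                  prior_pseudocount = prior_pseudocount)
    resp <- matrix(1, N, 1, dimnames = list(names(rankings), NULL))
    return(structure(list(K = 1L, weights = 1, components = list(fit$worths),
                          responsibilities = resp, loglik = fit$loglik,
                          bic = -2 * fit$loglik + n_par * log(N),
                          trace = fit$trace, converged = fit$converged,
                          items = items),
                     class = "pl_mixture"))
  }
  fl <- flatten_rankings(index_rankings(rankings, items))
  eps <- prior_pseudocount
  wg <- 1 / m
  run_em <- function(rs) {
    set.seed(mix_seed(seed, 7L, rs))
    # initialise from a random soft partition
    resp <- t(vapply(seq_len(N), function(i) rdirichlet1(K), numeric(K)))
    ws <- lapply(seq_len(K), function(k)
      mm_core(fl, m, resp[, k], eps, rep(1 / m, m), tol, 10)$w)
    alpha <- colSums(resp) / N
    obj <- -Inf; trace <- numeric(0); converged <- FALSE
    ll_mat <- matrix(0, N, K)
    for (iter in seq_len(max_iter)) {
      for (k in seq_len(K)) ll_mat[, k] <- flat_loglik(ws[[k]], fl)
      lp <- sweep(ll_mat, 2, log(alpha), "+")
      mx <- apply(lp, 1, max)
      lse <- mx + log(rowSums(exp(lp - mx)))
      resp <- exp(lp - lse)
      data_ll <- sum(lse)
      obj_new <- data_ll +
        sum(vapply(ws, ghost_prior, numeric(1), eps = eps, wg = wg))
      trace <- c(trace, obj_new)
      if (is.finite(obj) &&
          abs(obj_new - obj) < tol * (abs(obj) + 1e-12)) {
        converged <- TRUE
        obj <- obj_new
        break
      }
      obj <- obj_new
      alpha <- pmax(colSums(resp), 1e-12) / N
      for (k in seq_len(K))
        ws[[k]] <- mm_core(fl, m, resp[, k], eps, ws[[k]], tol, 1)$w
    }
    for (k in seq_len(K)) ll_mat[, k] <- flat_loglik(ws[[k]], fl)
    lp <- sweep(ll_mat, 2, log(alpha), "+")
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    list(ws = ws, alpha = alpha, resp = exp(lp - lse), loglik = sum(lse),
         trace = trace, converged = converged)
  }
  best <- NULL
  rs <- 0L; tried <- 0L
  while (tried < n_restarts) {
    rs <- rs + 1L
    fit <- run_em(rs)
    if (any(fit$alpha < 1e-8) && rs < n_restarts + 3L) {
      message("fit_pl_mixture: empty component, restarting with a new sub-seed")
      next
    }
    tried <- tried + 1L
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  comps <- lapply(best$ws, function(w)
    stats::setNames(w / sum(w), items))
  resp <- best$resp
  rownames(resp) <- names(rankings)
  structure(list(K = as.integer(K), weights = best$alpha, components = comps,
                 responsibilities = resp, loglik = best$loglik,
                 bic = -2 * best$loglik + n_par * log(N),
                 trace = best$trace, converged = best$converged,
                 items = items),
            class = "pl_mixture")
}

#' Choose the number of trajectories by lowest median BIC
#'
#' Fits mixtures with `K = 1..k_max` to every ordering iteration, takes the
#' median BIC per `K` across iterations, and selects the argmin (ties go to
#' the smaller `K`).
#'
#' @param rankings a `pl_rankings` object from [order_cohort()].
#' @param k_max largest K tried (default 5).
#' @param n_restarts,seed,tol,prior_pseudocount passed to
#'   [fit_pl_mixture()].
#' @param max_iter EM iteration cap per fit.
#' @return list: `selected_k`, `median_bic` (named by K), `bic` matrix
#'   (iterations x K), `fits` — the per-iteration fits at `selected_k`.
#' @export
select_k <- function(rankings, k_max = 5, n_restarts = 5, seed = 1,
                     tol = 1e-6, max_iter = 500, prior_pseudocount = 0.1) {
  stopifnot(k_max >= 1, length(rankings$iterations) >= 1)
  n_it <- length(rankings$iterations)
  bic <- matrix(NA_real_, n_it, k_max,
                dimnames = list(NULL, paste0("K", seq_len(k_max))))
  fits <- vector("list", n_it)
  for (it in seq_len(n_it)) {
    fits[[it]] <- vector("list", k_max)
    for (K in seq_len(k_max)) {
      f <- fit_pl_mixture(rankings$iterations[[it]], K = K,
                          n_restarts = n_restarts,
                          seed = mix_seed(seed, it, K), tol = tol,
                          max_iter = max_iter,
                          prior_pseudocount = prior_pseudocount)
      bic[it, K] <- f$bic
      fits[[it]][[K]] <- f
    }
  }
  med <- apply(bic, 2, stats::median)
  selected <- which(med == min(med))[1]
  list(selected_k = as.integer(selected), median_bic = med, bic = bic,
       fits = lapply(fits, `[[`, selected))
}

perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in perms(k - 1L)) for (pos in seq_len(k))
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Consolidate per-iteration mixture fits into one trajectory assignment
#'
#' Component labels are arbitrary within each iteration, so every fit's
#' labels are first aligned to the first iteration by the permutation
#' maximising the overlap of maximum-a-posteriori (MAP) assignments. Each
#' sample's final label is its modal aligned MAP label; ties go to the
#' label with the higher mean responsibility. Samples without events are
#' labelled `"UNCLASSIFIABLE"`.
#'
#' @param fits list of `pl_mixture` fits sharing `K`, over the same
#'   rankings (rows named by sample).
#' @param unclassifiable sample ids with zero present events.
#' @return list: `labels` (named character, `"T1"..`), `votes` (samples x
#'   K matrix of vote fractions), `mean_responsibility`.
#' @export
consolidate_assignments <- function(fits, unclassifiable = character(0)) {
  K <- unique(vapply(fits, function(f) f$K, integer(1)))
  stopifnot(length(K) == 1)
  sample_ids <- rownames(fits[[1]]$responsibilities)
  ref_map <- max.col(fits[[1]]$responsibilities)
  votes <- matrix(0, length(sample_ids), K,
                  dimnames = list(sample_ids, paste0("T", seq_len(K))))
  mean_resp <- votes
  for (f in fits) {
    resp <- f$responsibilities[sample_ids, , drop = FALSE]
    mp <- max.col(resp)
    best_perm <- seq_len(K); best_overlap <- -1L
    for (p in perms(K)) {
      overlap <- sum(p[mp] == ref_map)
      if (overlap > best_overlap) { best_overlap <- overlap; best_perm <- p }
    }
    aligned <- resp[, order(best_perm), drop = FALSE]
    votes[cbind(seq_along(mp), best_perm[mp])] <-
      votes[cbind(seq_along(mp), best_perm[mp])] + 1
    mean_resp <- mean_resp + aligned
  }
  votes <- votes / length(fits)
  mean_resp <- mean_resp / length(fits)
  labels <- vapply(seq_along(sample_ids), function(i) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1) top <- top[which.max(mean_resp[i, top])]
    colnames(votes)[top]
  }, character(1))
  names(labels) <- sample_ids
  if (length(unclassifiable)) {
    extra <- stats::setNames(rep("UNCLASSIFIABLE", length(unclassifiable)),
                             unclassifiable)
    labels <- c(labels, extra)
  }
  list(labels = labels, votes = votes, mean_responsibility = mean_resp)
}

#' Aggregate ordering of a trajectory with 95 percent intervals
#'
#' For each ordering iteration the subset's rankings are fitted with a
#' single Plackett-Luce model and events are ranked by decreasing worth;
#' the per-event median rank and the 2.5th/97.5th percentile ranks across
#' iterations summarise the trajectory. Prevalence is the fraction of
#' subset samples carrying the event.
#'
#' @param rankings a `pl_rankings` object.
#' @param sample_ids the subset's samples (>= 2).
#' @param min_carriers drop events carried by fewer subset samples.
#' @param prior_pseudocount,tol,max_iter passed to [fit_pl()].
#' @return data.frame: `event_id`, `median_rank`, `ci_low`, `ci_high`,
#'   `prevalence`, `n_carriers`, sorted by median rank.
#' @export
aggregate_ordering <- function(rankings, sample_ids, min_carriers = 1,
                               prior_pseudocount = 0.1, tol = 1e-6,
                               max_iter = 500) {
  sample_ids <- intersect(sample_ids, rankings$sample_ids)
  if (length(sample_ids) < 2)
    stop("aggregate ordering needs at least 2 samples", call. = FALSE)
  first <- rankings$iterations[[1]][sample_ids]
  carriers <- table(unlist(first, use.names = FALSE))
  keep_items <- names(carriers)[carriers >= min_carriers]
  n_it <- length(rankings$iterations)
  rank_mat <- matrix(NA_real_, n_it, length(keep_items),
                     dimnames = list(NULL, keep_items))
  for (it in seq_len(n_it)) {
    rks <- lapply(rankings$iterations[[it]][sample_ids],
                  function(r) r[r %in% keep_items])
    rks <- rks[lengths(rks) > 0]
    fit <- suppressWarnings(
      fit_pl(rks, items = keep_items, tol = tol, max_iter = max_iter,
             prior_pseudocount = prior_pseudocount))
    rk <- rank(-fit$worths, ties.method = "average")
    rank_mat[it, names(rk)] <- rk
  }
  out <- data.frame(
    event_id = keep_items,
    median_rank = apply(rank_mat, 2, stats::median, na.rm = TRUE),
    ci_low = apply(rank_mat, 2, stats::quantile, probs = 0.025,
                   na.rm = TRUE),
    ci_high = apply(rank_mat, 2, stats::quantile, probs = 0.975,
                    na.rm = TRUE),
    prevalence = as.numeric(carriers[keep_items]) / length(sample_ids),
    n_carriers = as.integer(carriers[keep_items]))
  out <- out[order(out$median_rank), ]
  rownames(out) <- NULL
  out
}
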