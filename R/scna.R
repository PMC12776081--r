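#' Classify an allele-specific copy-number state into an SCNA class
#'
#' The five mutually exclusive classes are conditioned on whole-genome
#' duplication because the diploid baseline shifts from 1+1 to 2+2 after a
#' WGD: a 2+1 segment is a gain in a non-WGD sample but a non-LOH loss in a
#' WGD sample. Homozygous deletion (total 0) and LOH (minor allele 0) take
#' precedence over the total-copy-number comparison, so a 3+0 state is LOH,
#' not a gain.
#'
#' @param major,minor integer allele copy numbers, `major >= minor >= 0`
#'   (vectorised).
#' @param wgd logical, whether the sample has undergone WGD (vectorised).
#' @return character vector in `c("HD","LOH","GAIN","NON_LOH_LOSS","NONE")`.
#' @export
classify_scna <- function(major, minor, wgd) {
  if (any(major < 0 | minor < 0)) stop("negative copy number", call. = FALSE)
  if (any(minor > major)) stop("minor > major", call. = FALSE)
  total <- major + minor
  baseline <- ifelse(wgd, 4L, 2L)
  out <- rep("NONE", length(total))
  out[total > baseline] <- "GAIN"
  out[total < baseline] <- "NON_LOH_LOSS"
  out[minor == 0] <- "LOH"
  out[total == 0] <- "HD"
  out
}

# Minimal number of +/-1 single-allele steps from (1,1) to (major, minor)
# with one genome doubling placed in the history; an allele at 0 copies can
# never be regained. A history is: monotone per-allele steps (1,1)->(a,b),
# the doubling (a,b)->(2a,2b) (an event, not a counted step), then steps
# (2a,2b)->target. The minimal step count between two states is the L1
# distance, infeasible when an allele must rise from 0. Returns
# c(early, late): minimum over histories whose first change precedes the
# doubling ((a,b) != (1,1)) and minimum with all steps after it.
wgd_step_counts <- function(major, minor) {
  target <- c(major, minor)
  leg <- function(from, to) {
    if (any(from == 0 & to > 0)) return(Inf)
    sum(abs(to - from))
  }
  late <- min(leg(c(2, 2), target), leg(c(2, 2), rev(target)))
  cap <- max(ceiling(max(target) / 2) + 1, 2)
  early <- Inf
  for (a in 0:cap) for (b in 0:cap) {
    if (a == 1 && b == 1) next
    pre <- leg(c(1, 1), c(a, b))
    post <- min(leg(c(2 * a, 2 * b), target),
                leg(c(2 * a, 2 * b), rev(target)))
    early <- min(early, pre + post)
  }
  c(early = early, late = late)
}

#' Time a clonal SCNA relative to whole-genome duplication by parsimony
#'
#' For a clonal segment in a WGD sample, decides whether the copy-number
#' change most parsimoniously happened before ("early clonal") or after
#' ("late clonal") the doubling: the minimum number of single-copy
#' gain/loss steps with the change beginning before WGD is compared with
#' the minimum when every step follows WGD; ties resolve to early. A clonal
#' 2+1 (non-LOH loss) is late (one post-WGD loss beats any pre-WGD
#' history), whereas 2+0 LOH is early (one pre-WGD loss then doubling).
#'
#' @param major,minor allele copy numbers of the clonal state (vectorised).
#' @param wgd must be `TRUE`; timing is undefined for non-WGD samples.
#' @return character vector, `"EARLY_CLONAL"` or `"LATE_CLONAL"`.
#' @export
classify_wgd_timing <- function(major, minor, wgd = TRUE) {
  if (!all(wgd)) stop("WGD timing applies only to WGD samples", call. = FALSE)
  if (any(major < 0 | minor < 0)) stop("negative copy number", call. = FALSE)
  mapply(function(M, m) {
    cnt <- wgd_step_counts(M, m)
    if (all(is.infinite(cnt)))
      stop(sprintf("state (%d,%d) unreachable", M, m), call. = FALSE)
    if (cnt["early"] <= cnt["late"]) "EARLY_CLONAL" else "LATE_CLONAL"
  }, as.integer(major), as.integer(minor), USE.NAMES = FALSE)
}

#' Genomic filter mask for recurrence scanning
#'
#' Excluded territory: centromeres, 5 Mb at each telomere, the HLA region,
#' the short arms of the acrocentric chromosomes (13, 14, 15, 21, 22) and
#' the whole of chromosomes X and Y. Coordinates scale with the genome the
#' cohort lives on, so the same construction serves the miniature synthetic
#' genome; a BED file of regions can replace it entirely.
#'
#' @param genome `chrom`/`length` table.
#' @param telomere_pad bases masked at each chromosome end.
#' @param centromere_frac fraction of each chromosome, centred at the
#'   midpoint, treated as centromeric.
#' @param acro_frac fraction of acrocentric chromosomes masked as the p-arm.
#' @return `GRanges` of excluded regions, sorted and merged.
#' @export
default_mask <- function(genome = mini_genome(), telomere_pad = 5e6,
                         centromere_frac = 0.03, acro_frac = 0.4) {
  len <- stats::setNames(genome$length, genome$chrom)
  gr <- list()
  add <- function(chrom, start, end)
    gr[[length(gr) + 1L]] <<- data.frame(chrom = chrom, start = start,
                                         end = end)
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[i]; L <- genome$length[i]
    if (grepl("chr[XY]$", chrom)) { add(chrom, 0, L); next }
    add(chrom, 0, min(telomere_pad, L))                       # p telomere
    add(chrom, max(0, L - telomere_pad), L)                   # q telomere
    half <- centromere_frac / 2
    add(chrom, floor(L * (0.5 - half)), ceiling(L * (0.5 + half)))
    if (chrom %in% paste0("chr", c(13, 14, 15, 21, 22)))
      add(chrom, 0, floor(L * acro_frac))                     # acrocentric p
  }
  # HLA on chr6: scale the ~29.6-32.4 Mb GRCh38 locus to the genome
  if ("chr6" %in% genome$chrom) {
    L6 <- len[["chr6"]]
    add("chr6", floor(L6 * 0.119), ceiling(L6 * 0.131))
  }
  tab <- do.call(rbind, gr)
  mask <- GenomicRanges::GRanges(
    factor(tab$chrom, levels = genome$chrom),
    IRanges::IRanges(tab$start + 1, tab$end), seqlengths = len)
  GenomicRanges::reduce(sort(mask))
}

#' Read a filter mask from BED
#' @param path BED file (0-based half-open).
#' @param genome `chrom`/`length` table.
#' @return sorted, merged `GRanges`.
#' @export
read_mask_bed <- function(path, genome = mini_genome()) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  gr <- GenomicRanges::GRanges(norm_chrom(bed$chrom),
                               IRanges::IRanges(bed$start + 1, bed$end))
  gr <- GenomicRanges::reduce(sort(gr))
  GenomeInfoDb::seqlevels(gr) <- genome$chrom
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(genome$length, genome$chrom)
  gr
}

#' Remove masked territory from a set of intervals
#'
#' Any bin overlapping the mask is dropped wholesale; segments are instead
#' intersected with the retained territory (controlled by `mode`).
#'
#' @param x `GRanges` of bins or segments.
#' @param mask `GRanges` of excluded regions.
#' @param mode `"drop"` removes any interval overlapping the mask (bins);
#'   `"intersect"` trims intervals to unmasked territory (segments).
#' @return filtered `GRanges` (metadata columns preserved under `"drop"`).
#' @export
apply_filters <- function(x, mask, mode = c("drop", "intersect")) {
  mode <- match.arg(mode)
  if (mode == "drop") {
    x[!IRanges::overlapsAny(x, mask)]
  } else {
    hits <- GenomicRanges::setdiff(x, mask, ignore.strand = TRUE)
    hits
  }
}

segments_to_granges <- function(segments) {
  GenomicRanges::GRanges(
    segments$chrom,
    IRanges::IRanges(segments$start + 1, segments$end),
    sample_id = segments$sample_id,
    major1 = segments$major1, minor1 = segments$minor1, frac1 = segments$frac1,
    major2 = segments$major2, minor2 = segments$minor2, frac2 = segments$frac2)
}

# class of each segment state; a segment "carries" class c if either of its
# cellular states is of class c
segment_classes <- function(segments, wgd_by_sample) {
  wgd <- wgd_by_sample[segments$sample_id]
  cls1 <- classify_scna(segments$major1, segments$minor1, wgd)
  cls2 <- rep(NA_character_, nrow(segments))
  two <- !is.na(segments$major2)
  if (any(two))
    cls2[two] <- classify_scna(segments$major2[two], segments$minor2[two],
                               wgd[two])
  list(state1 = cls1, state2 = cls2)
}

#' Upper-tail exact binomial recurrence probability
#'
#' Probability of observing at least `k` altered samples out of `n` when
#' each is altered independently with the cohort-background probability
#' `p_bar`; the exact tail sum, not a normal approximation.
#'
#' @param k observed altered-sample count (vectorised).
#' @param n cohort size.
#' @param p_bar background alteration probability in `[0,1]`.
#' @return `P(X >= k)` for `X ~ Binomial(n, p_bar)`.
#' @export
binomial_recurrence_p <- function(k, n, p_bar) {
  if (any(p_bar < 0 | p_bar > 1)) stop("p_bar outside [0,1]", call. = FALSE)
  stopifnot(all(k >= 0), all(k <= n))
  stats::pbinom(k - 1, size = n, prob = p_bar, lower.tail = FALSE)
}

#' Scan the genome for recurrently altered loci
#'
#' Tiles unmasked autosomal territory into fixed-size bins and, separately
#' for gains, LOH and homozygous deletions, tests each bin for more altered
#' samples than expected under a per-class background rate (mean across
#' samples of the unmasked genome fraction carrying the class). P-values
#' are exact binomial upper tails, adjusted by Benjamini-Hochberg jointly
#' across bins and classes; significant adjacent bins are merged, extended
#' to the union of the overlapping same-class sample segments, and merged
#' again. Non-LOH losses are classified but not scanned.
#'
#' @param cohort a `pl_cohort`.
#' @param mask excluded territory (`GRanges`); default `default_mask()` on
#'   the cohort genome.
#' @param bin_size bin width in bases (default 1 Mb).
#' @param alpha FDR threshold (default 0.05).
#' @return list with `regions` (`GRanges` with `class` metadata) and `bins`
#'   (per-bin test table).
#' @export
scan_recurrent_scnas <- function(cohort, mask = NULL, bin_size = 1e6,
                                 alpha = 0.05) {
  if (!nrow(cohort$samples)) stop("empty cohort", call. = FALSE)
  if (bin_size <= 0) stop("bin_size must be positive", call. = FALSE)
  if (is.null(mask)) mask <- default_mask(cohort$genome)
  genome <- cohort$genome
  seqlen <- stats::setNames(genome$length, genome$chrom)
  territory <- GenomicRanges::GRanges(
    genome$chrom, IRanges::IRanges(1, genome$length), seqlengths = seqlen)
  unmasked <- GenomicRanges::setdiff(territory, mask, ignore.strand = TRUE)
  total_unmasked <- sum(IRanges::width(unmasked))

  bins <- GenomicRanges::slidingWindows(territory, width = bin_size,
                                        step = bin_size)
  bins <- unlist(bins)
  bins <- apply_filters(bins, mask, "drop")

  wgd_by_sample <- stats::setNames(cohort$samples$wgd,
                                   cohort$samples$sample_id)
  seg <- cohort$segments
  cls <- segment_classes(seg, wgd_by_sample)
  gr_all <- segments_to_granges(seg)
  GenomeInfoDb::seqlevels(gr_all) <- genome$chrom
  GenomeInfoDb::seqlengths(gr_all) <- seqlen
  n <- nrow(cohort$samples)

  res <- list(); region_list <- list()
  for (class in c("GAIN", "LOH", "HD")) {
    pick <- cls$state1 == class | (!is.na(cls$state2) & cls$state2 == class)
    gr <- gr_all[pick]
    # per-sample background: unmasked bases of this class / total unmasked
    # (segments are disjoint within a sample, so overlap widths just add)
    ov <- GenomicRanges::findOverlaps(gr, unmasked)
    w <- IRanges::width(IRanges::pintersect(
      GenomicRanges::granges(gr)[S4Vectors::queryHits(ov)],
      unmasked[S4Vectors::subjectHits(ov)]))
    class_bases <- rowsum(as.numeric(w), gr$sample_id[S4Vectors::queryHits(ov)])
    p_bar <- sum(class_bases) / (n * as.numeric(total_unmasked))
    # per bin: number of distinct samples with class overlap
    hits <- GenomicRanges::findOverlaps(bins, gr)
    k <- rep(0L, length(bins))
    if (length(hits)) {
      tab <- unique(data.frame(bin = S4Vectors::queryHits(hits),
                               sid = gr$sample_id[S4Vectors::subjectHits(hits)]))
      cnt <- table(tab$bin)
      k[as.integer(names(cnt))] <- as.integer(cnt)
    }
    res[[class]] <- data.frame(
      class = class, chrom = as.character(GenomeInfoDb::seqnames(bins)),
      start = GenomicRanges::start(bins) - 1, end = GenomicRanges::end(bins),
      k = k, n = n, p_bar = p_bar,
      p = binomial_recurrence_p(k, n, p_bar))
  }
  bin_tab <- do.call(rbind, res)
  bin_tab$fdr <- bh_fdr(bin_tab$p)
  bin_tab$significant <- bin_tab$fdr < alpha

  for (class in c("GAIN", "LOH", "HD")) {
    sig <- bin_tab[bin_tab$class == class & bin_tab$significant, ]
    if (!nrow(sig)) next
    sig_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      sig$chrom, IRanges::IRanges(sig$start + 1, sig$end),
      seqlengths = seqlen))
    pick <- cls$state1 == class | (!is.na(cls$state2) & cls$state2 == class)
    gr <- gr_all[pick]
    # extend each merged region to the union of overlapping sample segments
    hits <- GenomicRanges::findOverlaps(sig_gr, gr)
    if (length(hits)) {
      ext <- c(sig_gr[unique(S4Vectors::queryHits(hits))],
               GenomicRanges::granges(gr[unique(S4Vectors::subjectHits(hits))]))
      sig_gr <- GenomicRanges::reduce(ext)
    }
    sig_gr <- GenomicRanges::intersect(sig_gr, unmasked, ignore.strand = TRUE)
    sig_gr$class <- class
    region_list[[class]] <- sig_gr
  }
  regions <- if (length(region_list)) {
    out <- do.call(c, unname(region_list))
    sort(out)
  } else GenomicRanges::GRanges()
  list(regions = regions, bins = bin_tab)
}

#' Build the cohort-wide event catalog
#'
#' One event per recurrent SCNA region, one per driver gene whose SNV
#' prevalence meets `min_snv_prev` (inclusive; the 3 percent rule), and one
#' whole-genome-duplication event. Prevalence is the fraction of cohort
#' samples carrying the event.
#'
#' @param cohort a `pl_cohort`.
#' @param regions `GRanges` from [scan_recurrent_scnas()] with a `class`
#'   column.
#' @param driver_list candidate genes (default the cohort's list).
#' @param min_snv_prev minimum SNV prevalence (default 0.03).
#' @param min_overlap_frac passed through to presence counting.
#' @return data.frame catalog: `event_id`, `kind`, `chrom`, `start`, `end`,
#'   `gene`, `prevalence`.
#' @export
build_catalog <- function(cohort, regions, driver_list = cohort$driver_list,
                          min_snv_prev = 0.03, min_overlap_frac = 0.5) {
  stopifnot(min_snv_prev > 0, min_snv_prev < 1)
  n <- nrow(cohort$samples)
  rows <- list()
  if (length(regions)) {
    for (i in seq_along(regions)) {
      r <- regions[i]
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = sprintf("%s_%s_%.1fMb", r$class,
                           as.character(GenomeInfoDb::seqnames(r)),
                           GenomicRanges::start(r) / 1e6),
        kind = r$class,
        chrom = as.character(GenomeInfoDb::seqnames(r)),
        start = GenomicRanges::start(r) - 1, end = GenomicRanges::end(r),
        gene = NA_character_, prevalence = NA_real_)
    }
  }
  mutated <- table(unique(cohort$snvs[c("sample_id", "gene")])$gene)
  for (g in driver_list) {
    prev <- if (g %in% names(mutated)) mutated[[g]] / n else 0
    if (prev >= min_snv_prev)
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = paste0("SNV_", g), kind = "SNV",
        chrom = NA_character_, start = NA_real_, end = NA_real_,
        gene = g, prevalence = prev)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    event_id = "WGD", kind = "WGD", chrom = NA_character_,
    start = NA_real_, end = NA_real_, gene = NA_character_,
    prevalence = mean(cohort$samples$wgd))
  catalog <- do.call(rbind, rows)
  if (anyDuplicated(catalog$event_id))
    catalog$event_id <- make.unique(catalog$event_id, sep = "_")
  scna <- catalog$kind %in% c("GAIN", "LOH", "HD")
  if (any(scna)) {
    pres <- presence_matrix(cohort, catalog, min_overlap_frac)
    catalog$prevalence[match(colnames(pres), catalog$event_id)] <-
      colMeans(pres)
  }
  if (!nrow(catalog)) stop("empty event catalog: nothing to order",
                           call. = FALSE)
  rownames(catalog) <- NULL
  catalog
}

#' Events present in one sample, with clonality and WGD timing
#'
#' An SCNA event is present when same-class segments cover at least
#' `min_overlap_frac` of its region; it is subclonal when the covering
#' segment carries two cellular states with the altered state at fraction
#' < 1, in which case the altered-state fraction is matched to the nearest
#' mutation-cluster CCF. An SNV event is present when the gene is mutated,
#' clonal when its cluster's CCF reaches `clonal_band`. WGD is present in
#' WGD samples and is always clonal. Clonal events in WGD samples receive a
#' parsimony pre/post-WGD timing; SNVs are timed by mutant multiplicity
#' (>= 2 implies pre-WGD).
#'
#' @param cohort a `pl_cohort`.
#' @param sample_id one sample.
#' @param catalog event catalog from [build_catalog()].
#' @param min_overlap_frac region coverage needed to call an SCNA present.
#' @param clonal_band CCF at or above which a cluster is clonal.
#' @return data.frame: `event_id`, `clonality`, `timing`, `cluster_id`,
#'   `ccf`. Zero rows when the sample carries none of the catalog.
#' @export
event_presence <- function(cohort, sample_id, catalog,
                           min_overlap_frac = 0.5, clonal_band = 0.9) {
  smp <- cohort$samples[cohort$samples$sample_id == sample_id, ]
  stopifnot(nrow(smp) == 1)
  seg <- sample_segments(cohort, sample_id)
  clus <- cohort$clusters[cohort$clusters$sample_id == sample_id, ]
  clonal_cluster <- if (nrow(clus))
    clus$cluster_id[which.max(clus$ccf)] else NA
  out <- list()
  scna_cat <- catalog[catalog$kind %in% c("GAIN", "LOH", "HD"), , drop = FALSE]
  if (nrow(scna_cat) && nrow(seg)) {
    cls <- segment_classes(seg, stats::setNames(smp$wgd, sample_id))
    for (i in seq_len(nrow(scna_cat))) {
      ev <- scna_cat[i, ]
      match1 <- cls$state1 == ev$kind
      match2 <- !is.na(cls$state2) & cls$state2 == ev$kind
      hit <- (match1 | match2) & seg$chrom == ev$chrom &
        seg$start < ev$end & seg$end > ev$start
      if (!any(hit)) next
      cov <- sum(pmin(seg$end[hit], ev$end) - pmax(seg$start[hit], ev$start))
      if (cov / (ev$end - ev$start) < min_overlap_frac) next
      h <- which(hit)
      two_state <- !is.na(seg$frac2[h])
      subclonal <- any(two_state)
      if (subclonal) {
        j <- h[two_state][1]
        alt_is_2 <- match2[j]
        frac <- if (alt_is_2) seg$frac2[j] else seg$frac1[j]
        altM <- if (alt_is_2) seg$major2[j] else seg$major1[j]
        altm <- if (alt_is_2) seg$minor2[j] else seg$minor1[j]
        cl <- if (nrow(clus)) clus$cluster_id[which.min(abs(clus$ccf - frac))]
              else NA
        out[[length(out) + 1L]] <- data.frame(
          event_id = ev$event_id, clonality = "SUBCLONAL",
          timing = NA_character_, cluster_id = as.character(cl), ccf = frac)
      } else {
        j <- h[1]
        timing <- if (smp$wgd)
          classify_wgd_timing(seg$major1[j], seg$minor1[j]) else NA_character_
        out[[length(out) + 1L]] <- data.frame(
          event_id = ev$event_id, clonality = "CLONAL", timing = timing,
          cluster_id = as.character(clonal_cluster), ccf = 1)
      }
    }
  }
  snv_cat <- catalog[catalog$kind == "SNV", , drop = FALSE]
  if (nrow(snv_cat)) {
    snv <- cohort$snvs[cohort$snvs$sample_id == sample_id, ]
    for (i in seq_len(nrow(snv_cat))) {
      g <- snv_cat$gene[i]
      hit <- snv[snv$gene == g, ]
      if (!nrow(hit)) next
      hit <- hit[1, ]
      ccf <- clus$ccf[match(hit$cluster_id, clus$cluster_id)]
      clonal <- !is.na(ccf) && ccf >= clonal_band
      timing <- if (smp$wgd && clonal) {
        if (hit$multiplicity >= 2) "EARLY_CLONAL" else "LATE_CLONAL"
      } else NA_character_
      out[[length(out) + 1L]] <- data.frame(
        event_id = snv_cat$event_id[i],
        clonality = if (clonal) "CLONAL" else "SUBCLONAL",
        timing = timing, cluster_id = as.character(hit$cluster_id), ccf = ccf)
    }
  }
  if (smp$wgd && "WGD" %in% catalog$event_id)
    out[[length(out) + 1L]] <- data.frame(
      event_id = "WGD", clonality = "CLONAL", timing = "WGD",
      cluster_id = as.character(clonal_cluster), ccf = 1)
  if (!length(out))
    return(data.frame(event_id = character(), clonality = character(),
                      timing = character(), cluster_id = character(),
                      ccf = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Binary presence matrix of catalog events across samples
#' @param cohort a `pl_cohort`.
#' @param catalog event catalog.
#' @param min_overlap_frac,clonal_band see [event_presence()].
#' @return logical matrix, samples x events.
#' @export
presence_matrix <- function(cohort, catalog, min_overlap_frac = 0.5,
                            clonal_band = 0.9) {
  ids <- cohort$samples$sample_id
  mat <- matrix(FALSE, nrow = length(ids), ncol = nrow(catalog),
                dimnames = list(ids, catalog$event_id))
  for (sid in ids) {
    pres <- event_presence(cohort, sid, catalog, min_overlap_frac, clonal_band)
    mat[sid, pres$event_id] <- TRUE
  }
  mat
}
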