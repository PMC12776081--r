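#' Cohort container
#'
#' A `pl_cohort` is a plain list of linked tables describing a tumour cohort:
#' \describe{
#'   \item{samples}{one row per tumour: `sample_id`, `purity` (0,1],
#'     `nrpcc` (reads per chromosome copy), `wgd` (logical), `smoking`
#'     (`"ever"`/`"never"`), `ancestry` (`"EUR"`/`"EAS"`/`"OTHER"`), `sex`
#'     (`"M"`/`"F"`), `age_dx` (years), `sbs4` (logical), `sv_count`,
#'     `kataegis`, `snv_total`, `survival_weeks` (may be `NA`).}
#'   \item{segments}{allele-specific copy-number segments in 0-based
#'     half-open coordinates: `sample_id`, `chrom`, `start`, `end`,
#'     `major1`, `minor1`, `frac1` and optional second subclonal state
#'     `major2`, `minor2`, `frac2` (`NA` when the segment is clonal).
#'     A segment is clonal iff it has exactly one state.}
#'   \item{snvs}{driver-gene SNV calls: `sample_id`, `gene`, `cluster_id`,
#'     `multiplicity` (mutant-allele copies, >= 1).}
#'   \item{clusters}{mutation clusters: `sample_id`, `cluster_id`, `ccf`
#'     (cancer cell fraction in (0,1]), `n_mutations`.}
#'   \item{signatures}{optional wide activity matrix, `sample_id` plus one
#'     non-negative column per signature.}
#'   \item{driver_list}{character vector of candidate driver genes.}
#'   \item{genome}{`chrom`/`length` table defining the reference territory.}
#' }
#'
#' @param samples,segments,snvs,clusters,signatures,driver_list,genome see
#'   Description.
#' @param provenance free-form list recording how the cohort was made.
#' @return A validated object of class `pl_cohort`.
#' @export
new_cohort <- function(samples, segments, snvs, clusters,
                       driver_list, genome = mini_genome(),
                       signatures = NULL, provenance = list()) {
  unrowname <- function(df) { rownames(df) <- NULL; df }
  cohort <- structure(
    list(samples = unrowname(as.data.frame(samples)),
         segments = unrowname(as.data.frame(segments)),
         snvs = unrowname(as.data.frame(snvs)),
         clusters = unrowname(as.data.frame(clusters)),
         signatures = if (is.null(signatures)) NULL else
           unrowname(as.data.frame(signatures)),
         driver_list = as.character(driver_list),
         genome = as.data.frame(genome),
         provenance = provenance),
    class = "pl_cohort")
  validate_cohort(cohort)
  cohort
}

#' @export
print.pl_cohort <- function(x, ...) {
  cat(sprintf("pl_cohort: %d samples, %d segments, %d SNV calls, %d clusters\n",
              nrow(x$samples), nrow(x$segments), nrow(x$snvs), nrow(x$clusters)))
  cat(sprintf("driver list: %d genes; genome: %d chromosomes (%.0f Mb)\n",
              length(x$driver_list), nrow(x$genome), sum(x$genome$length) / 1e6))
  invisible(x)
}

SAMPLE_COLS <- c("sample_id", "purity", "nrpcc", "wgd", "smoking", "ancestry",
                 "sex", "age_dx", "sbs4", "sv_count", "kataegis", "snv_total",
                 "survival_weeks")
SEGMENT_COLS <- c("sample_id", "chrom", "start", "end",
                  "major1", "minor1", "frac1", "major2", "minor2", "frac2")
SNV_COLS <- c("sample_id", "gene", "cluster_id", "multiplicity")
CLUSTER_COLS <- c("sample_id", "cluster_id", "ccf", "n_mutations")

#' Validate a cohort's structural invariants
#'
#' Checks schema columns, coordinate sanity (`end > start`, minor <= major,
#' state fractions summing to 1 within 1e-6, at most two states), referential
#' integrity of SNV cluster links and driver-list membership, uniqueness of
#' sample ids, and non-overlap of segments within a chromosome. Errors name
#' the offending sample and row.
#'
#' @param cohort a `pl_cohort`.
#' @return `cohort`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "pl_cohort"))
  for (spec in list(list("samples", SAMPLE_COLS), list("segments", SEGMENT_COLS),
                    list("snvs", SNV_COLS), list("clusters", CLUSTER_COLS))) {
    missing <- setdiff(spec[[2]], names(cohort[[spec[[1]]]]))
    if (length(missing))
      stop(sprintf("schema error in '%s': missing column(s) %s",
                   spec[[1]], paste(missing, collapse = ", ")), call. = FALSE)
  }
  smp <- cohort$samples
  if (anyDuplicated(smp$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  if (nrow(smp) && (any(smp$purity <= 0 | smp$purity > 1)))
    stop("purity must lie in (0, 1]", call. = FALSE)

  seg <- cohort$segments
  if (nrow(seg)) {
    bad <- which(seg$end <= seg$start)
    if (length(bad))
      stop(sprintf("segment end <= start (sample %s, row %d)",
                   seg$sample_id[bad[1]], bad[1]), call. = FALSE)
    bad <- which(seg$minor1 > seg$major1 |
                   (!is.na(seg$minor2) & seg$minor2 > seg$major2))
    if (length(bad))
      stop(sprintf("validation error: minor > major (sample %s, row %d)",
                   seg$sample_id[bad[1]], bad[1]), call. = FALSE)
    if (any(seg$major1 < 0 | seg$minor1 < 0, na.rm = TRUE))
      stop("negative copy number in segments", call. = FALSE)
    two <- !is.na(seg$frac2)
    fsum <- ifelse(two, seg$frac1 + seg$frac2, seg$frac1)
    bad <- which(abs(fsum - 1) > 1e-6)
    if (length(bad))
      stop(sprintf("state fractions do not sum to 1 (sample %s, row %d)",
                   seg$sample_id[bad[1]], bad[1]), call. = FALSE)
    # non-overlap within sample x chromosome
    key <- paste(seg$sample_id, seg$chrom)
    ord <- order(key, seg$start)
    s <- seg[ord, ]; k <- key[ord]
    same <- k[-1] == k[-length(k)]
    if (any(same & s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments within a chromosome", call. = FALSE)
  }
  if (nrow(cohort$snvs)) {
    bad <- setdiff(cohort$snvs$gene, cohort$driver_list)
    if (length(bad))
      stop(sprintf("SNV gene(s) not in driver list: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    have <- paste(cohort$clusters$sample_id, cohort$clusters$cluster_id)
    want <- paste(cohort$snvs$sample_id, cohort$snvs$cluster_id)
    orphan <- which(!want %in% have)
    if (length(orphan))
      stop(sprintf("validation error: SNV references unknown cluster (sample %s, cluster %s)",
                   cohort$snvs$sample_id[orphan[1]],
                   cohort$snvs$cluster_id[orphan[1]]), call. = FALSE)
  }
  if (nrow(cohort$clusters) &&
      any(cohort$clusters$ccf <= 0 | cohort$clusters$ccf > 1 + 1e-9))
    stop("cluster CCF must lie in (0, 1]", call. = FALSE)
  invisible(cohort)
}

#' Mini reference genome used by the synthetic cohort
#'
#' 22 autosomes plus X and Y, 100 Mb each; scans over real Battenberg output
#' take a table of true chromosome lengths instead.
#'
#' @param n_autosomes number of autosomes.
#' @param chrom_length length of every chromosome in bases.
#' @return data.frame with `chrom` and `length`.
#' @export
mini_genome <- function(n_autosomes = 22, chrom_length = 1e8) {
  data.frame(chrom = paste0("chr", c(seq_len(n_autosomes), "X", "Y")),
             length = chrom_length)
}

norm_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
}

#' Read a cohort from its TSV file set
#'
#' Consumes Battenberg/DPClust-style tabular exports: a sample sheet, a
#' segment table (up to two subclonal states per row, state-2 columns blank
#' when clonal), an SNV table, a cluster table and a driver list (one gene
#' per line). Coordinates are normalised internally to 0-based half-open;
#' the input dialect defaults to 1-based inclusive as in Battenberg-style
#' tables. Chromosome names are normalised to a "chr" prefix.
#'
#' @param sample_sheet_path,segments_path,snv_path,clusters_path,driver_list_path
#'   input file paths.
#' @param signatures_path optional wide signature-activity TSV.
#' @param genome reference territory (`chrom`, `length`).
#' @param coords `"1-based-inclusive"` (default) or `"0-based-half-open"`.
#' @return A `pl_cohort`.
#' @export
read_cohort <- function(sample_sheet_path, segments_path, snv_path,
                        clusters_path, driver_list_path,
                        signatures_path = NULL, genome = mini_genome(),
                        coords = c("1-based-inclusive", "0-based-half-open")) {
  coords <- match.arg(coords)
  for (p in c(sample_sheet_path, segments_path, snv_path, clusters_path,
              driver_list_path))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  rd <- function(p) utils::read.delim(p, sep = "\t", stringsAsFactors = FALSE,
                                      check.names = FALSE)
  samples <- rd(sample_sheet_path)
  segments <- rd(segments_path)
  snvs <- rd(snv_path)
  clusters <- rd(clusters_path)
  if (!"survival_weeks" %in% names(samples)) samples$survival_weeks <- NA_real_
  if (nrow(samples)) {
    samples$wgd <- as.logical(samples$wgd)
    samples$sbs4 <- as.logical(samples$sbs4)
  }
  if (nrow(segments)) {
    segments$chrom <- norm_chrom(segments$chrom)
    if (coords == "1-based-inclusive") segments$start <- segments$start - 1
  }
  signatures <- if (!is.null(signatures_path)) rd(signatures_path) else NULL
  driver_list <- readLines(driver_list_path)
  driver_list <- driver_list[nzchar(driver_list)]
  new_cohort(samples, segments, snvs, clusters, driver_list, genome,
             signatures,
             provenance = list(coords_in = coords))
}

#' Write a cohort as a round-trippable TSV file set
#'
#' Emits `samples.tsv`, `segments.tsv`, `snvs.tsv`, `clusters.tsv`,
#' `driver_list.txt`, `genome.tsv` and, when present, `signatures.tsv`.
#' Coordinates are written 1-based inclusive so that
#' `read_cohort()` on the output reproduces the cohort exactly; numeric
#' fields are written at full precision (15 significant digits).
#'
#' @param cohort a `pl_cohort`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, out_dir) {
  validate_cohort(cohort)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
    df[num] <- lapply(df[num], function(x) ifelse(x == "NA", NA, x))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  seg <- cohort$segments
  if (nrow(seg)) seg$start <- seg$start + 1   # back to 1-based inclusive
  files <- c(
    samples = wr(cohort$samples, "samples.tsv"),
    segments = wr(seg, "segments.tsv"),
    snvs = wr(cohort$snvs, "snvs.tsv"),
    clusters = wr(cohort$clusters, "clusters.tsv"),
    genome = wr(cohort$genome, "genome.tsv"))
  if (!is.null(cohort$signatures))
    files <- c(files, signatures = wr(cohort$signatures, "signatures.tsv"))
  writeLines(cohort$driver_list, file.path(out_dir, "driver_list.txt"))
  files <- c(files, driver_list = file.path(out_dir, "driver_list.txt"))
  invisible(files)
}

#' Quality-control filter on sequencing power and purity
#'
#' Retains samples whose reads-per-chromosome-copy and tumour purity both
#' meet their minimum (thresholds are inclusive: "a minimum of 10" keeps
#' exactly 10). Excluded sample ids are reported via `message()`. Filtering
#' is idempotent and preserves sample order.
#'
#' @param cohort a `pl_cohort`.
#' @param min_nrpcc minimum reads per chromosome copy (default 10).
#' @param min_purity minimum tumour purity (default 0.30).
#' @return The filtered `pl_cohort`.
#' @export
qc_filter <- function(cohort, min_nrpcc = 10, min_purity = 0.30) {
  stopifnot(min_nrpcc >= 0, min_purity >= 0)
  keep <- cohort$samples$nrpcc >= min_nrpcc & cohort$samples$purity >= min_purity
  dropped <- cohort$samples$sample_id[!keep]
  if (length(dropped))
    message("qc_filter: excluding ", length(dropped), " sample(s): ",
            paste(dropped, collapse = ", "))
  if (!any(keep)) warning("qc_filter removed every sample", call. = FALSE)
  subset_cohort(cohort, cohort$samples$sample_id[keep])
}

#' Restrict a cohort to a set of samples
#' @param cohort a `pl_cohort`.
#' @param sample_ids ids to keep, in cohort order.
#' @return A `pl_cohort` containing only those samples.
#' @export
subset_cohort <- function(cohort, sample_ids) {
  keep <- cohort$samples$sample_id %in% sample_ids
  out <- cohort
  out$samples <- cohort$samples[keep, , drop = FALSE]
  for (tab in c("segments", "snvs", "clusters")) {
    out[[tab]] <- cohort[[tab]][cohort[[tab]]$sample_id %in% sample_ids, ,
                                drop = FALSE]
    rownames(out[[tab]]) <- NULL
  }
  if (!is.null(cohort$signatures))
    out$signatures <- cohort$signatures[
      cohort$signatures$sample_id %in% sample_ids, , drop = FALSE]
  rownames(out$samples) <- NULL
  if (!is.null(out$signatures)) rownames(out$signatures) <- NULL
  out
}

#' Per-sample segment table
#' @param cohort a `pl_cohort`.
#' @param sample_id one sample id.
#' @return data.frame of the sample's segments.
#' @export
sample_segments <- function(cohort, sample_id) {
  cohort$segments[cohort$segments$sample_id == sample_id, , drop = FALSE]
}
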