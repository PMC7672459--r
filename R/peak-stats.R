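# Peak-PQS overlap statistics, fold-change stratification and
# enrichment summaries.

#' Fraction of peaks overlapping at least one PQS
#'
#' A peak is PQS-positive when any motif overlaps it by one or more
#' nucleotides; motif strand is ignored (a peak is double-stranded DNA).
#' Restricting `motifs` to subsets of classes reproduces the
#' four-subtypes-only versus with-hybrids comparison.
#'
#' @param peaks Data frame with chrom/start/end.
#' @param motifs Data frame with chrom/start/end (any subtype mix).
#' @return List with `fraction` (flagged / total) and logical `positive`
#'   per peak.
#' @export
peak_pqs_overlap <- function(peaks, motifs) {
  if (!nrow(peaks)) stop("empty peak list")
  flag <- logical(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    mi <- which(motifs$chrom == ch)
    if (!length(mi)) next
    flag[pi] <- IRanges::overlapsAny(.ir(peaks$start[pi], peaks$end[pi]),
                                     .ir(motifs$start[mi], motifs$end[mi]))
  }
  list(fraction = mean(flag), positive = flag)
}

#' Stratify peaks by fold-change threshold and genomic region
#'
#' For each ascending threshold, peaks with `fold_enrichment >= t` are
#' counted per region label under the midpoint rule and expressed as percent
#' of the peaks passing that threshold; `pct_genic` is the percent falling
#' in the gene +/- flank union (promoter, intragenic or TES flank).
#'
#' @param peaks Data frame with chrom/start/end/fold_enrichment.
#' @param partition A [partition_regions()] result.
#' @param thresholds Ascending numeric fold-change thresholds.
#' @return Data frame with one row per (threshold, label): `threshold`,
#'   `label`, `count`, `pct`, `n_passing`, `pct_genic`.
#' @export
stratify_peaks <- function(peaks, partition, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE)) stop("thresholds must be ascending")
  asg <- assign_to_regions(peaks, partition, rule = "midpoint")
  lab <- attr(asg, "label")
  out <- list()
  for (t in thresholds) {
    pass <- peaks$fold_enrichment >= t
    n <- sum(pass)
    cnt <- vapply(partition$labels, function(l) sum(pass & lab == l, na.rm = TRUE), 0)
    genic <- sum(cnt[c("promoter", "intragenic", "tes_flank")])
    out[[length(out) + 1L]] <- data.frame(
      threshold = t, label = partition$labels, count = unname(cnt),
      pct = if (n) unname(cnt) / n * 100 else 0,
      n_passing = n, pct_genic = if (n) genic / n * 100 else 0,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean profiles stratified by PQS load
#'
#' Splits a signal matrix's rows into disjoint load strata (e.g. 0, 1-2, >=3
#' motifs near the TSS) and returns the mean profile of each.
#'
#' @param sm A `signal_matrix` whose rows correspond to `loads`.
#' @param loads Integer vector, one load per matrix row.
#' @param load_strata Named list of `c(lo, hi)` inclusive load ranges; must
#'   be disjoint.
#' @return List with `profiles` (named list of mean-profile vectors) and
#'   `sizes` (rows per stratum).
#' @export
enrichment_by_load <- function(sm, loads, load_strata) {
  m <- if (inherits(sm, "signal_matrix")) sm$values else sm
  if (length(loads) != nrow(m)) stop("loads length must match matrix rows")
  if (length(load_strata) > 1L) {
    for (i in seq_along(load_strata)[-1]) for (j in seq_len(i - 1L)) {
      a <- load_strata[[i]]; b <- load_strata[[j]]
      if (a[1] <= b[2] && b[1] <= a[2]) stop("load strata not disjoint")
    }
  }
  member <- lapply(load_strata, function(r) loads >= r[1] & loads <= r[2])
  profiles <- lapply(member, function(sel)
    if (any(sel)) colMeans(m[sel, , drop = FALSE]) else numeric(ncol(m)))
  list(profiles = profiles, sizes = vapply(member, sum, 0L))
}

#' Mean G4P enrichment profile at motif centers, per subtype
#'
#' Computes a reference-point profile of the (already input-subtracted)
#' track around motif centers (`floor((start + end) / 2)`, ties toward
#' start), separately for each subtype; rows are oriented by motif strand.
#'
#' @param track A [coverage_track()] (typically subtract mode, RPKM).
#' @param motifs Output of [scan_genome()].
#' @param half_width,bin_size Window geometry as in
#'   [reference_point_matrix()].
#' @return Named list (one entry per subtype present in `motifs`) of lists
#'   with `profile` (mean profile) and `n` (motif count); subtypes with zero
#'   motifs are reported with `n = 0` and a zero profile.
#' @export
enrichment_at_subtypes <- function(track, motifs, half_width = 1000L, bin_size = 50L) {
  subs <- sort(unique(motifs$subtype))
  out <- list()
  for (s in subs) {
    m <- motifs[motifs$subtype == s, , drop = FALSE]
    if (!nrow(m)) {
      out[[s]] <- list(profile = numeric(2L * half_width %/% bin_size), n = 0L)
      next
    }
    anchors <- data.frame(chrom = m$chrom, pos = (m$start + m$end) %/% 2L,
                          strand = m$strand, stringsAsFactors = FALSE)
    sm <- reference_point_matrix(track, anchors, half_width, bin_size)
    out[[s]] <- list(profile = mean_profile(sm), n = nrow(m))
  }
  out
}

#' Deterministic pipeline summary report
#'
#' One long-format table aggregating motif counts per subtype and subtype
#' combination, peak PQS-positivity (four subtypes only, and counting
#' hybrids in), region nucleotide percentages, and the peak stratification
#' table.  Rerunning on identical inputs yields a byte-identical file.
#'
#' @param motifs Output of [scan_genome()].
#' @param peaks Data frame with chrom/start/end/fold_enrichment.
#' @param partition A [partition_regions()] result.
#' @param thresholds Fold-change thresholds for [stratify_peaks()].
#' @param path Optional output path; when given the table is written as TSV.
#' @return Data frame with columns `section`, `name`, `value` (value
#'   formatted with 6 significant digits for determinism).
#' @export
summary_report <- function(motifs, peaks, partition,
                           thresholds = c(2, 3, 4, 5, 6, 8, 10), path = NULL) {
  fmt <- function(x) formatC(x, format = "g", digits = 6)
  rows <- list()
  add <- function(section, name, value)
    rows[[length(rows) + 1L]] <<- data.frame(section = section, name = name,
                                             value = fmt(value), stringsAsFactors = FALSE)
  for (s in sort(unique(motifs$subtype)))
    add("motif_counts", s, sum(motifs$subtype == s))
  merged <- merge_subtype_calls(motifs)
  for (s in sort(unique(merged$subtype)))
    add("motif_combinations", s, sum(merged$subtype == s))
  four <- motifs[motifs$subtype %in% c("4G", "4GL15", "GVBQ", "Bulge"), , drop = FALSE]
  add("peaks", "pct_pqs_positive_four_subtypes",
      peak_pqs_overlap(peaks, four)$fraction * 100)
  add("peaks", "pct_pqs_positive_with_hybrids",
      peak_pqs_overlap(peaks, motifs)$fraction * 100)
  fr <- partition_fractions(partition)
  for (k in seq_len(nrow(fr)))
    add("region_pct_nucleotides", fr$label[k], fr$fraction[k] * 100)
  strat <- stratify_peaks(peaks, partition, thresholds)
  for (k in seq_len(nrow(strat))) {
    add("stratification",
        paste0("fold_ge_", fmt(strat$threshold[k]), "_", strat$label[k], "_count"),
        strat$count[k])
    add("stratification",
        paste0("fold_ge_", fmt(strat$threshold[k]), "_", strat$label[k], "_pct"),
        strat$pct[k])
  }
  res <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
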