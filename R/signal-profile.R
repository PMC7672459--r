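# Coverage-track algebra and metaprofile/heatmap matrices.
#
# Bin values are means of per-base signal (sum over the bin divided by the
# bin size); bases outside chromosome bounds contribute 0.  Rows of
# minus-strand anchors are column-reversed so that "downstream" is always
# rightward.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' RPKM-normalise a coverage track
#'
#' Converts base coverage to reads-per-kilobase-per-million in fixed bins:
#' the read-equivalents in a bin are its summed base coverage divided by the
#' read length, and the bin value is read-equivalents / (bin kb x million
#' mapped reads).  The result is re-expanded to base resolution so all track
#' operations compose.
#'
#' @param track A [coverage_track()] with `total_mapped_reads` and
#'   `read_length` set.
#' @param bin_size Bin width in bases (default 50).
#' @return A [coverage_track()] with mode `"rpkm"`.
#' @export
rpkm_normalize <- function(track, bin_size = 50L) {
  if (is.null(track$total_mapped_reads) || is.null(track$read_length))
    stop("rpkm_normalize needs total_mapped_reads and read_length")
  vals <- lapply(track$values, function(v) {
    L <- length(v)
    nb <- ceiling(L / bin_size)
    pad <- c(v, numeric(nb * bin_size - L))
    sums <- colSums(matrix(pad, nrow = bin_size))
    widths <- pmin(seq_len(nb) * bin_size, L) - (seq_len(nb) - 1L) * bin_size
    re <- sums / track$read_length
    rpkm <- re / ((widths / 1000) * (track$total_mapped_reads / 1e6))
    rep(rpkm, times = widths)
  })
  coverage_track(vals, track$chrom_sizes, track$total_mapped_reads,
                 track$read_length, mode = "rpkm")
}

#' Compare two coverage tracks
#'
#' @param a,b [coverage_track()]s over the same chromosomes.
#' @param mode `"subtract"` (a - b per base) or `"ratio"`
#'   ((a + pseudocount) / (b + pseudocount)).
#' @param pseudocount Ratio-mode pseudocount (default 1.0).
#' @return A [coverage_track()] with the comparison mode recorded.
#' @export
compare_tracks <- function(a, b, mode = c("subtract", "ratio"), pseudocount = 1.0) {
  mode <- match.arg(mode)
  if (!setequal(names(a$values), names(b$values)))
    stop("mismatched chromosome sets")
  vals <- lapply(setNames(nm = names(a$values)), function(ch) {
    if (mode == "subtract") a$values[[ch]] - b$values[[ch]]
    else (a$values[[ch]] + pseudocount) / (b$values[[ch]] + pseudocount)
  })
  coverage_track(vals, a$chrom_sizes, a$total_mapped_reads, a$read_length,
                 mode = mode)
}

.window_bins <- function(v, from0, to0, bin_size) {
  # bin means over 0-based half-open [from0, to0); out-of-bounds bases are 0
  idx <- (from0 + 1L):to0
  w <- numeric(length(idx))
  ok <- idx >= 1L & idx <= length(v)
  w[ok] <- v[idx[ok]]
  colSums(matrix(w, nrow = bin_size)) / bin_size
}

#' Reference-point signal matrix
#'
#' One row per anchor; the window `[pos - half_width, pos + half_width)` is
#' averaged per bin.  Rows of minus-strand anchors are column-reversed so the
#' right half is always downstream.
#'
#' @param track A [coverage_track()].
#' @param anchors Data frame with `chrom`, `pos` (0-based anchor base),
#'   `strand` (`+`/`-`/`.`; `.` treated as `+`) and optionally `id`.
#' @param half_width Window half-width in bases; must be a multiple of
#'   `bin_size`.
#' @param bin_size Bin width in bases (> 0).
#' @return Object of class `signal_matrix`: list with `values` (rows =
#'   anchors, columns = bins), `bin_size`, `half_width`, `mode`.
#' @export
reference_point_matrix <- function(track, anchors, half_width = 3000L, bin_size = 50L) {
  if (bin_size <= 0L) stop("bin_size must be positive")
  if (half_width %% bin_size != 0L) stop("half_width must be a multiple of bin_size")
  nb <- 2L * half_width %/% bin_size
  m <- matrix(0, nrow = nrow(anchors), ncol = nb)
  for (k in seq_len(nrow(anchors))) {
    v <- track$values[[anchors$chrom[k]]]
    if (is.null(v)) stop("anchor chromosome '", anchors$chrom[k], "' not in track")
    row <- .window_bins(v, anchors$pos[k] - half_width, anchors$pos[k] + half_width, bin_size)
    if (!is.null(anchors$strand) && anchors$strand[k] == "-") row <- rev(row)
    m[k, ] <- row
  }
  rownames(m) <- if (!is.null(anchors$id)) anchors$id else as.character(seq_len(nrow(anchors)))
  structure(list(values = m, bin_size = bin_size, half_width = half_width,
                 mode = "reference_point"), class = "signal_matrix")
}

#' Scaled-region signal matrix
#'
#' Gene bodies are linearly rescaled onto `body_bins` bins (weighted mean of
#' the covered bases per bin, so a gene shorter than `body_bins` still
#' contributes every base and preserves its mean); flanks are binned at fixed
#' width as in [reference_point_matrix()].  Minus-strand rows are reversed.
#'
#' @param track A [coverage_track()].
#' @param genes Output of [load_genes()].
#' @param body_bins Number of bins across the gene body.
#' @param flank Flank size in bases on each side.
#' @param bin_size Flank bin width in bases.
#' @return A `signal_matrix` with `flank_bins + body_bins + flank_bins`
#'   columns, mode `"scale_regions"`.
#' @export
scale_regions_matrix <- function(track, genes, body_bins = 100L, flank = 2000L,
                                 bin_size = 50L) {
  if (flank %% bin_size != 0L) stop("flank must be a multiple of bin_size")
  fb <- flank %/% bin_size
  nb <- 2L * fb + body_bins
  m <- matrix(0, nrow = nrow(genes), ncol = nb)
  for (k in seq_len(nrow(genes))) {
    v <- track$values[[genes$chrom[k]]]
    s <- genes$start[k]; e <- genes$end[k]
    L <- e - s
    left <- .window_bins(v, s - flank, s, bin_size)
    right <- .window_bins(v, e, e + flank, bin_size)
    body <- numeric(body_bins)
    for (b in seq_len(body_bins)) {
      a0 <- s + (b - 1) * L / body_bins        # real-valued 0-based bounds
      b0 <- s + b * L / body_bins
      j <- floor(a0):(ceiling(b0) - 1)
      wgt <- pmin(b0, j + 1) - pmax(a0, j)
      keep <- wgt > 0 & j >= 0 & j < length(v)
      body[b] <- sum(v[j[keep] + 1L] * wgt[keep]) / (b0 - a0)
    }
    row <- c(left, body, right)
    if (genes$strand[k] == "-") row <- rev(row)
    m[k, ] <- row
  }
  rownames(m) <- genes$name
  structure(list(values = m, bin_size = bin_size, body_bins = body_bins,
                 flank = flank, mode = "scale_regions"), class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix (", x$mode, "): ", nrow(x$values), " regions x ",
      ncol(x$values), " bins of ", x$bin_size, " bp\n", sep = "")
  invisible(x)
}

#' Column-mean profile of a signal matrix
#'
#' @param sm A `signal_matrix` (or plain matrix).
#' @return Numeric vector of column means.
#' @export
mean_profile <- function(sm) {
  m <- if (inherits(sm, "signal_matrix")) sm$values else sm
  colMeans(m)
}

#' Scale a matrix linearly to the 0-255 range
#'
#' The global matrix minimum maps to 0 and the maximum to 255 (per matrix,
#' not per row).  A constant matrix maps to all zeros.
#'
#' @param m Numeric matrix (or `signal_matrix`).
#' @return Numeric matrix with values in \[0, 255\].
#' @export
heatmap_scale <- function(m) {
  if (inherits(m, "signal_matrix")) m <- m$values
  rng <- range(m)
  if (rng[1] == rng[2]) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Sort matrix rows by a summary statistic
#'
#' The sort is stable (ties keep input order) and the returned order can be
#' applied to other matrices over the same regions so several heatmaps share
#' one row order.
#'
#' @param m Numeric matrix or `signal_matrix`.
#' @param key `"mean"` or `"max"`.
#' @param descending Sort direction (default decreasing).
#' @return List with `values` (sorted matrix) and `order` (row permutation).
#' @export
sort_rows <- function(m, key = c("mean", "max"), descending = TRUE) {
  key <- match.arg(key)
  vals <- if (inherits(m, "signal_matrix")) m$values else m
  stat <- if (key == "mean") rowMeans(vals) else apply(vals, 1, max)
  ord <- order(if (descending) -stat else stat)
  list(values = vals[ord, , drop = FALSE], order = ord)
}

#' Shuffle intervals to random motif-free positions
#'
#' Each interval is relocated, in input order, to a uniformly random
#' same-chromosome position such that the relocated span overlaps neither
#' the exclusion intervals (e.g. all PQS spans) nor a previously placed
#' shuffled interval.  Lengths are preserved and the result is deterministic
#' given `seed`.
#'
#' @param intervals Data frame with chrom/start/end.
#' @param chrom_sizes Named integer vector.
#' @param exclusion Data frame with chrom/start/end, or `NULL`.
#' @param seed Integer seed.
#' @param max_tries Retries per interval before giving up (default 1000).
#' @return Data frame like `intervals` with new start/end.
#' @export
shuffle_intervals <- function(intervals, chrom_sizes, exclusion = NULL, seed = 1L,
                              max_tries = 1000L) {
  .with_seed(seed, {
    out <- intervals
    placed <- list()
    for (k in seq_len(nrow(intervals))) {
      ch <- intervals$chrom[k]
      len <- intervals$end[k] - intervals$start[k]
      L <- chrom_sizes[[ch]]
      if (is.null(L)) stop("chromosome '", ch, "' not in chrom_sizes")
      excl <- if (!is.null(exclusion)) exclusion[exclusion$chrom == ch, , drop = FALSE] else NULL
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- sample.int(L - len + 1L, 1L) - 1L
        hit <- .overlaps_any(s, s + len, excl)
        if (!hit && length(placed)) {
          pl <- placed[[ch]]
          if (!is.null(pl)) hit <- .overlaps_any(s, s + len, pl)
        }
        if (!hit) {
          out$start[k] <- s
          out$end[k] <- s + len
          placed[[ch]] <- rbind(placed[[ch]], data.frame(start = s, end = s + len))
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("no feasible shuffled placement for interval ", k, " (", ch,
                    ":", intervals$start[k], "-", intervals$end[k], ")")
    }
    out
  })
}
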