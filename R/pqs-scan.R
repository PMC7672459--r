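# PQS scanning: canonical (4G), long-loop (4GL15), G-vacancy (GVBQ),
# single-nucleotide bulge (Bulge) and two/three-tract hybrid motifs.
#
# Conventions used throughout this file:
#  * sequences are uppercase over {A,C,G,T,N}
#  * internally positions are 1-based; reported intervals are 0-based
#    half-open
#  * loops may contain any of A/C/G/T; N is disallowed anywhere inside a
#    motif and truncates candidates (the printed "." of the canonical
#    pattern would match N, but motifs spanning unknown bases are not
#    reported)

.empty_motifs <- function() {
  data.frame(start = integer(), end = integer(), subtype = character(),
             n_tracts = integer(), tracts = character(), loops = character(),
             bulge_offset = integer(), stringsAsFactors = FALSE)
}

.seq_state <- function(seq) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  isG <- chars == "G"
  isN <- chars == "N"
  grun <- integer(n)
  if (n) {
    r <- rle(isG)
    pos <- 1L
    for (k in seq_along(r$lengths)) {
      l <- r$lengths[k]
      if (r$values[k]) grun[pos:(pos + l - 1L)] <- l:1L
      pos <- pos + l
    }
  }
  # maximal G runs
  runs <- if (any(isG)) {
    r <- rle(isG)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep], len = r$lengths[keep])
  } else data.frame(start = integer(), len = integer())
  list(n = n, chars = chars, isG = isG, isN = isN, grun = grun, runs = runs)
}

# ---------------------------------------------------------------------------
# canonical 4G scanner: replicates backtracking-regex semantics of
# G{3,}(.{1,7}?G{3,}){3,} -- greedy G-runs, lazy loops, leftmost
# non-overlapping matches, scanning resuming after each match end.

.match_4g_at <- function(st, p) {
  n <- st$n; grun <- st$grun; isN <- st$isN
  fail <- new.env(parent = emptyenv())
  reps <- function(q, cnt) {
    key <- if (cnt < 3L) paste0(q, ":", cnt) else NULL
    if (!is.null(key) && !is.null(fail[[key]])) return(NULL)
    for (l in 1:7) {
      lc <- q + l - 1L                       # newest loop char
      if (lc > n || isN[lc]) break           # longer loops contain it too
      s <- q + l
      if (s + 2L > n) break                  # no room for a 3-G tract
      g <- grun[s]
      if (g >= 3L) {
        for (gg in seq.int(g, 3L)) {
          res <- reps(s + gg, cnt + 1L)
          if (!is.null(res)) {
            res$tracts <- c(gg, res$tracts)
            res$loops <- c(l, res$loops)
            return(res)
          }
        }
      }
    }
    if (cnt >= 3L) return(list(end = q, tracts = integer(), loops = integer()))
    fail[[key]] <- TRUE
    NULL
  }
  for (g0 in seq.int(st$grun[p], 3L)) {
    res <- reps(p + g0, 0L)
    if (!is.null(res)) {
      res$tracts <- c(g0, res$tracts)
      res$start <- p
      return(res)
    }
  }
  NULL
}

#' Find canonical 4G PQS motifs
#'
#' Matches the canonical consensus of four or more G-tracts of three or more
#' guanines separated by 1-7 nt loops, with standard regex-engine semantics
#' (greedy tracts, minimal loops, leftmost non-overlapping matches; scanning
#' resumes at the base after each match).  N never participates in a motif.
#'
#' @param seq Uppercase sequence over A/C/G/T/N.
#' @return Motif data frame with 0-based half-open `start`/`end`, `subtype`,
#'   `n_tracts`, and comma-separated `tracts` (G counts) and `loops`
#'   (loop lengths).
#' @examples
#' find_4g("GGGAGGGTGGGAGGG")
#' @export
find_4g <- function(seq) {
  st <- .seq_state(seq)
  if (st$n < 15L) return(.empty_motifs())
  out <- list()
  pos <- 1L
  runs <- st$runs
  ri <- 1L
  while (ri <= nrow(runs)) {
    rs <- runs$start[ri]; rl <- runs$len[ri]
    a <- max(rs, pos)
    if (a > rs + rl - 3L) { ri <- ri + 1L; next }
    m <- .match_4g_at(st, a)
    if (is.null(m)) {
      pos <- rs + rl                         # anchors inside this stretch fail too
      ri <- ri + 1L
    } else {
      out[[length(out) + 1L]] <- data.frame(
        start = a - 1L, end = m$end - 1L, subtype = "4G",
        n_tracts = length(m$tracts),
        tracts = paste(m$tracts, collapse = ","),
        loops = paste(m$loops, collapse = ","),
        bulge_offset = NA_integer_, stringsAsFactors = FALSE)
      pos <- m$end
      while (ri <= nrow(runs) && runs$start[ri] + runs$len[ri] - 1L < pos) ri <- ri + 1L
    }
  }
  if (!length(out)) .empty_motifs() else do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# non-canonical candidate enumeration
#
# A candidate is any span that parses as four G-tracts and three loops under
# the subtype predicate:
#   4GL15 -- four intact tracts (>=3 G), exactly one loop of 8-15 nt,
#            the others 1-7 nt
#   GVBQ  -- exactly one vacancy tract of exactly two G at the first or last
#            position, three intact tracts, loops 1-7 nt
#   Bulge -- exactly one tract of three G interrupted by one non-G
#            (G.B.GG or GG.B.G), three intact tracts, loops 1-7 nt

.bulge_forms <- function(st, q) {
  # returns integer vector of 0-based offsets of the bulged base within a
  # 4-char bulged tract starting at q, or empty
  n <- st$n; isG <- st$isG; isN <- st$isN
  if (q + 3L > n) return(integer())
  out <- integer()
  if (isG[q] && !isG[q + 1L] && !isN[q + 1L] && isG[q + 2L] && isG[q + 3L])
    out <- c(out, 1L)                        # G B GG
  if (isG[q] && isG[q + 1L] && !isG[q + 2L] && !isN[q + 2L] && isG[q + 3L])
    out <- c(out, 2L)                        # GG B G
  out
}

# all motif end positions (1-based exclusive) reachable from tract i starting
# at q; u = subtype-specific "special element used" flag
.nc_ends <- function(st, subtype, q, i, u, memo) {
  key <- paste0(q, ":", i, ":", u)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  n <- st$n; grun <- st$grun; isN <- st$isN
  res <- integer()
  # tract alternatives: list of (consumed, u_after)
  alts <- list()
  if (q <= n && grun[q] >= 3L)
    for (g in 3L:grun[q]) alts[[length(alts) + 1L]] <- c(g, u)
  if (subtype == "GVBQ" && !u && (i == 1L || i == 4L) && q <= n && grun[q] >= 2L)
    alts[[length(alts) + 1L]] <- c(2L, 1L)
  if (subtype == "Bulge" && !u && length(.bulge_forms(st, q)))
    alts[[length(alts) + 1L]] <- c(4L, 1L)
  for (alt in alts) {
    after <- q + alt[1L]
    u2 <- alt[2L]
    if (i == 4L) {
      if (u2 == 1L || subtype == "none") res <- c(res, after)
      next
    }
    lmax <- if (subtype == "4GL15" && !u2) 15L else 7L
    for (l in 1:lmax) {
      lc <- after + l - 1L
      if (lc > n || isN[lc]) break
      u3 <- if (subtype == "4GL15" && l >= 8L) 1L else u2
      res <- c(res, .nc_ends(st, subtype, after + l, i + 1L, u3, memo))
    }
  }
  res <- sort(unique(res))
  memo[[key]] <- res
  res
}

# first parse (deterministic order) of span [a, target_end) -- used only for
# the few selected candidates
.nc_parse <- function(st, subtype, a, target_end) {
  n <- st$n; grun <- st$grun; isN <- st$isN
  rec <- function(q, i, u, tracts, loops, boff) {
    alts <- list()
    if (subtype == "GVBQ" && !u && (i == 1L || i == 4L) && q <= n && grun[q] >= 2L)
      alts[[length(alts) + 1L]] <- list(2L, 1L, 2L, NA_integer_)
    if (subtype == "Bulge" && !u) {
      bf <- .bulge_forms(st, q)
      if (length(bf)) alts[[length(alts) + 1L]] <- list(4L, 1L, 3L, q - a + bf[1L])
    }
    if (q <= n && grun[q] >= 3L)
      for (g in grun[q]:3L) alts[[length(alts) + 1L]] <- list(g, u, g, NA_integer_)
    for (alt in alts) {
      after <- q + alt[[1L]]
      u2 <- alt[[2L]]
      tr2 <- c(tracts, alt[[3L]])
      bo2 <- if (is.na(boff)) alt[[4L]] else boff
      if (i == 4L) {
        if (after == target_end && (u2 == 1L)) return(list(tracts = tr2, loops = loops, boff = bo2))
        next
      }
      lmax <- if (subtype == "4GL15" && !u2) 15L else 7L
      for (l in 1:lmax) {
        lc <- after + l - 1L
        if (lc > n || isN[lc]) break
        u3 <- if (subtype == "4GL15" && l >= 8L) 1L else u2
        res <- rec(after + l, i + 1L, u3, tr2, c(loops, l), bo2)
        if (!is.null(res)) return(res)
      }
    }
    NULL
  }
  rec(a, 1L, 0L, integer(), integer(), NA_integer_)
}

.overlaps_any <- function(start, end, spans, min_nt = 1L) {
  # start/end scalar 0-based half-open; spans data.frame start/end
  if (is.null(spans) || !nrow(spans)) return(FALSE)
  ov <- pmin(end, spans$end) - pmax(start, spans$start)
  any(ov >= min_nt)
}

.select_leftmost <- function(cand) {
  # cand: data.frame start/end (0-based); earlier start wins, shortest at a
  # shared start; keep greedily non-overlapping
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- -1L
  for (k in seq_len(nrow(cand))) {
    if (cand$start[k] >= last_end) {
      keep[k] <- TRUE
      last_end <- cand$end[k]
    }
  }
  cand[keep, , drop = FALSE]
}

#' Find non-canonical PQS motifs of one subtype
#'
#' A first round enumerates every span that parses as four G-tracts under the
#' subtype predicate; filtering rounds then discard candidates overlapping a
#' canonical 4G motif span by at least `overlap_nt` nucleotides, and the
#' survivors are reported left to right, non-overlapping within the subtype
#' (earlier start wins; the shortest candidate wins at a shared start).
#'
#' @param seq Uppercase sequence over A/C/G/T/N.
#' @param subtype One of `"4GL15"`, `"GVBQ"`, `"Bulge"`.
#' @param canonical_spans Data frame of 4G spans on the same strand (the
#'   output of [find_4g()] on `seq`), or `NULL` for none.
#' @param overlap_nt Minimum overlap with a 4G span that disqualifies a
#'   candidate (default 1).
#' @return Motif data frame as in [find_4g()]; `bulge_offset` is the 0-based
#'   position of the bulged base relative to motif start (Bulge only).
#' @examples
#' find_noncanonical("GGTGGGAGGGTGGG", "GVBQ")
#' @export
find_noncanonical <- function(seq, subtype, canonical_spans = NULL, overlap_nt = 1L) {
  if (!subtype %in% c("4GL15", "GVBQ", "Bulge"))
    stop("unknown non-canonical subtype: ", subtype)
  st <- .seq_state(seq)
  min_len <- switch(subtype, "4GL15" = 22L, "GVBQ" = 14L, "Bulge" = 16L)
  if (st$n < min_len) return(.empty_motifs())
  runs3 <- st$runs[st$runs$len >= 3L, , drop = FALSE]
  need <- if (subtype == "4GL15") 4L else 3L
  if (!nrow(runs3)) return(.empty_motifs())
  # islands of >=3G runs whose neighbours are reachable: consecutive intact
  # tracts sit at most max(loop) apart for 4GL15 (15 nt) but a bulged tract
  # built from short G runs can bridge loop+bulge+loop = 7+4+7 = 18 nt
  rs <- runs3$start; re <- runs3$start + runs3$len       # 1-based, re exclusive
  brk <- which(rs[-1] - re[-length(re)] > 18L)
  grp <- rep.int(seq_len(length(brk) + 1L), diff(c(0L, brk, length(rs))))
  cand <- list()
  covered_to <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    cap <- sum((runs3$len[idx] + 1L) %/% 4L)
    if (cap < need) next
    wstart <- max(1L, rs[idx[1L]] - 12L, covered_to + 1L)
    wend <- min(st$n, re[idx[length(idx)]] - 1L + 12L)
    covered_to <- wend
    memo <- new.env(parent = emptyenv())
    for (a in wstart:wend) {
      if (!st$isG[a]) next
      ends <- .nc_ends(st, subtype, a, 1L, 0L, memo)
      if (length(ends))
        cand[[length(cand) + 1L]] <- data.frame(start = a - 1L, end = ends - 1L)
    }
  }
  if (!length(cand)) return(.empty_motifs())
  cand <- unique(do.call(rbind, cand))
  ok <- !vapply(seq_len(nrow(cand)), function(k)
    .overlaps_any(cand$start[k], cand$end[k], canonical_spans, overlap_nt), TRUE)
  cand <- .select_leftmost(cand[ok, , drop = FALSE])
  if (!nrow(cand)) return(.empty_motifs())
  rows <- lapply(seq_len(nrow(cand)), function(k) {
    p <- .nc_parse(st, subtype, cand$start[k] + 1L, cand$end[k] + 1L)
    data.frame(start = cand$start[k], end = cand$end[k], subtype = subtype,
               n_tracts = length(p$tracts),
               tracts = paste(p$tracts, collapse = ","),
               loops = paste(p$loops, collapse = ","),
               bulge_offset = if (subtype == "Bulge") p$boff else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Find two/three-tract hybrid-G4 motifs
#'
#' Maximal runs of intact G-tracts (>=3 G) separated by 1-7 nt loops that
#' contain exactly two or three tracts; a three-tract run is reported as one
#' Hybrid3, never as two Hybrid2.  Runs overlapping any four-tract motif span
#' (canonical or surviving non-canonical) are discarded.
#'
#' @param seq Uppercase sequence over A/C/G/T/N.
#' @param four_tract_spans Data frame of spans (start/end, 0-based) of 4G and
#'   surviving non-canonical motifs on the same strand, or `NULL`.
#' @param overlap_nt Disqualifying overlap, as in [find_noncanonical()].
#' @return Motif data frame as in [find_4g()], subtype `Hybrid2`/`Hybrid3`.
#' @examples
#' find_hybrid("GGGAGGGTGGG")
#' @export
find_hybrid <- function(seq, four_tract_spans = NULL, overlap_nt = 1L) {
  st <- .seq_state(seq)
  runs3 <- st$runs[st$runs$len >= 3L, , drop = FALSE]
  if (!nrow(runs3)) return(.empty_motifs())
  rs <- runs3$start; rl <- runs3$len; re <- rs + rl      # re exclusive
  ngaps <- length(rs) - 1L
  gap_ok <- if (ngaps > 0) vapply(seq_len(ngaps), function(k) {
    gl <- rs[k + 1L] - re[k]
    gl >= 1L && gl <= 7L && !any(st$isN[re[k]:(rs[k + 1L] - 1L)])
  }, TRUE) else logical()
  brk <- which(!gap_ok)
  grp <- rep.int(seq_len(length(brk) + 1L), diff(c(0L, brk, length(rs))))
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    k <- length(idx)
    if (k != 2L && k != 3L) next
    span_s <- rs[idx[1L]] - 1L
    span_e <- re[idx[k]] - 1L
    if (.overlaps_any(span_s, span_e, four_tract_spans, overlap_nt)) next
    loops <- if (k > 1L) rs[idx[-1L]] - re[idx[-k]] else integer()
    out[[length(out) + 1L]] <- data.frame(
      start = span_s, end = span_e,
      subtype = if (k == 2L) "Hybrid2" else "Hybrid3",
      n_tracts = k, tracts = paste(rl[idx], collapse = ","),
      loops = paste(loops, collapse = ","),
      bulge_offset = NA_integer_, stringsAsFactors = FALSE)
  }
  if (!length(out)) .empty_motifs() else do.call(rbind, out)
}

.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

.scan_one_strand <- function(seq, subtypes, overlap_nt) {
  m4 <- find_4g(seq)
  spans4 <- m4[, c("start", "end")]
  nc <- lapply(c("4GL15", "GVBQ", "Bulge"), function(sub)
    find_noncanonical(seq, sub, spans4, overlap_nt))
  nc_all <- do.call(rbind, nc)
  res <- list()
  if ("4G" %in% subtypes) res$m4 <- m4
  for (k in 1:3) {
    sub <- c("4GL15", "GVBQ", "Bulge")[k]
    if (sub %in% subtypes) res[[sub]] <- nc[[k]]
  }
  if ("Hybrid" %in% subtypes) {
    four <- rbind(spans4, nc_all[, c("start", "end")])
    res$hyb <- find_hybrid(seq, four, overlap_nt)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) .empty_motifs() else out
}

#' Scan a genome for PQS motifs on both strands
#'
#' The plus strand is scanned directly; the minus strand is scanned on the
#' reverse complement and coordinates are mirrored back to the plus-strand
#' reference (`start' = L - end`).  Canonical 4G spans are always computed
#' for the non-canonical overlap filter, and surviving non-canonical spans
#' for the hybrid filter, regardless of which subtypes are requested.
#' `tracts`, `loops` and `bulge_offset` always describe the motif read 5'->3'
#' on its own strand.
#'
#' @param genome Named character vector of chromosome sequences (see
#'   [parse_fasta()]), or a single unnamed sequence (named `"seq"`).
#' @param subtypes Non-empty subset of `c("4G","4GL15","GVBQ","Bulge","Hybrid")`.
#' @param strands Subset of `c("+","-")`.
#' @param overlap_nt Disqualifying overlap for the non-canonical/hybrid
#'   filters (default 1 nt).
#' @return Motif data frame with `chrom`, 0-based half-open `start`/`end`,
#'   `strand`, `subtype`, `n_tracts`, `tracts`, `loops`, `bulge_offset`,
#'   sorted by (chrom, start, end).
#' @export
scan_genome <- function(genome, subtypes = c("4G", "4GL15", "GVBQ", "Bulge", "Hybrid"),
                        strands = c("+", "-"), overlap_nt = 1L) {
  if (!length(subtypes)) stop("subtype list must not be empty")
  bad <- setdiff(subtypes, c("4G", "4GL15", "GVBQ", "Bulge", "Hybrid"))
  if (length(bad)) stop("unknown subtype(s): ", paste(bad, collapse = ", "))
  if (!length(strands) || !all(strands %in% c("+", "-"))) stop("strands must be '+' and/or '-'")
  if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
  out <- list()
  for (ch in names(genome)) {
    L <- nchar(genome[[ch]])
    if ("+" %in% strands) {
      m <- .scan_one_strand(genome[[ch]], subtypes, overlap_nt)
      if (nrow(m)) {
        m$chrom <- ch; m$strand <- "+"
        out[[length(out) + 1L]] <- m
      }
    }
    if ("-" %in% strands) {
      m <- .scan_one_strand(.revcomp(genome[[ch]]), subtypes, overlap_nt)
      if (nrow(m)) {
        s <- L - m$end
        m$end <- L - m$start
        m$start <- s
        m$chrom <- ch; m$strand <- "-"
        out[[length(out) + 1L]] <- m
      }
    }
  }
  if (!length(out)) {
    res <- .empty_motifs()
    res$chrom <- character(); res$strand <- character()
  } else {
    res <- do.call(rbind, out)
  }
  res <- res[order(res$chrom, res$start, res$end, res$strand), c("chrom", "start", "end", "strand", "subtype", "n_tracts", "tracts", "loops", "bulge_offset")]
  rownames(res) <- NULL
  res
}

#' Merge overlapping motif calls of different subtypes
#'
#' Calls on the same chromosome and strand whose spans overlap by at least
#' one nucleotide are merged (transitively) into one motif whose interval is
#' the union span and whose `subtype` is the sorted `|`-joined union of
#' labels; `n_tracts` is the maximum over the merged calls.  Venn-style
#' subtype-combination counts can be tabulated from the result.
#'
#' @param motifs Output of [scan_genome()].
#' @return Data frame with `chrom`, `start`, `end`, `strand`, `subtype`,
#'   `n_tracts`, `n_merged`.
#' @export
merge_subtype_calls <- function(motifs) {
  if (!nrow(motifs)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), subtype = character(),
                      n_tracts = integer(), n_merged = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (key in unique(paste(motifs$chrom, motifs$strand))) {
    m <- motifs[paste(motifs$chrom, motifs$strand) == key, , drop = FALSE]
    ir <- IRanges::IRanges(m$start + 1L, m$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (g in seq_along(red)) {
      i <- which(grp == g)
      out[[length(out) + 1L]] <- data.frame(
        chrom = m$chrom[i[1L]],
        start = BiocGenerics::start(red)[g] - 1L,
        end = BiocGenerics::end(red)[g],
        strand = m$strand[i[1L]],
        subtype = paste(sort(unique(unlist(strsplit(m$subtype[i], "|", fixed = TRUE)))), collapse = "|"),
        n_tracts = max(m$n_tracts[i]),
        n_merged = length(i), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end, res$strand), ]
  rownames(res) <- NULL
  res
}
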