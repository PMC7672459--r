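# Independent oracles used by the property and acceptance tests.
#
# These deliberately take a different route from the package code: the 4G
# oracle is base R's PCRE engine evaluating the published pattern; the
# non-canonical oracle tests every substring against an anchored-regex
# subtype predicate and applies its own selection/filter code; the profile
# oracle averages bases one window at a time.

random_seq <- function(len, gc_bias = FALSE) {
  p <- if (gc_bias) c(.15, .15, .55, .15) else rep(.25, 4)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

oracle_4g <- function(s) {
  m <- gregexpr("G{3,}(.{1,7}?G{3,}){3,}", s, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + as.integer(attr(m, "match.length")))
}

oracle_nc_pattern <- function(subtype) {
  S <- "[ACGT]{1,7}"; L2 <- "[ACGT]{8,15}"; G <- "G{3,}"
  B <- "(?:G[ACT]GG|GG[ACT]G)"
  alt <- switch(subtype,
    "4GL15" = c(paste0(G, L2, G, S, G, S, G), paste0(G, S, G, L2, G, S, G),
                paste0(G, S, G, S, G, L2, G)),
    "GVBQ"  = c(paste0("GG", S, G, S, G, S, G), paste0(G, S, G, S, G, S, "GG")),
    "Bulge" = c(paste0(B, S, G, S, G, S, G), paste0(G, S, B, S, G, S, G),
                paste0(G, S, G, S, B, S, G), paste0(G, S, G, S, G, S, B)))
  paste0("^(?:", paste(alt, collapse = "|"), ")$")
}

oracle_select <- function(cand) {
  if (!nrow(cand)) return(cand)
  cand <- cand[order(cand$start, cand$end - cand$start), , drop = FALSE]
  rows <- list(); last_end <- -1L
  for (k in seq_len(nrow(cand)))
    if (cand$start[k] >= last_end) {
      rows[[length(rows) + 1L]] <- cand[k, ]
      last_end <- cand$end[k]
    }
  do.call(rbind, rows)
}

oracle_noncanonical <- function(s, subtype, spans4) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  gpos <- which(ch == "G")
  empty <- data.frame(start = integer(), end = integer())
  if (!length(gpos)) return(empty)
  r <- rle(ch == "G")
  rmax <- max(r$lengths[r$values])
  minlen <- switch(subtype, "4GL15" = 22L, "GVBQ" = 14L, "Bulge" = 16L)
  maxlen <- 4L * rmax + 29L
  pat <- oracle_nc_pattern(subtype)
  cand <- list()
  for (i in gpos) {
    js <- gpos[gpos >= i + minlen - 1L & gpos <= i + maxlen - 1L]
    if (!length(js)) next
    hit <- grepl(pat, substring(s, i, js), perl = TRUE)
    if (any(hit)) cand[[length(cand) + 1L]] <- data.frame(start = i - 1L, end = js[hit])
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  if (nrow(spans4)) {
    keep <- vapply(seq_len(nrow(cand)), function(k)
      !any(pmin(cand$end[k], spans4$end) - pmax(cand$start[k], spans4$start) >= 1L), TRUE)
    cand <- cand[keep, , drop = FALSE]
  }
  out <- oracle_select(cand)
  rownames(out) <- NULL
  out
}

oracle_hybrid <- function(s, four_spans) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  r <- rle(ch == "G")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 3L
  rs <- starts[keep]; re <- ends[keep] + 1L
  empty <- data.frame(start = integer(), end = integer(), n_tracts = integer())
  if (!length(rs)) return(empty)
  link <- if (length(rs) > 1L) vapply(seq_len(length(rs) - 1L), function(k) {
    gl <- rs[k + 1L] - re[k]
    gl >= 1L && gl <= 7L && !any(ch[re[k]:(rs[k + 1L] - 1L)] == "N")
  }, TRUE) else logical()
  grp <- cumsum(c(1L, !link))
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g); k <- length(idx)
    if (k != 2L && k != 3L) next
    sp <- c(rs[idx[1L]] - 1L, re[idx[k]] - 1L)
    if (nrow(four_spans) &&
        any(pmin(sp[2], four_spans$end) - pmax(sp[1], four_spans$start) >= 1L)) next
    out[[length(out) + 1L]] <- data.frame(start = sp[1], end = sp[2], n_tracts = k)
  }
  if (!length(out)) empty else do.call(rbind, out)
}

# full six-class oracle scan of one strand, mirroring the module contracts
oracle_scan_strand <- function(s) {
  spans4 <- oracle_4g(s)
  nc <- lapply(c("4GL15", "GVBQ", "Bulge"), function(sub) {
    o <- oracle_noncanonical(s, sub, spans4)
    if (nrow(o)) o$subtype <- sub
    o
  })
  nc_spans <- do.call(rbind, lapply(nc, function(d) d[, c("start", "end")]))
  hy <- oracle_hybrid(s, rbind(spans4, nc_spans))
  out <- data.frame(start = spans4$start, end = spans4$end,
                    subtype = rep("4G", nrow(spans4)))
  for (d in nc) if (nrow(d)) out <- rbind(out, d[, c("start", "end", "subtype")])
  if (nrow(hy))
    out <- rbind(out, data.frame(start = hy$start, end = hy$end,
                                 subtype = ifelse(hy$n_tracts == 2L, "Hybrid2", "Hybrid3")))
  out[order(out$start, out$end, out$subtype), ]
}

motif_key <- function(df) {
  if (!nrow(df)) return(character())
  sort(paste(df$start, df$end, df$subtype, sep = ":"))
}

# per-base reference-point profile oracle (exact bin-mean arithmetic)
oracle_refpoint_row <- function(values, pos, strand, half_width, bin_size) {
  nb <- 2L * half_width %/% bin_size
  row <- numeric(nb)
  for (b in seq_len(nb)) {
    from <- pos - half_width + (b - 1L) * bin_size
    idx <- (from + 1L):(from + bin_size)
    v <- numeric(bin_size)
    ok <- idx >= 1L & idx <= length(values)
    v[ok] <- values[idx[ok]]
    row[b] <- sum(v) / bin_size
  }
  if (strand == "-") rev(row) else row
}

# small default simulation shared by fixture-level tests (kept modest so the
# module test files stay fast; the full-size genome is exercised in the
# acceptance tests)
small_config <- function(seed = 1L) {
  sim_config(seed = seed, n_chroms = 2L, chrom_length = 60000L, n_genes = 8L,
             motif_counts = c("4G" = 6L, "4GL15" = 4L, "GVBQ" = 4L,
                              "Bulge" = 4L, "Hybrid2" = 3L, "Hybrid3" = 3L))
}
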