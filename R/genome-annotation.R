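# Gene models, TSS/TES anchors and the four-region genome partition
# (promoter = TSS +/- flank, TES flank, intragenic, intergenic).

#' Load gene models from gene BED records
#'
#' Records with identical (chrom, start, end, strand) are collapsed to one
#' (coordinate deduplication); strandless records are rejected because a TSS
#' is undefined without strand.
#'
#' @param intervals Data frame from
#'   `parse_interval_file(..., dialect = "gene_bed")`.
#' @return Data frame of gene models ordered by coordinate, with `tss` and
#'   `tes` columns giving the 0-based positions of the TSS/TES base
#'   (TSS = start for `+` genes, end - 1 for `-` genes).
#' @export
load_genes <- function(intervals) {
  if (any(!intervals$strand %in% c("+", "-")))
    stop("gene records must be stranded (+/-): TSS undefined otherwise")
  key <- paste(intervals$chrom, intervals$start, intervals$end, intervals$strand)
  g <- intervals[!duplicated(key), , drop = FALSE]
  g <- g[order(g$chrom, g$start, g$end, g$strand), , drop = FALSE]
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g$tes <- ifelse(g$strand == "+", g$end - 1L, g$start)
  rownames(g) <- NULL
  g
}

.ir <- function(start0, end0) IRanges::IRanges(start = start0 + 1L, end = end0)

.ir_clip <- function(ir, L) {
  ir <- IRanges::restrict(ir, start = 1L, end = L)
  ir[BiocGenerics::width(ir) > 0L]
}

#' Partition chromosomes into promoter, TES-flank, intragenic and intergenic
#'
#' Windows are clipped to chromosome bounds.  Where windows overlap, the
#' precedence is promoter > TES flank > intragenic > intergenic, so every
#' base receives exactly one label.
#'
#' @param genes Output of [load_genes()].
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param flank Flank size in bases around TSS and TES (default 2000).
#' @return Object of class `region_partition`: per-chromosome `IRanges` per
#'   label, plus `chrom_sizes` and `flank`.
#' @export
partition_regions <- function(genes, chrom_sizes, flank = 2000L) {
  if (nrow(genes) && !all(genes$chrom %in% names(chrom_sizes)))
    stop("gene chromosome absent from chrom_sizes")
  labels <- c("promoter", "tes_flank", "intragenic", "intergenic")
  parts <- list()
  for (ch in names(chrom_sizes)) {
    L <- chrom_sizes[[ch]]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) && any(g$end > L)) stop("gene beyond chromosome bounds on ", ch)
    all_ir <- IRanges::IRanges(1L, L)
    if (!nrow(g)) {
      parts[[ch]] <- list(promoter = IRanges::IRanges(), tes_flank = IRanges::IRanges(),
                          intragenic = IRanges::IRanges(), intergenic = all_ir)
      next
    }
    # windows are anchored on the TSS/TES interval coordinate (start of a
    # + gene, end of a - gene, and vice versa), so a + gene [4000, 7000)
    # with flank 2000 yields promoter [2000, 6000) and TES window
    # [5000, 9000)
    tssc <- ifelse(g$strand == "+", g$start, g$end)
    tesc <- ifelse(g$strand == "+", g$end, g$start)
    prom <- IRanges::reduce(.ir_clip(.ir(tssc - flank, tssc + flank), L))
    tes <- IRanges::reduce(.ir_clip(.ir(tesc - flank, tesc + flank), L))
    body <- IRanges::reduce(.ir_clip(.ir(g$start, g$end), L))
    tes <- IRanges::setdiff(tes, prom)
    intra <- IRanges::setdiff(IRanges::setdiff(body, prom), tes)
    inter <- IRanges::setdiff(IRanges::setdiff(IRanges::setdiff(all_ir, prom), tes), intra)
    parts[[ch]] <- list(promoter = prom, tes_flank = tes, intragenic = intra,
                        intergenic = inter)
  }
  structure(list(regions = parts, chrom_sizes = chrom_sizes, flank = flank,
                 labels = labels),
            class = "region_partition")
}

#' Nucleotide counts and fractions per partition label
#'
#' @param partition A [partition_regions()] result.
#' @return Data frame with label, nucleotides and fraction (fractions sum to
#'   1 exactly over the genome).
#' @export
partition_fractions <- function(partition) {
  nt <- vapply(partition$labels, function(lab)
    sum(vapply(partition$regions, function(p) sum(BiocGenerics::width(p[[lab]])), 0)),
    0)
  data.frame(label = partition$labels, nucleotides = unname(nt),
             fraction = unname(nt) / sum(partition$chrom_sizes),
             stringsAsFactors = FALSE)
}

#' @export
print.region_partition <- function(x, ...) {
  cat("region_partition over", length(x$chrom_sizes), "chromosome(s), flank =",
      x$flank, "bp\n")
  print(partition_fractions(x))
  invisible(x)
}

#' Assign intervals to partition labels
#'
#' Under the `midpoint` rule (default; used for peaks) each item lands in
#' exactly one label and fractions sum to 1.  Under `any_overlap` an item is
#' counted once per label it overlaps (reads-style accounting).
#'
#' @param items Data frame with chrom/start/end (0-based half-open).
#' @param partition A [partition_regions()] result.
#' @param rule `"midpoint"` or `"any_overlap"`.
#' @return Data frame with label, count, fraction; plus a `label` vector
#'   attribute giving the per-item midpoint label when `rule = "midpoint"`.
#' @export
assign_to_regions <- function(items, partition, rule = c("midpoint", "any_overlap")) {
  rule <- match.arg(rule)
  labels <- partition$labels
  counts <- setNames(numeric(length(labels)), labels)
  item_label <- rep(NA_character_, nrow(items))
  for (ch in unique(items$chrom)) {
    if (!ch %in% names(partition$regions)) stop("item chromosome '", ch, "' not in partition")
    i <- which(items$chrom == ch)
    p <- partition$regions[[ch]]
    if (rule == "midpoint") {
      mid <- (items$start[i] + items$end[i]) %/% 2L
      pt <- .ir(mid, mid + 1L)
      for (lab in labels) {
        hit <- IRanges::overlapsAny(pt, p[[lab]])
        counts[lab] <- counts[lab] + sum(hit)
        item_label[i[hit]] <- lab
      }
    } else {
      ir <- .ir(items$start[i], items$end[i])
      for (lab in labels)
        counts[lab] <- counts[lab] + sum(IRanges::overlapsAny(ir, p[[lab]]))
    }
  }
  out <- data.frame(label = labels, count = unname(counts),
                    fraction = unname(counts) / max(1L, nrow(items)),
                    stringsAsFactors = FALSE)
  if (rule == "midpoint") attr(out, "label") <- item_label
  out
}

#' Per-TSS PQS load
#'
#' Counts motifs overlapping the TSS +/- `half_width` window by at least one
#' nucleotide, per gene and (optionally) per motif subtype.
#'
#' @param genes Output of [load_genes()].
#' @param motifs Output of [scan_genome()] (motif strand is ignored).
#' @param half_width Window half-width in bases (default 3000).
#' @param per_subtype If `TRUE`, add one count column per subtype present
#'   plus `n_subtypes`, the number of distinct subtypes in the window (used
#'   to restrict to TSSs carrying only one subtype).
#' @return Data frame with one row per gene: `name`, `chrom`, `tss`,
#'   `strand`, `load` (and per-subtype columns if requested).
#' @export
pqs_load <- function(genes, motifs, half_width = 3000L, per_subtype = FALSE) {
  out <- data.frame(name = genes$name, chrom = genes$chrom, tss = genes$tss,
                    strand = genes$strand, load = 0L, stringsAsFactors = FALSE)
  subs <- if (nrow(motifs)) sort(unique(motifs$subtype)) else character()
  if (per_subtype) for (s in subs) out[[s]] <- 0L
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    mi <- which(motifs$chrom == ch)
    if (!length(mi)) next
    win <- .ir(genes$tss[gi] - half_width, genes$tss[gi] + half_width)
    mir <- .ir(motifs$start[mi], motifs$end[mi])
    out$load[gi] <- IRanges::countOverlaps(win, mir)
    if (per_subtype) for (s in subs) {
      out[[s]][gi] <- IRanges::countOverlaps(win, mir[motifs$subtype[mi] == s])
    }
  }
  if (per_subtype)
    out$n_subtypes <- rowSums(as.matrix(out[, subs, drop = FALSE]) > 0L)
  out
}
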