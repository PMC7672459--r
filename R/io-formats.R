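#' Parse FASTA text or file into a named vector of sequences
#'
#' Sequences are uppercased and validated against the alphabet A, C, G, T, N.
#' Multi-line records are concatenated; record order is preserved.
#'
#' @param x Either a path to a FASTA file or a character scalar containing
#'   FASTA-formatted text (detected by a leading `>`).
#' @return Named character vector; names are the words before the first
#'   whitespace of each header, values the uppercased sequences.
#' @examples
#' parse_fasta(">c1\nacgt\nACGT")
#' @export
parse_fasta <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  is_text <- startsWith(x, ">") || grepl("\n", x, fixed = TRUE) || !file.exists(x)
  lines <- if (is_text) strsplit(x, "\n", fixed = TRUE)[[1]] else readLines(x)
  lines <- sub("\r$", "", lines)
  names_out <- character()
  seqs <- character()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      hdr <- sub("^>\\s*", "", ln)
      hdr <- strsplit(hdr, "\\s+")[[1]][1]
      if (is.na(hdr) || !nzchar(hdr)) stop("FASTA format error: empty record name at line ", i)
      names_out <- c(names_out, hdr)
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else {
      if (is.null(cur)) {
        if (!nzchar(trimws(ln))) next
        stop("FASTA format error: sequence before first header at line ", i)
      }
      seqs[cur] <- paste0(seqs[cur], toupper(trimws(ln)))
    }
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    j <- which(bad > 0)[1]
    stop("FASTA format error: illegal character '",
         substr(seqs[j], bad[j], bad[j]), "' in record '", names_out[j],
         "' at sequence position ", bad[j])
  }
  setNames(seqs, names_out)
}

.skip_bed_line <- function(lines) {
  grepl("^(#|track|browser)", lines) | !nzchar(trimws(lines))
}

.read_delim_lines <- function(x) {
  lines <- if (length(x) == 1L && grepl("\t", x)) strsplit(x, "\n", fixed = TRUE)[[1]] else readLines(x)
  lines <- sub("\r$", "", lines)
  lines[!.skip_bed_line(lines)]
}

#' Parse a BED-family interval file
#'
#' All coordinates are 0-based, half-open.  `track`, `browser` and comment
#' lines are skipped.
#'
#' @param x Path to a tab-delimited file, or a character scalar of its
#'   contents (detected by an embedded tab).
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"`, `"gene_bed"`.
#' @return A data frame. `bed3`: chrom/start/end with strand `"."`;
#'   `bed6`: adds name, score, strand; `narrowPeak`: adds
#'   `fold_enrichment` (column 7), `qvalue` (column 9, -log10 scale as
#'   stored) and `summit_offset` (column 10, `NA` when -1); `gene_bed`:
#'   BED6 where strand must later be `+`/`-` for gene models.
#' @export
parse_interval_file <- function(x, dialect = c("bed3", "bed6", "narrowPeak", "gene_bed")) {
  dialect <- match.arg(dialect)
  lines <- .read_delim_lines(x)
  need <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L, gene_bed = 6L)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && any(lengths(parts) < need))
    stop("interval format error: line with fewer than ", need, " columns for dialect '", dialect, "'")
  get <- function(i) vapply(parts, `[[`, "", i)
  if (!length(parts)) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     name = character(), score = numeric(), strand = character(),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(chrom = get(1), start = as.integer(get(2)), end = as.integer(get(3)),
                     stringsAsFactors = FALSE)
    if (anyNA(df$start) || anyNA(df$end)) stop("interval format error: non-integer coordinate")
    if (any(df$start < 0)) stop("interval format error: negative start")
    if (any(df$start >= df$end)) stop("interval format error: start >= end")
    if (dialect == "bed3") {
      df$name <- "."; df$score <- 0; df$strand <- "."
    } else {
      df$name <- get(4)
      df$score <- suppressWarnings(as.numeric(get(5)))
      df$strand <- get(6)
      if (!all(df$strand %in% c("+", "-", "."))) stop("interval format error: bad strand field")
    }
  }
  if (dialect == "narrowPeak" && length(parts)) {
    df$fold_enrichment <- as.numeric(get(7))
    if (any(!is.finite(df$fold_enrichment))) stop("interval format error: non-finite fold enrichment")
    df$pvalue <- as.numeric(get(8))
    df$qvalue <- as.numeric(get(9))
    so <- as.integer(get(10))
    so[so < 0] <- NA_integer_
    if (any(!is.na(so) & so >= (df$end - df$start)))
      stop("interval format error: summit offset outside peak")
    df$summit_offset <- so
  } else if (dialect == "narrowPeak") {
    df$fold_enrichment <- numeric(); df$pvalue <- numeric()
    df$qvalue <- numeric(); df$summit_offset <- integer()
  }
  if (dialect == "gene_bed" && nrow(df)) {
    # strand "." is rejected later by load_genes(), where a TSS is needed
  }
  df
}

#' Read a chrom.sizes file
#'
#' @param x Path or tab-separated text (`chrom\tlength` per line).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(x) {
  lines <- .read_delim_lines(x)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sizes <- vapply(parts, function(p) as.integer(p[2]), 1L)
  if (anyNA(sizes) || any(sizes <= 0)) stop("chrom.sizes format error")
  setNames(sizes, vapply(parts, `[[`, "", 1))
}

#' Construct a base-resolution coverage track
#'
#' @param values Named list of numeric vectors, one per chromosome, one value
#'   per base.
#' @param chrom_sizes Named integer vector; every chromosome in `values` must
#'   be present with matching length.
#' @param total_mapped_reads,read_length Optional library metadata needed by
#'   [rpkm_normalize()].
#' @param mode Free-text label of what the values represent (e.g. "raw",
#'   "subtract", "ratio", "rpkm").
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, chrom_sizes, total_mapped_reads = NULL,
                           read_length = NULL, mode = "raw") {
  stopifnot(is.list(values), !is.null(names(values)))
  if (!all(names(values) %in% names(chrom_sizes)))
    stop("coverage track chromosome absent from chrom_sizes")
  for (ch in names(values)) {
    v <- values[[ch]]
    if (length(v) != chrom_sizes[[ch]])
      stop("coverage vector length mismatch for ", ch)
    if (any(!is.finite(v))) stop("non-finite coverage value on ", ch)
  }
  structure(list(values = values, chrom_sizes = chrom_sizes,
                 total_mapped_reads = total_mapped_reads,
                 read_length = read_length, mode = mode),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$values), "chromosome(s), mode =", x$mode, "\n")
  for (ch in names(x$values))
    cat(" ", ch, ":", length(x$values[[ch]]), "bp, total signal",
        format(sum(x$values[[ch]])), "\n")
  invisible(x)
}

#' Parse a bedGraph file into a coverage track
#'
#' Intervals must be non-overlapping per chromosome; unspecified bases get 0.
#'
#' @param x Path or tab-separated text.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @inheritParams coverage_track
#' @return A [coverage_track()].
#' @export
parse_bedgraph <- function(x, chrom_sizes, total_mapped_reads = NULL,
                           read_length = NULL, mode = "raw") {
  lines <- .read_delim_lines(x)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && any(lengths(parts) < 4L)) stop("bedGraph format error: need 4 columns")
  chrom <- vapply(parts, `[[`, "", 1)
  start <- as.integer(vapply(parts, `[[`, "", 2))
  end <- as.integer(vapply(parts, `[[`, "", 3))
  val <- as.numeric(vapply(parts, `[[`, "", 4))
  if (anyNA(start) || anyNA(end) || any(start < 0) || any(start >= end))
    stop("bedGraph format error: bad interval")
  if (any(!is.finite(val))) stop("bedGraph format error: non-finite value")
  values <- lapply(setNames(nm = names(chrom_sizes)), function(ch) numeric(chrom_sizes[[ch]]))
  for (ch in unique(chrom)) {
    if (!ch %in% names(chrom_sizes)) stop("bedGraph chromosome '", ch, "' absent from chrom_sizes")
    i <- which(chrom == ch)
    if (any(end[i] > chrom_sizes[[ch]])) stop("bedGraph interval beyond chromosome size on ", ch)
    o <- i[order(start[i])]
    if (any(start[o][-1] < end[o][-length(o)]))
      stop("bedGraph format error: overlapping intervals on ", ch)
    v <- values[[ch]]
    for (j in o) v[(start[j] + 1L):end[j]] <- val[j]
    values[[ch]] <- v
  }
  coverage_track(values, chrom_sizes, total_mapped_reads, read_length, mode)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal values are collapsed; zero runs are omitted.
#'
#' @param track A [coverage_track()].
#' @param path Output file path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    r <- rle(track$values[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         formatC(r$values[keep], format = "g", digits = 10)), con)
  }
  invisible(NULL)
}

#' Write motifs or intervals as BED6
#'
#' The name field is the subtype label (multiple subtypes joined by `|`), the
#' score the number of G-tracts capped at 1000.  Plain intervals get name `.`
#' and score 0.  Round-trips through [parse_interval_file()] preserve
#' coordinates, strand and name.
#'
#' @param x Data frame with chrom/start/end and optionally strand, subtype (or
#'   name) and n_tracts (or score).
#' @param path Output file path.
#' @export
write_bed <- function(x, path) {
  name <- if (!is.null(x$subtype)) x$subtype else if (!is.null(x$name)) x$name else "."
  score <- if (!is.null(x$n_tracts)) pmin(x$n_tracts, 1000L) else if (!is.null(x$score)) x$score else 0L
  strand <- if (!is.null(x$strand)) x$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, x$start, x$end,
                     name, format(score, trim = TRUE), strand), path)
  invisible(NULL)
}

#' Write peaks in ENCODE narrowPeak format
#'
#' @param peaks Data frame with chrom/start/end/name/strand/fold_enrichment and
#'   optionally pvalue, qvalue, summit_offset.
#' @param path Output file path.
#' @export
write_narrowpeak <- function(peaks, path) {
  pv <- if (!is.null(peaks$pvalue)) peaks$pvalue else -1
  qv <- if (!is.null(peaks$qvalue)) peaks$qvalue else -1
  so <- if (!is.null(peaks$summit_offset)) ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset) else -1L
  nm <- if (!is.null(peaks$name)) peaks$name else sprintf("peak_%d", seq_len(nrow(peaks)))
  st <- if (!is.null(peaks$strand)) peaks$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
                     peaks$chrom, peaks$start, peaks$end, nm, 0L, st,
                     formatC(peaks$fold_enrichment, format = "g", digits = 10),
                     formatC(pv, format = "g", digits = 10),
                     formatC(qv, format = "g", digits = 10), so), path)
  invisible(NULL)
}
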