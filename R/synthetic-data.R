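# Deterministic synthetic fixtures: a small genome with planted PQS motifs
# of known subtype near synthetic TSSs, an input track, and a "G4P" track
# whose enrichment at motifs scales with the host gene's expression tier and
# is larger downstream of the TSS than upstream.
#
# Design notes (see the methods vignette for rationale):
#  * the background is G/C-run-suppressed (no run of 3+ G or C), so planted
#    motifs are the only PQS sources and planted-truth tests are exact;
#  * every planted motif is flanked by A/T-only pads so background guanines
#    can never extend a planted tract;
#  * planted loops use only A/T, intact tracts of non-canonical motifs are
#    exactly 3 G, and bulges sit in an interior tract -- choices that make
#    each planted sequence parse as its own subtype and no other.

#' Simulation configuration
#'
#' @param seed Integer seed driving every random choice.
#' @param n_chroms,chrom_length Genome shape (default 2 x 500 kb).
#' @param n_genes Total gene count, split evenly across chromosomes.
#' @param expression_tiers Relative expression activities cycled over genes.
#' @param motif_counts Named integer vector of planted motifs per subtype.
#' @param promoter_fraction Fraction of motifs placed within 1.5 kb of a TSS.
#' @param amplitudes Named per-subtype enrichment amplitudes (signal units
#'   above background at the bump center for a tier-1 upstream motif).
#' @param asymmetry Multiplier (>= 1) applied to motifs downstream of their
#'   host TSS.
#' @param background Input track background level.
#' @param noise_sd Gaussian noise sd of the input track.
#' @param enrichment_sd Gaussian bump sd in bases.
#' @param pad A/T-only pad width around each planted motif.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 500000L,
                       n_genes = 40L, expression_tiers = c(1, 2, 4),
                       motif_counts = c("4G" = 30L, "4GL15" = 20L, "GVBQ" = 20L,
                                        "Bulge" = 20L, "Hybrid2" = 15L, "Hybrid3" = 15L),
                       promoter_fraction = 0.7,
                       amplitudes = c("4G" = 4, "Bulge" = 3, "4GL15" = 2,
                                      "GVBQ" = 1, "Hybrid2" = 0.5, "Hybrid3" = 0.5),
                       asymmetry = 1.5, background = 1.0, noise_sd = 0.2,
                       enrichment_sd = 100, pad = 12L) {
  stopifnot(seed == as.integer(seed), n_chroms >= 1L, chrom_length >= 1000L,
            n_genes >= 0L, all(motif_counts >= 0L), asymmetry >= 1,
            promoter_fraction >= 0, promoter_fraction <= 1,
            background >= 0, noise_sd >= 0, enrichment_sd > 0, pad >= 8L)
  if (!all(names(motif_counts) %in% c("4G", "4GL15", "GVBQ", "Bulge", "Hybrid2", "Hybrid3")))
    stop("unknown subtype in motif_counts")
  if (sum(motif_counts) * 100L > n_chroms * chrom_length)
    stop("infeasible motif plan for genome size")
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
                 expression_tiers = expression_tiers, motif_counts = motif_counts,
                 promoter_fraction = promoter_fraction, amplitudes = amplitudes,
                 asymmetry = asymmetry, background = background, noise_sd = noise_sd,
                 enrichment_sd = enrichment_sd, pad = as.integer(pad)),
            class = "sim_config")
}

.sub_seed <- function(seed, k) (seed + k) %% (.Machine$integer.max - 1L)

#' Synthetic gene models
#'
#' Genes are laid out deterministically (no randomness): each chromosome is
#' divided into equal slots and the gene occupies the middle half of its
#' slot, strands alternating, expression tiers cycling.
#'
#' @param config A [sim_config()].
#' @return Data frame compatible with [load_genes()] output, plus a `tier`
#'   column.
#' @export
make_genes <- function(config) {
  if (config$n_genes == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      tss = integer(), tes = integer(), tier = numeric(),
                      stringsAsFactors = FALSE))
  npc <- ceiling(config$n_genes / config$n_chroms)
  rows <- list()
  k <- 0L
  for (ci in seq_len(config$n_chroms)) {
    ch <- paste0("chr", ci)
    W <- config$chrom_length %/% npc
    for (gi in seq_len(npc)) {
      if (k >= config$n_genes) break
      k <- k + 1L
      s <- (gi - 1L) * W + W %/% 4L
      e <- (gi - 1L) * W + (3L * W) %/% 4L
      strand <- if (gi %% 2L == 1L) "+" else "-"
      rows[[k]] <- data.frame(chrom = ch, start = s, end = e,
                              name = sprintf("gene_%s_%d", ch, gi), score = 0,
                              strand = strand,
                              tss = if (strand == "+") s else e - 1L,
                              tes = if (strand == "+") e - 1L else s,
                              tier = config$expression_tiers[(k - 1L) %% length(config$expression_tiers) + 1L],
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.background_chars <- function(L) {
  ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  repeat {
    r <- rle(ch)
    bad <- which(r$lengths >= 3L & r$values %in% c("G", "C"))
    if (!length(bad)) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in bad) {
      idx <- (starts[b] + 2L):ends[b]
      ch[idx] <- sample(c("A", "T"), length(idx), replace = TRUE)
    }
  }
  ch
}

.at_loop <- function(len) paste(sample(c("A", "T"), len, replace = TRUE), collapse = "")

.motif_sequence <- function(subtype) {
  # returns list(seq, n_tracts); loops A/T only, constraints per design notes
  tract <- function(g) strrep("G", g)
  if (subtype == "4G") {
    gs <- sample(3:4, 4L, replace = TRUE)
    ls <- sample(1:7, 3L, replace = TRUE)
    seq <- paste0(tract(gs[1]), .at_loop(ls[1]), tract(gs[2]), .at_loop(ls[2]),
                  tract(gs[3]), .at_loop(ls[3]), tract(gs[4]))
    list(seq = seq, n_tracts = 4L)
  } else if (subtype == "4GL15") {
    ls <- sample(1:7, 3L, replace = TRUE)
    ls[sample(3L, 1L)] <- sample(8:15, 1L)
    seq <- paste0(tract(3), .at_loop(ls[1]), tract(3), .at_loop(ls[2]),
                  tract(3), .at_loop(ls[3]), tract(3))
    list(seq = seq, n_tracts = 4L)
  } else if (subtype == "GVBQ") {
    ls <- sample(1:7, 3L, replace = TRUE)
    parts <- c(tract(3), tract(3), tract(3))
    if (sample(2L, 1L) == 1L) parts <- c(tract(2), parts) else parts <- c(parts, tract(2))
    seq <- paste0(parts[1], .at_loop(ls[1]), parts[2], .at_loop(ls[2]),
                  parts[3], .at_loop(ls[3]), parts[4])
    list(seq = seq, n_tracts = 4L)
  } else if (subtype == "Bulge") {
    ls <- sample(1:7, 3L, replace = TRUE)
    b <- sample(c("A", "C", "T"), 1L)
    bulged <- if (sample(2L, 1L) == 1L) paste0("G", b, "GG") else paste0("GG", b, "G")
    parts <- c(tract(3), tract(3), tract(3))
    pos <- sample(2:3, 1L)                     # interior tract keeps the
    parts <- append(parts, bulged, after = pos - 1L)  # subtype unambiguous
    seq <- paste0(parts[1], .at_loop(ls[1]), parts[2], .at_loop(ls[2]),
                  parts[3], .at_loop(ls[3]), parts[4])
    list(seq = seq, n_tracts = 4L)
  } else if (subtype %in% c("Hybrid2", "Hybrid3")) {
    k <- if (subtype == "Hybrid2") 2L else 3L
    gs <- sample(3:4, k, replace = TRUE)
    ls <- sample(1:7, k - 1L, replace = TRUE)
    seq <- tract(gs[1])
    for (i in seq_len(k - 1L)) seq <- paste0(seq, .at_loop(ls[i]), tract(gs[i + 1L]))
    list(seq = seq, n_tracts = k)
  } else stop("unknown subtype: ", subtype)
}

#' Generate a synthetic genome with planted PQS motifs
#'
#' The background has no G or C run of 3 or more, so the planted motifs are
#' the only PQS sources.  Motifs are planted on both strands (minus-strand
#' motifs are inserted as their reverse complement), a `promoter_fraction`
#' of them within 1.5 kb of a synthetic TSS.  A post-check rescans the
#' genome and errors on any deviation from the truth table, so the
#' generator/scanner pair is self-verifying.
#'
#' @param config A [sim_config()].
#' @param verify Rescan the genome and check it against the truth table
#'   (default `TRUE`).
#' @return List with `genome` (named character vector), `genes`
#'   ([make_genes()] output) and `truth` (data frame: chrom, start, end,
#'   strand, subtype, n_tracts, host gene, tier, side, amplitude).
#' @export
make_genome <- function(config, verify = TRUE) {
  genes <- make_genes(config)
  res <- .with_seed(config$seed, {
    chars <- lapply(setNames(nm = paste0("chr", seq_len(config$n_chroms))),
                    function(ch) .background_chars(config$chrom_length))
    occupied <- lapply(chars, function(x) data.frame(start = integer(), end = integer()))
    centers <- lapply(chars, function(x) integer())
    # keep bump footprints non-overlapping so each planted amplitude is
    # exact at its motif center; the promoter slot windows below are tuned
    # to respect this separation at the default enrichment_sd
    sep <- ceiling(6 * config$enrichment_sd)
    plan <- rep(names(config$motif_counts), config$motif_counts)
    n_prox <- round(length(plan) * config$promoter_fraction)
    proximal <- seq_along(plan) <= n_prox     # plan order is arbitrary, fine
    truth <- list()
    gene_cycle <- if (nrow(genes)) rep_len(seq_len(nrow(genes)), length(plan)) else integer()
    # per-gene slot counters for each TSS side, and a per-subtype side
    # alternator so every subtype is planted evenly downstream/upstream
    hits_down <- integer(nrow(genes))
    hits_up <- integer(nrow(genes))
    side_cycle <- setNames(integer(length(config$motif_counts)), names(config$motif_counts))
    for (k in seq_along(plan)) {
      sub <- plan[k]
      ms <- .motif_sequence(sub)
      len <- nchar(ms$seq)
      placed <- FALSE
      gi <- if (nrow(genes)) gene_cycle[k] else NA_integer_
      down <- side_cycle[[sub]] %% 2L == 0L
      slot <- if (nrow(genes)) { if (down) hits_down[gi] else hits_up[gi] } else 0L
      use_prox <- proximal[k] && nrow(genes) && slot < 2L
      for (try in 1:200) {
        if (use_prox) {
          # balanced design: each subtype alternates between the
          # downstream and upstream side of the host TSS, in two offset
          # slots per side chosen so bump footprints stay apart
          g <- genes[gi, ]
          ch <- g$chrom
          u <- if (slot == 0L) sample(seq.int(300L, 600L), 1L)
               else sample(seq.int(1200L, 1400L), 1L)
          dir <- if (g$strand == "+") 1L else -1L
          off <- if (down) u * dir else -u * dir
          center <- g$tss + off
          s <- center - len %/% 2L
        } else {
          ch <- paste0("chr", sample(config$n_chroms, 1L))
          s <- sample.int(config$chrom_length - len - 2L * config$pad, 1L) + config$pad
        }
        e <- s + len
        if (s < config$pad + 1L || e > config$chrom_length - config$pad) next
        if (.overlaps_any(s - config$pad, e + config$pad, occupied[[ch]])) next
        c_new <- (s + e) %/% 2L
        if (length(centers[[ch]]) && min(abs(centers[[ch]] - c_new)) < sep) next
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") ms$seq else .revcomp(ms$seq)
        v <- chars[[ch]]
        v[(s - config$pad + 1L):s] <- sample(c("A", "T"), config$pad, replace = TRUE)
        v[(s + 1L):e] <- strsplit(ins, "", fixed = TRUE)[[1]]
        v[(e + 1L):(e + config$pad)] <- sample(c("A", "T"), config$pad, replace = TRUE)
        chars[[ch]] <- v
        occupied[[ch]] <- rbind(occupied[[ch]], data.frame(start = s - config$pad,
                                                           end = e + config$pad))
        centers[[ch]] <- c(centers[[ch]], c_new)
        if (use_prox) {
          side_cycle[[sub]] <- side_cycle[[sub]] + 1L
          if (down) hits_down[gi] <- hits_down[gi] + 1L else hits_up[gi] <- hits_up[gi] + 1L
        }
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = ch, start = s, end = e, strand = strand, subtype = sub,
          n_tracts = ms$n_tracts, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("infeasible motif plan: could not place a ", sub, " motif")
    }
    empty_truth <- data.frame(chrom = character(), start = integer(),
                              end = integer(), strand = character(),
                              subtype = character(), n_tracts = integer(),
                              stringsAsFactors = FALSE)
    list(genome = vapply(chars, paste, "", collapse = ""),
         truth = if (length(truth)) do.call(rbind, truth) else empty_truth)
  })
  truth <- res$truth[order(res$truth$chrom, res$truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  # host gene, expression tier and TSS side determine the planted amplitude
  center <- (truth$start + truth$end) %/% 2L
  truth$gene <- rep(NA_character_, nrow(truth))
  truth$tier <- rep(1, nrow(truth))
  truth$side <- rep("distal", nrow(truth))
  if (nrow(genes)) {
    for (k in seq_len(nrow(truth))) {
      gi <- which(genes$chrom == truth$chrom[k] & abs(genes$tss - center[k]) <= 1500L)
      if (length(gi)) {
        gi <- gi[1L]
        truth$gene[k] <- genes$name[gi]
        truth$tier[k] <- genes$tier[gi]
        delta <- center[k] - genes$tss[gi]
        truth$side[k] <- if ((genes$strand[gi] == "+") == (delta > 0)) "downstream" else "upstream"
      }
    }
  }
  truth$amplitude <- unname(config$amplitudes[truth$subtype]) * truth$tier *
    ifelse(truth$side == "downstream", config$asymmetry, 1)
  out <- list(genome = res$genome, genes = genes, truth = truth)
  if (verify) {
    got <- scan_genome(out$genome)
    a <- do.call(paste, c(got[, c("chrom", "start", "end", "strand", "subtype")], sep = ":"))
    b <- do.call(paste, c(truth[, c("chrom", "start", "end", "strand", "subtype")], sep = ":"))
    if (!identical(sort(a), sort(b)))
      stop("generator self-check failed: scan does not reproduce the truth table")
  }
  out
}

#' Simulate input and G4P coverage tracks plus peak calls
#'
#' The input track is `background + N(0, noise_sd)` floored at 0; the G4P
#' track adds, at each planted motif, a Gaussian bump of sd `enrichment_sd`
#' whose amplitude is the truth table's planted amplitude (subtype amplitude
#' x host tier x asymmetry when downstream of the TSS).  Peaks are emitted
#' at planted motifs with `fold_enrichment` = (local G4P mean) / (local
#' input mean) over the motif center +/- 250 bp.
#'
#' @param config A [sim_config()].
#' @param sim Output of [make_genome()].
#' @return List with `g4p` and `input` ([coverage_track()]s, read length 50)
#'   and `peaks` (narrowPeak-style data frame).
#' @export
simulate_tracks <- function(config, sim) {
  truth <- sim$truth
  chrom_sizes <- setNames(rep(config$chrom_length, config$n_chroms),
                          paste0("chr", seq_len(config$n_chroms)))
  .with_seed(.sub_seed(config$seed, 7919L), {
    input_vals <- lapply(setNames(nm = names(chrom_sizes)), function(ch)
      pmax(0, config$background + rnorm(chrom_sizes[[ch]], 0, config$noise_sd)))
    g4p_vals <- input_vals
    half <- ceiling(4 * config$enrichment_sd)
    for (k in seq_len(nrow(truth))) {
      ch <- truth$chrom[k]
      c0 <- (truth$start[k] + truth$end[k]) %/% 2L
      i0 <- max(0L, c0 - half); i1 <- min(chrom_sizes[[ch]] - 1L, c0 + half)
      x <- i0:i1
      g4p_vals[[ch]][x + 1L] <- g4p_vals[[ch]][x + 1L] +
        truth$amplitude[k] * exp(-(x - c0)^2 / (2 * config$enrichment_sd^2))
    }
    rl <- 50L
    input <- coverage_track(input_vals, chrom_sizes,
                            total_mapped_reads = round(sum(vapply(input_vals, sum, 0)) / rl),
                            read_length = rl, mode = "raw")
    g4p <- coverage_track(g4p_vals, chrom_sizes,
                          total_mapped_reads = round(sum(vapply(g4p_vals, sum, 0)) / rl),
                          read_length = rl, mode = "raw")
    peaks <- do.call(rbind, lapply(seq_len(nrow(truth)), function(k) {
      ch <- truth$chrom[k]
      c0 <- (truth$start[k] + truth$end[k]) %/% 2L
      s <- max(0L, c0 - 250L); e <- min(chrom_sizes[[ch]], c0 + 250L)
      idx <- (s + 1L):e
      data.frame(chrom = ch, start = s, end = e, name = sprintf("peak_%d", k),
                 score = 0L, strand = ".",
                 fold_enrichment = sum(g4p$values[[ch]][idx]) / sum(input$values[[ch]][idx]),
                 pvalue = -1, qvalue = 3, summit_offset = c0 - s,
                 stringsAsFactors = FALSE)
    }))
    list(g4p = g4p, input = input, peaks = peaks)
  })
}

#' Simulate an EMSA titration series
#'
#' @param f1,kd1,kd2 True model parameters (see [predict_bound()]).
#' @param x Free probe concentration grid (molar).
#' @param noise_sd Gaussian noise sd added to Y (then clipped to \[0, 1\]).
#' @param seed Integer seed.
#' @return Data frame with `x` and `y`.
#' @export
simulate_emsa <- function(f1, kd1, kd2, x, noise_sd = 0, seed = 1L) {
  y0 <- predict_bound(x, kd1, kd2, f1)
  .with_seed(seed, {
    y <- pmin(pmax(y0 + rnorm(length(x), 0, noise_sd), 0), 1)
    data.frame(x = x, y = y)
  })
}

#' Simulate a ChIP-qPCR Ct quadruple with known true enrichment
#'
#' Constructed so [ddct_enrichment()] recovers `true_fold` exactly at
#' `sd = 0`.
#'
#' @param true_fold True fold enrichment (> 0).
#' @param base_ct Baseline cycle number for the three balanced wells.
#' @param efficiency Amplification efficiency (see [ddct_enrichment()]).
#' @param sd Gaussian noise sd added to each Ct.
#' @param seed Integer seed.
#' @return List with the four Ct values.
#' @export
simulate_ct <- function(true_fold, base_ct = 25, efficiency = 2.0, sd = 0, seed = 1L) {
  stopifnot(true_fold > 0)
  .with_seed(seed, {
    e <- rnorm(4L, 0, sd)
    list(ct_chip_target = base_ct - log(true_fold) / log(efficiency) + e[1],
         ct_chip_ref = base_ct + e[2],
         ct_input_target = base_ct + e[3],
         ct_input_ref = base_ct + e[4])
  })
}

#' Write a complete synthetic fixture set to a directory
#'
#' Writes `genome.fa`, `genes.bed`, `chrom.sizes`, `truth.tsv`,
#' `input.bedgraph`, `g4p.bedgraph` and `peaks.narrowPeak`.  Outputs are
#' byte-identical across reruns with the same config.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param verify Passed to [make_genome()].
#' @return Invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(config, outdir, verify = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_genome(config, verify = verify)
  trk <- simulate_tracks(config, sim)
  fa <- file(file.path(outdir, "genome.fa"), "w")
  for (ch in names(sim$genome)) {
    writeLines(paste0(">", ch), fa)
    s <- sim$genome[[ch]]
    writeLines(substring(s, seq(1, nchar(s), 70), pmin(seq(70, nchar(s) + 69, 70), nchar(s))), fa)
  }
  close(fa)
  g <- sim$genes
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", g$chrom, g$start, g$end, g$name,
                     0L, g$strand), file.path(outdir, "genes.bed"))
  writeLines(sprintf("chr%d\t%d", seq_len(config$n_chroms), config$chrom_length),
             file.path(outdir, "chrom.sizes"))
  utils::write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bedgraph(trk$input, file.path(outdir, "input.bedgraph"))
  write_bedgraph(trk$g4p, file.path(outdir, "g4p.bedgraph"))
  write_narrowpeak(trk$peaks, file.path(outdir, "peaks.narrowPeak"))
  invisible(list(sim = sim, tracks = trk))
}
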