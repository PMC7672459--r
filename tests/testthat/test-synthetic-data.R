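test_that("synthetic genes are disjoint, stranded and tiered", {
  cfg <- small_config()
  g <- make_genes(cfg)
  expect_identical(nrow(g), cfg$n_genes)
  expect_setequal(unique(g$strand), c("+", "-"))
  for (ch in unique(g$chrom)) {
    gg <- g[g$chrom == ch, ]
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  expect_setequal(unique(g$tier), cfg$expression_tiers)
  cfg0 <- sim_config(n_genes = 0L)
  expect_identical(nrow(make_genes(cfg0)), 0L)
})

test_that("the generator/scanner pair is self-verifying on a small genome", {
  cfg <- small_config()
  sim <- make_genome(cfg, verify = TRUE)     # verify errors on any deviation
  got <- scan_genome(sim$genome)
  expect_identical(nrow(got), sum(cfg$motif_counts))
  key <- function(d) sort(paste(d$chrom, d$start, d$end, d$strand, d$subtype))
  expect_identical(key(got), key(sim$truth))
  # zero-motif plan
  cfg0 <- sim_config(n_chroms = 1L, chrom_length = 20000L, n_genes = 2L,
                     motif_counts = c("4G" = 0L))
  sim0 <- make_genome(cfg0, verify = FALSE)
  expect_identical(nrow(scan_genome(sim0$genome)), 0L)
})

test_that("generation is byte-identical for a seed and differs across seeds", {
  cfg <- small_config(seed = 5L)
  s1 <- make_genome(cfg, verify = FALSE)
  s2 <- make_genome(cfg, verify = FALSE)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  s3 <- make_genome(small_config(seed = 6L), verify = FALSE)
  expect_false(identical(s1$genome, s3$genome))
})

test_that("planted bump amplitudes encode subtype, tier and TSS side", {
  cfg <- small_config()
  cfg$noise_sd <- 0                            # noiseless construction checks
  sim <- make_genome(cfg, verify = FALSE)
  trk <- simulate_tracks(cfg, sim)
  diff_tr <- compare_tracks(trk$g4p, trk$input, "subtract")
  tr <- sim$truth
  for (k in seq_len(nrow(tr))) {
    c0 <- (tr$start[k] + tr$end[k]) %/% 2L
    expect_equal(diff_tr$values[[tr$chrom[k]]][c0 + 1L], tr$amplitude[k],
                 tolerance = 1e-6)
  }
  # amplitude ratios: same subtype, same side, different tier scale linearly
  sub <- tr[tr$side == "downstream" & tr$subtype == "4G", ]
  if (length(unique(sub$tier)) > 1) {
    a <- tapply(sub$amplitude / cfg$amplitudes[["4G"]] / cfg$asymmetry, sub$tier, unique)
    expect_equal(as.numeric(a), sort(unique(sub$tier)))
  }
  # downstream / upstream of the same subtype and tier differ by the
  # asymmetry factor
  both <- tr[tr$side != "distal", ]
  pair <- split(both$amplitude, paste(both$subtype, both$tier, both$side))
  for (s in unique(both$subtype)) for (ti in unique(both$tier)) {
    d <- pair[[paste(s, ti, "downstream")]]
    u <- pair[[paste(s, ti, "upstream")]]
    if (length(d) && length(u))
      expect_equal(unique(d) / unique(u), cfg$asymmetry)
  }
})

test_that("emitted peaks sit on planted motifs with local-mean fold enrichment", {
  cfg <- small_config()
  sim <- make_genome(cfg, verify = FALSE)
  trk <- simulate_tracks(cfg, sim)
  expect_identical(nrow(trk$peaks), nrow(sim$truth))
  expect_true(all(trk$peaks$fold_enrichment > 1))
  ov <- peak_pqs_overlap(trk$peaks, sim$truth)
  expect_equal(ov$fraction, 1)
})

test_that("EMSA simulation sits on the model curve and is seeded", {
  x <- c(0, 10^seq(-10, -6, length.out = 11))
  d0 <- simulate_emsa(0.6, 1e-9, 1e-7, x, noise_sd = 0, seed = 3)
  expect_equal(d0$y, predict_bound(x, 1e-9, 1e-7, 0.6))
  expect_equal(d0$y[1], 0)
  d1 <- simulate_emsa(0.6, 1e-9, 1e-7, x, noise_sd = 0.05, seed = 3)
  d2 <- simulate_emsa(0.6, 1e-9, 1e-7, x, noise_sd = 0.05, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(d1$y >= 0 & d1$y <= 1))
})

test_that("simulated Ct quads recover the planted fold", {
  q <- simulate_ct(1, sd = 0)
  expect_equal(ddct_enrichment(q), 1)
  q4 <- simulate_ct(4, efficiency = 2, sd = 0)
  expect_equal(q4$ct_chip_target, 23)             # delta-delta-Ct of -2
  expect_equal(ddct_enrichment(q4), 4)
  # noisy recovery stays within 3 sd of truth on average
  folds <- vapply(1:100, function(s)
    ddct_enrichment(simulate_ct(4, sd = 0.1, seed = s)), 1)
  expect_lt(abs(mean(folds) - 4), 3 * sd(folds))
})

test_that("the fixture writer emits a consistent, reloadable file set", {
  cfg <- small_config()
  dir <- withr::local_tempdir()
  simulate_dataset(cfg, dir, verify = FALSE)
  genome <- parse_fasta(file.path(dir, "genome.fa"))
  cs <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_identical(unname(nchar(genome)), unname(as.integer(cs)))
  genes <- load_genes(parse_interval_file(file.path(dir, "genes.bed"), "gene_bed"))
  expect_identical(nrow(genes), cfg$n_genes)
  peaks <- parse_interval_file(file.path(dir, "peaks.narrowPeak"), "narrowPeak")
  truth <- utils::read.delim(file.path(dir, "truth.tsv"))
  expect_identical(nrow(peaks), nrow(truth))
  g4p <- parse_bedgraph(file.path(dir, "g4p.bedgraph"), cs)
  input <- parse_bedgraph(file.path(dir, "input.bedgraph"), cs)
  expect_gt(sum(g4p$values$chr1), sum(input$values$chr1))
  motifs <- scan_genome(genome)
  expect_identical(nrow(motifs), nrow(truth))
})
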