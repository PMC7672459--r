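toy_track <- function(v, name = "c1", ...) {
  coverage_track(setNames(list(v), name), setNames(length(v), name), ...)
}

test_that("RPKM follows the read-equivalents formula and its invariances", {
  # one 100-bp bin holding 5 read-equivalents out of 1e6 mapped reads -> 50
  v <- c(rep(5 * 50 / 100, 100))               # 5 reads of length 50 over 100 bp
  tr <- toy_track(v, total_mapped_reads = 1e6, read_length = 50)
  r <- rpkm_normalize(tr, bin_size = 100L)
  expect_equal(unique(r$values$c1), 50)
  # doubling both coverage and library size leaves RPKM unchanged
  tr2 <- toy_track(2 * v, total_mapped_reads = 2e6, read_length = 50)
  expect_equal(rpkm_normalize(tr2, 100L)$values$c1, r$values$c1)
  # empty bin stays 0
  tr3 <- toy_track(c(v, numeric(100)), total_mapped_reads = 1e6, read_length = 50)
  expect_equal(rpkm_normalize(tr3, 100L)$values$c1[101:200], rep(0, 100))
  expect_error(rpkm_normalize(toy_track(v), 100L), "total_mapped_reads")
})

test_that("track comparison subtracts or ratios with a pseudocount", {
  a <- toy_track(rep(10, 4)); b <- toy_track(rep(4, 4))
  expect_equal(compare_tracks(a, b, "subtract")$values$c1, rep(6, 4))
  expect_equal(compare_tracks(a, b, "ratio")$values$c1, rep(2.2, 4))
  expect_equal(compare_tracks(a, a, "subtract")$values$c1, rep(0, 4))
  expect_equal(compare_tracks(a, a, "ratio")$values$c1, rep(1, 4))
  expect_error(compare_tracks(a, toy_track(rep(1, 4), name = "c2"), "subtract"),
               "mismatched")
})

test_that("reference-point rows average bins and orient minus anchors downstream-right", {
  tr <- toy_track(rep(3, 2000))
  anchors <- data.frame(chrom = "c1", pos = 1000L, strand = "+")
  sm <- reference_point_matrix(tr, anchors, half_width = 500L, bin_size = 50L)
  expect_equal(unname(sm$values[1, ]), rep(3, 20))
  # single spike at TSS+100 of a minus-strand gene lands right of center
  v <- numeric(2000); v[1000 - 100 + 1] <- 10    # minus gene: downstream = lower coords
  trs <- toy_track(v)
  am <- data.frame(chrom = "c1", pos = 999L, strand = "-")
  smm <- reference_point_matrix(trs, am, half_width = 500L, bin_size = 50L)
  ref <- oracle_refpoint_row(v, 999L, "-", 500L, 50L)
  expect_identical(unname(smm$values[1, ]), ref)
  expect_gt(sum(smm$values[1, 11:20]), sum(smm$values[1, 1:10]))
  # anchor at chromosome start zero-fills the left bins
  sm0 <- reference_point_matrix(tr, data.frame(chrom = "c1", pos = 0L, strand = "+"),
                                half_width = 500L, bin_size = 50L)
  expect_equal(unname(sm0$values[1, 1:10]), rep(0, 10))
  expect_error(reference_point_matrix(tr, anchors, 500L, 0L), "positive")
  expect_error(reference_point_matrix(tr, anchors, 501L, 50L), "multiple")
})

test_that("reference-point matrices agree exactly with the per-base oracle", {
  set.seed(8)
  for (i in 1:20) {
    v <- round(runif(3000, 0, 10), 2)
    tr <- toy_track(v)
    anchors <- data.frame(chrom = "c1",
                          pos = sample(0:2999, 5),
                          strand = sample(c("+", "-"), 5, replace = TRUE))
    sm <- reference_point_matrix(tr, anchors, half_width = 400L, bin_size = 20L)
    for (k in 1:5)
      expect_identical(unname(sm$values[k, ]),
                       oracle_refpoint_row(v, anchors$pos[k], anchors$strand[k], 400L, 20L))
  }
})

test_that("double strand flip restores the original matrix", {
  set.seed(4)
  v <- runif(2000)
  tr <- toy_track(v)
  a1 <- data.frame(chrom = "c1", pos = c(500L, 900L), strand = c("+", "-"))
  a2 <- a1; a2$strand <- c("-", "+")
  m1 <- reference_point_matrix(tr, a1, 200L, 20L)$values
  m2 <- reference_point_matrix(tr, a2, 200L, 20L)$values
  expect_identical(m1, t(apply(m2, 1, rev)))
})

test_that("scaled-region matrices preserve body indicators and short-gene means", {
  v <- numeric(5000); v[2001:3000] <- 1         # 1 on the body [2000, 3000)
  tr <- toy_track(v)
  genes <- data.frame(chrom = "c1", start = 2000L, end = 3000L, name = "g1",
                      strand = "+", stringsAsFactors = FALSE)
  sm <- scale_regions_matrix(tr, genes, body_bins = 40L, flank = 500L, bin_size = 50L)
  expect_equal(unname(sm$values[1, 11:50]), rep(1, 40))
  expect_equal(unname(sm$values[1, c(1:10, 51:60)]), rep(0, 20))
  # gene shorter than body_bins: per-bin weighted means still average to the
  # gene mean
  set.seed(6)
  v2 <- runif(5000)
  genes2 <- data.frame(chrom = "c1", start = 100L, end = 117L, name = "tiny",
                       strand = "+", stringsAsFactors = FALSE)
  sm2 <- scale_regions_matrix(toy_track(v2), genes2, body_bins = 40L,
                              flank = 500L, bin_size = 50L)
  expect_equal(mean(sm2$values[1, 11:50]), mean(v2[101:117]))
  # minus-strand rows are reversed
  genes3 <- genes; genes3$strand <- "-"
  sm3 <- scale_regions_matrix(tr, genes3, 40L, 500L, 50L)
  expect_equal(unname(sm3$values[1, ]), rev(unname(sm$values[1, ])))
})

test_that("heatmap scaling maps the global range onto 0-255", {
  m <- rbind(c(0, 5), c(10, 10))
  expect_equal(heatmap_scale(m), rbind(c(0, 127.5), c(255, 255)))
  expect_equal(heatmap_scale(matrix(7, 2, 2)), matrix(0, 2, 2))
  set.seed(2)
  r <- heatmap_scale(matrix(rnorm(30), 5))
  expect_equal(range(r), c(0, 255))
})

test_that("row sorting is stable and its order transfers to other matrices", {
  m <- rbind(r1 = c(3, 3), r2 = c(1, 1), r3 = c(2, 2))
  s <- sort_rows(m, "mean")
  expect_identical(rownames(s$values), c("r1", "r3", "r2"))
  # ties keep input order
  mt <- rbind(a = c(1, 3), b = c(2, 2), c = c(0, 0))
  st <- sort_rows(mt, "mean")
  expect_identical(rownames(st$values), c("a", "b", "c"))
  # shared order contract
  other <- rbind(r1 = 10, r2 = 20, r3 = 30)
  expect_identical(rownames(other[s$order, , drop = FALSE]), c("r1", "r3", "r2"))
  expect_error(sort_rows(m, "median"))
})

test_that("shuffling preserves lengths, respects exclusions and is seeded", {
  cs <- c(c1 = 1000L)
  iv <- data.frame(chrom = "c1", start = 100L, end = 115L)
  excl <- data.frame(chrom = "c1", start = 0L, end = 900L)
  for (seed in 1:25) {
    sh <- shuffle_intervals(iv, cs, excl, seed = seed)
    expect_gte(sh$start, 900L)
    expect_lte(sh$end, 1000L)
    expect_identical(sh$end - sh$start, 15L)
  }
  set.seed(99)  # shuffling must not consume or disturb the global stream
  before <- .Random.seed
  s1 <- shuffle_intervals(iv, cs, NULL, seed = 7)
  expect_identical(.Random.seed, before)
  s2 <- shuffle_intervals(iv, cs, NULL, seed = 7)
  expect_identical(s1, s2)
  starts <- vapply(1:100, function(sd) shuffle_intervals(iv, cs, NULL, seed = sd)$start, 1L)
  expect_gt(length(unique(starts)), 50L)
  expect_error(shuffle_intervals(iv, cs, data.frame(chrom = "c1", start = 0L, end = 1000L),
                                 seed = 1), "no feasible")
})
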