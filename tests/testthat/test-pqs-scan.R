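test_that("canonical 4G matching follows the published consensus", {
  m <- find_4g("GGGAGGGTGGGAGGG")
  expect_identical(m$start, 0L)
  expect_identical(m$end, 15L)
  expect_identical(m$n_tracts, 4L)
  expect_identical(m$loops, "1,1,1")
  expect_identical(nrow(find_4g("GGGAGGGTGGG")), 0L)   # three tracts only
  # minimal match length of the pattern is 15: a pure-G run must split into
  # tracts and single-G loops exactly as a backtracking engine would
  expect_identical(nrow(find_4g(strrep("G", 12))), 0L)
  g15 <- find_4g(strrep("G", 15))
  expect_identical(g15$start, 0L)
  expect_identical(g15$end, 15L)
  expect_identical(nrow(find_4g("")), 0L)
})

test_that("4G matcher is exactly the PCRE semantics of the printed pattern", {
  set.seed(101)
  for (i in 1:300) {
    s <- random_seq(200, gc_bias = (i %% 2 == 0))
    ref <- oracle_4g(s)
    got <- find_4g(s)
    expect_identical(got$start, ref$start)
    expect_identical(got$end, ref$end)
  }
})

test_that("N truncates motifs instead of matching as a loop base", {
  expect_identical(nrow(find_4g("GGGNGGGTGGGAGGG")), 0L)
  m <- find_4g("GGGNGGGAGGGTGGGAGGG")
  expect_identical(m$start, 4L)
  expect_identical(m$end, 19L)
})

test_that("long-loop motifs require exactly one loop of 8-15 nt", {
  m <- find_noncanonical("GGGAGGGTGGGTTTTTTTTTGGG", "4GL15")
  expect_identical(m$start, 0L)
  expect_identical(m$end, 23L)
  expect_identical(m$loops, "1,1,9")
  # all-short and two-long arrangements both fail
  expect_identical(nrow(find_noncanonical("GGGAGGGTGGGAGGG", "4GL15")), 0L)
  expect_identical(
    nrow(find_noncanonical("GGGTTTTTTTTTGGGTTTTTTTTTGGGAGGG", "4GL15")), 0L)
})

test_that("G-vacancy motifs carry one terminal two-G tract", {
  m <- find_noncanonical("GGTGGGAGGGTGGG", "GVBQ")
  expect_identical(m$start, 0L)
  expect_identical(m$end, 14L)
  expect_identical(m$tracts, "2,3,3,3")
  # vacancy in the other terminal tract
  m2 <- find_noncanonical("GGGAGGGTGGGTGG", "GVBQ")
  expect_identical(m2$tracts, "3,3,3,2")
})

test_that("candidates overlapping a canonical motif are filtered out", {
  s <- "GGGAGGGTGGGAGGG"
  m4 <- find_4g(s)
  expect_identical(nrow(find_noncanonical(s, "GVBQ", m4)), 0L)
  # without the canonical spans the permissive parse would fire
  expect_gt(nrow(find_noncanonical(s, "GVBQ")), 0L)
})

test_that("bulge motifs have one tract of three G broken by one non-G", {
  m <- find_noncanonical("GGAGTGGGAGGGTGGG", "Bulge")
  expect_identical(m$start, 0L)
  expect_identical(m$end, 16L)
  expect_identical(m$bulge_offset, 2L)            # GG.A.G
  m2 <- find_noncanonical("GAGGTGGGAGGGTGGG", "Bulge")
  expect_identical(m2$bulge_offset, 1L)           # G.A.GG
  # all tracts intact: the bulge predicate fails even with no 4G around
  s <- "GGGGTGGGAGGGTGGG"
  expect_identical(nrow(find_noncanonical(s, "Bulge", find_4g(s))), 0L)
  expect_error(find_noncanonical("GGG", "nope"), "unknown")
})

test_that("hybrid motifs group maximal 2-3 tract runs and defer to 4-tract spans", {
  h2 <- find_hybrid("GGGAGGG")
  expect_identical(h2$subtype, "Hybrid2")
  expect_identical(h2$end, 7L)
  h3 <- find_hybrid("GGGAGGGTGGG")
  expect_identical(h3$subtype, "Hybrid3")          # one Hybrid3, not two Hybrid2
  expect_identical(nrow(h3), 1L)
  s <- "GGGAGGGTGGGAGGG"
  expect_identical(nrow(find_hybrid(s, find_4g(s))), 0L)
})

test_that("scanner equals the brute-force substring oracle on random sequences", {
  set.seed(77)
  for (i in 1:60) {
    s <- random_seq(300, gc_bias = TRUE)
    got <- scan_genome(c(x = s), strands = "+")
    expect_identical(motif_key(got), motif_key(oracle_scan_strand(s)),
                     info = paste("seq", i))
  }
})

test_that("minus-strand scanning mirrors the reverse complement", {
  m <- scan_genome(c(c1 = "CCCTCCCACCCTCCC"))
  expect_identical(m$strand, "-")
  expect_identical(m$start, 0L)
  expect_identical(m$end, 15L)
  expect_identical(m$subtype, "4G")
  set.seed(31)
  for (i in 1:40) {
    s <- random_seq(250, gc_bias = TRUE)
    minus <- scan_genome(c(x = s), strands = "-")
    plus_rc <- scan_genome(c(x = revcomp_chr(s)), strands = "+")
    L <- nchar(s)
    mirrored <- data.frame(start = L - plus_rc$end, end = L - plus_rc$start,
                           subtype = plus_rc$subtype)
    expect_identical(motif_key(minus), motif_key(mirrored))
  }
})

test_that("records with no G or C runs yield nothing; multi-chrom output is sorted", {
  expect_identical(nrow(scan_genome(c(a = "ATATATATATATATATAT"))), 0L)
  g <- c(b = "TTGGGAGGGTGGGAGGGTT", a = "TTGGGAGGGTGGGAGGGTT")
  m <- scan_genome(g)
  expect_identical(m$chrom, c("a", "b"))
  expect_error(scan_genome(g, subtypes = character()), "empty")
  expect_error(scan_genome(g, subtypes = "5G"), "unknown")
})

test_that("no reported non-canonical or hybrid motif overlaps a 4G span", {
  set.seed(13)
  for (i in 1:25) {
    s <- random_seq(300, gc_bias = TRUE)
    m <- scan_genome(c(x = s), strands = "+")
    m4 <- m[m$subtype == "4G", ]
    rest <- m[m$subtype != "4G", ]
    for (k in seq_len(nrow(rest)))
      expect_false(any(pmin(rest$end[k], m4$end) - pmax(rest$start[k], m4$start) >= 1L))
  }
})

test_that("tract/loop structure reconstructs the motif span", {
  set.seed(19)
  for (i in 1:30) {
    s <- random_seq(300, gc_bias = TRUE)
    m <- scan_genome(c(x = s), strands = "+")
    for (k in seq_len(nrow(m))) {
      tr <- as.integer(strsplit(m$tracts[k], ",")[[1]])
      lp <- if (nzchar(m$loops[k])) as.integer(strsplit(m$loops[k], ",")[[1]]) else integer()
      expect_identical(sum(tr) + sum(lp) + as.integer(m$subtype[k] == "Bulge"),
                       m$end[k] - m$start[k])
      # every motif starts and ends on a guanine
      slice <- substr(s, m$start[k] + 1L, m$end[k])
      expect_identical(substr(slice, 1L, 1L), "G")
      expect_identical(substr(slice, nchar(slice), nchar(slice)), "G")
    }
  }
})

test_that("overlapping calls of different subtypes merge into one multi-subtype motif", {
  motifs <- data.frame(chrom = "c1", start = c(0L, 0L), end = c(23L, 20L),
                       strand = "+", subtype = c("4GL15", "Bulge"),
                       n_tracts = 4L, tracts = "", loops = "", bulge_offset = NA)
  m <- merge_subtype_calls(motifs)
  expect_identical(nrow(m), 1L)
  expect_identical(m$subtype, "4GL15|Bulge")
  expect_identical(m$end, 23L)
  # disjoint calls stay separate
  motifs2 <- data.frame(chrom = "c1", start = c(0L, 50L), end = c(15L, 64L),
                        strand = "+", subtype = c("4G", "GVBQ"), n_tracts = 4L,
                        tracts = "", loops = "", bulge_offset = NA)
  expect_identical(nrow(merge_subtype_calls(motifs2)), 2L)
  # transitive union across three mutually overlapping calls
  motifs3 <- data.frame(chrom = "c1", start = c(0L, 10L, 18L), end = c(15L, 20L, 30L),
                        strand = "+", subtype = c("4G", "GVBQ", "Bulge"),
                        n_tracts = c(4L, 4L, 4L), tracts = "", loops = "",
                        bulge_offset = NA)
  m3 <- merge_subtype_calls(motifs3)
  expect_identical(nrow(m3), 1L)
  expect_identical(m3$subtype, "4G|Bulge|GVBQ")
  expect_identical(m3$n_merged, 3L)
  # opposite strands never merge
  motifs4 <- motifs
  motifs4$strand <- c("+", "-")
  expect_identical(nrow(merge_subtype_calls(motifs4)), 2L)
})
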