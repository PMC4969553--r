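test_that("purity tracts are maximal same-class runs broken by N", {
  t1 <- find_purity_tracts("AGGAAGCTCT", min_len = 3)
  expect_equal(t1$start, c(0L, 6L))
  expect_equal(t1$end, c(6L, 10L))
  expect_equal(t1$tract_type, c("purine", "pyrimidine"))

  expect_equal(nrow(find_purity_tracts("ACACAC", min_len = 3)), 0)

  t3 <- find_purity_tracts("AAANAAA", min_len = 3)
  expect_equal(t3$start, c(0L, 4L))
  expect_equal(t3$end, c(3L, 7L))
  expect_equal(t3$tract_type, c("purine", "purine"))
})

test_that("a mirror repeat with an impure spacer is found across the tract break", {
  hits <- find_mirror_repeats("TTAAGGAGTGAGGAATT")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 15L)
  expect_equal(hits$arm_len, 6L)
  expect_equal(hits$spacer_len, 1L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$tract_type, "purine")
  expect_equal(hits$arm1_seq, "AAGGAG")
  expect_equal(hits$spacer_seq, "T")
  expect_equal(hits$arm2_seq, "GAGGAA")
  expect_equal(hits$arm2_seq, paste(rev(strsplit(hits$arm1_seq, "")[[1]]),
                                    collapse = ""))
})

test_that("arm and spacer gates are enforced at defaults", {
  # arm below the 6 bp minimum is never reported
  expect_equal(nrow(find_mirror_repeats(mirror_construct("AAGGA"))), 0)
  expect_equal(nrow(find_mirror_repeats("AAGGAGTGAGGAA",
                                        hdna_params(min_arm = 7L))), 0)
  # spacer 0: a 12 bp pure run cannot host an arm-6 pair with spacer >= 1
  expect_equal(nrow(find_mirror_repeats(mirror_construct("AAGGAG",
                                                         spacer = ""))), 0)
  # spacer 13 exceeds the maximum; the 12 bp spacer control is reported
  sp13 <- "CCTTACGTACGTT"
  sp12 <- "CCTTACGTACGT"
  expect_equal(nrow(find_mirror_repeats(mirror_construct("AAGGAG", sp13))), 0)
  h12 <- find_mirror_repeats(mirror_construct("AAGGAG", sp12))
  expect_equal(h12$spacer_len, 12L)
  expect_equal(h12$arm_len, 6L)
})

test_that("one symmetry mismatch is tolerated only from arm length 10", {
  arm10 <- "AAGGAGGAGG"
  # innermost pair flipped: every admissible arm carries the mismatch
  h <- find_mirror_repeats(mirror_construct(arm10, "T", flip_pairs = 1L))
  expect_equal(nrow(h), 1)
  expect_equal(h$arm_len, 10L)
  expect_equal(h$mismatches, 1L)
  # same construct truncated to arm 9: the gate rejects the mismatch-bearing
  # arm; only shorter perfect sub-mirrors (shifted spacer) may remain
  h9 <- find_mirror_repeats(mirror_construct("AAGGAGGAG", "T",
                                             flip_pairs = 1L))
  expect_false(any(h9$mismatches > 0L))
  expect_false(any(h9$arm_len >= 9L))
  # two mismatches exceed the budget even at arm 10
  h2 <- find_mirror_repeats(mirror_construct(arm10, "T",
                                             flip_pairs = c(1L, 2L)))
  expect_false(any(h2$mismatches > 0L))
  expect_false(any(h2$arm_len >= 9L))
  # the mismatch may sit at the outermost pair of an arm-10 hit
  hout <- find_mirror_repeats(mirror_construct(arm10, "T", flip_pairs = 10L))
  expect_true(any(hout$arm_len == 10L & hout$mismatches == 1L))
})

test_that("mismatched bases must preserve the arms' purity class", {
  # flipping an arm2 base to a pyrimidine breaks the tract, not just symmetry
  a2 <- strsplit("GGAGGAGGAA", "")[[1]]
  a2[8] <- "T"
  seq <- paste0("TT", "AAGGAGGAGG", "C", paste(a2, collapse = ""), "TT")
  h <- find_mirror_repeats(seq)
  expect_false(any(h$arm_len >= 10L))
})

test_that("poly-purine runs collapse to one suppressed-maximal hit", {
  h <- find_mirror_repeats(strrep("A", 30))
  b <- brute_force_mirror_repeats(strrep("A", 30))
  expect_equal(h, b)
  expect_gt(nrow(h), 0)
  # no reported hit is contained in another with an arm at least as long
  if (nrow(h) > 1) {
    for (i in seq_len(nrow(h))) {
      others <- h[-i, ]
      expect_false(any(others$start <= h$start[i] & others$end >= h$end[i] &
                         others$arm_len >= h$arm_len[i]))
    }
  }
})

test_that("degenerate inputs return empty without error", {
  expect_equal(nrow(find_mirror_repeats("")), 0)
  expect_equal(nrow(find_mirror_repeats("AGAGA")), 0)
  expect_equal(nrow(brute_force_mirror_repeats("")), 0)
})

test_that("scanner and exhaustive oracle agree on random sequences", {
  set.seed(101)
  for (i in 1:60) {
    gc <- runif(1, 0.2, 0.8)
    seq <- random_seq(sample(100:300, 1), gc)
    expect_equal(find_mirror_repeats(seq), brute_force_mirror_repeats(seq),
                 info = paste("seq", i))
  }
})

test_that("mirror repeats are preserved under reverse complement", {
  set.seed(202)
  for (i in 1:25) {
    seq <- random_seq(200, runif(1, 0.3, 0.7))
    L <- nchar(seq)
    h <- find_mirror_repeats(seq)
    hr <- find_mirror_repeats(rc(seq))
    # reflect and swap classes
    refl <- data.frame(start = L - hr$end, end = L - hr$start,
                       arm_len = hr$arm_len, spacer_len = hr$spacer_len,
                       mismatches = hr$mismatches,
                       tract_type = as.character(
                         ifelse(hr$tract_type == "purine",
                                "pyrimidine", "purine")))
    o <- order(refl$start, -refl$arm_len, refl$spacer_len)
    refl <- refl[o, ]
    rownames(refl) <- NULL
    expect_equal(refl,
                 h[, c("start", "end", "arm_len", "spacer_len", "mismatches",
                       "tract_type")])
  }
})

test_that("planted mirror repeats are recovered at exact coordinates", {
  set.seed(303)
  for (i in 1:20) {
    arm <- sample(6:20, 1); spacer <- sample(1:12, 1)
    spec <- plant_spec(600, gc_content = 0.5,
                       motifs = list(list(kind = "mirror_repeat", arm = arm,
                                          spacer = spacer)),
                       seed = 1000L + i)
    sim <- generate_sequence(spec)
    h <- find_mirror_repeats(sim$record)
    tr <- sim$truth
    match <- h$start == tr$start & h$end == tr$end & h$arm_len == tr$arm_len &
      h$spacer_len == tr$spacer_len & h$mismatches == tr$mismatches
    expect_true(any(match), info = sprintf("arm=%d spacer=%d", arm, spacer))
  }
})
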