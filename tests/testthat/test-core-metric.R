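test_that("weighted set size interpolates between count and length", {
  lens <- c(c1 = 4, c2 = 9)
  expect_equal(weighted_length(c("c1", "c2"), lens, alpha = 1), 13)
  expect_equal(weighted_length(c("c1", "c2"), lens, alpha = 0), 1)
  expect_equal(weighted_length(c("c1", "c2"), lens, alpha = 0.5), sqrt(13))
  expect_error(weighted_length(character(0), lens, 1), "non-empty")
  expect_error(weighted_length("c1", lens, 1.5), "alpha")
})

test_that("unique contigs partition the symmetric difference", {
  A <- make_bs(list(P = c("a", "b")), unit_lengths(c("a", "b")))
  B <- make_bs(list(Q = c("b", "c")), unit_lengths(c("b", "c")))
  u <- unique_contigs(A, B)
  expect_equal(u, list(only_A = "a", only_B = "c"))
  expect_equal(unique_contigs(A, A), list(only_A = character(0),
                                          only_B = character(0)))
  E <- make_bs(stats::setNames(list(), character(0)),
               stats::setNames(numeric(0), character(0)))
  expect_equal(unique_contigs(A, E)$only_A, c("a", "b"))
})

test_that("refinement groups a bin's contigs by their bin in the other set", {
  other <- make_bs(list(Q1 = c("a", "b", "x"), Q2 = c("c", "y")),
                   unit_lengths(c("a", "b", "x", "c", "y")))
  parts <- refine_bin(c("a", "b", "c"), other)
  expect_equal(lapply(parts, sort)[order(vapply(parts, length, 1L), decreasing = TRUE)],
               list(c("a", "b"), "c"))
  expect_equal(refine_bin(c("a", "b"), other), list(c("a", "b")))
  expect_error(refine_bin(c("a", "zz"), other), "absent")
})

test_that("closed-form refinement cost matches brute-force split minimisation", {
  lens <- c(p = 6, q = 3, r = 1)
  # worked case: parts of weight 6, 3, 1 at alpha 1 -> (6+3+1) - 6 = 4
  expect_equal(refinement_cost(list("p", "q", "r"), lens, 1), 4)
  expect_equal(brute_refinement_cost(c(6, 3, 1), 1), 4)
  expect_equal(refinement_cost(list(c("p", "q", "r")), lens, 1), 0)
  # alpha = 0: k parts cost k - 1 binary splits
  expect_equal(refinement_cost(list("p", "q", "r"), lens, 0), 2)
  # randomized equivalence, up to 6 parts, alpha in {0, .3, .5, 1}
  set.seed(42)
  for (trial in 1:40) {
    k <- sample(2:6, 1)
    pl <- sample(1:100, k, replace = TRUE)
    ids <- sprintf("x%d", seq_len(k))
    lens_t <- stats::setNames(pl, ids)
    a <- sample(c(0, 0.3, 0.5, 1), 1)
    expect_equal(refinement_cost(as.list(ids), lens_t, a),
                 brute_refinement_cost(pl, a), tolerance = 1e-12)
  }
})

test_that("one binary split costs the smaller weighted side", {
  lens <- c(a = 6, b = 3, c = 1)
  expect_equal(split_cost("a", c("b", "c"), lens, 1), 4)
  expect_equal(split_cost("a", c("b", "c"), lens, 0), 1)
  expect_equal(split_cost(c("a", "b"), "c", lens, 0.5), 1)
  expect_error(split_cost(c("a", "b"), c("b", "c"), lens, 1), "disjoint")
})

test_that("repeat-free dissimilarity matches hand-computed cases", {
  lens <- unit_lengths(c("a", "b", "c", "d"))
  A <- make_bs(list(P1 = c("a", "b"), P2 = c("c", "d")), lens)
  B <- make_bs(list(Q = c("a", "b", "c", "d")), lens)
  r <- dissimilarity_no_repeats(A, B, alpha = 1)
  expect_equal(r$cost_splits, 0)
  expect_equal(r$cost_joins, 2)    # (2 + 2) - 2 over Q's refinement
  expect_equal(r$cost_extra, 0)
  expect_equal(r$cost_missing, 0)
  expect_equal(r$total, 2)
  expect_equal(r$normalized_total, 2 / 8)

  expect_equal(dissimilarity_no_repeats(A, A, 0.5)$total, 0)

  A2 <- make_bs(list(P = "a"), c(a = 10))
  B2 <- make_bs(list(Q = "b"), c(b = 10))
  r2 <- dissimilarity_no_repeats(A2, B2, 1)
  expect_equal(c(r2$cost_extra, r2$cost_missing, r2$total), c(10, 10, 20))
  expect_equal(r2$normalized_total, 1)

  # repeated contig violates the precondition
  A3 <- make_bs(list(P1 = "a", P2 = "a"), c(a = 5))
  expect_error(dissimilarity_no_repeats(A3, A3, 1), "repeat")
})

test_that("components sum to the total, raw and normalized, with bounds", {
  for (seed in 1:20) {
    A <- generate_binset(seed)
    p <- perturb_binset(A, seed + 1000, n_splits = 1, n_extra = 2,
                        n_missing = 1, n_joins = 1)
    r <- bin_dissimilarity(p$binset, A, alpha = 0.5)
    expect_equal(r$cost_extra + r$cost_missing + r$cost_splits + r$cost_joins,
                 r$total, tolerance = 1e-9)
    expect_equal(r$normalized_extra + r$normalized_missing +
                 r$normalized_splits + r$normalized_joins,
                 r$normalized_total, tolerance = 1e-9)
    expect_gte(r$normalized_total, 0)
    expect_lte(r$normalized_total, 1)
  }
})

test_that("swapping the arguments swaps extra/missing and splits/joins", {
  for (seed in 21:35) {
    A <- generate_binset(seed)
    B <- perturb_binset(A, seed + 500, n_splits = 1, n_extra = 1,
                        n_missing = 1)$binset
    ab <- bin_dissimilarity(A, B, alpha = 0.5)
    ba <- bin_dissimilarity(B, A, alpha = 0.5)
    expect_equal(ab$total, ba$total, tolerance = 1e-9)
    expect_equal(ab$cost_extra, ba$cost_missing, tolerance = 1e-9)
    expect_equal(ab$cost_splits, ba$cost_joins, tolerance = 1e-9)
  }
})

test_that("alpha = 0 reduces to pure event counting", {
  lens <- unit_lengths(sprintf("c%d", 1:6))
  A <- make_bs(list(P1 = c("c1", "c2", "c3"), P2 = c("c4", "c5")), lens)
  B <- make_bs(list(Q1 = c("c1", "c2"), Q2 = c("c3", "c4"), Q3 = "c6"), lens)
  r <- dissimilarity_no_repeats(A, B, alpha = 0)
  # unique: c5 (A side), c6 (B side); split P1; join Q2 from two parts
  expect_equal(r$cost_extra, 1)
  expect_equal(r$cost_missing, 1)
  expect_equal(r$cost_splits, 1)
  expect_equal(r$cost_joins, 1)
  expect_equal(r$total, 4)
})

test_that("equal-length fragmentation example: alpha < 1 penalises fragmentation", {
  for (k in 2:5) {
    ids <- sprintf("u%02d", seq_len(2 * k))
    lens <- stats::setNames(rep(10, 2 * k), ids)
    truth <- make_bs(list(P = ids), lens)
    two_halves <- make_bs(list(h1 = ids[1:k], h2 = ids[(k + 1):(2 * k)]), lens)
    shattered <- make_bs(c(list(h1 = ids[1:k]),
                           stats::setNames(as.list(ids[(k + 1):(2 * k)]),
                                           sprintf("s%d", 1:k))), lens)
    d1_a <- bin_dissimilarity(two_halves, truth, alpha = 1)$normalized_total
    d1_b <- bin_dissimilarity(shattered, truth, alpha = 1)$normalized_total
    expect_identical(d1_a, d1_b)       # equal at alpha = 1 (both 0.25 here)
    expect_equal(d1_a, 0.25)
    for (a in c(0, 0.25, 0.5, 0.75)) {
      expect_lt(bin_dissimilarity(two_halves, truth, alpha = a)$normalized_total,
                bin_dissimilarity(shattered, truth, alpha = a)$normalized_total)
    }
  }
})
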