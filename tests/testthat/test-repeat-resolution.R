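test_that("repeat families are the contigs with total copy number above two", {
  lens <- c(r = 4, a = 9, x = 2)
  A <- make_bs(list(A1 = c("r", "a"), A2 = "r"), lens)
  B <- make_bs(list(B1 = c("r", "a"), B2 = "x", B3 = "x", B4 = "x"), lens)
  fam <- repeat_families(A, B)
  expect_setequal(fam$contig, c("r", "x"))
  expect_equal(fam[fam$contig == "r", c("k1", "k2")],
               data.frame(k1 = 2L, k2 = 1L), ignore_attr = TRUE)
  expect_equal(fam[fam$contig == "x", c("k1", "k2")],
               data.frame(k1 = 0L, k2 = 3L), ignore_attr = TRUE)
  # a appears once per side: not a family
  expect_false("a" %in% fam$contig)
})

test_that("maximal matching counts follow C(max, min) * min!", {
  expect_equal(count_matchings(2, 3), 6)
  expect_equal(count_matchings(1, 1), 1)
  expect_equal(count_matchings(0, 4), 1)
  expect_equal(count_matchings(3, 3), 6)
  # enumeration size always equals the closed form
  set.seed(7)
  for (trial in 1:25) {
    k1 <- sample(1:3, 1); k2 <- sample(1:3, 1)
    lens <- c(r = 5)
    bins_a <- stats::setNames(rep(list("r"), k1), sprintf("A%d", seq_len(k1)))
    bins_b <- stats::setNames(rep(list("r"), k2), sprintf("B%d", seq_len(k2)))
    A <- make_bs(bins_a, lens); B <- make_bs(bins_b, lens)
    expect_length(enumerate_matchings("r", A, B), count_matchings(k1, k2))
  }
})

test_that("resolution renames copies so the instance becomes repeat-free", {
  lens <- c(r = 4, a = 9)
  A <- make_bs(list(X = c("r", "a")), lens)
  B <- make_bs(list(Y1 = "r", Y2 = c("r", "a")), lens)
  ms <- enumerate_matchings("r", A, B)
  expect_length(ms, 2)
  # pick the matching pairing A's copy with B's {r, a} bin
  m <- ms[[which(vapply(ms, function(x) x$b_bin == "Y2", logical(1)))]]
  res <- resolve_matchings(A, B, list(r = m))
  expect_equal(res$A$bins$X, c("r#1", "a"))
  expect_setequal(res$B$bins$Y1, "r#B1")
  expect_setequal(res$B$bins$Y2, c("r#1", "a"))
  # repeat-free and occurrence-weighted length conserved
  expect_equal(nrow(repeat_families(res$A, res$B)), 0)
  occ_len <- function(bs) sum(bs$lengths[unlist(bs$bins, use.names = FALSE)])
  expect_equal(occ_len(res$A) + occ_len(res$B), occ_len(A) + occ_len(B))
  # matchings referencing a bin without the contig are rejected
  bad <- data.frame(a_bin = "X", b_bin = "nope")
  expect_error(resolve_matchings(A, B, list(r = bad)), "not containing")
})

test_that("branch-and-bound picks the optimal matching on the worked repeat case", {
  lens <- c(r = 4, a = 9)
  A <- make_bs(list(X = c("r", "a")), lens)
  B <- make_bs(list(Y1 = "r", Y2 = c("r", "a")), lens)
  r <- bin_dissimilarity(A, B, alpha = 0.5)
  # optimal matching pairs r with B's {r, a} copy; the lone copy is unique
  expect_equal(r$total, 2)                     # 4^0.5
  expect_equal(r$normalized_total, 2 / 12)     # Eq-normalisation with copies
  expect_equal(r$matchings$r$b_bin, "Y2")
  # the alternative matching costs 2 + min(2, 3) = 4
  alt <- resolve_matchings(A, B, list(r = data.frame(a_bin = "X", b_bin = "Y1")))
  expect_equal(dissimilarity_no_repeats(alt$A, alt$B, 0.5)$total, 4)
})

test_that("no-repeat inputs fall through to the polynomial computation", {
  A <- generate_binset(101)
  B <- perturb_binset(A, 102, n_splits = 1)$binset
  expect_equal(bin_dissimilarity(B, A, 0.5)$total,
               dissimilarity_no_repeats(B, A, 0.5)$total)
  expect_length(bin_dissimilarity(B, A, 0.5)$matchings, 0)
})

test_that("contigs duplicated twice on one side resolve as forced uniques", {
  lens <- c(d = 7, a = 3)
  A <- make_bs(list(A1 = c("d", "a"), A2 = "d"), lens)
  B <- make_bs(list(B1 = "a"), lens)
  # d has copy number 2 + 0: not a repeat family, but still a repeat
  expect_equal(nrow(repeat_families(A, B)), 0)
  r <- bin_dissimilarity(A, B, alpha = 1)
  expect_equal(r$cost_extra, 14)   # both copies of d are unique to A
  expect_equal(r$total, 14)
  e <- exhaustive_dissimilarity(A, B, alpha = 1)
  expect_equal(e$total, 14)
})

test_that("branch-and-bound equals the exhaustive oracle on random instances", {
  for (seed in 1:60) {
    inst <- random_repeat_instance(seed)
    for (a in c(0, 0.5, 1)) {
      bb <- bin_dissimilarity(inst$A, inst$B, alpha = a)
      ex <- exhaustive_dissimilarity(inst$A, inst$B, alpha = a)
      expect_identical(bb$total, ex$total)
      expect_equal(bb$normalized_total, ex$normalized_total, tolerance = 1e-12)
    }
  }
})

test_that("pruning does not change the optimum and symmetry holds under repeats", {
  for (seed in 61:85) {
    inst <- random_repeat_instance(seed)
    with_b <- bin_dissimilarity(inst$A, inst$B, 0.5, use_bound = TRUE,
                                debug = TRUE)
    no_b <- bin_dissimilarity(inst$A, inst$B, 0.5, use_bound = FALSE)
    expect_identical(with_b$total, no_b$total)
    expect_gte(with_b$search$pruned, 0)
    # symmetry of the total under argument swap
    rev <- bin_dissimilarity(inst$B, inst$A, 0.5)
    expect_equal(with_b$total, rev$total, tolerance = 1e-9)
  }
})

test_that("partial dissimilarity never decreases as families are added", {
  # monotonicity of the bound: resolving a prefix of the families and
  # dropping the rest can never cost more than the full optimum
  for (seed in 86:100) {
    inst <- random_repeat_instance(seed)
    fam <- repeat_families(inst$A, inst$B)
    full <- bin_dissimilarity(inst$A, inst$B, 0.5)
    if (!nrow(fam)) next
    # root instance: all repeat-family contigs removed
    strip <- function(bs, drop) {
      bins <- lapply(bs$bins, function(b) b[!(b %in% drop)])
      bins <- bins[vapply(bins, length, integer(1)) > 0L]
      structure(list(label = bs$label, bins = bins, lengths = bs$lengths),
                class = "bin_set")
    }
    A0 <- strip(inst$A, fam$contig)
    B0 <- strip(inst$B, fam$contig)
    root <- dissimilarity_no_repeats(A0, B0, 0.5)
    expect_lte(root$total, full$total + 1e-9)
  }
})

test_that("exhaustive enumeration refuses instances above its cap", {
  lens <- c(r = 5, s = 6)
  mk <- function(pre, n, ctg) stats::setNames(rep(list(ctg), n),
                                              sprintf("%s%d", pre, seq_len(n)))
  A <- make_bs(c(mk("A", 3, "r"), mk("C", 3, "s")), lens)
  B <- make_bs(c(mk("B", 3, "r"), mk("D", 3, "s")), lens)
  expect_equal(prod(repeat_families(A, B)$n_matchings), 36)
  expect_error(exhaustive_dissimilarity(A, B, 0.5, cap = 10), "cap")
  expect_equal(exhaustive_dissimilarity(A, B, 0.5)$total,
               bin_dissimilarity(A, B, 0.5)$total)
})
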