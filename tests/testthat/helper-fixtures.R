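# shorthand constructor: bins as list, lengths as named vector
make_bs <- function(bins, lens, label = "t") bin_set(bins, lens, label = label)

unit_lengths <- function(ids) stats::setNames(rep(1, length(ids)), ids)

# Independent oracle for the refinement cost: minimum total cost over ALL
# sequences of binary splits that separate the given parts, by recursion over
# bipartitions of the part multiset (memoised). Costs a split as
# min(weight(left), weight(right)) with weight(S) = (sum of raw lengths)^alpha.
brute_refinement_cost <- function(part_lengths, alpha) {
  k <- length(part_lengths)
  memo <- new.env(parent = emptyenv())
  cost <- function(idx) {
    if (length(idx) == 1L) return(0)
    key <- paste(sort(idx), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- Inf
    n <- length(idx)
    # enumerate proper non-empty subsets via bitmask (first element fixed in
    # one side to halve the work)
    for (mask in 0:(2^(n - 1L) - 2L)) {
      inl <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(n - 1L) - 1L))))
      left <- idx[inl]; right <- idx[!inl]
      w <- min(sum(part_lengths[left])^alpha, sum(part_lengths[right])^alpha)
      best <- min(best, w + cost(left) + cost(right))
    }
    memo[[key]] <- best
    best
  }
  cost(seq_len(k))
}

# Random small instance with repeated contigs: two bin sets over a shared
# universe, with up to `max_fam` contigs duplicated into extra bins so that
# repeat families (k1 + k2 > 2, each side <= max_copies) arise.
random_repeat_instance <- function(seed, max_fam = 3, max_copies = 3) {
  set.seed(seed)
  n_ctg <- sample(4:8, 1)
  ids <- sprintf("c%02d", seq_len(n_ctg))
  lens <- stats::setNames(sample(1:50, n_ctg, replace = TRUE), ids)
  assign_bins <- function(prefix) {
    n_bins <- sample(2:4, 1)
    grp <- sample(seq_len(n_bins), n_ctg, replace = TRUE)
    bins <- split(ids, grp)
    names(bins) <- sprintf("%s%d", prefix, seq_along(bins))
    bins
  }
  a_bins <- assign_bins("A")
  b_bins <- assign_bins("B")
  # duplicate a few contigs into additional bins to create repeat families
  n_fam <- sample(1:max_fam, 1)
  fam_ctg <- sample(ids, n_fam)
  for (ctg in fam_ctg) {
    for (side in c("a", "b")) {
      bins <- if (side == "a") a_bins else b_bins
      extra <- sample(0:(max_copies - 1), 1)
      cand <- names(bins)[!vapply(bins, function(b) ctg %in% b, logical(1))]
      for (bn in utils::head(sample(cand), extra))
        bins[[bn]] <- c(bins[[bn]], ctg)
      if (side == "a") a_bins <- bins else b_bins <- bins
    }
  }
  list(A = make_bs(a_bins, lens, "A"), B = make_bs(b_bins, lens, "B"))
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

bins_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("plasmid\tcontig\tcontig_len",
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}
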