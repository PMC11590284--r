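#' Repeat families of a pair of bin sets
#'
#' A contig family comprises all copies of one contig id across the two sets;
#' it is a repeat family when the total copy number `k1 + k2` exceeds 2 (with
#' `k1` the number of left-set bins containing it and `k2` the right-set
#' count). Repeat families are what the matching search of
#' [bin_dissimilarity()] must resolve.
#'
#' @param A,B `bin_set` objects.
#' @return Data frame with columns `contig`, `k1`, `k2`, `n_matchings`
#'   (number of maximal matchings, `C(max,min) * min!`) and `length`, ordered
#'   by decreasing `n_matchings`, ties by decreasing length then contig id.
#' @export
repeat_families <- function(A, B) {
  k1 <- copy_number(A)
  k2 <- copy_number(B)
  ids <- union(names(k1), names(k2))
  c1 <- ifelse(ids %in% names(k1), k1[ids], 0L)
  c2 <- ifelse(ids %in% names(k2), k2[ids], 0L)
  fam <- ids[c1 + c2 > 2L]
  lens <- validate_pair(A, B)
  df <- data.frame(contig = fam,
                   k1 = as.integer(c1[match(fam, ids)]),
                   k2 = as.integer(c2[match(fam, ids)]),
                   stringsAsFactors = FALSE)
  df$n_matchings <- if (nrow(df)) mapply(count_matchings, df$k1, df$k2) else numeric(0)
  df$length <- if (nrow(df)) as.numeric(lens[df$contig]) else numeric(0)
  df[order(-df$n_matchings, -df$length, df$contig), , drop = FALSE]
}

#' Number of maximal matchings between the copies of one contig
#'
#' With `k1` copies on one side and `k2` on the other, a maximal matching has
#' `min(k1, k2)` edges; there are `C(max(k1,k2), min(k1,k2)) * min(k1,k2)!`
#' of them.
#'
#' @param k1,k2 Non-negative integer copy counts.
#' @return Number of maximal matchings (1 when either count is 0).
#' @export
count_matchings <- function(k1, k2) {
  stopifnot(k1 >= 0, k2 >= 0)
  choose(max(k1, k2), min(k1, k2)) * factorial(min(k1, k2))
}

# ordered k-selections (k-permutations) of 1..n in lexicographic order
k_permutations <- function(n, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) { out[[length(out) + 1L]] <<- prefix; return() }
    for (x in remaining) rec(c(prefix, x), setdiff(remaining, x))
  }
  rec(integer(0), seq_len(n))
  out
}

#' Enumerate all maximal matchings of one repeat family
#'
#' Copies of the family contig are identified by the (unique) ids of the bins
#' that contain them, taken in sorted order per side. Each matching pairs
#' every copy on the smaller side with a distinct copy on the larger side; the
#' enumeration order is deterministic (lexicographic over larger-side
#' positions).
#'
#' @param contig Contig id of the family.
#' @param A,B `bin_set` objects containing the family.
#' @return List of matchings; each matching is a data frame with columns
#'   `a_bin`, `b_bin` (one row per edge; zero rows when a side has no copy).
#' @export
enumerate_matchings <- function(contig, A, B) {
  a_bins <- sort(names(A$bins)[vapply(A$bins, function(b) contig %in% b, logical(1))])
  b_bins <- sort(names(B$bins)[vapply(B$bins, function(b) contig %in% b, logical(1))])
  k1 <- length(a_bins); k2 <- length(b_bins)
  k <- min(k1, k2)
  if (k1 <= k2) {
    sel <- k_permutations(k2, k)
    lapply(sel, function(s) data.frame(a_bin = a_bins, b_bin = b_bins[s],
                                       stringsAsFactors = FALSE))
  } else {
    sel <- k_permutations(k1, k)
    lapply(sel, function(s) data.frame(a_bin = a_bins[s], b_bin = b_bins,
                                       stringsAsFactors = FALSE))
  }
}

# Fresh ids for the resolved copies of `contig` under `matching`:
#   matched edge i  -> "<contig>#<i>" on both sides
#   unmatched copy  -> "<contig>#A<j>" / "<contig>#B<j>"
# Returns list(a = named chr (bin id -> new contig id), b = likewise,
#              new_lengths = named numeric)
resolved_ids <- function(contig, matching, a_bins, b_bins, len) {
  k <- nrow(matching)
  a_new <- character(0); b_new <- character(0)
  if (k > 0) {
    edge_ids <- paste0(contig, "#", seq_len(k))
    a_new <- stats::setNames(edge_ids, matching$a_bin)
    b_new <- stats::setNames(edge_ids, matching$b_bin)
  }
  un_a <- setdiff(a_bins, matching$a_bin)
  if (length(un_a))
    a_new <- c(a_new, stats::setNames(paste0(contig, "#A", seq_along(un_a)), un_a))
  un_b <- setdiff(b_bins, matching$b_bin)
  if (length(un_b))
    b_new <- c(b_new, stats::setNames(paste0(contig, "#B", seq_along(un_b)), un_b))
  new_ids <- unique(c(a_new, b_new))
  list(a = a_new, b = b_new,
       new_lengths = stats::setNames(rep(len, length(new_ids)), new_ids))
}

#' Resolve repeat families with a chosen set of matchings
#'
#' Applies one maximal matching per repeat family: the two copies on an edge
#' receive a shared fresh id (so they behave as the same contig), unmatched
#' copies receive side-local fresh ids (so they become unique contigs). Ids
#' use the reserved `#` character and cannot collide with input ids. Contigs
#' duplicated on a single side with total copy number 2 (not a repeat family,
#' but still a repeat) are resolved the only way possible: both copies
#' unmatched. The output pair is repeat-free.
#'
#' @param A,B `bin_set` objects.
#' @param matchings Named list: for each repeat-family contig id, a matching
#'   data frame as produced by [enumerate_matchings()].
#' @return List with resolved `bin_set`s `A` and `B`.
#' @export
resolve_matchings <- function(A, B, matchings) {
  lens <- validate_pair(A, B)
  fam <- repeat_families(A, B)
  need <- fam$contig
  miss <- setdiff(need, names(matchings))
  if (length(miss))
    stop("no matching supplied for repeat family(ies): ",
         paste(miss, collapse = ", "), call. = FALSE)
  # one-side duplicates with k1+k2 == 2 also need renaming (forced resolution)
  forced <- one_side_duplicates(A, B)
  a_bins <- A$bins; b_bins <- B$bins
  new_lens <- lens
  for (ctg in c(need, forced)) {
    in_a <- sort(names(a_bins)[vapply(a_bins, function(b) ctg %in% b, logical(1))])
    in_b <- sort(names(b_bins)[vapply(b_bins, function(b) ctg %in% b, logical(1))])
    m <- if (ctg %in% need) matchings[[ctg]] else
      data.frame(a_bin = character(0), b_bin = character(0))
    if (nrow(m)) {
      if (!all(m$a_bin %in% in_a) || !all(m$b_bin %in% in_b))
        stop("matching for '", ctg, "' references a bin not containing it",
             call. = FALSE)
      if (anyDuplicated(m$a_bin) || anyDuplicated(m$b_bin))
        stop("matching for '", ctg, "' uses a copy twice", call. = FALSE)
    }
    r <- resolved_ids(ctg, m, in_a, in_b, lens[[ctg]])
    for (bn in names(r$a)) a_bins[[bn]][a_bins[[bn]] == ctg] <- r$a[[bn]]
    for (bn in names(r$b)) b_bins[[bn]][b_bins[[bn]] == ctg] <- r$b[[bn]]
    new_lens <- c(new_lens, r$new_lengths)
    new_lens <- new_lens[names(new_lens) != ctg]
  }
  list(A = structure(list(label = A$label, bins = a_bins, lengths = new_lens,
                          resolved = TRUE), class = "bin_set"),
       B = structure(list(label = B$label, bins = b_bins, lengths = new_lens,
                          resolved = TRUE), class = "bin_set"))
}

# contigs with k1+k2 == 2 but both copies on the same side
one_side_duplicates <- function(A, B) {
  k1 <- copy_number(A); k2 <- copy_number(B)
  ids <- union(names(k1), names(k2))
  c1 <- ifelse(ids %in% names(k1), k1[ids], 0L)
  c2 <- ifelse(ids %in% names(k2), k2[ids], 0L)
  ids[(c1 + c2) == 2L & (c1 == 2L | c2 == 2L)]
}

#' Repeat-aware dissimilarity between two bin sets
#'
#' The main comparison entry point. Contigs occurring in several bins are made
#' distinguishable by a maximal matching per repeat family; the dissimilarity
#' is the minimum, over all combinations of matchings, of the repeat-free
#' dissimilarity of the resolved pair. The minimum is found exactly by a
#' branch-and-bound: families are stacked level by level (widest family
#' first), a node's partial dissimilarity never decreases towards the leaves,
#' and a subtree is explored only when its partial value is strictly below the
#' incumbent. With no repeat family the result equals
#' [dissimilarity_no_repeats()].
#'
#' @param A Left ("predicted") `bin_set`.
#' @param B Right ("reference") `bin_set`.
#' @param alpha Length-weight exponent in `[0, 1]`; 0.5 balances counting and
#'   length weighting.
#' @param min_len Minimum contig length in bp; shorter contigs are discarded
#'   from both sets (and from the normalisation) before comparison.
#' @param use_bound Disable to force exhaustive tree exploration (the result
#'   is identical; used for verification).
#' @param debug If `TRUE`, attach node/prune counters in `$search`.
#' @return A `bin_comparison`; `$matchings` holds the optimal matching per
#'   repeat family (first optimum in deterministic enumeration order).
#' @export
bin_dissimilarity <- function(A, B, alpha = 0.5, min_len = 0,
                              use_bound = TRUE, debug = FALSE) {
  check_alpha(alpha)
  A <- filter_min_length(A, min_len)
  B <- filter_min_length(B, min_len)
  lens <- validate_pair(A, B)
  denom <- norm_denominator(A, B, alpha)
  fam <- repeat_families(A, B)

  if (nrow(fam) == 0L && !length(one_side_duplicates(A, B))) {
    comp <- core_components(A$bins, B$bins, lens, alpha)
    return(make_comparison(comp, alpha, denom))
  }

  # per-family copy locations and enumerated matchings (deterministic order)
  fam_match <- lapply(fam$contig, enumerate_matchings, A = A, B = B)
  names(fam_match) <- fam$contig

  # root: strip all repeat-family contigs; resolve forced one-side duplicates
  forced <- one_side_duplicates(A, B)
  a_root <- lapply(A$bins, function(b) b[!(b %in% fam$contig) & !(b %in% forced)])
  b_root <- lapply(B$bins, function(b) b[!(b %in% fam$contig) & !(b %in% forced)])
  ext_lens <- lens
  for (ctg in forced) {
    in_a <- sort(names(A$bins)[vapply(A$bins, function(b) ctg %in% b, logical(1))])
    in_b <- sort(names(B$bins)[vapply(B$bins, function(b) ctg %in% b, logical(1))])
    r <- resolved_ids(ctg, data.frame(a_bin = character(0), b_bin = character(0)),
                      in_a, in_b, lens[[ctg]])
    for (bn in names(r$a)) a_root[[bn]] <- c(a_root[[bn]], r$a[[bn]])
    for (bn in names(r$b)) b_root[[bn]] <- c(b_root[[bn]], r$b[[bn]])
    ext_lens <- c(ext_lens, r$new_lengths)
  }
  # pre-register lengths of every fresh id any matching can create
  for (i in seq_len(nrow(fam))) {
    ctg <- fam$contig[i]
    kmin <- min(fam$k1[i], fam$k2[i]); kmax <- max(fam$k1[i], fam$k2[i])
    ids <- c(if (kmin > 0) paste0(ctg, "#", seq_len(kmin)),
             if (kmax > kmin) paste0(ctg, "#A", seq_len(kmax - kmin)),
             if (kmax > kmin) paste0(ctg, "#B", seq_len(kmax - kmin)))
    ext_lens <- c(ext_lens, stats::setNames(rep(lens[[ctg]], length(ids)), ids))
  }

  add_family <- function(a_bins, b_bins, ctg, matching) {
    in_a <- sort(names(A$bins)[vapply(A$bins, function(b) ctg %in% b, logical(1))])
    in_b <- sort(names(B$bins)[vapply(B$bins, function(b) ctg %in% b, logical(1))])
    r <- resolved_ids(ctg, matching, in_a, in_b, lens[[ctg]])
    for (bn in names(r$a)) a_bins[[bn]] <- c(a_bins[[bn]], r$a[[bn]])
    for (bn in names(r$b)) b_bins[[bn]] <- c(b_bins[[bn]], r$b[[bn]])
    list(a = a_bins, b = b_bins)
  }

  n_fam <- nrow(fam)
  nodes <- 0L; pruned <- 0L

  # incumbent: identity matching (copies paired in sorted bin-id order),
  # i.e. the first enumerated matching of every family
  inc_a <- a_root; inc_b <- b_root
  inc_match <- list()
  for (i in seq_len(n_fam)) {
    ctg <- fam$contig[i]
    inc_match[[ctg]] <- fam_match[[ctg]][[1L]]
    st <- add_family(inc_a, inc_b, ctg, inc_match[[ctg]])
    inc_a <- st$a; inc_b <- st$b
  }
  best_comp <- core_components(inc_a, inc_b, ext_lens, alpha)
  best_total <- best_comp$total
  best_match <- inc_match

  dfs <- function(a_bins, b_bins, level) {
    ctg <- fam$contig[level]
    for (m in fam_match[[ctg]]) {
      st <- add_family(a_bins, b_bins, ctg, m)
      comp <- core_components(st$a, st$b, ext_lens, alpha)
      nodes <<- nodes + 1L
      if (level == n_fam) {
        if (comp$total < best_total) {
          best_total <<- comp$total
          best_comp <<- comp
          trail[[level]] <<- m
          best_match <<- stats::setNames(trail[seq_len(n_fam)], fam$contig)
        }
      } else {
        if (use_bound && comp$total >= best_total) {
          pruned <<- pruned + 1L
          next
        }
        trail[[level]] <<- m
        dfs(st$a, st$b, level + 1L)
      }
    }
  }
  trail <- vector("list", n_fam)
  if (n_fam > 0L) dfs(a_root, b_root, 1L)

  make_comparison(best_comp, alpha, denom, matchings = best_match,
                  search = if (debug) list(nodes = nodes, pruned = pruned))
}

#' Exhaustive minimum over all repeat resolutions (verification oracle)
#'
#' Evaluates the repeat-free dissimilarity of every combination of maximal
#' matchings by full Cartesian product and returns the minimum. Exponential in
#' the number of families; refuses instances whose product of matching counts
#' exceeds `cap`. Exists to verify [bin_dissimilarity()], which must return
#' identical totals.
#'
#' @inheritParams bin_dissimilarity
#' @param cap Maximum number of resolution combinations to evaluate.
#' @return A `bin_comparison`.
#' @export
exhaustive_dissimilarity <- function(A, B, alpha = 0.5, min_len = 0,
                                     cap = 1e5) {
  check_alpha(alpha)
  A <- filter_min_length(A, min_len)
  B <- filter_min_length(B, min_len)
  lens <- validate_pair(A, B)
  denom <- norm_denominator(A, B, alpha)
  fam <- repeat_families(A, B)
  if (nrow(fam) == 0L && !length(one_side_duplicates(A, B))) {
    comp <- core_components(A$bins, B$bins, lens, alpha)
    return(make_comparison(comp, alpha, denom))
  }
  n_comb <- prod(fam$n_matchings)
  if (n_comb > cap)
    stop("instance has ", format(n_comb, big.mark = ","),
         " resolution combinations, above the cap of ", cap, call. = FALSE)
  fam_match <- lapply(fam$contig, enumerate_matchings, A = A, B = B)
  names(fam_match) <- fam$contig
  idx <- rep(1L, nrow(fam))
  best <- NULL; best_match <- NULL
  repeat {
    m <- stats::setNames(lapply(seq_len(nrow(fam)),
                                function(i) fam_match[[i]][[idx[i]]]),
                         fam$contig)
    res <- resolve_matchings(A, B, m)
    comp <- core_components(res$A$bins, res$B$bins, res$A$lengths, alpha)
    if (is.null(best) || comp$total < best$total) {
      best <- comp; best_match <- m
    }
    # advance mixed-radix counter
    i <- 1L
    while (i <= nrow(fam)) {
      idx[i] <- idx[i] + 1L
      if (idx[i] <= length(fam_match[[i]])) break
      idx[i] <- 1L; i <- i + 1L
    }
    if (i > nrow(fam)) break
  }
  if (nrow(fam) == 0L) {  # only forced one-side duplicates
    res <- resolve_matchings(A, B, list())
    best <- core_components(res$A$bins, res$B$bins, res$A$lengths, alpha)
    best_match <- list()
  }
  make_comparison(best, alpha, denom, matchings = best_match)
}
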