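#' Length-weighted size of a contig set
#'
#' For a non-empty set of contigs `X` with total length `L`, the weighted size
#' is `L^alpha`. The exponent `alpha` in `[0, 1]` interpolates between pure
#' counting (`alpha = 0`: every non-empty set weighs 1) and pure length
#' (`alpha = 1`).
#'
#' @param contig_ids Character vector of contig ids (non-empty set).
#' @param lengths Named numeric vector of contig lengths in bp.
#' @param alpha Length-weight exponent in `[0, 1]`.
#' @return A single number, `(sum of lengths)^alpha`.
#' @export
weighted_length <- function(contig_ids, lengths, alpha) {
  check_alpha(alpha)
  if (!length(contig_ids)) stop("weighted_length is defined on non-empty sets",
                                call. = FALSE)
  l <- lengths[contig_ids]
  if (anyNA(l)) stop("missing length for contig(s): ",
                     paste(contig_ids[is.na(l)], collapse = ", "), call. = FALSE)
  sum(l)^alpha
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]", call. = FALSE)
  invisible(alpha)
}

#' Contigs unique to one side of a comparison
#'
#' Splits the symmetric difference of the two contig universes into the ids
#' found only in `A` and the ids found only in `B`. Each unique contig `c`
#' contributes `l(c)^alpha` to the dissimilarity (it must be discarded before
#' either set can be transformed into the other).
#'
#' @param A,B `bin_set` objects.
#' @return List with character vectors `only_A` and `only_B`.
#' @export
unique_contigs <- function(A, B) {
  ua <- unique(unlist(A$bins, use.names = FALSE))
  ub <- unique(unlist(B$bins, use.names = FALSE))
  list(only_A = setdiff(ua, ub), only_B = setdiff(ub, ua))
}

#' Refinement of a bin against another bin set
#'
#' Partitions the contigs of `P` by which bin of `other` contains them: the
#' unique partition `P_1, ..., P_k` such that each `P_i` is the intersection
#' of `P` with one bin of `other`. It is the intermediate state between the
#' splitting and joining phases of the dissimilarity. Every contig of `P`
#' must occur in exactly one bin of `other` (call after removing unique
#' contigs).
#'
#' @param P Character vector: the contigs of the bin to refine.
#' @param other A `bin_set` (repeat-free over the contigs of `P`).
#' @return List of character vectors, the parts of the partition.
#' @export
refine_bin <- function(P, other) {
  mem <- bin_membership(other$bins)
  m <- mem[P]
  if (anyNA(m))
    stop("contig(s) of the bin are absent from the other set: ",
         paste(P[is.na(m)], collapse = ", "), call. = FALSE)
  unname(split(P, m))
}

# contig id -> containing bin id; errors if a contig sits in >1 bin
bin_membership <- function(bins) {
  occ <- unlist(bins, use.names = FALSE)
  if (anyDuplicated(occ))
    stop("repeat-free operation called on a set with repeated contig(s): ",
         paste(unique(occ[duplicated(occ)]), collapse = ", "), call. = FALSE)
  stats::setNames(rep(names(bins), lengths(bins)), occ)
}

#' Cost of the cheapest split sequence producing a refinement
#'
#' The cheapest sequence of binary splits turning a bin into parts
#' `P_1, ..., P_k` carves the parts off in increasing order of weighted size,
#' giving the closed form `sum_i L_alpha(P_i) - max_i L_alpha(P_i)`. By the
#' split/join symmetry the same value is the cheapest join sequence
#' reassembling the bin from its parts.
#'
#' @param parts List of character vectors (the refinement parts; non-empty,
#'   pairwise disjoint).
#' @param lengths Named numeric vector of contig lengths.
#' @param alpha Length-weight exponent in `[0, 1]`.
#' @return A single non-negative number; 0 when there is a single part.
#' @export
refinement_cost <- function(parts, lengths, alpha) {
  check_alpha(alpha)
  if (!length(parts)) stop("refinement must have at least one part", call. = FALSE)
  w <- vapply(parts, weighted_length, numeric(1), lengths = lengths, alpha = alpha)
  sum(w) - max(w)
}

#' Cost of one binary split (or join)
#'
#' Splitting a bin into the disjoint non-empty parts `P1` and `P2` costs the
#' smaller of their weighted sizes; joining the same two parts costs the same.
#'
#' @param P1,P2 Character vectors of contig ids (disjoint, non-empty).
#' @param lengths Named numeric vector of contig lengths.
#' @param alpha Length-weight exponent in `[0, 1]`.
#' @return `min(L_alpha(P1), L_alpha(P2))`.
#' @export
split_cost <- function(P1, P2, lengths, alpha) {
  if (length(intersect(P1, P2)))
    stop("split parts must be disjoint", call. = FALSE)
  min(weighted_length(P1, lengths, alpha),
      weighted_length(P2, lengths, alpha))
}

# Core computation on plain named lists of character vectors, repeat-free.
# Returns the four raw components. Used both by the user-facing wrapper and by
# every node of the branch-and-bound.
core_components <- function(A_bins, B_bins, lens, alpha) {
  A_bins <- A_bins[vapply(A_bins, length, integer(1)) > 0L]
  B_bins <- B_bins[vapply(B_bins, length, integer(1)) > 0L]
  mem_a <- bin_membership(A_bins)
  mem_b <- bin_membership(B_bins)
  ua <- names(mem_a); ub <- names(mem_b)
  only_a <- setdiff(ua, ub)
  only_b <- setdiff(ub, ua)
  cost_extra   <- if (length(only_a)) sum(lens[only_a]^alpha) else 0
  cost_missing <- if (length(only_b)) sum(lens[only_b]^alpha) else 0

  shared <- intersect(ua, ub)
  cost_splits <- 0
  cost_joins <- 0
  if (length(shared)) {
    ga <- mem_a[shared]            # bin of each shared contig in A'
    gb <- mem_b[shared]            # ... and in B'
    len_sh <- lens[shared]
    # splits: refine each A' bin by the B' bins; Lemma-1 closed form per bin
    cost_splits <- sum(vapply(split(seq_along(shared), ga), function(idx) {
      w <- vapply(split(len_sh[idx], gb[idx]), function(v) sum(v)^alpha, numeric(1))
      sum(w) - max(w)
    }, numeric(1)))
    cost_joins <- sum(vapply(split(seq_along(shared), gb), function(idx) {
      w <- vapply(split(len_sh[idx], ga[idx]), function(v) sum(v)^alpha, numeric(1))
      sum(w) - max(w)
    }, numeric(1)))
  }
  total <- cost_extra + cost_missing + cost_splits + cost_joins
  list(cost_extra = cost_extra, cost_missing = cost_missing,
       cost_splits = cost_splits, cost_joins = cost_joins, total = total)
}

# Denominator of the normalisation: per-occurrence sum of l(c)^alpha over both
# sets (a contig in several bins counts once per bin).
norm_denominator <- function(A, B, alpha) {
  occ_a <- unlist(A$bins, use.names = FALSE)
  occ_b <- unlist(B$bins, use.names = FALSE)
  da <- if (length(occ_a)) sum(A$lengths[occ_a]^alpha) else 0
  db <- if (length(occ_b)) sum(B$lengths[occ_b]^alpha) else 0
  da + db
}

make_comparison <- function(comp, alpha, denominator, matchings = list(),
                            search = NULL) {
  norm <- function(x) if (denominator > 0) x / denominator else 0
  structure(list(
    alpha = alpha,
    cost_extra = comp$cost_extra, cost_missing = comp$cost_missing,
    cost_splits = comp$cost_splits, cost_joins = comp$cost_joins,
    total = comp$total,
    denominator = denominator,
    normalized_extra = norm(comp$cost_extra),
    normalized_missing = norm(comp$cost_missing),
    normalized_splits = norm(comp$cost_splits),
    normalized_joins = norm(comp$cost_joins),
    normalized_total = norm(comp$total),
    matchings = matchings,
    search = search), class = "bin_comparison")
}

#' @export
print.bin_comparison <- function(x, ...) {
  cat(sprintf("<bin_comparison alpha=%g>\n", x$alpha))
  cat(sprintf("  total D = %.6g   normalized d = %.6g\n", x$total,
              x$normalized_total))
  cat(sprintf("  components (raw | normalized):\n"))
  for (k in c("extra", "missing", "splits", "joins"))
    cat(sprintf("    %-8s %.6g | %.6g\n", k, x[[paste0("cost_", k)]],
                x[[paste0("normalized_", k)]]))
  if (length(x$matchings))
    cat(sprintf("  repeat families resolved: %d\n", length(x$matchings)))
  if (!is.null(x$search))
    cat(sprintf("  search: %d nodes, %d pruned\n", x$search$nodes,
                x$search$pruned))
  invisible(x)
}

#' Dissimilarity between two repeat-free bin sets
#'
#' Computes the split/join dissimilarity for a pair of bin sets in which every
#' contig occurs at most once per side: the weighted total of (1) contigs
#' unique to either side, (2) the cheapest splits turning the left bins into
#' the common refinement and (3) the cheapest joins assembling the right bins
#' from it. The first argument is the "left"/predicted set, the second the
#' "right"/reference set: `cost_extra` counts contigs only in the left set and
#' `cost_missing` contigs only in the right set. Use [bin_dissimilarity()] for
#' inputs that may contain repeated contigs.
#'
#' @param A,B `bin_set` objects, each repeat-free.
#' @param alpha Length-weight exponent in `[0, 1]`.
#' @return A `bin_comparison` object holding the four raw components, the
#'   total, the normalisation denominator and the normalized components
#'   (components sum to the total in both scales; the normalized total lies in
#'   `[0, 1]`).
#' @export
dissimilarity_no_repeats <- function(A, B, alpha = 0.5) {
  check_alpha(alpha)
  lens <- validate_pair(A, B)
  comp <- core_components(A$bins, B$bins, lens, alpha)
  make_comparison(comp, alpha, norm_denominator(A, B, alpha))
}
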