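#' Length-weighted overlap between two bins
#'
#' The overlap between a predicted bin and a reference bin is the cumulative
#' length of the contigs in their intersection.
#'
#' @param P,T Character vectors of contig ids.
#' @param lengths Named numeric vector of contig lengths in bp.
#' @return Overlap in bp (0 for disjoint bins).
#' @export
bin_overlap <- function(P, T, lengths) {
  shared <- intersect(P, T)
  if (!length(shared)) return(0)
  l <- lengths[shared]
  if (anyNA(l)) stop("missing length for contig(s): ",
                     paste(shared[is.na(l)], collapse = ", "), call. = FALSE)
  sum(l)
}

#' Length-weighted precision, recall and F1 of a binning prediction
#'
#' Precision credits each predicted bin with its best overlap against any
#' reference bin, summed and divided by the total predicted length; recall is
#' the mirror image over reference bins. F1 combines them as
#' `2pr / (p + r)` (0 when `p + r = 0`). These are the classic high-level
#' accuracy statistics the split/join dissimilarity refines.
#'
#' @param A Predicted `bin_set`.
#' @param B Reference (ground truth) `bin_set`.
#' @return List with numbers `precision`, `recall`, `f1`, all in `[0, 1]`.
#'   Conventions for degenerate input: an empty prediction set has precision
#'   0 (recall 0 unless the truth is also empty); two empty sets score 1
#'   everywhere (perfect agreement, reported with a message).
#' @export
precision_recall_f1 <- function(A, B) {
  lens <- validate_pair(A, B)
  if (!length(A$bins) && !length(B$bins)) {
    message("both bin sets empty: scores defined as 1")
    return(list(precision = 1, recall = 1, f1 = 1))
  }
  best_against <- function(bins, others) {
    vapply(bins, function(P) {
      if (!length(others)) return(0)
      max(vapply(others, bin_overlap, numeric(1), P = P, lengths = lens))
    }, numeric(1))
  }
  tot_a <- sum(vapply(A$bins, function(b) sum(lens[b]), numeric(1)))
  tot_b <- sum(vapply(B$bins, function(b) sum(lens[b]), numeric(1)))
  p <- if (length(A$bins) && tot_a > 0)
    sum(best_against(A$bins, B$bins)) / tot_a else 0
  r <- if (length(B$bins) && tot_b > 0)
    sum(best_against(B$bins, A$bins)) / tot_b else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1)
}
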