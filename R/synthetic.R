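# sample that never treats a length-1 vector as 1:n
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a random bin set
#'
#' Produces a reproducible bin set with the requested shape: `n_bins` bins,
#' each holding a uniform number of contigs within `contigs_per_bin`, with
#' contig lengths uniform within `length_range`. All contig ids are distinct
#' (no repeats); use [perturb_binset()] with `n_duplicate > 0` to create
#' repeat families. The defaults emulate a bacterial isolate's plasmid
#' complement: a handful of bins of 2–6 contigs with lengths from 500 bp to
#' 50 kb.
#'
#' @param seed Integer seed; the same seed always yields the same set.
#' @param n_bins Number of bins.
#' @param contigs_per_bin Length-2 integer range (inclusive) of contigs per
#'   bin.
#' @param length_range Length-2 range (inclusive, bp) of contig lengths.
#' @param label Label of the resulting set.
#' @param prefix Prefix for generated contig ids.
#' @return A `bin_set`.
#' @export
generate_binset <- function(seed, n_bins = 5, contigs_per_bin = c(2, 6),
                            length_range = c(500, 50000),
                            label = paste0("sim", seed), prefix = "ctg") {
  stopifnot(n_bins >= 1, length(contigs_per_bin) == 2,
            contigs_per_bin[1] >= 1, contigs_per_bin[1] <= contigs_per_bin[2],
            length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2])
  with_seed(seed, {
    sizes <- resample(contigs_per_bin[1]:contigs_per_bin[2], n_bins,
                      replace = TRUE)
    n_ctg <- sum(sizes)
    ids <- sprintf("%s%04d", prefix, seq_len(n_ctg))
    lens <- stats::setNames(
      as.numeric(resample(length_range[1]:length_range[2], n_ctg,
                          replace = TRUE)), ids)
    bins <- split(ids, rep(seq_len(n_bins), sizes))
    names(bins) <- sprintf("bin%02d", seq_len(n_bins))
    bin_set(bins, lens, label = label)
  })
}

#' Apply a controlled set of edits to a bin set
#'
#' Derives a perturbed copy of `bs` by applying, in kind order, `n_missing`
#' contig drops, `n_extra` contig additions, `n_duplicate` duplications of an
#' existing contig into another bin (each creating a repeat), `n_splits` bin
#' splits and `n_joins` bin joins, with seeded random choices within each
#' kind. Comparing the perturbed set (left) against the original (right) with
#' [bin_dissimilarity()] then shows the injected edits in the matching score
#' components: drops appear as missing, additions as extra, splits applied
#' here as joins (the perturbed bins must be re-joined) and vice versa.
#'
#' @param bs Source `bin_set` (unmodified).
#' @param seed Integer seed.
#' @param n_splits,n_joins,n_extra,n_missing,n_duplicate Non-negative edit
#'   counts.
#' @return List with elements `binset` (the perturbed `bin_set`) and `log`
#'   (data frame with columns `kind` and `detail`, one row per applied edit,
#'   in application order; the seed is stored in `attr(log, "seed")`).
#'   Infeasible requests fail before any edit is reported.
#' @export
perturb_binset <- function(bs, seed, n_splits = 0, n_joins = 0, n_extra = 0,
                           n_missing = 0, n_duplicate = 0) {
  stopifnot(n_splits >= 0, n_joins >= 0, n_extra >= 0, n_missing >= 0,
            n_duplicate >= 0)
  with_seed(seed, {
    bins <- bs$bins
    lens <- bs$lengths
    log_kind <- character(0); log_detail <- character(0)
    note <- function(kind, detail) {
      log_kind <<- c(log_kind, kind); log_detail <<- c(log_detail, detail)
    }
    pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)

    # drops (-> "missing" in the perturbed-vs-original comparison)
    for (i in seq_len(n_missing)) {
      ctg <- unique(unlist(bins, use.names = FALSE))
      if (!length(ctg)) stop("cannot drop a contig from an empty bin set",
                             call. = FALSE)
      v <- pick(ctg)
      bins <- lapply(bins, function(b) b[b != v])
      bins <- bins[vapply(bins, length, integer(1)) > 0L]
      note("drop_contig", v)
    }
    # additions (-> "extra")
    for (i in seq_len(n_extra)) {
      if (!length(bins)) stop("cannot add a contig to an empty bin set",
                              call. = FALSE)
      nid <- sprintf("extra%04d", i)
      lens[nid] <- as.numeric(pick(500:50000))
      tgt <- pick(names(bins))
      bins[[tgt]] <- c(bins[[tgt]], nid)
      note("add_contig", paste0(nid, "->", tgt))
    }
    # duplications (create repeat families)
    for (i in seq_len(n_duplicate)) {
      cand <- list()
      for (bn in names(bins)) {
        movable <- setdiff(unique(unlist(bins, use.names = FALSE)), bins[[bn]])
        for (v in movable) cand[[length(cand) + 1L]] <- c(v, bn)
      }
      if (!length(cand))
        stop("no feasible duplication (every contig already in every bin)",
             call. = FALSE)
      ch <- cand[[pick(seq_along(cand))]]
      bins[[ch[2]]] <- c(bins[[ch[2]]], ch[1])
      note("duplicate_into_bin", paste0(ch[1], "->", ch[2]))
    }
    # splits: cut one bin into two non-empty halves
    for (i in seq_len(n_splits)) {
      big <- names(bins)[vapply(bins, length, integer(1)) >= 2L]
      if (!length(big)) stop("no bin with >= 2 contigs left to split",
                             call. = FALSE)
      bn <- pick(big)
      b <- bins[[bn]]
      cut <- pick(seq_len(length(b) - 1L))
      sel <- sample(seq_along(b))
      part1 <- b[sel[seq_len(cut)]]
      part2 <- b[sel[-seq_len(cut)]]
      n1 <- paste0(bn, ".s1"); n2 <- paste0(bn, ".s2")
      bins[[bn]] <- NULL
      bins[[n1]] <- part1
      bins[[n2]] <- part2
      note("split", paste0(bn, "->", n1, "+", n2))
    }
    # joins: merge two bins (skip merges that would duplicate a contig
    # within the merged bin)
    for (i in seq_len(n_joins)) {
      if (length(bins) < 2L) stop("fewer than 2 bins left to join",
                                  call. = FALSE)
      pairs <- utils::combn(names(bins), 2, simplify = FALSE)
      ok <- Filter(function(p) !length(intersect(bins[[p[1]]], bins[[p[2]]])),
                   pairs)
      if (!length(ok)) stop("no pair of bins with disjoint contigs to join",
                            call. = FALSE)
      p <- ok[[pick(seq_along(ok))]]
      nn <- paste0(p[1], "+", p[2])
      merged <- c(bins[[p[1]]], bins[[p[2]]])
      bins[[p[1]]] <- NULL; bins[[p[2]]] <- NULL
      bins[[nn]] <- merged
      note("join", paste0(p[1], "+", p[2], "->", nn))
    }

    used <- unique(unlist(bins, use.names = FALSE))
    out <- bin_set(bins, lens[names(lens) %in% c(used, names(bs$lengths))],
                   label = paste0(bs$label, "_perturbed"))
    log <- data.frame(kind = log_kind, detail = log_detail,
                      stringsAsFactors = FALSE)
    attr(log, "seed") <- seed
    list(binset = out, log = log)
  })
}
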