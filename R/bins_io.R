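#' Construct a bin set
#'
#' A bin set is a named collection of plasmid bins over a shared contig
#' universe. Each bin is an unordered set of contig identifiers; a contig may
#' occur in several bins (a cross-bin repeat) but never twice within one bin.
#' Every contig carries a length in base pairs.
#'
#' @param bins Named list of character vectors; names are bin identifiers,
#'   elements are contig identifiers.
#' @param lengths Named numeric vector mapping contig id to length in bp.
#' @param label Free-text label for the set (e.g. a tool name or
#'   `"ground_truth"`).
#' @return An object of class `bin_set` with elements `label`, `bins` and
#'   `lengths`.
#' @examples
#' bs <- bin_set(list(B1 = c("a", "b"), B2 = "a"),
#'               c(a = 100, b = 50), label = "toy")
#' copy_number(bs)
#' @export
bin_set <- function(bins, lengths, label = "binset") {
  bins <- lapply(bins, function(b) unique(as.character(b)))
  lengths <- stats::setNames(as.numeric(lengths), names(lengths))
  bs <- structure(list(label = as.character(label)[1],
                       bins = bins, lengths = lengths),
                  class = "bin_set")
  validate_binset(bs)
  bs
}

#' @export
print.bin_set <- function(x, ...) {
  n_occ <- sum(lengths(x$bins))
  cat(sprintf("<bin_set '%s': %d bins, %d contigs (%d occurrences), %s bp>\n",
              x$label, length(x$bins),
              length(unique(unlist(x$bins, use.names = FALSE))),
              n_occ,
              format(sum(x$lengths[unique(unlist(x$bins, use.names = FALSE))]),
                     big.mark = ",")))
  invisible(x)
}

validate_binset <- function(bs) {
  b <- bs$bins
  if (length(b)) {
    if (is.null(names(b)) || anyNA(names(b)) || any(names(b) == ""))
      stop("all bins must be named", call. = FALSE)
    if (anyDuplicated(names(b)))
      stop("bin ids must be unique within a bin set", call. = FALSE)
    if (any(lengths(b) == 0L))
      stop("bins must be non-empty", call. = FALSE)
    dup <- vapply(b, anyDuplicated, integer(1))
    if (any(dup > 0L))
      stop("contig repeated within bin(s): ",
           paste(names(b)[dup > 0L], collapse = ", "),
           " (within-bin repeats are not modelled)", call. = FALSE)
  }
  ids <- unique(unlist(b, use.names = FALSE))
  # '#' is reserved for the fresh ids of resolved repeat copies
  pat <- if (isTRUE(bs$resolved)) "[\t\n]" else "[\t\n#]"
  bad_id <- grepl(pat, ids) | ids == ""
  if (any(bad_id))
    stop("invalid contig id(s) (empty, whitespace or reserved '#'): ",
         paste(utils::head(ids[bad_id], 5), collapse = ", "), call. = FALSE)
  miss <- setdiff(ids, names(bs$lengths))
  if (length(miss))
    stop("no length for contig(s): ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  if (length(bs$lengths) && (anyNA(bs$lengths) || any(bs$lengths < 1) ||
                             any(bs$lengths != floor(bs$lengths))))
    stop("contig lengths must be positive integers (bp)", call. = FALSE)
  invisible(bs)
}

#' Copy number of every contig in a bin set
#'
#' The copy number of a contig is the number of bins that contain it.
#'
#' @param bs A `bin_set`.
#' @return Named integer vector, one entry per distinct contig.
#' @export
copy_number <- function(bs) {
  occ <- unlist(bs$bins, use.names = FALSE)
  if (!length(occ)) return(stats::setNames(integer(0), character(0)))
  tab <- table(occ)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a bin set from a tab-separated file
#'
#' The expected dialect is a headered TSV with columns `plasmid`, `contig` and
#' `contig_len`; lines starting with `#` are ignored. Each row assigns one
#' contig occurrence to one bin.
#'
#' @param path Path to the TSV file.
#' @param label Label for the resulting set; defaults to the file name.
#' @param dedupe If `TRUE`, rows repeating the same (bin, contig) pair collapse
#'   to a single occurrence with a warning; if `FALSE` (default) they are an
#'   error, since within-bin repeats are outside the model.
#' @return A `bin_set`.
#' @seealso [write_bins()], [filter_min_length()]
#' @export
read_bins <- function(path, label = basename(path), dedupe = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("plasmid", "contig", "contig_len")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("bin table ", path, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  len <- suppressWarnings(as.numeric(df$contig_len))
  if (anyNA(len) || any(len < 1) || any(len != floor(len)))
    stop("contig_len must be a positive integer in every row of ", path,
         call. = FALSE)
  key <- paste(df$plasmid, df$contig, sep = "\r")
  if (anyDuplicated(key)) {
    if (!dedupe)
      stop("duplicate (plasmid, contig) row(s) in ", path,
           "; within-bin repeats are not modelled (set dedupe = TRUE to collapse)",
           call. = FALSE)
    warning("collapsing ", sum(duplicated(key)), " duplicate (plasmid, contig) row(s) in ",
            path, call. = FALSE)
    keep <- !duplicated(key)
    df <- df[keep, , drop = FALSE]
    len <- len[keep]
  }
  # one length per contig id across the whole file
  by_ctg <- tapply(len, df$contig, function(v) length(unique(v)))
  if (any(by_ctg > 1))
    stop("contig(s) with conflicting lengths in ", path, ": ",
         paste(utils::head(names(by_ctg)[by_ctg > 1], 5), collapse = ", "),
         call. = FALSE)
  lens <- tapply(len, df$contig, `[`, 1)
  bins <- split(df$contig, df$plasmid)
  bin_set(bins, stats::setNames(as.numeric(lens), names(lens)), label = label)
}

#' Write a bin set to the TSV dialect read by [read_bins()]
#'
#' @param bs A `bin_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bs, path) {
  rows <- do.call(rbind, lapply(names(bs$bins), function(p) {
    ctg <- sort(bs$bins[[p]])
    data.frame(plasmid = p, contig = ctg,
               contig_len = as.integer(bs$lengths[ctg]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(plasmid = character(0), contig = character(0),
                       contig_len = integer(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Contig lengths from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header; each
#' length is the number of sequence characters.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named numeric vector of lengths in bp.
#' @export
lengths_from_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  w <- Biostrings::width(seqs)
  if (any(w == 0L))
    stop("empty sequence for record(s): ", paste(ids[w == 0L], collapse = ", "),
         call. = FALSE)
  stats::setNames(as.numeric(w), ids)
}

#' Drop contigs shorter than a minimum length
#'
#' Removes every contig occurrence whose length is below `min_len` from every
#' bin; bins emptied by the filter are dropped (an empty bin has no defined
#' split/join cost). The default `min_len = 0` keeps everything. Filtering
#' before comparison shrinks the matching search space on assemblies with many
#' short contigs.
#'
#' @param bs A `bin_set`.
#' @param min_len Minimum contig length in bp to retain (`>= 0`).
#' @return A new, filtered `bin_set`; the input is unmodified.
#' @export
filter_min_length <- function(bs, min_len = 0) {
  stopifnot(is.numeric(min_len), length(min_len) == 1L, min_len >= 0)
  if (min_len == 0) return(bs)
  keep_id <- names(bs$lengths)[bs$lengths >= min_len]
  bins <- lapply(bs$bins, function(b) b[b %in% keep_id])
  bins <- bins[lengths(bins) > 0L]
  structure(list(label = bs$label, bins = bins,
                 lengths = bs$lengths[names(bs$lengths) %in% keep_id]),
            class = "bin_set")
}

#' Validate a pair of bin sets for comparison
#'
#' Checks that any contig id present in both sets has the same length on both
#' sides and returns the union length mapping.
#'
#' @param A,B `bin_set` objects.
#' @return Named numeric vector: the merged contig-length mapping.
#' @export
validate_pair <- function(A, B) {
  validate_binset(A); validate_binset(B)
  shared <- intersect(names(A$lengths), names(B$lengths))
  bad <- shared[A$lengths[shared] != B$lengths[shared]]
  if (length(bad))
    stop("contig(s) with conflicting lengths between '", A$label, "' and '",
         B$label, "': ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  c(A$lengths, B$lengths[setdiff(names(B$lengths), names(A$lengths))])
}
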