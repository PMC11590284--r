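#' Read hybrid-assembly contig metadata
#'
#' Expects a headered TSV with columns `id`, `length` and `circular`
#' (`true`/`false`, case-insensitive); `#` comment lines are ignored.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `id` (character), `length` (numeric bp)
#'   and `circular` (logical).
#' @export
read_hybrid_meta <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("id", "length", "circular")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("hybrid metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  len <- suppressWarnings(as.numeric(df$length))
  if (anyNA(len) || any(len < 1))
    stop("hybrid contig lengths must be positive", call. = FALSE)
  circ <- tolower(df$circular) %in% c("true", "t", "yes", "1")
  data.frame(id = df$id, length = len, circular = circ,
             stringsAsFactors = FALSE)
}

#' Classify hybrid contigs as chromosome, plasmid or ambiguous
#'
#' Circular contigs longer than 500,000 bp are chromosomes; circular contigs
#' shorter than 500,000 bp are plasmids; everything else (all non-circular
#' contigs) is ambiguous. A circular contig of exactly 500,000 bp is neither
#' "longer" nor "shorter"; it is labelled plasmid and reported as a boundary
#' case.
#'
#' @param hybrid Data frame as returned by [read_hybrid_meta()] (columns
#'   `id`, `length`, `circular`).
#' @param threshold Length threshold in bp separating plasmids from
#'   chromosomes among circular contigs.
#' @return The input data frame with an added factor column `label` with
#'   levels `chromosome`, `plasmid`, `ambiguous`.
#' @export
classify_hybrid_contigs <- function(hybrid, threshold = 500000) {
  stopifnot(all(c("id", "length", "circular") %in% names(hybrid)))
  lab <- ifelse(!hybrid$circular, "ambiguous",
                ifelse(hybrid$length > threshold, "chromosome", "plasmid"))
  at_bound <- hybrid$circular & hybrid$length == threshold
  if (any(at_bound))
    message("circular contig(s) exactly at the ", threshold,
            " bp threshold labelled plasmid: ",
            paste(hybrid$id[at_bound], collapse = ", "))
  hybrid$label <- factor(lab, levels = c("chromosome", "plasmid", "ambiguous"))
  hybrid
}

#' Read BLAST-style tabular alignment hits
#'
#' Parses the standard 12-column tabular alignment format (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore; no header) and attaches the query length of each hit from a
#' separate mapping (e.g. from [lengths_from_fasta()]).
#'
#' @param path Path to the tabular hits file.
#' @param query_lengths Named numeric vector mapping query (short-read contig)
#'   id to its length in bp.
#' @return Data frame of hits with columns `qseqid`, `sseqid`, `pident`,
#'   `length`, `qstart`, `qend`, `qlen`.
#' @export
read_blast_hits <- function(path, query_lengths) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 12)
    stop("expected 12 tab-separated columns (BLAST outfmt 6), got ", ncol(df),
         call. = FALSE)
  names(df)[1:12] <- cols
  df <- df[, cols[c(1:4, 7:8)]]
  df$qseqid <- as.character(df$qseqid)
  df$sseqid <- as.character(df$sseqid)
  ql <- query_lengths[df$qseqid]
  if (anyNA(ql))
    stop("no query length for contig(s): ",
         paste(unique(df$qseqid[is.na(ql)]), collapse = ", "), call. = FALSE)
  df$qlen <- as.numeric(ql)
  df
}

#' Filter alignment hits on identity and query coverage
#'
#' Keeps hits with percent identity of at least `min_identity` and query
#' coverage (aligned length over query length, in percent) of at least
#' `min_coverage`; hits below either threshold — "identity below 95%" or
#' "covering less than 80% of the short-read contig" under the defaults — are
#' discarded, so hits exactly at a threshold survive. Coverage is per hit by
#' default; with `union_coverage = TRUE` the query intervals of all hits of a
#' (query, subject) pair are merged first and the pair is kept or dropped as
#' a whole (for mappers that fragment alignments).
#'
#' @param hits Data frame as from [read_blast_hits()] (needs `qseqid`,
#'   `sseqid`, `pident`, `length`, `qlen`; plus `qstart`, `qend` when
#'   `union_coverage = TRUE`).
#' @param min_identity Minimum percent identity to keep.
#' @param min_coverage Minimum query coverage percentage to keep.
#' @param union_coverage Merge query intervals per (query, subject) pair
#'   before the coverage test.
#' @return The surviving rows of `hits`.
#' @export
filter_hits <- function(hits, min_identity = 95, min_coverage = 80,
                        union_coverage = FALSE) {
  keep_id <- hits$pident >= min_identity
  hits <- hits[keep_id, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  if (!union_coverage) {
    cov <- 100 * hits$length / hits$qlen
    return(hits[cov >= min_coverage, , drop = FALSE])
  }
  stopifnot(all(c("qstart", "qend") %in% names(hits)))
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  covered <- vapply(split(seq_len(nrow(hits)), key), function(idx) {
    s <- pmin(hits$qstart[idx], hits$qend[idx])
    e <- pmax(hits$qstart[idx], hits$qend[idx])
    o <- order(s)
    s <- s[o]; e <- e[o]
    tot <- 0; cur_s <- s[1]; cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] > cur_e + 1) { tot <- tot + cur_e - cur_s + 1; cur_s <- s[i]; cur_e <- e[i] }
      else cur_e <- max(cur_e, e[i])
    }
    tot <- tot + cur_e - cur_s + 1
    100 * tot / hits$qlen[idx][1]
  }, numeric(1))
  ok_pairs <- names(covered)[covered >= min_coverage]
  hits[key %in% ok_pairs, , drop = FALSE]
}

#' Build ground-truth plasmid bins from filtered hits
#'
#' One bin per hybrid contig labelled `plasmid`, containing every short-read
#' query contig with at least one surviving hit to it. A query hitting two
#' plasmids joins both bins (creating a cross-bin repeat); plasmids with no
#' surviving hit yield no bin; hits to chromosome- or ambiguous-labelled
#' contigs are ignored. Multiple hits of one query to one plasmid collapse to
#' a single membership.
#'
#' @param hits Filtered hits (see [filter_hits()]).
#' @param hybrid Classified hybrid metadata (see [classify_hybrid_contigs()]).
#' @param label Label for the resulting `bin_set`.
#' @return A `bin_set` whose lengths are the query contig lengths.
#' @export
build_truth_bins <- function(hits, hybrid, label = "ground_truth") {
  if (!"label" %in% names(hybrid))
    hybrid <- classify_hybrid_contigs(hybrid)
  plasmids <- hybrid$id[hybrid$label == "plasmid"]
  hits <- hits[hits$sseqid %in% plasmids, , drop = FALSE]
  if (!nrow(hits))
    return(bin_set(stats::setNames(list(), character(0)),
                   stats::setNames(numeric(0), character(0)), label = label))
  bins <- lapply(split(hits$qseqid, hits$sseqid), unique)
  bins <- bins[vapply(bins, length, integer(1)) > 0L]
  qlen <- tapply(hits$qlen, hits$qseqid, `[`, 1)
  bin_set(bins, stats::setNames(as.numeric(qlen), names(qlen)), label = label)
}
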