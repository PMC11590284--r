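#' Compare two bin files and write a machine-readable report
#'
#' Reads the two bin TSV files, computes the repeat-aware dissimilarity and
#' the precision/recall/F1 baseline, and writes a JSON report containing the
#' raw and normalized totals, all four components, the optimal matchings, the
#' parameters and the input file digests.
#'
#' @param left,right Paths to bin TSV files (left = predicted,
#'   right = reference).
#' @param alpha Length-weight exponent in `[0, 1]`.
#' @param min_len Minimum contig length in bp.
#' @param dedupe Collapse duplicated (bin, contig) rows on input.
#' @param out Optional path; when given, the report is written there as JSON.
#' @return The report, invisibly: a list with elements `parameters`,
#'   `inputs`, `dissimilarity`, `scores` and `matchings`.
#' @export
compare_report <- function(left, right, alpha = 0.5, min_len = 0,
                           dedupe = FALSE, out = NULL) {
  check_alpha(alpha)
  A <- read_bins(left, label = basename(left), dedupe = dedupe)
  B <- read_bins(right, label = basename(right), dedupe = dedupe)
  res <- bin_dissimilarity(A, B, alpha = alpha, min_len = min_len)
  sc <- precision_recall_f1(filter_min_length(A, min_len),
                            filter_min_length(B, min_len))
  rep <- list(
    parameters = list(alpha = alpha, min_len = min_len),
    inputs = list(left = basename(left), right = basename(right),
                  left_md5 = unname(tools::md5sum(left)),
                  right_md5 = unname(tools::md5sum(right))),
    dissimilarity = list(
      total = res$total, normalized_total = res$normalized_total,
      denominator = res$denominator,
      components = list(extra = res$cost_extra, missing = res$cost_missing,
                        splits = res$cost_splits, joins = res$cost_joins),
      normalized_components = list(
        extra = res$normalized_extra, missing = res$normalized_missing,
        splits = res$normalized_splits, joins = res$normalized_joins)),
    scores = sc,
    matchings = lapply(res$matchings, function(m)
      list(a_bin = m$a_bin, b_bin = m$b_bin)))
  if (!is.null(out))
    jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(rep)
}

#' Batch comparison over a manifest of sample pairs
#'
#' The manifest is a headered TSV with columns `sample`, `left` and `right`
#' (paths to bin TSV files). Every pair is compared with
#' [bin_dissimilarity()]; when `right_is_truth` the F1 baseline is computed
#' as well. Rows that fail to read or validate are excluded with a warning.
#' The summary reports mean and sample (n-1) standard deviation per metric
#' column.
#'
#' @param manifest Path to the manifest TSV.
#' @param alpha Length-weight exponent.
#' @param min_len Minimum contig length in bp.
#' @param right_is_truth Treat the right side as ground truth and emit
#'   precision/recall/F1 columns.
#' @param out Optional path prefix; writes `<out>_rows.tsv`,
#'   `<out>_summary.tsv` and `<out>.json`.
#' @return List with data frames `rows` (one per surviving sample: the four
#'   normalized components, `d`, and the score triple) and `summary` (mean
#'   and sd per column; sd is 0 with an attached `n = 1` note for a single
#'   row).
#' @export
batch_compare <- function(manifest, alpha = 0.5, min_len = 0,
                          right_is_truth = TRUE, out = NULL) {
  man <- utils::read.delim(manifest, header = TRUE, sep = "\t",
                           comment.char = "#", colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("sample", "left", "right")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(man))) {
    r <- tryCatch({
      A <- read_bins(man$left[i], label = man$left[i])
      B <- read_bins(man$right[i], label = man$right[i])
      res <- bin_dissimilarity(A, B, alpha = alpha, min_len = min_len)
      row <- data.frame(
        sample = man$sample[i], left = man$left[i], right = man$right[i],
        splits = res$normalized_splits, joins = res$normalized_joins,
        extra = res$normalized_extra, missing = res$normalized_missing,
        d = res$normalized_total, stringsAsFactors = FALSE)
      if (right_is_truth) {
        sc <- precision_recall_f1(filter_min_length(A, min_len),
                                  filter_min_length(B, min_len))
        row$precision <- sc$precision; row$recall <- sc$recall
        row$f1 <- sc$f1
      }
      row
    }, error = function(e) {
      warning("manifest row '", man$sample[i], "' excluded: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(r)) rows[[length(rows) + 1L]] <- r
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(0))
  num_cols <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
                      character(0))
  summary <- data.frame(
    metric = num_cols,
    mean = vapply(num_cols, function(cn) mean(rows[[cn]]), numeric(1)),
    sd = vapply(num_cols, function(cn)
      if (nrow(rows) > 1L) stats::sd(rows[[cn]]) else 0, numeric(1)),
    n = nrow(rows), row.names = NULL, stringsAsFactors = FALSE)
  if (nrow(rows) == 1L) attr(summary, "note") <- "sd undefined for n = 1, reported as 0"
  if (!is.null(out)) {
    utils::write.table(rows, paste0(out, "_rows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summary, paste0(out, "_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(alpha = alpha, min_len = min_len, rows = rows,
                              summary = summary),
                         paste0(out, ".json"), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  list(rows = rows, summary = summary)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper used to correlate the F1 score with the normalized
#' dissimilarity across samples (on benchmark data the two are strongly
#' negatively correlated).
#'
#' @param x,y Numeric vectors of equal length (at least 2), each with
#'   non-zero variance.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}
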