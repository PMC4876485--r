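#' Color presence of contigs
#'
#' A contig is present in a color when its average coverage there is strictly
#' greater than `eps` (default 0, i.e. any non-zero colored average coverage).
#'
#' @param contigs a [contig_set()].
#' @param eps presence threshold.
#' @return logical matrix, one row per contig, one column per color.
#' @export
color_presence <- function(contigs, eps = 0) {
  stopifnot(inherits(contigs, "contig_set"))
  contigs$coverage > eps
}

pairwise_comparison <- function(i, j, total_i, total_j, shared) {
  exclusive_i <- total_i - shared
  exclusive_j <- total_j - shared
  structure(list(i = i, j = j, total_i = total_i, total_j = total_j,
                 shared = shared,
                 exclusive_i = exclusive_i, exclusive_j = exclusive_j,
                 ratio_i_wrt_j = if (total_i > 0) exclusive_i / total_i else 0,
                 ratio_j_wrt_i = if (total_j > 0) exclusive_j / total_j else 0),
            class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf(paste0("<pairwise_comparison> colors %s vs %s\n",
                     "  total:     %s / %s bp\n  shared:    %s bp\n",
                     "  exclusive: %s / %s bp\n  ratio:     %.4f / %.4f\n"),
              x$i, x$j, format(x$total_i, big.mark = ","),
              format(x$total_j, big.mark = ","),
              format(x$shared, big.mark = ","),
              format(x$exclusive_i, big.mark = ","),
              format(x$exclusive_j, big.mark = ","),
              x$ratio_i_wrt_j, x$ratio_j_wrt_i))
  invisible(x)
}

#' Shared/exclusive decomposition of two colors
#'
#' Contigs present in both colors are shared; contigs present in color `i`
#' but not `j` are exclusive of `i` with respect to `j`. The exclusivity
#' ratio of `i` w.r.t. `j` is exclusive/total assembly size of `i`. Because
#' contigs come from a single union graph, any sequence of length >= k shared
#' between colors already lies in common contigs, so the decomposition needs
#' no alignment. Ratios are kept at full precision; the report layer rounds.
#'
#' @param contigs a [contig_set()].
#' @param i,j 0-based color indices (`i == j` is allowed and gives ratio 0
#'   with `shared == total_i`).
#' @param eps presence threshold, see [color_presence()].
#' @param min_len contigs shorter than `max(k, min_len)` are ignored.
#' @return object of class `pairwise_comparison` with fields `total_i`,
#'   `total_j`, `shared`, `exclusive_i`, `exclusive_j`, `ratio_i_wrt_j`,
#'   `ratio_j_wrt_i`.
#' @export
compare_pair <- function(contigs, i, j, eps = 0, min_len = 1L) {
  stopifnot(inherits(contigs, "contig_set"))
  m <- contigs$m
  if (i < 0 || i >= m || j < 0 || j >= m)
    stop_usage("color indices must be in 0..", m - 1L)
  lmin <- max(min_len, if (!is.na(contigs$k)) contigs$k else 1L)
  use <- contigs$length >= lmin
  pres <- color_presence(contigs, eps)[use, , drop = FALSE]
  len <- contigs$length[use]
  pi <- pres[, i + 1L]
  pj <- pres[, j + 1L]
  if (i == j) {
    total <- sum(len[pi])
    return(pairwise_comparison(i, j, total, total, total))
  }
  pairwise_comparison(i, j,
                      total_i = sum(len[pi]), total_j = sum(len[pj]),
                      shared = sum(len[pi & pj]))
}

#' Exclusivity arithmetic from printed assembly totals
#'
#' Applies the same decomposition as [compare_pair()] when only the total and
#' shared assembly sizes are known (e.g. from a published pairwise table):
#' exclusive = total - shared and ratio = exclusive/total.
#'
#' @param total_i,total_j total assembly sizes (bp) of the two colors
#'   (`total_j` may be `NA` when only one direction is of interest).
#' @param shared shared assembly size (bp).
#' @param i,j optional color indices for labeling.
#' @return a `pairwise_comparison`.
#' @examples
#' exclusivity_from_totals(5228480, NA, 5210548)$ratio_i_wrt_j
#' @export
exclusivity_from_totals <- function(total_i, total_j, shared, i = 0L, j = 1L) {
  if (shared < 0 || total_i < shared ||
      (!is.na(total_j) && total_j < shared))
    stop_usage("need shared <= total for both colors")
  pairwise_comparison(i, j, total_i,
                      if (is.na(total_j)) shared else total_j, shared)
}

#' Exclusivity-ratio matrix over all colors
#'
#' Entry (i, j) is the exclusivity ratio of color i with respect to color j;
#' the diagonal is exactly 0. A color with zero total assembly size gets a
#' zero row (flagged with a warning).
#'
#' @inheritParams compare_pair
#' @param labels optional row/column labels (defaults to `color0..`).
#' @param percent if `TRUE`, entries are percentages (0..100).
#' @return numeric `m x m` matrix with dimnames.
#' @export
exclusivity_matrix <- function(contigs, eps = 0, min_len = 1L, labels = NULL,
                               percent = FALSE) {
  stopifnot(inherits(contigs, "contig_set"))
  m <- contigs$m
  labels <- labels %||% paste0("color", seq_len(m) - 1L)
  if (length(labels) != m) stop_usage("need one label per color")
  mat <- matrix(0, m, m, dimnames = list(labels, labels))
  empty <- logical(m)
  for (i in seq_len(m) - 1L) {
    for (j in seq_len(m) - 1L) {
      if (i == j) next
      pc <- compare_pair(contigs, i, j, eps = eps, min_len = min_len)
      mat[i + 1L, j + 1L] <- pc$ratio_i_wrt_j
      if (pc$total_i == 0) empty[i + 1L] <- TRUE
    }
  }
  if (any(empty))
    warning("color(s) with zero total assembly size: ",
            paste(labels[empty], collapse = ", "), "; their rows are 0",
            call. = FALSE)
  if (percent) mat <- 100 * mat
  mat
}

#' Write the pairwise comparison table as TSV
#'
#' One row per ordered pair (i < j) with totals, shared/exclusive bp and both
#' ratios (4 decimals).
#'
#' @inheritParams exclusivity_matrix
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pairwise_tsv <- function(contigs, path, eps = 0, min_len = 1L) {
  stopifnot(inherits(contigs, "contig_set"))
  m <- contigs$m
  rows <- list()
  for (i in seq_len(m) - 1L) {
    for (j in seq_len(m) - 1L) {
      if (j <= i) next
      pc <- compare_pair(contigs, i, j, eps = eps, min_len = min_len)
      rows[[length(rows) + 1L]] <- sprintf(
        "%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.4f\t%.4f", i, j,
        pc$total_i, pc$total_j, pc$shared, pc$exclusive_i, pc$exclusive_j,
        pc$ratio_i_wrt_j, pc$ratio_j_wrt_i)
    }
  }
  writeLines(c(paste("i", "j", "total_i", "total_j", "shared", "exclusive_i",
                     "exclusive_j", "ratio_ij", "ratio_ji", sep = "\t"),
               unlist(rows)), path)
  invisible(path)
}
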