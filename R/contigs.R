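#' Construct a contig set
#'
#' A contig is a DNA sequence (emitted in canonical orientation, i.e. the
#' lexicographic minimum of the sequence and its reverse complement) plus a
#' per-color average coverage vector: the unweighted mean of the constituent
#' canonical k-mers' multiplicities in that color. Contigs are stored sorted
#' by (length descending, sequence ascending), which makes every downstream
#' output deterministic.
#'
#' @param sequence character vector of contig sequences.
#' @param coverage numeric matrix with one row per contig and one column per
#'   color.
#' @param k k-mer size the contigs were built with (`NA` if unknown, e.g.
#'   contigs re-read from disk without context).
#' @param paths optional list of per-contig k-mer index paths (internal).
#' @return list of class `contig_set` with elements `sequence`, `coverage`,
#'   `length`, `kmer_count`, `k`, `m`.
#' @export
contig_set <- function(sequence, coverage, k = NA_integer_, paths = NULL) {
  sequence <- as.character(sequence)
  if (is.null(dim(coverage))) coverage <- matrix(coverage, nrow = length(sequence))
  if (nrow(coverage) != length(sequence))
    stop_usage("coverage must have one row per contig")
  if (any(coverage < 0)) stop_usage("coverages must be non-negative")
  ord <- order_c(-nchar(sequence), sequence)
  sequence <- sequence[ord]
  coverage <- coverage[ord, , drop = FALSE]
  out <- structure(list(sequence = sequence, coverage = coverage,
                        length = nchar(sequence),
                        kmer_count = if (is.na(k)) rep(NA_integer_, length(sequence))
                                     else nchar(sequence) - as.integer(k) + 1L,
                        k = as.integer(k), m = ncol(coverage)),
                   class = "contig_set")
  if (!is.null(paths)) attr(out, "paths") <- paths[ord]
  out
}

#' @export
length.contig_set <- function(x) length(x$sequence)

#' @export
print.contig_set <- function(x, ...) {
  cat("<contig_set> ", length(x$sequence), " contigs, ", x$m, " color(s), ",
      sum(x$length), " bp total", if (!is.na(x$k)) paste0(", k=", x$k), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.contig_set <- function(x, ...) {
  df <- data.frame(sequence = x$sequence, length = x$length,
                   stringsAsFactors = FALSE)
  cov <- x$coverage
  colnames(cov) <- paste0("cov_", seq_len(ncol(cov)) - 1L)
  cbind(df, as.data.frame(cov))
}

# Subset a contig_set by a logical or integer index.
subset_contigs <- function(x, idx) {
  contig_set(x$sequence[idx], x$coverage[idx, , drop = FALSE], k = x$k)
}
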