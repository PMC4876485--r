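#' Assembly length statistics
#'
#' Contigs are filtered to `length >= min_len` first, then N50 (and NG50 when
#' a genome size is supplied) are computed: N50 is the largest contig length
#' L such that contigs of length >= L sum to at least half the filtered
#' assembly total; NG50 uses half the genome size instead and is `NA` when
#' the cumulative total never reaches it.
#'
#' @param contigs a [contig_set()] or a numeric vector of contig lengths.
#' @param min_len minimum contig length included (bp).
#' @param genome_size reference genome size for NG50 (optional).
#' @return list of class `assembly_stats`: `num_contigs`, `total_bp`,
#'   `max_len`, `N50`, `NG50`, `empty`.
#' @examples
#' length_stats(c(5, 4, 3, 2, 1), min_len = 1)$N50  # 4
#' @export
length_stats <- function(contigs, min_len = 1L, genome_size = NULL) {
  len <- if (inherits(contigs, "contig_set")) contigs$length else as.numeric(contigs)
  len <- len[len >= min_len]
  if (length(len) == 0L)
    return(structure(list(num_contigs = 0L, total_bp = 0, max_len = 0,
                          N50 = 0, NG50 = NA_real_, empty = TRUE),
                     class = "assembly_stats"))
  len <- sort(len, decreasing = TRUE)
  total <- sum(len)
  cum <- cumsum(len)
  n50 <- len[which(cum >= total / 2)[1L]]
  ng50 <- NA_real_
  if (!is.null(genome_size)) {
    hit <- which(cum >= genome_size / 2)
    if (length(hit)) ng50 <- len[hit[1L]]
  }
  structure(list(num_contigs = length(len), total_bp = total,
                 max_len = len[1L], N50 = n50, NG50 = ng50, empty = FALSE),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("<assembly_stats> contigs=", x$num_contigs,
      " total=", format(x$total_bp, big.mark = ","),
      " max=", format(x$max_len, big.mark = ","),
      " N50=", format(x$N50, big.mark = ","),
      if (!is.na(x$NG50)) paste0(" NG50=", format(x$NG50, big.mark = ",")),
      "\n", sep = "")
  invisible(x)
}

#' k-mer based reference evaluation of an assembly
#'
#' A lightweight surrogate for alignment-based evaluators: the reference's
#' canonical k-mers are compared with the assembly's. A reference position is
#' covered when at least one k-window containing it has its canonical k-mer
#' present in the contigs; missing bases are the uncovered positions. The
#' metric is monotone in true assembly completeness but makes no claim of
#' exactness against alignment pipelines.
#'
#' @param contigs a [contig_set()] or character vector of contig sequences.
#' @param reference a single reference sequence (A/C/G/T; other bytes are
#'   masked out of the window set).
#' @param k k-mer size (must not exceed the reference length).
#' @return list of class `reference_eval`: `reference_len`, `ref_kmers`,
#'   `missing_kmers`, `missing_fraction`, `covered_positions`,
#'   `missing_bases`.
#' @export
reference_kmer_eval <- function(contigs, reference, k) {
  seqs <- if (inherits(contigs, "contig_set")) contigs$sequence else as.character(contigs)
  reference <- toupper(reference)
  if (length(reference) != 1L) stop_usage("reference must be one sequence")
  n <- nchar(reference)
  if (k > n) stop_usage("k (", k, ") exceeds the reference length (", n, ")")
  wins <- cpp_kmer_windows(reference, as.integer(k))
  ref_kmers <- unique(wins[!is.na(wins)])
  asm_kmers <- if (length(seqs)) cpp_count_kmers(toupper(seqs), as.integer(k))$kmers
               else character()
  missing <- length(setdiff(ref_kmers, asm_kmers))
  present <- !is.na(wins) & (wins %in% asm_kmers)
  if (any(present)) {
    st <- which(present)
    delta <- numeric(n + 1L)
    delta[st] <- delta[st] + 1
    delta[st + k] <- delta[st + k] - 1
    covered_pos <- sum(cumsum(delta)[seq_len(n)] > 0)
  } else covered_pos <- 0L
  structure(list(reference_len = n, ref_kmers = length(ref_kmers),
                 missing_kmers = missing,
                 missing_fraction = if (length(ref_kmers)) missing / length(ref_kmers) else 0,
                 covered_positions = covered_pos,
                 missing_bases = n - covered_pos),
            class = "reference_eval")
}

#' @export
print.reference_eval <- function(x, ...) {
  cat(sprintf(paste0("<reference_eval> ref=%s bp, missing k-mers=%s (%.4f),",
                     " missing bases=%s (%.4f)\n"),
              format(x$reference_len, big.mark = ","),
              format(x$missing_kmers, big.mark = ","), x$missing_fraction,
              format(x$missing_bases, big.mark = ","),
              x$missing_bases / x$reference_len))
  invisible(x)
}

#' Blackout regions of a coverage track
#'
#' Maximal runs of positions whose depth is at or below `threshold`, as
#' 0-based half-open intervals, plus the fraction of the track they cover.
#'
#' @param track numeric vector of per-position depths (0-based positions).
#' @param threshold depth at or below which a position counts as blacked out.
#' @return list with `intervals` (two-column matrix `start`, `end`; 0-based,
#'   half-open, disjoint, sorted, maximal) and `fraction`.
#' @examples
#' blackout_regions(c(0, 0, 3, 4, 0))
#' @export
blackout_regions <- function(track, threshold = 0) {
  n <- length(track)
  if (n == 0L)
    return(list(intervals = matrix(integer(), 0L, 2L,
                                   dimnames = list(NULL, c("start", "end"))),
                fraction = 0))
  r <- rle(track <= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  sel <- r$values
  intervals <- cbind(start = starts[sel], end = ends[sel])
  list(intervals = intervals, fraction = sum(intervals[, 2] - intervals[, 1]) / n)
}

#' Write intervals as BED
#'
#' @param intervals two-column matrix of 0-based half-open intervals.
#' @param path output path.
#' @param chrom chromosome/sequence name for column 1.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, chrom = "genome") {
  lines <- if (nrow(intervals)) paste(chrom, intervals[, 1], intervals[, 2],
                                      sep = "\t") else character()
  writeLines(lines, path)
  invisible(path)
}
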