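#' Assembly configuration
#'
#' Bundles the tunable parameters of the coassembler. Defaults follow the
#' standard single-cell run configuration: `k = 25`, coverage cutoff 100 and a
#' 100 bp minimum contig length.
#'
#' @param k odd k-mer size, between 3 and 31 (2-bit packing bound).
#' @param coverage_cutoff final trimming threshold on the max-over-colors
#'   average unitig coverage (>= 0). `0` disables trimming.
#' @param min_contig_len minimum contig length kept in the output (bp).
#' @param presence_epsilon a contig is "present" in a color when its average
#'   coverage there is strictly greater than this.
#' @param num_colors number of colors `m` (usually taken from the manifest).
#' @param tip_len_factor dead-end unitigs shorter than `tip_len_factor * k`
#'   are candidates for tip clipping.
#' @param trim_steps number of progressive trimming thresholds rising linearly
#'   from `coverage_cutoff / trim_steps` to `coverage_cutoff`.
#' @param seed optional integer seed echoed into run reports (the assembler
#'   itself is deterministic and never draws random numbers).
#' @return list of class `assembly_config`.
#' @export
assembly_config <- function(k = 25L, coverage_cutoff = 100, min_contig_len = 100L,
                            presence_epsilon = 0, num_colors = 1L,
                            tip_len_factor = 2, trim_steps = 10L, seed = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k > 31L || k %% 2L == 0L)
    stop_usage("k must be an odd integer between 3 and 31 (got ", k, ")")
  if (coverage_cutoff < 0) stop_usage("coverage_cutoff must be >= 0")
  if (min_contig_len < 1) stop_usage("min_contig_len must be >= 1")
  if (presence_epsilon < 0) stop_usage("presence_epsilon must be >= 0")
  if (num_colors < 1) stop_usage("num_colors must be >= 1")
  if (trim_steps < 1) stop_usage("trim_steps must be >= 1")
  structure(list(k = k, coverage_cutoff = coverage_cutoff,
                 min_contig_len = as.integer(min_contig_len),
                 presence_epsilon = presence_epsilon,
                 num_colors = as.integer(num_colors),
                 tip_len_factor = tip_len_factor,
                 trim_steps = as.integer(trim_steps), seed = seed),
            class = "assembly_config")
}

#' Canonicalize odd-length k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer and
#' its reverse complement, which makes the graph strand-agnostic. Odd length
#' guarantees a k-mer never equals its own reverse complement, so the
#' orientation flag is always well defined.
#'
#' @param s character vector of DNA strings over A/C/G/T, all of the same odd
#'   length.
#' @return data.frame with columns `kmer` (canonical string) and `orientation`
#'   (`"forward"` if the input was already canonical, else `"reverse"`).
#' @examples
#' canonicalize(c("ACG", "TTT"))
#' @export
canonicalize <- function(s) {
  if (length(s) == 0L)
    return(data.frame(kmer = character(), orientation = character(),
                      stringsAsFactors = FALSE))
  len <- unique(nchar(s))
  if (length(len) != 1L || len %% 2L == 0L)
    stop_usage("all k-mers must share one odd length")
  if (any(grepl("[^ACGT]", s)))
    stop_usage("ambiguous base in k-mer; split reads on non-ACGT first")
  rc <- revcomp(s)
  fwd <- s <= rc
  data.frame(kmer = ifelse(fwd, s, rc),
             orientation = ifelse(fwd, "forward", "reverse"),
             stringsAsFactors = FALSE)
}

#' Split sequences into unambiguous fragments
#'
#' Returns the maximal runs of A/C/G/T (uppercased first); every other byte
#' (N, IUPAC codes, anything) separates fragments. Fragments shorter than k
#' are harmless: they simply contribute no k-mers downstream.
#'
#' @param x character vector of sequences.
#' @return list of character vectors, one per input sequence.
#' @examples
#' split_on_ambiguous("ACGNNGT")
#' @export
split_on_ambiguous <- function(x) {
  x <- toupper(x)
  out <- regmatches(x, gregexpr("[ACGT]+", x))
  lapply(out, function(f) f[nzchar(f)])
}

#' Create an empty colored k-mer table
#'
#' The k-mer table is the vertex set of the colored de Bruijn graph: each
#' canonical k-mer maps to a length-`m` vector of per-color multiplicities,
#' and observed canonical (k+1)-mers are kept as edge witnesses.
#'
#' @param k odd k-mer size (3..31).
#' @param m number of colors.
#' @return list of class `kmer_table` with elements `k`, `m`, `kmers`
#'   (canonical, sorted), `counts` (numeric matrix, one column per color) and
#'   `edges` (canonical (k+1)-mers, sorted).
#' @export
kmer_table <- function(k, m) {
  k <- as.integer(k)
  m <- as.integer(m)
  if (k < 3L || k > 31L || k %% 2L == 0L)
    stop_usage("k must be an odd integer between 3 and 31")
  if (m < 1L) stop_usage("m must be >= 1")
  structure(list(k = k, m = m, kmers = character(),
                 counts = matrix(0, 0L, m), edges = character()),
            class = "kmer_table")
}

COUNT_SATURATION <- 2^32 - 1

#' Count the k-mers of a read set into one color
#'
#' Every k-window of every unambiguous fragment of every read increments the
#' multiplicity of its canonical k-mer in column `color`; every (k+1)-window
#' is recorded as an edge witness. Other colors are untouched, so data sets
#' can be ingested in any order with identical results. Counts saturate at
#' 2^32 - 1.
#'
#' @param table a [kmer_table()].
#' @param reads character vector of sequences, or a data.frame with a
#'   `sequence` column as returned by [parse_fasta()] / [parse_fastq()].
#' @param color 0-based color index of this read set.
#' @return the updated `kmer_table`.
#' @export
count_kmers <- function(table, reads, color) {
  stopifnot(inherits(table, "kmer_table"))
  if (is.data.frame(reads)) reads <- reads$sequence
  color <- as.integer(color)
  if (is.na(color) || color < 0L || color >= table$m)
    stop_usage("color must be in 0..", table$m - 1L)
  if (length(reads) == 0L) return(table)
  res <- cpp_count_kmers(toupper(reads), table$k)
  if (length(res$kmers) == 0L && length(res$edges) == 0L) return(table)
  all_k <- sort_c(unique(c(table$kmers, res$kmers)))
  counts <- matrix(0, length(all_k), table$m)
  if (length(table$kmers))
    counts[match(table$kmers, all_k), ] <- table$counts
  idx <- match(res$kmers, all_k)
  counts[idx, color + 1L] <- pmin(counts[idx, color + 1L] + res$counts,
                                  COUNT_SATURATION)
  table$kmers <- all_k
  table$counts <- counts
  table$edges <- sort_c(unique(c(table$edges, res$edges)))
  table
}
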