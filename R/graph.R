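#' Build the colored de Bruijn graph from a k-mer table
#'
#' Vertices are the table's canonical k-mers; a (bidirected) connection exists
#' iff its canonical (k+1)-mer witness was observed in some read and both
#' endpoint k-mers are present. Adjacency is never inferred from (k-1)-overlap
#' alone.
#'
#' @param table a [kmer_table()].
#' @return list of class `colored_graph` with the table contents plus a
#'   logical `keep` mask of live vertices (all `TRUE` initially; cleaning
#'   operations clear entries).
#' @export
build_graph <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  structure(list(k = table$k, m = table$m, kmers = table$kmers,
                 counts = table$counts, edges = table$edges,
                 keep = rep(TRUE, length(table$kmers))),
            class = "colored_graph")
}

#' @export
print.colored_graph <- function(x, ...) {
  cat("<colored_graph> k=", x$k, ", ", sum(x$keep), "/", length(x$kmers),
      " live vertices, ", length(x$edges), " edge witnesses, m=", x$m, "\n",
      sep = "")
  invisible(x)
}

# Condense the live subgraph; returns the raw C++ result (paths over original
# k-mer indices, strands, sequences).
condense_raw <- function(g) {
  cpp_condense(g$kmers, g$edges, g$k, g$keep)
}

# Per-unitig average coverage matrix (unweighted mean of constituent k-mer
# multiplicities per color).
unitig_coverage <- function(g, paths) {
  m <- g$m
  v <- vapply(paths, function(p) colMeans(g$counts[p, , drop = FALSE]),
              numeric(m))
  if (m == 1L) matrix(v, ncol = 1L) else t(v)
}

#' Extract unitigs from the graph
#'
#' Returns the maximal non-branching paths of the color-blind union graph:
#' every internal vertex has exactly one predecessor and one successor. The
#' unitigs partition the live vertex set. Per-color average coverage is the
#' mean of the constituent k-mer multiplicities.
#'
#' @param g a [build_graph()] result.
#' @return a [contig_set()] (no length filtering applied).
#' @export
condense <- function(g) {
  stopifnot(inherits(g, "colored_graph"))
  res <- condense_raw(g)
  if (length(res$seqs) == 0L)
    return(contig_set(character(), matrix(0, 0L, g$m), k = g$k))
  cov <- unitig_coverage(g, res$paths)
  contig_set(res$seqs, cov, k = g$k, paths = res$paths)
}

#' Clip low-coverage tips
#'
#' Iteratively removes dead-end unitigs (exactly one endpoint without
#' continuation) shorter than `tip_len_factor * k` whose max-over-colors
#' average coverage is strictly lower than that of the best competing branch
#' at their attachment junction, re-condensing until a fixpoint. Isolated
#' linear pieces (both ends dead) are never tips.
#'
#' @param g a [colored_graph][build_graph()].
#' @param cfg an [assembly_config()].
#' @return the graph with clipped vertices removed from the live set.
#' @export
clip_tips <- function(g, cfg) {
  stopifnot(inherits(g, "colored_graph"), inherits(cfg, "assembly_config"))
  g$keep <- cpp_clip_tips(g$kmers, g$edges, g$k, g$keep, g$counts,
                          cfg$tip_len_factor * cfg$k)
  g
}

#' Progressive coverage-cutoff trimming with multi-color rescue
#'
#' Applies a rising schedule of `trim_steps` thresholds, linear from
#' `cutoff/trim_steps` up to `cutoff`. At each step the live subgraph is
#' re-condensed and every unitig whose *maximum* per-color average coverage
#' falls below the current threshold is deleted. Judging on the max over
#' colors is what realizes rescue: a region blacked out in one cell survives
#' as long as any other color covers it well. A cutoff of 0 leaves the graph
#' unchanged.
#'
#' @inheritParams clip_tips
#' @return the graph with trimmed vertices removed from the live set.
#' @export
trim_low_coverage <- function(g, cfg) {
  stopifnot(inherits(g, "colored_graph"), inherits(cfg, "assembly_config"))
  if (cfg$coverage_cutoff <= 0) return(g)
  thresholds <- cfg$coverage_cutoff * seq_len(cfg$trim_steps) / cfg$trim_steps
  for (t in thresholds) {
    res <- condense_raw(g)
    if (length(res$paths) == 0L) break
    covmax <- apply(unitig_coverage(g, res$paths), 1L, max)
    doomed <- covmax < t
    if (any(doomed))
      g$keep[unlist(res$paths[doomed], use.names = FALSE)] <- FALSE
  }
  g
}

#' Coassemble colored read sets into contigs
#'
#' Full pipeline: per-color k-mer counting, graph construction, tip clipping,
#' progressive coverage trimming with multi-color rescue, condensation into
#' color-oblivious contigs, and length filtering. Deterministic: identical
#' inputs and configuration give byte-identical contig output.
#'
#' @param manifest a [color_manifest()], or a path to a manifest file.
#' @param cfg an [assembly_config()]; its `num_colors` is taken from the
#'   manifest.
#' @return a [contig_set()] with `length >= min_contig_len`, ordered by
#'   (length descending, sequence ascending).
#' @examples
#' g <- random_genome(600, seed = 1)
#' cells <- make_replicate_cells(g, 2, mda_profile(mean_depth = 30, seed = 1))
#' mpath <- write_simulated_cells(cells, tempfile("sim"))
#' contigs <- assemble(mpath, assembly_config(k = 15, coverage_cutoff = 2))
#' contigs
#' @export
assemble <- function(manifest, cfg = assembly_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "color_manifest"),
            inherits(cfg, "assembly_config"))
  m <- nrow(manifest)
  tbl <- kmer_table(cfg$k, m)
  for (i in seq_len(m)) {
    for (p in manifest$paths[[i]]) {
      tbl <- count_kmers(tbl, read_reads(p), manifest$color[i])
    }
  }
  finish_assembly(tbl, cfg)
}

# count table -> cleaned, filtered, sorted contigs
finish_assembly <- function(tbl, cfg) {
  g <- build_graph(tbl)
  g <- clip_tips(g, cfg)
  g <- trim_low_coverage(g, cfg)
  contigs <- condense(g)
  keep <- contigs$length >= cfg$min_contig_len
  subset_contigs(contigs, keep)
}

#' Iterative multi-k coassembly
#'
#' Runs [assemble()] at the smallest k, then for each larger k injects the
#' previous round's contigs as pseudo-reads (multiplicity 1) into every color
#' in which the contig is present (average coverage strictly above
#' `presence_epsilon`) and reassembles. Longer k-mers resolve repeats that
#' break contigs at the smaller k. This mode is optional and off by default
#' in all pipelines; the plain single-k [assemble()] is the reference
#' behavior.
#'
#' @param manifest a [color_manifest()] or manifest file path.
#' @param k_list strictly ascending odd k values.
#' @param cfg an [assembly_config()]; its `k` is overridden per round.
#' @return the final round's [contig_set()].
#' @export
iterative_assemble <- function(manifest, k_list, cfg = assembly_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "color_manifest"))
  k_list <- as.integer(k_list)
  if (length(k_list) == 0L || any(diff(k_list) <= 0L) || any(k_list %% 2L == 0L))
    stop_usage("k_list must be strictly ascending odd integers")
  m <- nrow(manifest)
  reads_by_color <- lapply(seq_len(m), function(i)
    unlist(lapply(manifest$paths[[i]], function(p) read_reads(p)$sequence),
           use.names = FALSE))
  min_read <- suppressWarnings(min(nchar(unlist(reads_by_color, use.names = FALSE))))
  contigs <- NULL
  for (k in k_list) {
    if (is.finite(min_read) && k > min_read - 1L)
      warning("k=", k, " exceeds the shortest read length minus 1 (",
              min_read - 1L, "); only pseudo-reads can support this round",
              call. = FALSE)
    cfg_k <- cfg
    cfg_k$k <- k
    tbl <- kmer_table(k, m)
    for (i in seq_len(m)) {
      reads <- reads_by_color[[i]]
      if (!is.null(contigs)) {
        present <- contigs$coverage[, i] > cfg$presence_epsilon
        reads <- c(reads, contigs$sequence[present])
      }
      if (length(reads)) tbl <- count_kmers(tbl, reads, i - 1L)
    }
    contigs <- finish_assembly(tbl, cfg_k)
  }
  contigs
}

#' Dump the graph as TSV for inspection
#'
#' One row per live vertex: the canonical k-mer, its per-color counts, and
#' its forward-orientation successors.
#'
#' @param g a [colored_graph][build_graph()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(g, path) {
  stopifnot(inherits(g, "colored_graph"))
  adj <- cpp_adjacency(g$kmers, g$edges, g$k, g$keep)
  fwd <- adj[adj$from_strand == 0L, , drop = FALSE]
  succ_str <- ifelse(fwd$to_strand == 1L, revcomp(fwd$to), fwd$to)
  succ <- vapply(split(succ_str, fwd$from), paste, "", collapse = ",")
  live <- g$kmers[g$keep]
  counts <- g$counts[g$keep, , drop = FALSE]
  lines <- paste(live,
                 apply(counts, 1L, paste, collapse = ","),
                 unname(succ[match(live, names(succ))]) |>
                   (\(x) ifelse(is.na(x), "", x))(),
                 sep = "\t")
  writeLines(c("kmer\tcounts\tsuccessors", lines), path)
  invisible(path)
}
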