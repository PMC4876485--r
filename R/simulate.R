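#' Random genome sequence
#'
#' i.i.d. bases with the requested GC content; deterministic under `seed`.
#'
#' @param length genome length in bp (>= 1).
#' @param gc probability that a base is G or C (split evenly).
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return a single DNA string.
#' @export
random_genome <- function(length, gc = 0.5, seed = NULL) {
  if (length < 1) stop_usage("length must be >= 1")
  if (gc < 0 || gc > 1) stop_usage("gc must be in [0, 1]")
  with_seed_(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
}

#' MDA amplification-bias profile
#'
#' A parametric stand-in for the coverage bias of multiple displacement
#' amplification: a fraction `blackout_fraction` of the genome receives zero
#' amplification (split over `num_blackout_intervals` intervals placed
#' uniformly at random), and every other window of `window_bp` bases gets a
#' multiplicative lognormal gain `exp(N(0, gain_sigma^2))`. Read starts are
#' drawn proportionally to the gain; reads themselves are exact copies (up to
#' the substitution error rate) of the genome. This models where priming
#' succeeds, not MDA chemistry.
#'
#' Defaults are the package's standard simulation conditions: 2% blackout in
#' 4 intervals, unit log-gain dispersion, 500 bp windows, 50x depth with
#' 50 bp error-free single-end reads on a linear genome.
#'
#' @param blackout_fraction fraction of the genome with zero amplification
#'   (in `[0, 1)`).
#' @param num_blackout_intervals number of non-overlapping blackout intervals.
#' @param gain_sigma standard deviation of the per-window log-gain (>= 0).
#' @param window_bp window size for the gain process (bp).
#' @param mean_depth expected average sequencing depth.
#' @param read_len read length (bp).
#' @param error_rate per-base substitution probability (in `[0, 1)`).
#' @param circular treat the genome as circular (reads may wrap).
#' @param seed integer seed; simulation is fully deterministic given the seed.
#' @return list of class `mda_profile`.
#' @export
mda_profile <- function(blackout_fraction = 0.02, num_blackout_intervals = 4L,
                        gain_sigma = 1, window_bp = 500L, mean_depth = 50,
                        read_len = 50L, error_rate = 0, circular = FALSE,
                        seed = 1L) {
  if (blackout_fraction < 0 || blackout_fraction >= 1)
    stop_usage("blackout_fraction must be in [0, 1)")
  if (num_blackout_intervals < 0) stop_usage("num_blackout_intervals must be >= 0")
  if (gain_sigma < 0) stop_usage("gain_sigma must be >= 0")
  if (mean_depth <= 0) stop_usage("mean_depth must be > 0")
  if (error_rate < 0 || error_rate >= 1) stop_usage("error_rate must be in [0, 1)")
  structure(list(blackout_fraction = blackout_fraction,
                 num_blackout_intervals = as.integer(num_blackout_intervals),
                 gain_sigma = gain_sigma, window_bp = as.integer(window_bp),
                 mean_depth = mean_depth, read_len = as.integer(read_len),
                 error_rate = error_rate, circular = isTRUE(circular),
                 seed = seed),
            class = "mda_profile")
}

# Uniformly place n non-overlapping intervals with the given total length on
# [0, len): lengths are a uniform composition of total into n positive parts,
# gaps a uniform weak composition of the free space into n+1 parts.
place_blackouts <- function(len, total, n) {
  if (n == 0L || total == 0L)
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("start", "end"))))
  if (total < n)
    stop_usage("cannot place ", n, " blackout intervals in ", total, " bp")
  lens <- if (n == 1L) total else {
    cuts <- sort(sample.int(total - 1L, n - 1L))
    diff(c(0L, cuts, total))
  }
  free <- len - total
  gaps <- if (free == 0L) integer(n + 1L) else {
    c0 <- sort(sample.int(free + n, n))
    c(c0[1L] - 1L, diff(c0) - 1L, free + n - c0[n])
  }
  starts <- cumsum(gaps[seq_len(n)]) + c(0L, cumsum(lens))[seq_len(n)]
  cbind(start = starts, end = starts + lens)
}

#' Simulate one MDA-amplified single cell
#'
#' Generates (1) blackout intervals totaling exactly
#' `floor(blackout_fraction * len)` bp, (2) per-window lognormal amplification
#' weights (zero on windows inside blackouts), (3) read start positions
#' sampled proportionally to the weight of the start's window (never inside a
#' blackout), with read count Poisson around `mean_depth * len / read_len`,
#' and (4) single-end reads copied from the genome on a uniformly chosen
#' strand with i.i.d. substitution errors. Reads that start outside a
#' blackout may run into it: MDA dropout suppresses priming, not read
#' integrity, so realized blackout edges shrink by up to `read_len`.
#'
#' @param genome a single DNA string (length >= `read_len`).
#' @param profile an [mda_profile()].
#' @param genome_id identifier stored with the cell.
#' @return list of class `simulated_cell` with `genome_id`, `weight_track`
#'   (per-window gains, 0 on windows fully inside blackouts), `reads`
#'   (data.frame `id`, `sequence`, `quality`), `truth` (blackout intervals,
#'   0-based half-open), `starts` (0-based read start positions) and
#'   `coverage` (realized per-position read depth).
#' @export
simulate_cell <- function(genome, profile = mda_profile(), genome_id = "genome") {
  stopifnot(inherits(profile, "mda_profile"))
  genome <- toupper(genome)
  len <- nchar(genome)
  rl <- profile$read_len
  if (len < rl) stop_usage("genome shorter than read_len")
  with_seed_(profile$seed, {
    total_black <- floor(profile$blackout_fraction * len)
    truth <- place_blackouts(len, total_black, profile$num_blackout_intervals)

    nw <- ceiling(len / profile$window_bp)
    w <- exp(rnorm(nw, 0, profile$gain_sigma))
    # zero out windows lying fully inside a blackout interval
    win_start <- (seq_len(nw) - 1L) * profile$window_bp
    win_end <- pmin(win_start + profile$window_bp, len)
    if (nrow(truth)) {
      for (b in seq_len(nrow(truth)))
        w[win_start >= truth[b, 1] & win_end <= truth[b, 2]] <- 0
    }

    # per-position start weight: window gain, zeroed inside blackouts
    pos_w <- w[pmin((0:(len - 1L)) %/% profile$window_bp + 1L, nw)]
    if (nrow(truth)) {
      black <- logical(len)
      for (b in seq_len(nrow(truth)))
        black[(truth[b, 1] + 1L):truth[b, 2]] <- TRUE
      pos_w[black] <- 0
    }
    domain_max <- if (profile$circular) len else len - rl + 1L
    pw <- pos_w[seq_len(domain_max)]
    n_reads <- rpois(1L, profile$mean_depth * len / rl)
    if (sum(pw) <= 0) n_reads <- 0L
    starts <- if (n_reads > 0L)
      sample.int(domain_max, n_reads, replace = TRUE, prob = pw) - 1L
    else integer()

    gtxt <- if (profile$circular) paste0(genome, substr(genome, 1L, rl)) else genome
    seqs <- substring(gtxt, starts + 1L, starts + rl)
    if (length(seqs)) {
      rev <- runif(length(seqs)) < 0.5
      if (any(rev)) seqs[rev] <- revcomp(seqs[rev])
      if (profile$error_rate > 0) seqs <- add_substitutions(seqs, profile$error_rate)
    }

    cov <- numeric(len)
    if (length(starts)) {
      s1 <- starts + 1L
      e1 <- pmin(starts + rl, len) + 1L
      cov <- cumsum(tabulate(s1, len + 1L) - tabulate(e1, len + 1L))[seq_len(len)]
      if (profile$circular) {
        wrap <- starts + rl - len
        wrap <- wrap[wrap > 0]
        if (length(wrap))  # wrapped tails cover [0, wrap)
          cov <- cov + cumsum(c(length(wrap), numeric(len - 1L)) -
                                tabulate(wrap + 1L, len))
      }
    }

    structure(list(genome_id = genome_id, weight_track = w,
                   reads = data.frame(
                     id = if (length(seqs)) paste0(genome_id, "_r", seq_along(seqs))
                          else character(),
                     sequence = seqs,
                     quality = strrep("I", nchar(seqs)),
                     stringsAsFactors = FALSE),
                   truth = truth, starts = starts, coverage = cov),
              class = "simulated_cell")
  })
}

# i.i.d. substitutions: each base mutates with probability e to a uniformly
# chosen different base
add_substitutions <- function(seqs, e) {
  n <- length(seqs)
  rl <- nchar(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_len(n)) {
    hit <- which(runif(rl[i]) < e)
    if (length(hit)) {
      orig <- chars[[i]][hit]
      repl <- vapply(orig, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      chars[[i]][hit] <- repl
    }
  }
  vapply(chars, paste, "", collapse = "")
}

#' Simulate biological replicate cells of one genome
#'
#' Each cell gets independent blackout placement and window gains (seed
#' derived as `profile$seed + cell index`), modeling the observation that MDA
#' dropout does not recur at the same loci across cells.
#'
#' @param genome a single DNA string.
#' @param n_cells number of cells (>= 1).
#' @param profile an [mda_profile()]; per-cell seeds are derived from its
#'   `seed`.
#' @param genome_id identifier prefix.
#' @return list of [simulate_cell()] results.
#' @export
make_replicate_cells <- function(genome, n_cells, profile = mda_profile(),
                                 genome_id = "genome") {
  if (n_cells < 1) stop_usage("n_cells must be >= 1")
  lapply(seq_len(n_cells) - 1L, function(i) {
    p <- profile
    p$seed <- profile$seed + i
    simulate_cell(genome, p, genome_id = paste0(genome_id, "_cell", i))
  })
}

#' Write simulated cells to disk
#'
#' Writes one FASTQ (constant quality "I") or FASTA per cell, a BED file of
#' the true blackout intervals per cell, and an auto-generated color
#' manifest.
#'
#' @param cells list of [simulate_cell()] results.
#' @param dir output directory (created if needed).
#' @param format `"fastq"` or `"fasta"`.
#' @param genome optional genome string, written as `genome.fa`.
#' @return the manifest path, invisibly.
#' @export
write_simulated_cells <- function(cells, dir, format = c("fastq", "fasta"),
                                  genome = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- character(length(cells))
  paths <- character(length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    labels[i] <- cell$genome_id
    ext <- if (format == "fastq") ".fastq" else ".fasta"
    paths[i] <- file.path(dir, paste0(cell$genome_id, ext))
    rd <- cell$reads
    lines <- if (format == "fastq")
      as.vector(rbind(paste0("@", rd$id), rd$sequence, "+", rd$quality))
    else
      as.vector(rbind(paste0(">", rd$id), rd$sequence))
    writeLines(lines, paths[i])
    write_bed(cell$truth, file.path(dir, paste0(cell$genome_id, ".blackouts.bed")),
              chrom = cell$genome_id)
  }
  if (!is.null(genome))
    writeLines(c(">genome", genome), file.path(dir, "genome.fa"))
  mpath <- file.path(dir, "manifest.tsv")
  write_manifest(color_manifest(labels, as.list(paths)), mpath)
  invisible(mpath)
}
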