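# Independent pure-R brute-force reference implementations used as oracles.
# Deliberately naive (string-based, loop-based); shares no code with the
# package's compiled core.

o_rc <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = ""), "", USE.NAMES = FALSE)
}

o_canon <- function(x) {
  r <- o_rc(x)
  ifelse(x <= r, x, r)
}

o_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) character() else substring(s, 1:(n - k + 1), k:n)
}

# brute-force canonical k-mer counts and (k+1)-mer edge witnesses
o_count <- function(reads, k) {
  frags <- unlist(regmatches(toupper(reads), gregexpr("[ACGT]+", toupper(reads))))
  km <- unlist(lapply(frags, o_windows, k))
  em <- unlist(lapply(frags, o_windows, k + 1))
  cnt <- c(table(o_canon(km)))
  cnt <- cnt[sort(names(cnt), method = "radix")]
  list(counts = cnt,
       edges = sort(unique(o_canon(em)), method = "radix"),
       n_windows = length(km))
}

# brute-force maximal non-branching paths of the bidirected graph; returns the
# sorted canonical unitig sequences. Cycles start at the smallest canonical
# k-mer in forward orientation (the documented convention).
o_unitigs <- function(kmers, edges, k) {
  kmers <- sort(kmers, method = "radix")
  n <- length(kmers)
  if (n == 0L) return(character())
  id <- seq_len(n)
  names(id) <- kmers
  okey <- function(i, s) 2L * (i - 1L) + s + 1L
  flip <- function(o) if (o %% 2L == 1L) o + 1L else o - 1L
  onode <- function(o) (o - 1L) %/% 2L + 1L
  okmer <- function(o) {
    km <- kmers[onode(o)]
    if ((o - 1L) %% 2L == 1L) o_rc(km) else km
  }
  out <- vector("list", 2L * n)
  if (length(edges)) {
    both <- unique(c(edges, o_rc(edges)))
    p <- substr(both, 1L, k)
    s <- substr(both, 2L, k + 1L)
    pc <- o_canon(p)
    sc <- o_canon(s)
    pi <- unname(id[pc])
    si <- unname(id[sc])
    for (e in seq_along(both)) {
      if (is.na(pi[e]) || is.na(si[e])) next
      a <- okey(pi[e], as.integer(p[e] != pc[e]))
      b <- okey(si[e], as.integer(s[e] != sc[e]))
      out[[a]] <- c(out[[a]], b)
    }
    out <- lapply(out, function(v) sort(unique(v)))
  }
  deg <- function(o) length(out[[o]])
  visited <- logical(n)
  seqs <- character()
  for (start in seq_len(n)) {
    if (visited[start]) next
    visited[start] <- TRUE
    path <- okey(start, 0L)
    cur <- path
    repeat {
      if (deg(cur) != 1L) break
      nxt <- out[[cur]][[1L]]
      if (deg(flip(nxt)) != 1L) break
      if (visited[onode(nxt)]) break
      visited[onode(nxt)] <- TRUE
      path <- c(path, nxt)
      cur <- nxt
    }
    cur <- flip(path[[1L]])
    pre <- integer()
    repeat {
      if (deg(cur) != 1L) break
      nxt <- out[[cur]][[1L]]
      if (deg(flip(nxt)) != 1L) break
      if (visited[onode(nxt)]) break
      visited[onode(nxt)] <- TRUE
      pre <- c(pre, flip(nxt))
      cur <- nxt
    }
    if (length(pre)) path <- c(rev(pre), path)
    sq <- okmer(path[[1L]])
    if (length(path) > 1L)
      sq <- paste0(sq, paste(vapply(path[-1L],
                                    function(o) substr(okmer(o), k, k), ""),
                             collapse = ""))
    rcsq <- o_rc(sq)
    if (rcsq < sq) sq <- rcsq
    seqs <- c(seqs, sq)
  }
  sort(seqs, method = "radix")
}

canonicalize_seq <- function(s) {
  r <- o_rc(s)
  ifelse(s <= r, s, r)
}

# error-free tiling reads covering every (k+1)-window of the genome
tile_reads <- function(genome, read_len = 40L, step = 10L) {
  n <- nchar(genome)
  starts <- unique(c(seq(1L, max(1L, n - read_len + 1L), by = step),
                     max(1L, n - read_len + 1L)))
  substring(genome, starts, pmin(starts + read_len - 1L, n))
}

# genome whose canonical (k-1)-mers are all distinct (repeat-free at k),
# found by rejection sampling
repeat_free_genome <- function(len, k, seed) {
  for (i in 0:200) {
    g <- coasm::random_genome(len, seed = seed + i * 1000L)
    w <- o_canon(o_windows(g, k - 1L))
    if (!anyDuplicated(w)) return(g)
  }
  stop("no repeat-free genome found")
}

# assemble directly from in-memory per-color read vectors
assemble_reads <- function(reads_by_color, cfg) {
  tbl <- coasm::kmer_table(cfg$k, length(reads_by_color))
  for (i in seq_along(reads_by_color))
    tbl <- coasm::count_kmers(tbl, reads_by_color[[i]], i - 1L)
  coasm:::finish_assembly(tbl, cfg)
}
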