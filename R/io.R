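#' Read a FASTA file into read records
#'
#' Sequences are uppercased on ingest; gzip compression is detected
#' transparently (by content, not extension). Empty sequences are rejected.
#'
#' @param path path to a FASTA file, optionally gzip-compressed.
#' @return data.frame with columns `id`, `sequence`, `quality` (all `NA` for
#'   FASTA), one row per record in file order.
#' @seealso [parse_fastq()], [write_contigs()]
#' @export
parse_fasta <- function(path) {
  lines <- slurp_lines(path)
  if (length(lines)) {
    hdr <- startsWith(lines, ">")
    if (!hdr[1L])
      stop_format("line 1 of '", path, "' is not a FASTA header")
    hpos <- which(hdr)
    # a header immediately followed by another header (or EOF) has no sequence
    nxt <- c(hpos[-1L], length(lines) + 1L)
    empty <- nxt == hpos + 1L
    if (any(empty))
      stop_format("empty sequence for header at line ", hpos[empty][1L],
                  " in '", path, "'")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop_format("malformed FASTA in '", path, "': ",
                                    conditionMessage(e)))
  seqs <- toupper(as.character(set))
  ids <- names(set) %||% character(length(set))
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1L]
    stop_format("empty sequence for record ", bad, " ('", ids[bad],
                "') in '", path, "'")
  }
  data.frame(id = unname(ids), sequence = unname(seqs),
             quality = rep(NA_character_, length(seqs)),
             stringsAsFactors = FALSE)
}

# read all lines with transparent gzip, dropping trailing blank lines
slurp_lines <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  lines
}

#' Read a FASTQ file into read records
#'
#' Qualities are parsed and carried along but never used by the assembler.
#' Records with mismatched sequence/quality lengths are rejected; gzip is
#' transparent.
#'
#' @param path path to a FASTQ file (4 lines per record), optionally
#'   gzip-compressed.
#' @return data.frame with columns `id`, `sequence` (uppercase), `quality`.
#' @export
parse_fastq <- function(path) {
  lines <- slurp_lines(path)
  if (length(lines) %% 4L != 0L)
    stop_format("truncated FASTQ in '", path, "': record starting at line ",
                4L * (length(lines) %/% 4L) + 1L, " is incomplete")
  if (length(lines)) {
    at <- startsWith(lines[seq(1L, length(lines), by = 4L)], "@")
    if (!all(at))
      stop_format("line ", 4L * (which(!at)[1L] - 1L) + 1L, " of '", path,
                  "' is not a FASTQ record header")
    plus <- startsWith(lines[seq(3L, length(lines), by = 4L)], "+")
    if (!all(plus))
      stop_format("line ", 4L * (which(!plus)[1L] - 1L) + 3L, " of '", path,
                  "' is not a FASTQ separator")
  }
  parsed <- tryCatch({
    set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    list(seqs = toupper(as.character(set)),
         quals = as.character(S4Vectors::mcols(set)$qualities),
         ids = names(set) %||% character(length(set)))
  }, error = function(e) stop_format("malformed FASTQ in '", path, "': ",
                                     conditionMessage(e)))
  seqs <- parsed$seqs
  quals <- parsed$quals
  ids <- parsed$ids
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1L]
    stop_format("empty sequence for record ", bad, " in '", path, "'")
  }
  qlen <- nchar(quals, type = "bytes")
  if (any(is.na(quals)) || any(qlen != nchar(seqs))) {
    bad <- which(is.na(quals) | qlen != nchar(seqs))[1L]
    stop_format("quality/sequence length mismatch for record ", bad,
                " ('", ids[bad], "') in '", path, "'")
  }
  data.frame(id = unname(ids), sequence = unname(seqs),
             quality = unname(quals), stringsAsFactors = FALSE)
}

# Sniff FASTA vs FASTQ from the first byte (after transparent decompression).
read_reads <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L)
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  if (startsWith(first, "@")) parse_fastq(path)
  else if (startsWith(first, ">")) parse_fasta(path)
  else stop_format("'", path, "' is neither FASTA nor FASTQ (first line: '",
                   substr(first, 1, 20), "')")
}

#' Write contigs with per-color coverage annotations
#'
#' Writes plain FASTA with headers
#' `>contig_<n> len=<L> cov=<c0,c1,...>` where coverages are the per-color
#' average k-mer multiplicities printed with two decimals. Contigs are written
#' in (length descending, sequence ascending) order, so identical inputs give
#' byte-identical files.
#'
#' @param contigs a [contig_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  stopifnot(inherits(contigs, "contig_set"))
  n <- length(contigs$sequence)
  lines <- character(0)
  if (n > 0L) {
    cov <- apply(contigs$coverage, 1L,
                 function(r) paste(sprintf("%.2f", r), collapse = ","))
    hdr <- sprintf(">contig_%d len=%d cov=%s", seq_len(n) - 1L,
                   nchar(contigs$sequence), cov)
    lines <- as.vector(rbind(hdr, contigs$sequence))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a contig FASTA written by [write_contigs()]
#'
#' @param path contig FASTA path.
#' @param k the k-mer size the contigs were assembled with (optional; used
#'   only to recompute k-mer counts).
#' @return a [contig_set()].
#' @export
read_contigs <- function(path, k = NA_integer_) {
  rec <- parse_fasta(path)
  if (nrow(rec) == 0L)
    return(contig_set(character(), matrix(0, 0, 1), k = k))
  covs <- regmatches(rec$id, regexpr("cov=[0-9.,eE+-]+", rec$id))
  if (length(covs) != nrow(rec))
    stop_format("contig headers in '", path, "' lack cov= annotations")
  covlist <- lapply(strsplit(sub("^cov=", "", covs), ","), as.numeric)
  m <- unique(lengths(covlist))
  if (length(m) != 1L)
    stop_format("inconsistent number of colors in '", path, "'")
  contig_set(rec$sequence, do.call(rbind, covlist), k = k)
}

#' Construct a color manifest
#'
#' A manifest assigns each input read set a color: color `i` is the 0-based
#' position of its entry. Labels must be unique and every color needs at
#' least one file.
#'
#' @param labels character vector of color labels.
#' @param paths list of character vectors, one vector of file paths per color.
#' @return data.frame of class `color_manifest` with columns `color`, `label`,
#'   `paths` (list column).
#' @export
color_manifest <- function(labels, paths) {
  if (is.character(paths)) paths <- as.list(paths)
  if (length(labels) != length(paths) || length(labels) == 0L)
    stop_usage("labels and paths must have equal, positive length")
  if (anyDuplicated(labels)) stop_usage("manifest labels must be unique")
  if (any(lengths(paths) == 0L))
    stop_usage("every color needs at least one file")
  out <- data.frame(color = seq_along(labels) - 1L, label = as.character(labels),
                    stringsAsFactors = FALSE)
  out$paths <- lapply(paths, as.character)
  class(out) <- c("color_manifest", "data.frame")
  out
}

#' Read a color manifest file
#'
#' Plain-text, one line per color: `<label><TAB><comma-separated paths>`.
#' The color index is the 0-based line order.
#'
#' @param path manifest file path.
#' @return a [color_manifest()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_format("empty manifest: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop_format("manifest line ", which(lengths(parts) != 2L)[1L],
                " is not '<label>\\t<paths>' in '", path, "'")
  color_manifest(vapply(parts, `[[`, "", 1L),
                 lapply(parts, function(p) strsplit(p[[2L]], ",")[[1L]]))
}

#' Write a color manifest file
#'
#' @param manifest a [color_manifest()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "color_manifest"))
  writeLines(paste0(manifest$label, "\t",
                    vapply(manifest$paths, paste, "", collapse = ",")), path)
  invisible(path)
}
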