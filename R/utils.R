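`%||%` <- function(a, b) if (is.null(a)) b else a

# locale-independent string sort/order (all sequence strings are ACGT, but
# radix keeps byte order regardless of the session locale)
sort_c <- function(x) sort(x, method = "radix")
order_c <- function(...) order(..., method = "radix")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, case-insensitive;
#'   IUPAC ambiguity codes are complemented by Biostrings' rules).
#' @return character vector of reverse complements (uppercase).
#' @examples
#' revcomp(c("ACGT", "AAA"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state. A NULL seed leaves the RNG alone.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number", call. = FALSE)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_usage <- function(...) {
  stop(structure(class = c("coasm_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_io <- function(...) {
  stop(structure(class = c("coasm_io_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_format <- function(...) {
  stop(structure(class = c("coasm_format_error", "coasm_io_error", "error",
                           "condition"),
                 list(message = paste0(...), call = NULL)))
}
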