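#' @importFrom stats rnorm runif setNames
#' @importFrom utils head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a character vector of DNA sequences
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- character(length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out[!ok] <- x[!ok]
  out
}

## Count per-element Hamming mismatches between equal-length string vectors.
## Both vectors must be same-width within each element pair.
hamming_mm <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(integer(0))
  n <- nchar(x)
  stopifnot(all(n == nchar(y)))
  mapply(function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }, x, y, USE.NAMES = FALSE)
}

## Fast mismatch count of many same-width reads against one pattern.
prefix_mismatches <- function(reads, pattern) {
  if (length(reads) == 0L) return(integer(0))
  w <- nchar(pattern)
  short <- nchar(reads) < w
  mm <- rep.int(NA_integer_, length(reads))
  if (any(!short)) {
    sub <- substr(reads[!short], 1L, w)
    m <- matrix(unlist(strsplit(sub, "", fixed = TRUE), use.names = FALSE),
                ncol = w, byrow = TRUE)
    pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
    mm[!short] <- as.integer(rowSums(m != matrix(pat, nrow = nrow(m),
                                                 ncol = w, byrow = TRUE)))
  }
  mm
}

## sprintf-style read identifiers
make_read_ids <- function(prefix, n) {
  if (n == 0L) return(character(0))
  sprintf("%s:%08d", prefix, seq_len(n))
}

## Random fixed-length DNA strings (vectorized)
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## 0-based substring of a reference character scalar: [start, end)
ref_substr <- function(seq, start0, end0) {
  substring(seq, start0 + 1L, end0)
}

stop_param <- function(...) stop(..., call. = FALSE)
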