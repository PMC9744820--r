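## Default 21-nt insertion tag. Synthetic sequence chosen to avoid
## homopolymers, palindromic prefixes (a reverse-oriented partial tag at a
## junction must stay distinguishable from a forward one) and
## secondary-structure-prone motifs; real assays supply their own tag/oligo
## set via tag_design().
DEFAULT_TAG <- "GTACGCAGTTACCGGATGCTA"

#' Describe the insertion tag and its enrichment primers
#'
#' The tag design is the coordinate frame for extension verification: each
#' enrichment primer anneals inside the 21-nt tag and ends `boundary_offset`
#' bases away from the tag/genome insertion boundary, so the bases a
#' polymerase copies immediately after the primer are still tag bases and can
#' be checked to reject random-priming artifacts.
#'
#' Forward-side primers read from the tag into the genome downstream of the
#' insertion; reverse-side primers are reverse complements of a tag prefix
#' region and read into the upstream genome.
#'
#' @param tag_seq the 21-nt tag sequence (5' to 3' in insertion orientation).
#' @param pbs_len primer-binding-site length of the editing system, in bases
#'   (13 or 17 in the default configurations); carried for mismatch
#'   annotation, not used by the read machinery.
#' @param primers data.frame with columns `primer_id`, `seq`, `side`
#'   ("forward"/"reverse"), `boundary_offset` (>= 2). Defaults to
#'   [default_primers()] of `tag_seq`.
#' @return an object of class `peac_tag_design`.
#' @export
tag_design <- function(tag_seq = DEFAULT_TAG, pbs_len = 13L,
                       primers = default_primers(tag_seq)) {
  tag_seq <- toupper(tag_seq)
  if (nchar(tag_seq) != 21L || grepl("[^ACGT]", tag_seq)) {
    stop_param("'tag_seq' must be a 21-nt ACGT string")
  }
  if (!pbs_len %in% 1:20) stop_param("'pbs_len' must be in 1..20")
  req <- c("primer_id", "seq", "side", "boundary_offset")
  if (!all(req %in% names(primers))) {
    stop_param("'primers' needs columns: ", paste(req, collapse = ", "))
  }
  if (any(primers$boundary_offset < 2L)) {
    stop_param("every primer must end at least 2 bp from the insertion ",
               "boundary")
  }
  if (!all(primers$side %in% c("forward", "reverse"))) {
    stop_param("primer side must be 'forward' or 'reverse'")
  }
  primers <- as.data.frame(primers, stringsAsFactors = FALSE)
  ## per-primer geometry relative to the tag
  primers$expected_ext <- vapply(seq_len(nrow(primers)), function(i) {
    expected_extension(tag_seq, primers$seq[i], primers$side[i],
                       primers$boundary_offset[i])
  }, character(1))
  ## minimal retained tag length at which the primer can still anneal
  primers$min_tag_len <- vapply(seq_len(nrow(primers)), function(i) {
    primer_min_tag_len(tag_seq, primers$seq[i], primers$side[i])
  }, integer(1))
  structure(list(tag_seq = tag_seq, pbs_len = as.integer(pbs_len),
                 primers = primers),
            class = "peac_tag_design")
}

#' @export
print.peac_tag_design <- function(x, ...) {
  cat(sprintf("<peac_tag_design> tag %s (pbs_len %d)\n", x$tag_seq,
              x$pbs_len))
  print(x$primers[, c("primer_id", "seq", "side", "boundary_offset")],
        row.names = FALSE)
  invisible(x)
}

#' Default enrichment primer set for a tag
#'
#' Three forward and two reverse primers with different extension starting
#' points on the tag, mirroring a multi-primer enrichment design. F1/R2 (the
#' default analysis pair) leave a 4-base verification window; F2/R1 a 2-base
#' window; F3 a 6-base window.
#'
#' @param tag_seq the 21-nt tag.
#' @return data.frame of primers suitable for [tag_design()].
#' @export
default_primers <- function(tag_seq = DEFAULT_TAG) {
  sub <- function(a, b) substr(tag_seq, a, b)
  data.frame(
    primer_id = c("F1", "F2", "F3", "R1", "R2"),
    seq = c(sub(2, 17), sub(4, 19), sub(1, 15),
            revcomp(sub(3, 18)), revcomp(sub(5, 20))),
    side = c("forward", "forward", "forward", "reverse", "reverse"),
    boundary_offset = c(4L, 2L, 6L, 2L, 4L),
    stringsAsFactors = FALSE
  )
}

## Expected extension bases immediately 3' of a primer in a read, for a
## full-length tag. Forward: the remaining tag 3' bases; reverse: the
## reverse complement of the remaining tag 5' bases.
expected_extension <- function(tag_seq, primer_seq, side, boundary_offset) {
  L <- nchar(tag_seq)
  if (side == "forward") {
    pe <- L - boundary_offset                  # primer 3' position on tag
    stopifnot(substr(tag_seq, pe - nchar(primer_seq) + 1L, pe) == primer_seq)
    substr(tag_seq, pe + 1L, L)
  } else {
    ps <- boundary_offset + 1L                 # primer 3' maps tag position ps
    stopifnot(revcomp(substr(tag_seq, ps, ps + nchar(primer_seq) - 1L)) ==
                primer_seq)
    revcomp(substr(tag_seq, 1L, boundary_offset))
  }
}

## Shortest retained (5'-anchored) tag length that still contains the full
## primer annealing region. Truncation removes tag 3' bases (incomplete
## reverse transcription), so forward primers need the tag retained through
## their own 3' end; reverse primers through the far end of their region.
primer_min_tag_len <- function(tag_seq, primer_seq, side) {
  if (side == "forward") {
    as.integer(regexpr(primer_seq, tag_seq, fixed = TRUE)[1] +
                 nchar(primer_seq) - 1L)
  } else {
    region <- revcomp(primer_seq)
    as.integer(regexpr(region, tag_seq, fixed = TRUE)[1] +
                 nchar(region) - 1L)
  }
}

## Retained tag length needed for the extension window to be intact.
primer_intact_tag_len <- function(tag, primer_row) {
  if (primer_row$side == "forward") nchar(tag$tag_seq) else
    primer_row$min_tag_len
}
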