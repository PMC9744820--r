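#' Extract UMIs from the Tn5-side mate
#'
#' The UMI is the first `umi_len` bases of the Tn5-side read, followed by a
#' fixed spacer that is clipped along with it. Reads too short to contain
#' UMI + spacer are discarded (returned with `NA` UMI and a reason).
#'
#' @param read2 character vector of Tn5-side read sequences.
#' @param umi_len UMI length in bases.
#' @param umi_spacer fixed spacer sequence following the UMI.
#' @return data.frame with `umi`, `clipped` (remaining sequence) and
#'   `reason` (`NA` when extraction succeeded).
#' @export
extract_umi <- function(read2, umi_len = 10L, umi_spacer = "CAGT") {
  need <- umi_len + nchar(umi_spacer)
  ok <- nchar(read2) > need
  data.frame(
    umi = ifelse(ok, substr(read2, 1L, umi_len), NA_character_),
    clipped = ifelse(ok, substr(read2, need + 1L, nchar(read2)), ""),
    reason = ifelse(ok, NA_character_, "read_too_short"),
    stringsAsFactors = FALSE
  )
}

#' Match enrichment primers at read 5' ends
#'
#' Finds, for each read, the unique primer whose sequence matches the read
#' 5' end with at most `max_mm` mismatches. Ties are broken by fewest
#' mismatches, then by longest primer, then by declared primer order.
#'
#' @param reads character vector of primer-side read sequences.
#' @param tag a `peac_tag_design`.
#' @param max_mm maximum mismatches tolerated in the primer region.
#' @param primers_used optional subset of primer ids to consider.
#' @return data.frame with `primer_id` (NA if no match), `side`
#'   ("forward"/"reverse"/NA) and `primer_mm`.
#' @export
match_primer <- function(reads, tag, max_mm = 1L, primers_used = NULL) {
  pr <- tag$primers
  if (!is.null(primers_used)) {
    pr <- pr[pr$primer_id %in% primers_used, , drop = FALSE]
  }
  n <- length(reads)
  best_mm <- rep(NA_integer_, n)
  best_len <- rep(-1L, n)
  best_ord <- rep(NA_integer_, n)
  best_idx <- rep(NA_integer_, n)
  for (i in seq_len(nrow(pr))) {
    mm <- prefix_mismatches(reads, pr$seq[i])
    plen <- nchar(pr$seq[i])
    cand <- !is.na(mm) & mm <= max_mm
    better <- cand & (is.na(best_mm) | mm < best_mm |
                        (mm == best_mm & plen > best_len))
    best_mm[better] <- mm[better]
    best_len[better] <- plen
    best_ord[better] <- i
    best_idx[better] <- i
  }
  data.frame(
    primer_id = ifelse(is.na(best_idx), NA_character_,
                       pr$primer_id[best_idx]),
    side = ifelse(is.na(best_idx), NA_character_, pr$side[best_idx]),
    primer_mm = best_mm,
    stringsAsFactors = FALSE
  )
}

#' Verify the primer-extension sequence
#'
#' Each enrichment primer ends at least 2 bp away from the tag/genome
#' insertion boundary; the bases a read carries immediately 3' of the primer
#' must therefore equal the remaining tag bases. Random-priming reads carry
#' a primer followed by genomic sequence and fail this exact-match check
#' unless the genome coincidentally continues with the tag. The verified
#' window is the first `min(boundary_offset, min_ext)` bases after the
#' primer, so raising `min_ext` can only make the check stricter.
#'
#' @param reads character vector of primer-side reads.
#' @param primer_id primer id per read (NA means unmatched; verification is
#'   `FALSE`).
#' @param tag a `peac_tag_design`.
#' @param min_ext number of extension bases to verify (capped at each
#'   primer's `boundary_offset`).
#' @return logical vector.
#' @export
verify_extension <- function(reads, primer_id, tag, min_ext = 4L) {
  pr <- tag$primers
  out <- rep(FALSE, length(reads))
  for (i in seq_len(nrow(pr))) {
    sel <- which(!is.na(primer_id) & primer_id == pr$primer_id[i])
    if (length(sel) == 0L) next
    plen <- nchar(pr$seq[i])
    w <- min(pr$boundary_offset[i], min_ext)
    expect <- substr(pr$expected_ext[i], 1L, w)
    got <- substr(reads[sel], plen + 1L, plen + w)
    out[sel] <- nchar(got) == w & got == expect
  }
  out
}

#' Annotate a read-pair library: UMI, primer, extension verdict
#'
#' Runs [extract_umi()], [match_primer()] and [verify_extension()] over a
#' paired library and returns one row per pair, including the genomic
#' portion of the primer-side read (primer and full tag remnant trimmed)
#' for downstream alignment or truth-SAM joining. Pairs failing any stage
#' carry a rejection reason.
#'
#' @param fq1,fq2 FASTQ paths (primer side, Tn5 side) or data.frames from
#'   [read_fastq()].
#' @param tag a `peac_tag_design`.
#' @param umi_len,umi_spacer UMI geometry (see [extract_umi()]).
#' @param max_mm primer mismatch tolerance.
#' @param min_ext extension bases verified.
#' @param primers_used primer ids to consider.
#' @return data.frame with columns `read_id`, `umi`, `primer_id`, `side`
#'   ("F"/"R"), `ext_ok`, `trimmed_seq`, `mate_seq`, `reject_reason`.
#' @export
prep_reads <- function(fq1, fq2, tag, umi_len = 10L, umi_spacer = "CAGT",
                       max_mm = 1L, min_ext = 4L,
                       primers_used = c("F1", "R2")) {
  if (is.character(fq1)) fq1 <- read_fastq(fq1)
  if (is.character(fq2)) fq2 <- read_fastq(fq2)
  stopifnot(identical(fq1$read_id, fq2$read_id))
  n <- nrow(fq1)
  um <- extract_umi(fq2$seq, umi_len, umi_spacer)
  pm <- match_primer(fq1$seq, tag, max_mm, primers_used)
  ext <- verify_extension(fq1$seq, pm$primer_id, tag, min_ext)
  ## extension must never pass without a primer match
  ext[is.na(pm$primer_id)] <- FALSE

  pr <- tag$primers
  idx <- match(pm$primer_id, pr$primer_id)
  trim_len <- ifelse(is.na(idx), 0L,
                     nchar(pr$seq[idx]) + pr$boundary_offset[idx])
  trimmed <- substr(fq1$seq, trim_len + 1L, nchar(fq1$seq))

  reason <- rep(NA_character_, n)
  reason[is.na(pm$primer_id)] <- "no_primer"
  reason[!is.na(pm$primer_id) & !ext] <- "extension_mismatch"
  reason[!is.na(um$reason)] <- um$reason

  out <- data.frame(
    read_id = fq1$read_id,
    umi = um$umi,
    primer_id = pm$primer_id,
    side = ifelse(is.na(pm$side), NA_character_,
                  ifelse(pm$side == "forward", "F", "R")),
    ext_ok = ext & is.na(um$reason),
    trimmed_seq = ifelse(ext, trimmed, ""),
    mate_seq = um$clipped,
    reject_reason = reason,
    stringsAsFactors = FALSE
  )
  out
}

#' Write the per-read rejection log
#' @param prep output of [prep_reads()].
#' @param path TSV path.
#' @return invisibly, `path`.
#' @export
write_rejection_log <- function(prep, path) {
  bad <- prep[!is.na(prep$reject_reason), c("read_id", "reject_reason")]
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
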