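## All internal coordinates are 0-based half-open [start, end); SAM records
## are converted to/from 1-based at this boundary and human-readable TSVs
## state their convention in the column name or header comment.

#' Write a paired FASTQ file pair
#' @param reads1,reads2 character vectors of read sequences.
#' @param ids read identifiers (no "/1" suffix).
#' @param path1,path2 output paths.
#' @return invisibly, the two paths.
#' @keywords internal
write_fastq_pair <- function(reads1, reads2, ids, path1, path2) {
  write_fastq(reads1, ids, path1)
  write_fastq(reads2, ids, path2)
  invisible(c(path1, path2))
}

write_fastq <- function(reads, ids, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("[ /].*$", "", names(x))
  data.frame(read_id = ids, seq = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

## ---- SAM ----

sam_header <- function(ref) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length))
}

## records: data.frame(qname, flag, rname, pos (1-based), mapq, cigar,
## rnext, pnext, tlen, seq, tags). tags may be "" (omitted).
write_sam <- function(records, ref, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sam_header(ref), con)
  if (nrow(records)) {
    tags <- if ("tags" %in% names(records)) records$tags else ""
    lines <- paste(records$qname, records$flag, records$rname, records$pos,
                   records$mapq, records$cigar, records$rnext, records$pnext,
                   records$tlen, records$seq, "*", sep = "\t")
    has_tag <- nzchar(tags)
    lines[has_tag] <- paste(lines[has_tag], tags[has_tag], sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

## Parse query (read-coordinate) interval of "aSbMcS"-style cigars.
## Returns matrix with columns clip1, mlen, clip2.
parse_cigar_query <- function(cigar) {
  n <- length(cigar)
  out <- matrix(0L, nrow = n, ncol = 3,
                dimnames = list(NULL, c("clip1", "mlen", "clip2")))
  for (i in seq_len(n)) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cigar[i])[[1]]
    toks <- regmatches(cigar[i], gregexpr("\\d+[MIDNSHP=X]", cigar[i]))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", toks))
    type <- sub("^\\d+", "", toks)
    m <- which(type %in% c("M", "=", "X"))
    if (length(m) == 0L) next
    pre <- if (min(m) > 1L) sum(lens[seq_len(min(m) - 1L)][
      type[seq_len(min(m) - 1L)] == "S"]) else 0L
    post <- if (max(m) < length(lens)) sum(lens[(max(m) + 1L):length(lens)][
      type[(max(m) + 1L):length(lens)] == "S"]) else 0L
    out[i, ] <- c(pre, sum(lens[m]), post)
  }
  out
}

#' Read alignments from SAM/BAM into a flat table
#'
#' One row per read (primary alignment); a supplementary alignment of the
#' same read is folded into `chrom2/start2/end2/strand2` and flags the read
#' as split. Paired records are folded into one row whose `start`/`end` span
#' the whole fragment (both mates). Coordinates are converted to 0-based
#' half-open.
#'
#' @param path SAM or BAM file.
#' @param annotations optional data.frame keyed by `read_id` (e.g. the
#'   output of [prep_reads()]); its columns (`umi`, `primer_id`, `side`,
#'   `ext_ok`, ...) are joined onto the alignments. Reads without an
#'   annotation row are dropped with a message.
#' @param keep_seq keep the primary record's sequence (read orientation)?
#'   Needed for junction/tag inspection.
#' @return data.frame of alignments; attribute `n_skipped` counts reads
#'   dropped for missing annotations.
#' @export
read_alignments <- function(path, annotations = NULL, keep_seq = FALSE) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth", "mapq",
             "cigar", "isize", "seq"),
    tag = "RX"
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    out <- empty_alignments(keep_seq)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  flag <- res$flag
  cig <- parse_cigar_query(res$cigar)
  df <- data.frame(
    read_id = res$qname,
    flag = flag,
    chrom = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + cig[, "mlen"],
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mapq = ifelse(is.na(res$mapq), 0L, res$mapq),
    cigar = res$cigar,
    tlen = ifelse(is.na(res$isize), 0L, res$isize),
    clip1 = cig[, "clip1"],
    clip2 = cig[, "clip2"],
    qwidth = cig[, "clip1"] + cig[, "mlen"] + cig[, "clip2"],
    seq = as.character(res$seq),
    umi = if (!is.null(res$tag$RX)) as.character(res$tag$RX) else
      NA_character_,
    stringsAsFactors = FALSE
  )
  is_supp <- bitwAnd(flag, 2048L) > 0L
  is_second <- bitwAnd(flag, 128L) > 0L
  prim <- df[!is_supp & !is_second, , drop = FALSE]

  ## fold paired mates: fragment interval from tlen
  paired <- bitwAnd(prim$flag, 1L) > 0L
  fs <- prim$start
  fe <- prim$end
  pos_tl <- paired & prim$tlen > 0L
  neg_tl <- paired & prim$tlen < 0L
  fe[pos_tl] <- prim$start[pos_tl] + prim$tlen[pos_tl]
  fs[neg_tl] <- prim$end[neg_tl] + prim$tlen[neg_tl]  # tlen negative
  out <- data.frame(
    read_id = prim$read_id, chrom = prim$chrom,
    start = fs, end = fe,
    aln_start = prim$start, aln_end = prim$end,
    strand = prim$strand, mapq = prim$mapq, cigar = prim$cigar,
    umi = prim$umi, stringsAsFactors = FALSE
  )
  ## query interval of the primary segment in original read coordinates
  rev1 <- prim$strand == "-"
  out$qstart <- ifelse(rev1, prim$clip2 + 1L, prim$clip1 + 1L)
  out$qend <- out$qstart + (prim$end - prim$start) - 1L
  if (keep_seq) {
    s <- prim$seq
    s[rev1] <- revcomp(s[rev1])
    out$seq <- s
  }

  ## fold supplementary segments
  out$is_split <- FALSE
  out$chrom2 <- NA_character_
  out$start2 <- NA_integer_
  out$end2 <- NA_integer_
  out$strand2 <- NA_character_
  out$qstart2 <- NA_integer_
  supp <- df[is_supp, , drop = FALSE]
  if (nrow(supp)) {
    idx <- match(supp$read_id, out$read_id)
    keep <- !is.na(idx)
    supp <- supp[keep, , drop = FALSE]
    idx <- idx[keep]
    out$is_split[idx] <- TRUE
    out$chrom2[idx] <- supp$chrom
    out$start2[idx] <- supp$start
    out$end2[idx] <- supp$end
    out$strand2[idx] <- supp$strand
    out$qstart2[idx] <- ifelse(supp$strand == "-", supp$clip2 + 1L,
                               supp$clip1 + 1L)
  }
  ## anchor: genomic coordinate of the read's 5' end (the tag boundary for
  ## enrichment reads)
  out$anchor <- ifelse(out$strand == "+", out$start, out$end)

  n_skipped <- 0L
  if (!is.null(annotations)) {
    j <- match(out$read_id, annotations$read_id)
    keep <- !is.na(j)
    n_skipped <- sum(!keep)
    if (n_skipped > 0L) {
      message(n_skipped, " alignments skipped (no annotation)")
    }
    out <- out[keep, , drop = FALSE]
    j <- j[keep]
    for (col in setdiff(names(annotations), c("read_id", names(out)))) {
      out[[col]] <- annotations[[col]][j]
    }
    if ("umi" %in% names(annotations)) out$umi <- annotations$umi[j]
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_alignments <- function(keep_seq = FALSE) {
  out <- data.frame(
    read_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), aln_start = integer(0), aln_end = integer(0),
    strand = character(0), mapq = integer(0), cigar = character(0),
    umi = character(0), qstart = integer(0), qend = integer(0),
    stringsAsFactors = FALSE
  )
  if (keep_seq) out$seq <- character(0)
  out$is_split <- logical(0)
  out$chrom2 <- character(0)
  out$start2 <- integer(0)
  out$end2 <- integer(0)
  out$strand2 <- character(0)
  out$qstart2 <- integer(0)
  out$anchor <- integer(0)
  out
}

## ---- site tables ----

#' Write called sites as TSV and BED
#'
#' The BED intervals are the 23-nt protospacer+PAM span (0-based half-open);
#' the TSV carries all scores and filter verdicts, ordered by PEAC-ID.
#'
#' @param sites data.frame from [call_sites()]/[rank_sites()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.bed`.
#' @return invisibly, the two paths.
#' @export
write_sites <- function(sites, prefix) {
  tsv <- paste0(prefix, ".tsv")
  bed <- paste0(prefix, ".bed")
  df <- sites
  if (nrow(df)) {
    df <- df[order(df$peac_id), , drop = FALSE]
    if (is.list(df$mismatch_positions)) {
      df$mismatch_positions <- vapply(df$mismatch_positions, function(p) {
        paste(p, collapse = ",")
      }, character(1))
    }
  } else if (!is.null(df$mismatch_positions)) {
    df$mismatch_positions <- character(0)
  }
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_df <- if (nrow(df)) {
    has_match <- !is.na(df$match_start)
    data.frame(chrom = df$chrom[has_match],
               start = df$match_start[has_match],
               end = df$match_end[has_match],
               name = paste0("PEAC-", df$peac_id[has_match]),
               score = round(df$peac_score[has_match], 3),
               strand = df$match_strand[has_match])
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = numeric(0), strand = character(0))
  }
  write.table(bed_df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(tsv, bed))
}

#' Read a site TSV written by [write_sites()]
#' @param path TSV path.
#' @return data.frame with `mismatch_positions` restored as a list column.
#' @export
read_sites_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("mismatch_positions" %in% names(df)) {
    df$mismatch_positions <- lapply(
      strsplit(as.character(df$mismatch_positions), ","),
      function(x) as.integer(x[nzchar(x)])
    )
    if (nrow(df) == 0L) df$mismatch_positions <- list()
  }
  df
}

## ---- signal tracks ----

#' Write a per-base coverage track (bedGraph)
#'
#' Coverage of the primary-alignment intervals of (typically deduplicated)
#' reads, one track per amplicon side, for genome-browser inspection.
#'
#' @param aln alignment table (see [read_alignments()]).
#' @param ref the `peac_reference` (for sequence lengths).
#' @param path output bedGraph path.
#' @param side optional side filter ("F" or "R"); requires a `side` column.
#' @return invisibly, `path`.
#' @export
write_signal_track <- function(aln, ref, path, side = NULL) {
  if (!is.null(side) && nrow(aln)) aln <- aln[aln$side %in% side, ,
                                              drop = FALSE]
  if (nrow(aln) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    aln$chrom,
    IRanges::IRanges(aln$aln_start + 1L, aln$aln_end),
    seqlengths = setNames(ref$length, ref$name)
  )
  cov <- GenomicRanges::coverage(gr)
  rtracklayer::export.bedGraph(GenomicRanges::GRanges(cov), path)
  invisible(path)
}

#' Write translocation events as BEDPE
#' @param events event table from [call_junctions()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bedpe <- function(events, path) {
  if (nrow(events) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(
    chrom1 = events$chrom, start1 = events$receiver_cut,
    end1 = events$receiver_cut + 1L,
    chrom2 = ifelse(is.na(events$donor_cut), ".", events$chrom2),
    start2 = ifelse(is.na(events$donor_cut), -1L, events$donor_cut),
    end2 = ifelse(is.na(events$donor_cut), -1L, events$donor_cut + 1L),
    name = paste0(events$receiver_id, "_", events$model),
    score = round(events$score, 4),
    strand1 = ".", strand2 = ".",
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
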