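#' Translocation score
#'
#' Fraction of molecules at a receiver site whose joined partner is not the
#' expected downstream end: t / (n + t + c), with t the junction-supporting
#' read count, n the normal-join read count and c a pseudocount (default
#' 10) that damps scores at low coverage.
#'
#' @param t junction-supporting (translocation) read count, >= 0.
#' @param n normal-join read count, >= 0.
#' @param c pseudocount, >= 0.
#' @return numeric in \[0, 1).
#' @export
translocation_score <- function(t, n, c = 10) {
  if (any(t < 0) || any(n < 0) || any(c < 0)) {
    stop_param("t, n and c must be non-negative")
  }
  denom <- n + t + c
  if (any(denom == 0)) {
    stop_param("translocation score undefined for t = n = c = 0")
  }
  t / denom
}

#' Classify a DSB-end join into the five models
#'
#' Intra-site joins: (i) with tag, (ii) without. Inter-site joins: a distal
#' donor's upstream end without tag is (iii); its downstream end is (iv);
#' its tag-carrying upstream end — the tag then reading in reverse relative
#' to the receiver — is (v). Geometries that fit none of these (e.g. a
#' forward-oriented donor end with a tag) are returned as "unassigned"
#' rather than dropped.
#'
#' @param intra logical: donor is the receiver itself.
#' @param donor_end "upstream" or "downstream" (NA for intra joins).
#' @param tag_present logical: tag sequence at the junction.
#' @param tag_reversed logical: tag orientation reversed relative to the
#'   receiver.
#' @return character vector of model labels.
#' @export
classify_junction <- function(intra, donor_end, tag_present,
                              tag_reversed = FALSE) {
  n <- max(length(intra), length(donor_end), length(tag_present),
           length(tag_reversed))
  intra <- rep_len(intra, n)
  donor_end <- rep_len(donor_end, n)
  tag_present <- rep_len(tag_present, n)
  tag_reversed <- rep_len(tag_reversed, n)
  out <- rep("unassigned", n)
  out[intra & tag_present] <- "i"
  out[intra & !tag_present] <- "ii"
  inter <- !intra & !is.na(donor_end)
  out[inter & donor_end == "upstream" & !tag_present] <- "iii"
  out[inter & donor_end == "downstream" & !tag_present] <- "iv"
  out[inter & donor_end == "upstream" & tag_present & tag_reversed] <- "v"
  out
}

## Detect a (possibly partial, >= min_len) tag at the start of a junction
## gap sequence; returns "forward", "reverse" or NA.
detect_tag <- function(gap, tag_seq, min_len = 6L, max_mm = 1L) {
  n <- length(gap)
  out <- rep(NA_character_, n)
  glen <- nchar(gap)
  for (i in seq_len(n)) {
    if (glen[i] < min_len) next
    L <- min(glen[i], nchar(tag_seq))
    fwd <- substr(tag_seq, 1L, L)
    rev <- revcomp(fwd)
    g <- substr(gap[i], 1L, L)
    ## reversed tags sit at the gap's end in read orientation
    g_tail <- substr(gap[i], glen[i] - L + 1L, glen[i])
    if (sum(utf8ToInt(g) != utf8ToInt(fwd)) <= max_mm) {
      out[i] <- "forward"
    } else if (sum(utf8ToInt(g_tail) != utf8ToInt(rev)) <= max_mm) {
      out[i] <- "reverse"
    }
  }
  out
}

#' Flag clusters with unexpected upstream forward-amplicon signal
#'
#' Under normal joining, the forward-primer amplicon can only reach the
#' genome downstream of the tag. Forward-side reads mapping on the opposite
#' strand (hence covering the upstream flank) indicate a tag arriving in
#' reverse orientation via a model-(v) join at that receiver.
#'
#' @param clusters output of [cluster_cut_sites()] (or the audit table of
#'   [call_sites()]).
#' @param min_reads minimum unexpected-orientation deduplicated reads to
#'   raise the flag.
#' @return `clusters` with `unexpected_fwd` (count) and `flagged` columns.
#' @export
detect_unexpected_signals <- function(clusters, min_reads = 2L) {
  n <- nrow(clusters)
  minor <- pmin(clusters$fwd_plus, clusters$fwd_minus)
  ## a side with a single orientation has no unexpected component
  minor[clusters$fwd_plus == clusters$fwd_minus &
          clusters$fwd_plus + clusters$fwd_minus <= 1L] <- 0L
  clusters$unexpected_fwd <- minor
  clusters$flagged <- minor >= min_reads
  clusters
}

#' Call donor-receiver junctions from split reads
#'
#' Consumes nested-PCR/UDiTaS-style alignments in which each read is
#' anchored in a receiver's upstream flank. Reads whose second segment maps
#' back to the receiver's downstream flank (with or without an intervening
#' tag), and contiguous reads spanning the cut, are normal joins; reads
#' whose second segment maps to another site's flank are junction evidence,
#' keyed by (receiver, donor, donor end, tag presence) and classified into
#' the five join models.
#'
#' @param aln alignment table from [read_alignments()] with `keep_seq =
#'   TRUE` (split reads carry `chrom2/start2/end2/strand2/qstart2`).
#' @param sites site table with `site_id`, `chrom`, `cut`, `strand` (planted
#'   sites or called sites renamed accordingly).
#' @param tag `peac_tag_design`.
#' @param min_seg minimum aligned segment length in bases.
#' @param tol breakpoint-to-cut matching tolerance in bases.
#' @param pseudocount score pseudocount (see [translocation_score()]).
#' @return data.frame of events: receiver, donor (NA if unmatched), model,
#'   tag presence, donor cut, supporting (`t_reads`) and receiver normal
#'   (`n_reads`) counts, score (NA for intra-site rows), low-confidence
#'   flag. The attribute `"audit"` counts reads ignored per reason.
#' @export
call_junctions <- function(aln, sites, tag, min_seg = 20L, tol = 5L,
                           pseudocount = 10) {
  audit <- c(short_segment = 0L, unanchored = 0L)
  n_normal <- setNames(integer(nrow(sites)), sites$site_id)
  ev <- list()
  if (nrow(aln)) {
    for (i in seq_len(nrow(aln))) {
      r <- aln[i, ]
      seg1_len <- r$aln_end - r$aln_start
      ## receiver anchoring: the 5' segment must end at a site's cut, on
      ## the strand reading out of the upstream flank
      rc_hit <- which(sites$chrom == r$chrom &
                        ((sites$strand == "+" & r$strand == "+" &
                            abs(r$aln_end - sites$cut) <= tol) |
                           (sites$strand == "-" & r$strand == "-" &
                              abs(r$aln_start - sites$cut) <= tol)))
      if (!r$is_split) {
        ## contiguous read spanning a cut = normal (or never-cut) join
        span <- which(sites$chrom == r$chrom & sites$strand == r$strand &
                        r$aln_start + min_seg <= sites$cut &
                        r$aln_end - min_seg >= sites$cut)
        if (length(span)) {
          rcv <- sites$site_id[span[1L]]
          n_normal[rcv] <- n_normal[rcv] + 1L
        }
        next
      }
      if (length(rc_hit) == 0L) {
        audit["unanchored"] <- audit["unanchored"] + 1L
        next
      }
      seg2_len <- r$end2 - r$start2
      if (seg1_len < min_seg || seg2_len < min_seg) {
        audit["short_segment"] <- audit["short_segment"] + 1L
        next
      }
      rcv_i <- rc_hit[1L]
      rcv <- sites$site_id[rcv_i]
      rstrand <- sites$strand[rcv_i]

      ## tag between the segments?
      gap_start <- r$qend + 1L
      gap_end <- r$qstart2 - 1L
      gap <- if (gap_end >= gap_start) substr(r$seq, gap_start, gap_end)
        else ""
      tago <- detect_tag(gap, tag$tag_seq)
      ## anchored reads are written in the receiver's tag frame, so the
      ## detected orientation is already relative to the receiver
      tag_rel <- tago
      has_tag <- !is.na(tago)

      ## partner breakpoint: junction-side coordinate of segment 2
      jc <- if (r$strand2 == "+") r$start2 else r$end2
      dn_hit <- which(sites$chrom == r$chrom2 &
                        abs(sites$cut - jc) <= tol)
      if (length(dn_hit) && sites$site_id[dn_hit[1L]] == rcv &&
          ((rstrand == "+" & r$strand2 == "+") |
             (rstrand == "-" & r$strand2 == "-"))) {
        ## second segment continuous with the receiver downstream flank
        n_normal[rcv] <- n_normal[rcv] + 1L
        ev[[length(ev) + 1L]] <- data.frame(
          receiver_id = rcv, donor_id = rcv, intra = TRUE,
          donor_end = NA_character_, tag_present = has_tag,
          tag_reversed = identical(tag_rel, "reverse"),
          donor_cut = sites$cut[dn_hit[1L]], chrom = r$chrom,
          chrom2 = r$chrom2, stringsAsFactors = FALSE)
        next
      }
      if (length(dn_hit) == 0L) {
        ev[[length(ev) + 1L]] <- data.frame(
          receiver_id = rcv, donor_id = NA_character_, intra = FALSE,
          donor_end = NA_character_, tag_present = has_tag,
          tag_reversed = identical(tag_rel, "reverse"),
          donor_cut = jc, chrom = r$chrom, chrom2 = r$chrom2,
          stringsAsFactors = FALSE)
        next
      }
      dn_i <- dn_hit[1L]
      ## donor end: a segment reading in the donor's tag-frame downstream
      ## direction comes from the downstream end; an inverted segment from
      ## the upstream end
      donor_end <- if (r$strand2 == sites$strand[dn_i]) "downstream"
        else "upstream"
      ev[[length(ev) + 1L]] <- data.frame(
        receiver_id = rcv, donor_id = sites$site_id[dn_i], intra = FALSE,
        donor_end = donor_end, tag_present = has_tag,
        tag_reversed = identical(tag_rel, "reverse"),
        donor_cut = sites$cut[dn_i], chrom = r$chrom, chrom2 = r$chrom2,
        stringsAsFactors = FALSE)
    }
  }
  if (length(ev) == 0L) {
    out <- data.frame(
      receiver_id = character(0), donor_id = character(0),
      model = character(0), tag_present = logical(0),
      donor_cut = integer(0), chrom = character(0), chrom2 = character(0),
      receiver_cut = integer(0), t_reads = integer(0),
      n_reads = integer(0), score = numeric(0), low_confidence = logical(0),
      stringsAsFactors = FALSE)
    attr(out, "audit") <- audit
    attr(out, "n_normal") <- n_normal
    return(out)
  }
  evdf <- do.call(rbind, ev)
  evdf$model <- classify_junction(evdf$intra, evdf$donor_end,
                                  evdf$tag_present, evdf$tag_reversed)
  key <- paste(evdf$receiver_id, evdf$donor_id, evdf$model,
               evdf$tag_present, sep = "|")
  agg <- lapply(split(seq_len(nrow(evdf)), key), function(rows) {
    e <- evdf[rows[1L], ]
    e$t_reads <- length(rows)
    e$donor_cut <- modal_value(evdf$donor_cut[rows])
    e
  })
  out <- do.call(rbind, agg)
  out$receiver_cut <- sites$cut[match(out$receiver_id, sites$site_id)]
  out$n_reads <- n_normal[out$receiver_id]
  out$score <- ifelse(out$intra, NA_real_,
                      translocation_score(out$t_reads, out$n_reads,
                                          pseudocount))
  out$low_confidence <- out$t_reads < 2L
  out$intra <- NULL
  out$donor_end <- NULL
  out$tag_reversed <- NULL
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  attr(out, "n_normal") <- n_normal
  out
}
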