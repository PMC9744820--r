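#' Caller configuration
#'
#' @param window clustering window in bases: tag-anchored read starts within
#'   `window` of each other are merged, and WT evidence is counted within
#'   +/- `window` of a cluster's cut position.
#' @param max_wt maximum deduplicated wild-type reads tolerated in the
#'   cluster window (criterion 1; 0 = "no signal in the control").
#' @param wt_mode "absolute" (count <= max_wt) or "relative" (pass when the
#'   sample/WT read ratio is at least `wt_ratio`).
#' @param wt_ratio sample/WT ratio for the relative mode.
#' @param bidirectional_required if `TRUE` (default), criterion 2 uses the
#'   geometric mean sqrt(ext_fwd * ext_rev) > 0, requiring extension-verified
#'   support in both amplicon directions; if `FALSE`, one direction with
#'   >= 1 extension-verified read suffices.
#' @param min_strand_frac criterion 3: the modal orientation of each
#'   amplicon side must exceed this fraction of that side's reads.
#' @param search_window spacer search half-window around the cut, in bases.
#' @param max_mm_spacer maximum spacer mismatches for a reported match.
#' @return list of class `peac_call_config`.
#' @export
call_config <- function(window = 25L, max_wt = 0L, wt_mode = "absolute",
                        wt_ratio = 1000, bidirectional_required = TRUE,
                        min_strand_frac = 0.5, search_window = 25L,
                        max_mm_spacer = 7L) {
  wt_mode <- match.arg(wt_mode, c("absolute", "relative"))
  structure(list(window = as.integer(window), max_wt = as.integer(max_wt),
                 wt_mode = wt_mode, wt_ratio = wt_ratio,
                 bidirectional_required = isTRUE(bidirectional_required),
                 min_strand_frac = min_strand_frac,
                 search_window = as.integer(search_window),
                 max_mm_spacer = as.integer(max_mm_spacer)),
            class = "peac_call_config")
}

#' Deduplicate reads by mapped location and UMI
#'
#' Reads mapped to the same paired-end location (chromosome, strand, both
#' fragment ends) sharing the same UMI and primer are PCR duplicates and are
#' merged to one representative (highest mapping quality, ties broken by
#' input order). Reads without a UMI are keyed by location alone. The
#' operation is idempotent.
#'
#' @param aln alignment table from [read_alignments()].
#' @return the deduplicated subset of `aln`, in input order.
#' @export
deduplicate_reads <- function(aln) {
  if (nrow(aln) == 0L) return(aln)
  umi <- if ("umi" %in% names(aln)) ifelse(is.na(aln$umi), "", aln$umi)
    else ""
  primer <- if ("primer_id" %in% names(aln)) {
    ifelse(is.na(aln$primer_id), "", aln$primer_id)
  } else ""
  key <- paste(aln$chrom, aln$strand, aln$start, aln$end, umi, primer,
               sep = "\r")
  o <- order(key, -aln$mapq, seq_len(nrow(aln)), method = "radix")
  keep_sorted <- !duplicated(key[o])
  keep <- sort(o[keep_sorted])
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

modal_value <- function(x) {
  t <- table(x)
  as.integer(names(t)[which.max(t)])  # ties -> smallest (table is sorted)
}

#' Cluster tag-anchored cut-site evidence
#'
#' Groups deduplicated reads whose tag-anchored 5' positions lie within
#' `window` bases of each other on the same chromosome. Forward- and
#' reverse-amplicon evidence anchoring at the same inferred cut falls into
#' the same cluster. The cluster cut position is the modal anchor.
#'
#' @param aln deduplicated, primer-annotated alignments (rows without a
#'   primer are ignored).
#' @param window clustering window in bases.
#' @return data.frame of clusters (cut position, per-side and per-strand
#'   deduplicated counts, extension-verified subsets); the integer
#'   attribute `"assignment"` maps each used alignment row (attribute
#'   `"used_rows"`) to its cluster.
#' @export
cluster_cut_sites <- function(aln, window = 25L) {
  used <- which(!is.na(aln$side))
  a <- aln[used, , drop = FALSE]
  if (nrow(a) == 0L) {
    out <- data.frame(cluster_id = integer(0), chrom = character(0),
                      cut_pos = integer(0), n_reads = integer(0),
                      fwd_count = integer(0), rev_count = integer(0),
                      ext_fwd = integer(0), ext_rev = integer(0),
                      fwd_plus = integer(0), fwd_minus = integer(0),
                      rev_plus = integer(0), rev_minus = integer(0))
    attr(out, "assignment") <- integer(0)
    attr(out, "used_rows") <- integer(0)
    return(out)
  }
  gr <- GenomicRanges::GRanges(a$chrom,
                               IRanges::IRanges(a$anchor + 1L, width = 1L))
  red <- GenomicRanges::reduce(gr, min.gapwidth = window,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  assignment <- integer(nrow(a))
  for (i in seq_along(revmap)) assignment[revmap[[i]]] <- i

  ext <- if ("ext_ok" %in% names(a)) a$ext_ok else rep(TRUE, nrow(a))
  cl <- lapply(seq_along(red), function(i) {
    rows <- revmap[[i]]
    s <- a$side[rows]
    st <- a$strand[rows]
    e <- ext[rows]
    data.frame(
      cluster_id = i,
      chrom = as.character(GenomeInfoDb::seqnames(red))[i],
      cut_pos = modal_value(a$anchor[rows]),
      n_reads = length(rows),
      fwd_count = sum(s == "F"), rev_count = sum(s == "R"),
      ext_fwd = sum(s == "F" & e), ext_rev = sum(s == "R" & e),
      fwd_plus = sum(s == "F" & st == "+"),
      fwd_minus = sum(s == "F" & st == "-"),
      rev_plus = sum(s == "R" & st == "+"),
      rev_minus = sum(s == "R" & st == "-"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, cl)
  attr(out, "assignment") <- assignment
  attr(out, "used_rows") <- used
  out
}

#' Apply the three candidate criteria
#'
#' Criterion 1: no signal in the wild-type control — at most `max_wt`
#' deduplicated, primer-matched WT reads anchored within +/- `window` of the
#' cut (or a sample/WT ratio test in relative mode). Criterion 2: at least
#' one direction with an extension-verified read and a positive geometric
#' mean of the per-direction extension-verified counts (with
#' `bidirectional_required`, sqrt(f*r) > 0 forces both directions).
#' Criterion 3: consistent read orientation upstream and downstream of the
#' putative cut — each amplicon side's modal strand must dominate and the
#' two sides must imply the same protospacer orientation.
#'
#' @param clusters output of [cluster_cut_sites()].
#' @param wt_aln deduplicated, primer-annotated WT alignments.
#' @param config a [call_config()].
#' @return `clusters` with `wt_count`, `crit_wt`, `crit_ext`, `crit_strand`
#'   and `pass` columns.
#' @export
apply_candidate_filters <- function(clusters, wt_aln, config = call_config()) {
  n <- nrow(clusters)
  wt_count <- integer(n)
  if (n > 0L && nrow(wt_aln) > 0L) {
    wt_use <- wt_aln[!is.na(wt_aln$side), , drop = FALSE]
    if (nrow(wt_use) > 0L) {
      wgr <- GenomicRanges::GRanges(
        wt_use$chrom, IRanges::IRanges(wt_use$anchor + 1L, width = 1L))
      cgr <- GenomicRanges::GRanges(
        clusters$chrom,
        IRanges::IRanges(clusters$cut_pos + 1L - config$window,
                         clusters$cut_pos + 1L + config$window))
      wt_count <- GenomicRanges::countOverlaps(cgr, wgr)
    }
  }
  clusters$wt_count <- wt_count
  clusters$crit_wt <- if (config$wt_mode == "absolute") {
    wt_count <= config$max_wt
  } else {
    wt_count == 0L |
      (clusters$fwd_count + clusters$rev_count) / pmax(wt_count, 1L) >=
        config$wt_ratio
  }
  gm <- sqrt(clusters$ext_fwd * clusters$ext_rev)
  clusters$crit_ext <- if (config$bidirectional_required) {
    (clusters$ext_fwd >= 1L | clusters$ext_rev >= 1L) & gm > 0
  } else {
    clusters$ext_fwd >= 1L | clusters$ext_rev >= 1L
  }
  frac_ok <- function(a, b) {
    tot <- a + b
    tot == 0L | pmax(a, b) / pmax(tot, 1L) > config$min_strand_frac
  }
  f_modal <- ifelse(clusters$fwd_plus >= clusters$fwd_minus, "+", "-")
  r_modal <- ifelse(clusters$rev_plus >= clusters$rev_minus, "+", "-")
  both <- clusters$fwd_count > 0L & clusters$rev_count > 0L
  clusters$crit_strand <- frac_ok(clusters$fwd_plus, clusters$fwd_minus) &
    frac_ok(clusters$rev_plus, clusters$rev_minus) &
    (!both | f_modal != r_modal)
  clusters$pass <- clusters$crit_wt & clusters$crit_ext &
    clusters$crit_strand
  clusters
}

#' Enrichment score: RPM-normalized extension-verified support
#'
#' The per-site score is the sum over both amplicon directions of the
#' extension-verified deduplicated read count normalized to reads per
#' million of that direction's deduplicated library size.
#'
#' @param ext_fwd,ext_rev extension-verified deduplicated counts.
#' @param lib_fwd,lib_rev per-direction deduplicated library sizes.
#' @return numeric score vector (0 when no extension-verified reads).
#' @export
compute_peac_score <- function(ext_fwd, ext_rev, lib_fwd, lib_rev) {
  if (any(ext_fwd > 0 & lib_fwd <= 0) || any(ext_rev > 0 & lib_rev <= 0)) {
    stop_param("zero library size with nonzero read count")
  }
  rpm <- function(x, lib) ifelse(x == 0, 0, 1e6 * x / lib)
  rpm(ext_fwd, lib_fwd) + rpm(ext_rev, lib_rev)
}

#' Locate the best spacer/PAM match near a cut position
#'
#' Exhaustively scans both strands within +/- `search_window` of `cut_pos`
#' for 20-mers followed by an NGG or NAG PAM, and returns the
#' minimal-mismatch match with at most `max_mm` spacer mismatches. Ties are
#' broken by PAM class (NGG before NAG), then by distance of the implied cut
#' from `cut_pos`.
#'
#' @param ref `peac_reference`.
#' @param cut_pos 0-based cut coordinate.
#' @param spacer 20-nt spacer (5' to 3').
#' @param search_window half-window in bases.
#' @param max_mm maximum spacer mismatches.
#' @return one-row data.frame (`match_start`/`match_end` span the 23-nt
#'   protospacer+PAM region, 0-based half-open; `mismatch_positions` is a
#'   list column of spacer positions 1-20, 5' to 3') or `NULL` if no
#'   qualifying match exists.
#' @export
match_spacer <- function(ref, cut_pos, spacer, search_window = 25L,
                         max_mm = 7L) {
  spacer <- toupper(spacer)
  stopifnot(nchar(spacer) == 20L)
  w <- search_window
  cand <- list()
  ## + strand: protospacer at [s, s+20), PAM [s+20, s+23), cut = s + 17
  s_plus <- (cut_pos - w - CUT_OFFSET):(cut_pos + w - CUT_OFFSET)
  s_plus <- s_plus[s_plus >= 0L & s_plus + 23L <= ref$length]
  if (length(s_plus)) {
    seq20 <- ref_substr(ref$seq, s_plus, s_plus + 20L)
    pam <- ref_substr(ref$seq, s_plus + 20L, s_plus + 23L)
    cand$plus <- data.frame(start = s_plus, strand = "+", seq20 = seq20,
                            pam = pam, implied_cut = s_plus + CUT_OFFSET,
                            stringsAsFactors = FALSE)
  }
  ## - strand: protospacer at [s, s+20) read on the minus strand,
  ## PAM [s-3, s), cut = s + 3
  s_minus <- (cut_pos - w - 3L):(cut_pos + w - 3L)
  s_minus <- s_minus[s_minus - 3L >= 0L & s_minus + 20L <= ref$length]
  if (length(s_minus)) {
    seq20 <- revcomp(ref_substr(ref$seq, s_minus, s_minus + 20L))
    pam <- revcomp(ref_substr(ref$seq, s_minus - 3L, s_minus))
    cand$minus <- data.frame(start = s_minus, strand = "-", seq20 = seq20,
                             pam = pam, implied_cut = s_minus + 3L,
                             stringsAsFactors = FALSE)
  }
  if (length(cand) == 0L) return(NULL)
  df <- do.call(rbind, cand)
  pam_ok <- grepl("^[ACGT]GG$", df$pam) | grepl("^[ACGT]AG$", df$pam)
  df <- df[pam_ok, , drop = FALSE]
  if (nrow(df) == 0L) return(NULL)
  df$n_mismatch <- prefix_mismatches(df$seq20, spacer)
  df <- df[df$n_mismatch <= max_mm, , drop = FALSE]
  if (nrow(df) == 0L) return(NULL)
  df$pam_rank <- ifelse(grepl("GG$", df$pam), 0L, 1L)
  df$dist <- abs(df$implied_cut - cut_pos)
  df <- df[order(df$n_mismatch, df$pam_rank, df$dist, df$start, df$strand), ,
           drop = FALSE]
  best <- df[1L, , drop = FALSE]
  mmpos <- which(strsplit(best$seq20, "")[[1L]] !=
                   strsplit(spacer, "")[[1L]])
  out <- data.frame(
    match_start = ifelse(best$strand == "+", best$start, best$start - 3L),
    match_end = ifelse(best$strand == "+", best$start + 23L,
                       best$start + 20L),
    spacer_start = best$start, spacer_end = best$start + 20L,
    match_strand = best$strand, matched_seq = best$seq20, pam = best$pam,
    pam_variant = !grepl("GG$", best$pam),
    n_mismatch = best$n_mismatch, implied_cut = best$implied_cut,
    stringsAsFactors = FALSE
  )
  out$mismatch_positions <- list(as.integer(mmpos))
  rownames(out) <- NULL
  out
}

#' Rank sites by enrichment score
#'
#' Stable sort by score (descending), ties broken by coordinates; assigns
#' the rank label `peac_id` 1..N.
#'
#' @param sites data.frame with `peac_score`, `chrom`, `cut_pos`.
#' @return `sites` reordered with a `peac_id` column.
#' @export
rank_sites <- function(sites) {
  if (nrow(sites) == 0L) {
    sites$peac_id <- integer(0)
    return(sites)
  }
  o <- order(-sites$peac_score, sites$chrom, sites$cut_pos)
  sites <- sites[o, , drop = FALSE]
  sites$peac_id <- seq_len(nrow(sites))
  rownames(sites) <- NULL
  sites
}

#' Call candidate cut sites from annotated alignments
#'
#' The full caller: deduplicates sample and control libraries, clusters
#' tag-anchored evidence, applies the three candidate criteria, computes
#' enrichment scores with per-direction RPM normalization, locates the
#' spacer/PAM match at each passing cluster, and ranks passing sites.
#'
#' @param aln sample alignments annotated with `umi`, `primer_id`, `side`,
#'   `ext_ok` (see [read_alignments()] with [prep_reads()] annotations).
#' @param wt_aln wild-type control alignments, annotated likewise.
#' @param ref `peac_reference`.
#' @param spacer 20-nt spacer.
#' @param config a [call_config()].
#' @return list with `sites` (ranked passing sites) and `audit` (every
#'   cluster with per-criterion verdicts).
#' @export
call_sites <- function(aln, wt_aln, ref, spacer, config = call_config()) {
  ded <- deduplicate_reads(aln)
  wt_ded <- deduplicate_reads(wt_aln)
  clusters <- cluster_cut_sites(ded, config$window)
  clusters <- apply_candidate_filters(clusters, wt_ded, config)
  dedp <- ded[!is.na(ded$side), , drop = FALSE]
  lib_f <- sum(dedp$side == "F")
  lib_r <- sum(dedp$side == "R")
  clusters$peac_score <- compute_peac_score(clusters$ext_fwd,
                                            clusters$ext_rev,
                                            max(lib_f, 1L), max(lib_r, 1L))
  passing <- clusters[clusters$pass, , drop = FALSE]
  if (nrow(passing)) {
    matches <- lapply(passing$cut_pos, function(cp) {
      m <- match_spacer(ref, cp, spacer, config$search_window,
                        config$max_mm_spacer)
      if (is.null(m)) {
        m <- data.frame(match_start = NA_integer_, match_end = NA_integer_,
                        spacer_start = NA_integer_,
                        spacer_end = NA_integer_,
                        match_strand = NA_character_,
                        matched_seq = NA_character_, pam = NA_character_,
                        pam_variant = NA, n_mismatch = NA_integer_,
                        implied_cut = NA_integer_,
                        stringsAsFactors = FALSE)
        m$mismatch_positions <- list(integer(0))
      }
      m
    })
    passing <- cbind(passing, do.call(rbind, matches))
  } else {
    passing$match_start <- integer(0)
    passing$match_end <- integer(0)
    passing$spacer_start <- integer(0)
    passing$spacer_end <- integer(0)
    passing$match_strand <- character(0)
    passing$matched_seq <- character(0)
    passing$pam <- character(0)
    passing$pam_variant <- logical(0)
    passing$n_mismatch <- integer(0)
    passing$implied_cut <- integer(0)
    passing$mismatch_positions <- list()
  }
  sites <- rank_sites(passing)
  list(sites = sites, audit = clusters,
       lib_sizes = c(F = lib_f, R = lib_r))
}
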