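#' Default tag-truncation length distribution
#'
#' Reverse transcription of the insertion tag can terminate early, so both
#' partial and full-length insertion products exist. The default places 60%
#' of the mass on the full 21-nt product and spreads the remainder uniformly
#' over retained lengths 6..20 (truncation removes tag 3' bases).
#'
#' @return named numeric vector over retained lengths "0".."21", summing
#'   to 1.
#' @export
default_truncation_dist <- function() {
  d <- setNames(numeric(22), as.character(0:21))
  d["21"] <- 0.6
  d[as.character(6:20)] <- 0.4 / 15
  d
}

#' Simulation library parameters
#'
#' Bundles the knobs of the library simulator. Rates are per-molecule or
#' per-base probabilities; lengths are in bases.
#'
#' @param n_fragments number of unique molecules (read pairs before PCR
#'   duplication).
#' @param frag_len_mean,frag_len_sd,frag_len_min truncated-normal
#'   tagmentation fragment length model.
#' @param read_len read length of both mates.
#' @param umi_len UMI length (first bases of the Tn5-side mate).
#' @param umi_spacer fixed spacer sequence following the UMI.
#' @param seq_error_rate per-base substitution error probability.
#' @param tag_truncation_dist probability vector over retained tag lengths
#'   0..21 (see [default_truncation_dist()]).
#' @param random_priming_rate fraction of read pairs arising from enrichment
#'   primers mis-annealing at non-tag genomic loci.
#' @param background_rate fraction of read pairs with no primer sequence at
#'   all (carry-through fragments).
#' @param fwd_fraction molar fraction of the forward-primer sub-library.
#' @param pcr_duplicates each molecule is sequenced this many times.
#' @param primers_used primer ids used for enrichment (one forward and one
#'   reverse by default).
#' @param n_junction_reads size of the nested-PCR/UDiTaS-style junction
#'   sub-library (emitted only when junctions are specified).
#' @param seed RNG seed; all randomness in the simulator derives from it.
#' @return an object of class `peac_library_params`.
#' @export
library_params <- function(n_fragments = 50000L, frag_len_mean = 350,
                           frag_len_sd = 80, frag_len_min = 80L,
                           read_len = 150L, umi_len = 10L,
                           umi_spacer = "CAGT", seq_error_rate = 0,
                           tag_truncation_dist = default_truncation_dist(),
                           random_priming_rate = 0, background_rate = 0.02,
                           fwd_fraction = 0.5, pcr_duplicates = 1L,
                           primers_used = c("F1", "R2"),
                           n_junction_reads = 3000L, seed = 1L) {
  rates <- c(seq_error_rate, random_priming_rate, background_rate,
             fwd_fraction)
  if (any(rates < 0 | rates > 1)) stop_param("rates must be in [0, 1]")
  if (abs(sum(tag_truncation_dist) - 1) > 1e-8) {
    stop_param("tag_truncation_dist must sum to 1")
  }
  if (length(tag_truncation_dist) != 22L) {
    stop_param("tag_truncation_dist must cover retained lengths 0..21")
  }
  if (pcr_duplicates < 1L) stop_param("pcr_duplicates must be >= 1")
  structure(list(
    n_fragments = as.integer(n_fragments), frag_len_mean = frag_len_mean,
    frag_len_sd = frag_len_sd, frag_len_min = as.integer(frag_len_min),
    read_len = as.integer(read_len), umi_len = as.integer(umi_len),
    umi_spacer = umi_spacer, seq_error_rate = seq_error_rate,
    tag_truncation_dist = tag_truncation_dist,
    random_priming_rate = random_priming_rate,
    background_rate = background_rate, fwd_fraction = fwd_fraction,
    pcr_duplicates = as.integer(pcr_duplicates),
    primers_used = primers_used,
    n_junction_reads = as.integer(n_junction_reads),
    seed = as.integer(seed)
  ), class = "peac_library_params")
}

#' Specify a planted DSB-end join (translocation) event
#'
#' The five join models: (i) receiver ends religated with the tag inserted
#' (the intended edit); (ii) receiver ends religated without tag
#' (indel-only); (iii) a distal donor's upstream end joined, without tag;
#' (iv) a donor's downstream end joined; (v) a donor's tag-carrying upstream
#' end joined, which places the tag in reverse orientation relative to the
#' receiver and creates the unexpected-upstream enrichment signal.
#'
#' @param receiver,donor site ids (`site_id` from [plant_sites()]); equal
#'   for models i/ii.
#' @param model one of "i", "ii", "iii", "iv", "v".
#' @param rate fraction of receiver-cut molecules participating.
#' @return one-row data.frame; rows can be `rbind`-ed into a junction set.
#' @export
junction_spec <- function(receiver, donor, model, rate) {
  model <- match.arg(model, c("i", "ii", "iii", "iv", "v"))
  if (model %in% c("i", "ii") && receiver != donor) {
    stop_param("models i/ii join ends of the same receiver site")
  }
  if (model %in% c("iii", "iv", "v") && receiver == donor) {
    stop_param("models iii/iv/v need a distal donor site")
  }
  if (rate < 0 || rate > 1) stop_param("rate must be in [0, 1]")
  data.frame(junction_id = NA_character_, receiver = receiver,
             donor = donor, model = model,
             tag_present = model %in% c("i", "v"), rate = rate,
             stringsAsFactors = FALSE)
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

## Draw truncation lengths conditioned on the primer annealing region being
## retained (molecules whose tag is shorter never amplify with this primer).
draw_tag_len <- function(n, dist, min_len) {
  if (n == 0L) return(integer(0))
  lens <- as.integer(names(dist))
  keep <- lens >= min_len
  if (!any(keep) || sum(dist[keep]) <= 0) {
    stop_param("tag truncation distribution leaves no amplifiable molecules",
               " for a primer needing >= ", min_len, " retained bases")
  }
  sample(lens[keep], n, replace = TRUE, prob = dist[keep])
}

## Random-priming locus pool for one primer: genomic positions whose
## sequence matches the primer's 8 3'-terminal bases, the partial-annealing
## artifact the extension filter is designed to remove. Loci whose genome
## continues with the tag's own extension bases are excluded: reads from
## such loci are signal mimics, not removable artifacts, and would make the
## truth ledger's random-priming label incoherent. If the reference happens
## to contain too few qualifying loci, uniformly drawn loci stand in for
## weaker mis-annealing events.
rp_locus_pool <- function(ref, primer_row, margin = 500L, min_pool = 5L) {
  primer_seq <- primer_row$seq
  last8 <- substr(primer_seq, nchar(primer_seq) - 7L, nchar(primer_seq))
  subj <- Biostrings::DNAString(ref$seq)
  fwd <- Biostrings::start(Biostrings::matchPattern(last8, subj)) - 1L
  rev <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(last8)), subj)) - 1L
  pool <- data.frame(cut = c(fwd + 8L, rev),
                     dir = rep(c(1L, -1L), c(length(fwd), length(rev))))
  ok <- pool$cut > margin & pool$cut < ref$length - margin
  pool <- pool[ok, , drop = FALSE]
  mimics <- function(p) {
    w <- primer_row$boundary_offset
    nxt <- ifelse(p$dir == 1L,
                  ref_substr(ref$seq, p$cut, p$cut + w),
                  revcomp(ref_substr(ref$seq, p$cut - w, p$cut)))
    nxt == substr(primer_row$expected_ext, 1L, w)
  }
  if (nrow(pool)) pool <- pool[!mimics(pool), , drop = FALSE]
  while (nrow(pool) < min_pool) {
    extra <- data.frame(
      cut = margin + sample.int(ref$length - 2L * margin,
                                min_pool - nrow(pool)),
      dir = sample(c(1L, -1L), min_pool - nrow(pool), replace = TRUE))
    pool <- rbind(pool, extra[!mimics(extra), , drop = FALSE])
  }
  pool
}

inject_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  nc <- nchar(reads)
  total <- sum(nc)
  hit <- which(runif(total) < rate)
  if (length(hit) == 0L) return(reads)
  read_idx <- findInterval(hit - 1L, cumsum(c(0L, nc)),
                           rightmost.closed = FALSE)
  pos <- hit - cumsum(c(0L, nc))[read_idx]
  for (r in unique(read_idx)) {
    chars <- strsplit(reads[r], "")[[1L]]
    for (p in pos[read_idx == r]) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    reads[r] <- paste(chars, collapse = "")
  }
  reads
}

#' Simulate a tag-enrichment sequencing library with ground truth
#'
#' Emits paired FASTQ files emulating the two enrichment sub-libraries
#' (forward-primer amplicons reading tag-to-downstream genome, reverse-primer
#' amplicons reading tag-to-upstream genome), a truth SAM with the error-free
#' intended alignment of every genomic segment, and a per-read truth ledger.
#' Random-priming pairs carry a genuine primer sequence followed by genomic
#' (non-tag) bases; background pairs carry no primer. When junction specs are
#' given, model-(v) joins contribute unexpected-upstream amplicons to the
#' main library and a separate nested-PCR/UDiTaS-style junction sub-library
#' (split reads across the breakpoints) is emitted alongside.
#'
#' @param ref `peac_reference` (after [plant_sites()]).
#' @param sites site table from [plant_sites()], or `NULL` for a site-free
#'   library.
#' @param tag `peac_tag_design`.
#' @param params `peac_library_params`.
#' @param junctions optional junction set (rbind of [junction_spec()] rows).
#' @param out_dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return list with `paths` (named file paths) and `truth` (per-read
#'   ledger, realized site counts, junction ledger).
#' @export
simulate_library <- function(ref, sites, tag, params, junctions = NULL,
                             out_dir, prefix = "sample") {
  stopifnot(inherits(ref, "peac_reference"),
            inherits(tag, "peac_tag_design"),
            inherits(params, "peac_library_params"))
  if (!is.null(junctions) && nrow(junctions) > 0 &&
      (is.null(sites) || nrow(sites) == 0L)) {
    stop_param("junctions reference sites but the site list is empty")
  }
  pr <- tag$primers
  used <- pr[pr$primer_id %in% params$primers_used, , drop = FALSE]
  if (nrow(used) == 0L) stop_param("no usable primers in primers_used")
  longest <- max(nchar(pr$seq))
  if (params$read_len < params$umi_len + longest + 2L) {
    stop_param("read_len must be >= umi_len + longest primer + 2")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(params$seed, {
    sim_core(ref, sites, tag, params, junctions, out_dir, prefix)
  })
}

#' Simulate a wild-type control library
#'
#' Background-only library with no tag insertions: random-priming pairs (if
#' `random_priming_rate > 0`) plus primer-free background fragments. No read
#' can pass extension verification other than by genomic coincidence.
#'
#' @inheritParams simulate_library
#' @return as [simulate_library()].
#' @export
simulate_wt_control <- function(ref, tag, params, out_dir, prefix = "wt") {
  simulate_library(ref, sites = NULL, tag = tag, params = params,
                   junctions = NULL, out_dir = out_dir, prefix = prefix)
}

sim_core <- function(ref, sites, tag, params, junctions, out_dir, prefix) {
  n <- params$n_fragments
  read_len <- params$read_len
  no_sites <- is.null(sites) || nrow(sites) == 0L

  if (!is.null(junctions) && nrow(junctions)) {
    junctions$junction_id <- sprintf("J%02d", seq_len(nrow(junctions)))
    bad <- !(junctions$receiver %in% sites$site_id) |
      !(junctions$donor %in% sites$site_id)
    if (any(bad)) stop_param("junction references unknown site id")
  }

  ## ---- origin categories ----
  p_rp <- params$random_priming_rate
  p_bg <- params$background_rate
  cats <- data.frame(origin = character(0), kind = character(0),
                     site = character(0), donor = character(0),
                     prob = numeric(0), stringsAsFactors = FALSE)
  if (p_rp > 0) cats <- rbind(cats, data.frame(
    origin = "random_priming", kind = "rp", site = NA, donor = NA,
    prob = p_rp))
  site_mass <- 1 - p_rp - p_bg
  if (!no_sites) {
    w <- sites$edit_rate * sites$insertion_rate
    jv <- if (!is.null(junctions) && nrow(junctions)) {
      junctions[junctions$model == "v", , drop = FALSE]
    } else {
      data.frame(junction_id = character(0), receiver = character(0),
                 donor = character(0), rate = numeric(0),
                 stringsAsFactors = FALSE)
    }
    rv <- setNames(numeric(nrow(sites)), sites$site_id)
    if (nrow(jv)) for (k in seq_len(nrow(jv))) {
      rv[jv$receiver[k]] <- rv[jv$receiver[k]] + jv$rate[k]
    }
    wsite <- w * (1 - rv[sites$site_id])
    wj <- if (nrow(jv)) {
      w[match(jv$receiver, sites$site_id)] * jv$rate
    } else numeric(0)
    tot <- sum(wsite) + sum(wj)
    if (tot > 0) {
      if (any(wsite > 0)) cats <- rbind(cats, data.frame(
        origin = paste0("site:", sites$site_id[wsite > 0]), kind = "site",
        site = sites$site_id[wsite > 0], donor = NA,
        prob = site_mass * wsite[wsite > 0] / tot))
      if (length(wj) && any(wj > 0)) cats <- rbind(cats, data.frame(
        origin = paste0("junction:", jv$junction_id[wj > 0]), kind = "vjunc",
        site = jv$receiver[wj > 0], donor = jv$donor[wj > 0],
        prob = site_mass * wj[wj > 0] / tot))
    } else {
      site_mass <- 0
    }
  } else {
    site_mass <- 0
  }
  cats <- rbind(cats, data.frame(
    origin = "background", kind = "bg", site = NA, donor = NA,
    prob = max(0, 1 - p_rp - site_mass)))

  ci <- sample.int(nrow(cats), n, replace = TRUE, prob = cats$prob)
  kind <- cats$kind[ci]
  origin <- cats$origin[ci]
  anchor_site <- cats$site[ci]
  donor_site <- cats$donor[ci]

  side <- ifelse(runif(n) < params$fwd_fraction, "F", "R")
  side[kind == "bg"] <- NA

  ## primer per read
  used <- tag$primers[tag$primers$primer_id %in% params$primers_used, ,
                      drop = FALSE]
  fwd_rows <- which(used$side == "forward")
  rev_rows <- which(used$side == "reverse")
  if (length(fwd_rows) == 0L || length(rev_rows) == 0L) {
    stop_param("primers_used must include at least one forward and one ",
               "reverse primer")
  }
  pick <- function(rows, m) rows[sample.int(length(rows), m, replace = TRUE)]
  prow <- rep(NA_integer_, n)
  isF <- !is.na(side) & side == "F"
  isR <- !is.na(side) & side == "R"
  prow[isF] <- pick(fwd_rows, sum(isF))
  prow[isR] <- pick(rev_rows, sum(isR))
  primer_id <- ifelse(is.na(prow), NA_character_, used$primer_id[prow])
  primer_seq <- ifelse(is.na(prow), "", used$seq[prow])
  primer_bo <- ifelse(is.na(prow), NA_integer_, used$boundary_offset[prow])
  primer_min <- ifelse(is.na(prow), NA_integer_, used$min_tag_len[prow])
  primer_side <- ifelse(is.na(prow), NA_character_, used$side[prow])

  ## geometry: anchor cut and read1 direction
  cut <- rep(NA_integer_, n)
  dir <- rep(NA_integer_, n)
  tag_len <- rep(NA_integer_, n)
  margin <- read_len + 50L

  is_tagread <- kind %in% c("site", "vjunc")
  if (any(is_tagread)) {
    scut <- setNames(sites$cut, sites$site_id)
    sstr <- setNames(sites$strand, sites$site_id)
    ## effective tag-frame strand at the read's anchor
    eff_site <- anchor_site
    eff_strand <- sstr[eff_site]
    vF <- kind == "vjunc" & side == "F"
    vR <- kind == "vjunc" & side == "R"
    eff_strand[vF] <- flip_strand(sstr[anchor_site[vF]])
    eff_site[vR] <- donor_site[vR]
    eff_strand[vR] <- sstr[donor_site[vR]]
    cut[is_tagread] <- scut[eff_site[is_tagread]]
    anchor_site[is_tagread] <- eff_site[is_tagread]
    dir[is_tagread] <- ifelse(
      (eff_strand[is_tagread] == "+") == (side[is_tagread] == "F"), 1L, -1L)
    ## truncation conditioned on primer annealing
    for (pid in unique(primer_id[is_tagread])) {
      sel <- is_tagread & primer_id == pid
      tag_len[sel] <- draw_tag_len(sum(sel), params$tag_truncation_dist,
                                   primer_min[sel][1])
    }
  }
  is_rp <- kind == "rp"
  if (any(is_rp)) {
    for (pid in unique(primer_id[is_rp])) {
      sel <- which(is_rp & primer_id == pid)
      pool <- rp_locus_pool(ref, used[match(pid, used$primer_id), ],
                            margin = margin)
      k <- pool[sample.int(nrow(pool), length(sel), replace = TRUE), ]
      cut[sel] <- k$cut
      dir[sel] <- k$dir
    }
  }
  is_bg <- kind == "bg"
  if (any(is_bg)) {
    m <- sum(is_bg)
    cut[is_bg] <- margin + sample.int(ref$length - 2L * margin, m,
                                      replace = TRUE)
    dir[is_bg] <- sample(c(1L, -1L), m, replace = TRUE)
  }

  ## extension-boundary integrity: for forward primers the verification
  ## window sits at the truncation-prone tag 3' boundary
  ext_intact <- rep(FALSE, n)
  fwd_tag <- is_tagread & primer_side == "forward"
  rev_tag <- is_tagread & primer_side == "reverse"
  ext_intact[fwd_tag] <- tag_len[fwd_tag] >= primer_min[fwd_tag] +
    primer_bo[fwd_tag]
  ext_intact[rev_tag] <- TRUE

  ## read-1 prefix (primer + retained tag remnant)
  prefix1 <- character(n)
  if (any(fwd_tag)) {
    prefix1[fwd_tag] <- paste0(
      primer_seq[fwd_tag],
      substr(rep(tag$tag_seq, sum(fwd_tag)), primer_min[fwd_tag] + 1L,
             tag_len[fwd_tag]))
  }
  if (any(rev_tag)) {
    prefix1[rev_tag] <- paste0(primer_seq[rev_tag],
                               revcomp(substr(rep(tag$tag_seq, sum(rev_tag)),
                                              1L, primer_bo[rev_tag])))
  }
  prefix1[is_rp] <- primer_seq[is_rp]

  ## fragment length (tag boundary to Tn5 cut), clamped to the reference
  d <- pmax(params$frag_len_min,
            as.integer(round(rnorm(n, params$frag_len_mean,
                                   params$frag_len_sd))))
  avail <- ifelse(dir == 1L, ref$length - cut - 1L, cut - 1L)
  d <- pmin(d, avail)

  g1 <- pmin(read_len - nchar(prefix1), d)
  g2 <- pmin(read_len - params$umi_len - nchar(params$umi_spacer), d)

  fwd1 <- dir == 1L
  genomic1 <- character(n)
  genomic1[fwd1] <- ref_substr(ref$seq, cut[fwd1], cut[fwd1] + g1[fwd1])
  genomic1[!fwd1] <- revcomp(ref_substr(ref$seq, cut[!fwd1] - g1[!fwd1],
                                        cut[!fwd1]))
  genomic2 <- character(n)
  genomic2[fwd1] <- revcomp(ref_substr(ref$seq, cut[fwd1] + d[fwd1] -
                                         g2[fwd1], cut[fwd1] + d[fwd1]))
  genomic2[!fwd1] <- ref_substr(ref$seq, cut[!fwd1] - d[!fwd1],
                                cut[!fwd1] - d[!fwd1] + g2[!fwd1])

  umi <- random_dna(n, params$umi_len)
  read1 <- paste0(prefix1, genomic1)
  read2 <- paste0(umi, params$umi_spacer, genomic2)

  ## PCR duplication: each molecule sequenced pcr_duplicates times
  k <- params$pcr_duplicates
  mol <- rep(seq_len(n), each = k)
  N <- n * k
  ids <- make_read_ids(prefix, N)
  r1 <- inject_errors(read1[mol], params$seq_error_rate)
  r2 <- inject_errors(read2[mol], params$seq_error_rate)

  paths <- list(
    fq1 = file.path(out_dir, paste0(prefix, "_R1.fastq")),
    fq2 = file.path(out_dir, paste0(prefix, "_R2.fastq")),
    sam = file.path(out_dir, paste0(prefix, ".sam"))
  )
  write_fastq_pair(r1, r2, ids, paths$fq1, paths$fq2)

  ## truth SAM (error-free intended alignments of the genomic portions)
  cutm <- cut[mol]; dm <- d[mol]; g1m <- g1[mol]; g2m <- g2[mol]
  dirm <- dir[mol]
  pos1 <- ifelse(dirm == 1L, cutm + 1L, cutm - g1m + 1L)
  pos2 <- ifelse(dirm == 1L, cutm + dm - g2m + 1L, cutm - dm + 1L)
  seq1 <- ifelse(dirm == 1L,
                 ref_substr(ref$seq, cutm, cutm + g1m),
                 ref_substr(ref$seq, cutm - g1m, cutm))
  seq2 <- ifelse(dirm == 1L,
                 ref_substr(ref$seq, cutm + dm - g2m, cutm + dm),
                 ref_substr(ref$seq, cutm - dm, cutm - dm + g2m))
  flag1 <- 1L + 2L + 64L + ifelse(dirm == 1L, 32L, 16L)
  flag2 <- 1L + 2L + 128L + ifelse(dirm == 1L, 16L, 32L)
  umim <- umi[mol]
  rec <- data.frame(
    qname = rep(ids, 2L),
    flag = c(flag1, flag2),
    rname = ref$name,
    pos = c(pos1, pos2),
    mapq = 60L,
    cigar = c(paste0(g1m, "M"), paste0(g2m, "M")),
    rnext = "=",
    pnext = c(pos2, pos1),
    tlen = c(dirm * dm, -dirm * dm),
    seq = c(seq1, seq2),
    tags = paste0("RX:Z:", rep(umim, 2L)),
    stringsAsFactors = FALSE
  )
  ord <- order(rep(seq_len(N), 2L))
  write_sam(rec[ord, ], ref, paths$sam)

  per_read <- data.frame(
    read_id = ids,
    molecule_id = mol,
    origin = origin[mol],
    kind = kind[mol],
    anchor_site = anchor_site[mol],
    side = side[mol],
    primer_id = primer_id[mol],
    umi = umim,
    tag_len = tag_len[mol],
    ext_intact = ext_intact[mol],
    cut = cutm,
    dir = dirm,
    frag_start = ifelse(dirm == 1L, cutm, cutm - dm),
    frag_end = ifelse(dirm == 1L, cutm + dm, cutm),
    stringsAsFactors = FALSE
  )

  site_truth <- NULL
  if (!no_sites) {
    site_truth <- sites
    tab <- function(f) {
      as.integer(table(factor(per_read$anchor_site[f],
                              levels = sites$site_id)))
    }
    from_site <- per_read$kind == "site"
    site_truth$n_pairs <- tab(from_site)
    site_truth$n_molecules <- {
      u <- unique(per_read[from_site, c("molecule_id", "anchor_site")])
      as.integer(table(factor(u$anchor_site, levels = sites$site_id)))
    }
    site_truth$n_pairs_F <- tab(from_site & per_read$side == "F")
    site_truth$n_pairs_R <- tab(from_site & per_read$side == "R")
    site_truth$n_ext_intact <- tab(from_site & per_read$ext_intact)
  }

  jx <- NULL
  if (!is.null(junctions) && nrow(junctions)) {
    jx <- simulate_junction_library(ref, sites, tag, params, junctions,
                                    out_dir, prefix)
    paths <- c(paths, jx$paths)
  }

  truth <- list(per_read = per_read, sites = site_truth,
                junctions = if (is.null(jx)) NULL else jx$junctions,
                junction_reads = if (is.null(jx)) NULL else jx$per_read)
  write_truth_tables(truth, out_dir, prefix)
  list(paths = paths, truth = truth, params = params)
}

write_truth_tables <- function(truth, out_dir, prefix) {
  wt <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    df2 <- df
    if (!is.null(df2$mismatch_positions) &&
        is.list(df2$mismatch_positions)) {
      df2$mismatch_positions <- vapply(df2$mismatch_positions,
                                       paste, character(1), collapse = ",")
    }
    write.table(df2, file.path(out_dir, paste0(prefix, "_", name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(truth$per_read, "truth_reads")
  wt(truth$sites, "truth_sites")
  wt(truth$junctions, "truth_junctions")
  wt(truth$junction_reads, "truth_junction_reads")
  invisible(NULL)
}

## Nested-PCR / UDiTaS-style junction sub-library: every read is anchored in
## the receiver's upstream flank and reads across the join into the partner
## sequence. Emitted as single-end FASTQ plus a truth SAM whose split reads
## carry a primary (receiver-side) and a supplementary (partner-side)
## alignment.
simulate_junction_library <- function(ref, sites, tag, params, junctions,
                                      out_dir, prefix) {
  scut <- setNames(sites$cut, sites$site_id)
  sstr <- setNames(sites$strand, sites$site_id)
  sins <- setNames(sites$insertion_rate, sites$site_id)
  read_len <- params$read_len
  receivers <- unique(junctions$receiver)
  budget <- max(1L, params$n_junction_reads %/% length(receivers))

  rows <- list()
  for (rcv in receivers) {
    js <- junctions[junctions$receiver == rcv, , drop = FALSE]
    n_j <- pmax(1L, as.integer(round(js$rate * budget)))
    rem <- max(0L, budget - sum(n_j))
    n_tag <- as.integer(round(rem * sins[rcv]))
    n_plain <- rem - n_tag
    typ <- c(rep(js$junction_id, n_j),
             rep("normal_tag", n_tag), rep("normal_plain", n_plain))
    rows[[rcv]] <- data.frame(receiver = rcv, type = typ,
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  n <- nrow(tab)
  jidx <- match(tab$type, junctions$junction_id)
  model <- ifelse(is.na(jidx), ifelse(tab$type == "normal_tag",
                                      "normal_tag", "normal_plain"),
                  junctions$model[jidx])
  donor <- ifelse(is.na(jidx), tab$receiver, junctions$donor[jidx])
  tag_present <- model %in% c("i", "v", "normal_tag")
  tag_rev <- model == "v"

  u <- sample(40:70, n, replace = TRUE)
  d1 <- ifelse(model == "ii", sample(1:3, n, replace = TRUE), 0L)
  d2 <- ifelse(model == "ii", sample(1:3, n, replace = TRUE), 0L)
  tl <- rep(NA_integer_, n)
  if (any(tag_present)) {
    tl[tag_present] <- draw_tag_len(sum(tag_present),
                                    params$tag_truncation_dist, 0L)
  }
  gap <- character(n)
  fwd_gap <- tag_present & !tag_rev
  gap[fwd_gap] <- substr(rep(tag$tag_seq, sum(fwd_gap)), 1L, tl[fwd_gap])
  gap[tag_rev] <- revcomp(substr(rep(tag$tag_seq, sum(tag_rev)), 1L,
                                 tl[tag_rev]))
  seg1_len <- u - d1
  v <- read_len - seg1_len - nchar(gap)

  rcut <- scut[tab$receiver]
  rstr <- sstr[tab$receiver]
  dcut <- scut[donor]
  dstr <- sstr[donor]

  seg1_seq <- character(n)
  part_seq <- character(n)
  seg1_start <- seg1_end <- seg2_start <- seg2_end <- integer(n)
  seg2_strand <- character(n)
  for (i in seq_len(n)) {
    if (rstr[i] == "+") {
      seg1_start[i] <- rcut[i] - u[i]
      seg1_end[i] <- rcut[i] - d1[i]
      seg1_seq[i] <- ref_substr(ref$seq, seg1_start[i], seg1_end[i])
    } else {
      seg1_start[i] <- rcut[i] + d1[i]
      seg1_end[i] <- rcut[i] + u[i]
      seg1_seq[i] <- revcomp(ref_substr(ref$seq, seg1_start[i], seg1_end[i]))
    }
    m <- model[i]
    if (m %in% c("i", "ii", "normal_tag", "normal_plain")) {
      if (rstr[i] == "+") {
        seg2_start[i] <- rcut[i] + d2[i]
        seg2_end[i] <- seg2_start[i] + v[i]
        part_seq[i] <- ref_substr(ref$seq, seg2_start[i], seg2_end[i])
        seg2_strand[i] <- "+"
      } else {
        seg2_end[i] <- rcut[i] - d2[i]
        seg2_start[i] <- seg2_end[i] - v[i]
        part_seq[i] <- revcomp(ref_substr(ref$seq, seg2_start[i],
                                          seg2_end[i]))
        seg2_strand[i] <- "-"
      }
    } else if (m %in% c("iii", "v")) {
      if (dstr[i] == "+") {
        seg2_start[i] <- dcut[i] - v[i]
        seg2_end[i] <- dcut[i]
        part_seq[i] <- revcomp(ref_substr(ref$seq, seg2_start[i],
                                          seg2_end[i]))
        seg2_strand[i] <- "-"
      } else {
        seg2_start[i] <- dcut[i]
        seg2_end[i] <- dcut[i] + v[i]
        part_seq[i] <- ref_substr(ref$seq, seg2_start[i], seg2_end[i])
        seg2_strand[i] <- "+"
      }
    } else if (m == "iv") {
      if (dstr[i] == "+") {
        seg2_start[i] <- dcut[i]
        seg2_end[i] <- dcut[i] + v[i]
        part_seq[i] <- ref_substr(ref$seq, seg2_start[i], seg2_end[i])
        seg2_strand[i] <- "+"
      } else {
        seg2_end[i] <- dcut[i]
        seg2_start[i] <- dcut[i] - v[i]
        part_seq[i] <- revcomp(ref_substr(ref$seq, seg2_start[i],
                                          seg2_end[i]))
        seg2_strand[i] <- "-"
      }
    }
  }
  readseq <- paste0(seg1_seq, gap, part_seq)
  readseq <- inject_errors(readseq, params$seq_error_rate)
  ids <- make_read_ids(paste0(prefix, "-jx"), n)

  ## split unless the read is a contiguous normal join
  contiguous <- model == "normal_plain"
  primary_rev <- rstr == "-"
  qpre <- seg1_len + nchar(gap)       # query offset of the partner segment

  recs <- list()
  for (i in seq_len(n)) {
    if (contiguous[i]) {
      seqf <- if (rstr[i] == "+") readseq[i] else revcomp(readseq[i])
      recs[[length(recs) + 1L]] <- data.frame(
        qname = ids[i], flag = ifelse(primary_rev[i], 16L, 0L),
        rname = ref$name, pos = min(seg1_start[i], seg2_start[i]) + 1L,
        mapq = 60L, cigar = paste0(nchar(readseq[i]), "M"),
        rnext = "*", pnext = 0L, tlen = 0L, seq = seqf, tags = "",
        stringsAsFactors = FALSE)
      next
    }
    rest <- nchar(readseq[i]) - seg1_len[i]
    cig1 <- if (!primary_rev[i]) paste0(seg1_len[i], "M", rest, "S") else
      paste0(rest, "S", seg1_len[i], "M")
    seq1 <- if (!primary_rev[i]) readseq[i] else revcomp(readseq[i])
    supp_rev <- seg2_strand[i] == "-"
    cig2 <- if (!supp_rev) paste0(qpre[i], "S", v[i], "M") else
      paste0(v[i], "M", qpre[i], "S")
    recs[[length(recs) + 1L]] <- data.frame(
      qname = rep(ids[i], 2L),
      flag = c(ifelse(primary_rev[i], 16L, 0L),
               2048L + ifelse(supp_rev, 16L, 0L)),
      rname = ref$name,
      pos = c(seg1_start[i] + 1L, seg2_start[i] + 1L),
      mapq = 60L,
      cigar = c(cig1, cig2),
      rnext = "*", pnext = 0L, tlen = 0L,
      seq = c(seq1, "*"), tags = "",
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, recs)
  paths <- list(
    jx_fq = file.path(out_dir, paste0(prefix, "_junctions.fastq")),
    jx_sam = file.path(out_dir, paste0(prefix, "_junctions.sam"))
  )
  write_fastq(readseq, ids, paths$jx_fq)
  write_sam(rec, ref, paths$jx_sam)

  per_read <- data.frame(
    read_id = ids, origin = ifelse(is.na(jidx), model,
                                   paste0("junction:", tab$type)),
    receiver = tab$receiver, donor = donor, model = model,
    tag_present = tag_present, tag_len = tl, u = u, v = v,
    seg2_start = seg2_start, seg2_end = seg2_end,
    seg2_strand = seg2_strand, stringsAsFactors = FALSE
  )
  jt <- junctions
  jt$n_reads <- as.integer(table(factor(per_read$origin,
    levels = paste0("junction:", junctions$junction_id))))
  jt$n_normal_receiver <- vapply(jt$receiver, function(rcv) {
    sum(per_read$receiver == rcv &
          per_read$model %in% c("normal_tag", "normal_plain", "i", "ii"))
  }, integer(1))
  list(paths = paths, per_read = per_read, junctions = jt)
}
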