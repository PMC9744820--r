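#' Generate a random reference sequence
#'
#' Creates a synthetic chromosome used as the coordinate frame for planting
#' protospacer sites and simulating libraries. Bases are drawn i.i.d. with the
#' requested GC content, so the sequence stands in for a genome without
#' repeats or chromatin structure.
#'
#' @param length sequence length in bases (> 0).
#' @param gc target GC fraction, strictly between 0 and 1.
#' @param seed integer RNG seed; the same seed always yields the same
#'   sequence.
#' @param name chromosome label.
#' @return an object of class `peac_reference`: a list with elements `name`,
#'   `seq` (character scalar over A/C/G/T) and `length`.
#' @examples
#' ref <- generate_reference(10000, gc = 0.5, seed = 7)
#' nchar(ref$seq)
#' @export
generate_reference <- function(length, gc = 0.5, seed = 1L, name = "chrS") {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length <= 0) {
    stop_param("'length' must be a single positive number")
  }
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) {
    stop_param("'gc' must be strictly between 0 and 1")
  }
  length <- as.integer(length)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- withr::with_seed(as.integer(seed), {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  })
  structure(list(name = name, seq = seq, length = length),
            class = "peac_reference")
}

#' @export
print.peac_reference <- function(x, ...) {
  cat(sprintf("<peac_reference> %s: %d bp (GC %.3f)\n", x$name, x$length,
              gc_fraction(x)))
  invisible(x)
}

#' GC fraction of a reference
#' @param ref a `peac_reference`.
#' @return numeric scalar in \[0, 1\].
#' @export
gc_fraction <- function(ref) {
  f <- Biostrings::letterFrequency(Biostrings::DNAString(ref$seq), "GC")
  as.numeric(f) / ref$length
}

## Protospacer cut offset: blunt cut between spacer positions 17/18,
## i.e. 3 bp upstream of the PAM.
CUT_OFFSET <- 17L

site_cut_pos <- function(start0, strand) {
  ifelse(strand == "+", start0 + CUT_OFFSET, start0 + (20L - CUT_OFFSET))
}

#' Plant an on-target site and mismatched off-target sites into a reference
#'
#' Writes the 20-nt protospacer (with the requested number of mismatches
#' relative to `spacer`) followed by an NGG PAM into non-overlapping loci of
#' the reference, on random strands. The on-target site (0 mismatches) is
#' always planted first. The blunt Cas9 cut is modeled between protospacer
#' positions 17 and 18 (3 bp upstream of the PAM).
#'
#' @param ref a `peac_reference` from [generate_reference()].
#' @param spacer 20-nt on-target spacer sequence (5' to 3').
#' @param n_offtargets number of off-target variants to plant.
#' @param mismatch_counts integer vector (recycled to `n_offtargets`) of
#'   mismatch counts per off-target, each in 0..8.
#' @param seed integer RNG seed.
#' @param min_gap minimum distance in bases between planted cut positions.
#' @param margin distance kept free at both reference ends.
#' @param edit_rates fraction of molecules cut at each site (recycled over
#'   all sites, on-target first). Default decays with mismatch count.
#' @param insertion_rates fraction of edited molecules that carry the tag
#'   insertion (recycled likewise). Default 0.3.
#' @return a list with `ref` (the modified reference) and `sites`, a
#'   data.frame with 0-based half-open protospacer coordinates, strand, PAM,
#'   planted mismatch positions (list column, spacer positions 1-20 5'->3'),
#'   cut position and per-site rates.
#' @export
plant_sites <- function(ref, spacer, n_offtargets = 0L,
                        mismatch_counts = integer(0), seed = 1L,
                        min_gap = 2000L, margin = 2000L,
                        edit_rates = NULL, insertion_rates = 0.3) {
  stopifnot(inherits(ref, "peac_reference"))
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L || grepl("[^ACGT]", spacer)) {
    stop_param("'spacer' must be a 20-nt ACGT string")
  }
  n_offtargets <- as.integer(n_offtargets)
  if (n_offtargets > 0L) {
    if (length(mismatch_counts) == 0L) {
      stop_param("'mismatch_counts' required when n_offtargets > 0")
    }
    mismatch_counts <- rep_len(as.integer(mismatch_counts), n_offtargets)
    if (any(mismatch_counts < 0L | mismatch_counts > 8L)) {
      stop_param("mismatch_counts entries must be in 0..8")
    }
  } else {
    mismatch_counts <- integer(0)
  }
  n_sites <- n_offtargets + 1L
  mm_all <- c(0L, mismatch_counts)

  withr::with_seed(as.integer(seed), {
    usable <- ref$length - 2L * margin
    if (usable < n_sites * min_gap) {
      stop_param("reference too short to host ", n_sites,
                 " sites at min_gap ", min_gap)
    }
    ## sequential rejection sampling of cut positions
    cuts <- integer(0)
    tries <- 0L
    while (length(cuts) < n_sites) {
      cand <- margin + sample.int(usable, 1L)
      if (all(abs(cand - cuts) >= min_gap)) cuts <- c(cuts, cand)
      tries <- tries + 1L
      if (tries > 1000L * n_sites) {
        stop_param("could not place ", n_sites, " non-overlapping sites")
      }
    }
    strands <- c("+", sample(c("+", "-"), n_offtargets, replace = TRUE))

    spl <- strsplit(spacer, "")[[1L]]
    seqchars <- strsplit(ref$seq, "")[[1L]]
    mm_pos <- vector("list", n_sites)
    pams <- character(n_sites)
    starts <- integer(n_sites)
    for (i in seq_len(n_sites)) {
      k <- mm_all[i]
      pos <- if (k > 0L) sort(sample.int(20L, k)) else integer(0)
      mm_pos[[i]] <- pos
      var <- spl
      for (p in pos) var[p] <- sample(setdiff(DNA_BASES, spl[p]), 1L)
      pam <- paste0(sample(DNA_BASES, 1L), "GG")
      pams[i] <- pam
      site_seq <- paste0(paste(var, collapse = ""), pam)
      cut <- cuts[i]
      if (strands[i] == "+") {
        start0 <- cut - CUT_OFFSET            # protospacer start
        write0 <- start0                       # 23-nt written span
        wseq <- site_seq
      } else {
        start0 <- cut - (20L - CUT_OFFSET)     # protospacer start (0-based)
        write0 <- start0 - 3L                  # PAM sits 5' on the + strand
        wseq <- revcomp(site_seq)
      }
      starts[i] <- start0
      idx <- (write0 + 1L):(write0 + 23L)
      seqchars[idx] <- strsplit(wseq, "")[[1L]]
    }
    ref$seq <- paste(seqchars, collapse = "")

    if (is.null(edit_rates)) {
      edit_rates <- pmax(0.05, 0.8 * exp(-0.35 * mm_all))
    }
    sites <- data.frame(
      site_id = sprintf("S%02d", seq_len(n_sites) - 1L),
      chrom = ref$name,
      start = starts,
      end = starts + 20L,
      strand = strands,
      pam = pams,
      n_mismatch = mm_all,
      cut = cuts,
      edit_rate = rep_len(edit_rates, n_sites),
      insertion_rate = rep_len(insertion_rates, n_sites),
      stringsAsFactors = FALSE
    )
    sites$mismatch_positions <- mm_pos
    sites$on_target <- seq_len(n_sites) == 1L
    list(ref = ref, sites = sites)
  })
}

## Flank extraction in the site's tag frame ("upstream" ends at the cut,
## "downstream" starts at it). Returns sequences 5'->3' in tag orientation.
up_flank <- function(ref, cut, strand, len) {
  if (strand == "+") ref_substr(ref$seq, cut - len, cut)
  else revcomp(ref_substr(ref$seq, cut, cut + len))
}

down_flank <- function(ref, cut, strand, len) {
  if (strand == "+") ref_substr(ref$seq, cut, cut + len)
  else revcomp(ref_substr(ref$seq, cut - len, cut))
}
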