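## Shared fixtures, built once per session and cached.

.fx_cache <- new.env(parent = emptyenv())

FIX_SPACER <- "GTTCAGAGCTACGATGGTCA"

fx_memo <- function(key, builder) {
  if (!exists(key, envir = .fx_cache)) {
    assign(key, builder(), envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

## Moderate edited library + WT control, error-free, with random priming.
fx_small <- function() fx_memo("small", function() {
  od <- file.path(tempdir(), "fx_small")
  ref <- generate_reference(60000, 0.5, seed = 7)
  pl <- plant_sites(ref, FIX_SPACER, n_offtargets = 3,
                    mismatch_counts = c(1, 3, 4), seed = 2)
  ref <- pl$ref
  tag <- tag_design()
  sim <- simulate_library(ref, pl$sites, tag,
                          library_params(n_fragments = 6000,
                                         random_priming_rate = 0.02,
                                         seed = 11),
                          out_dir = od, prefix = "sample")
  wt <- simulate_wt_control(ref, tag,
                            library_params(n_fragments = 3000,
                                           random_priming_rate = 0.02,
                                           seed = 12),
                            out_dir = od, prefix = "wt")
  prep <- prep_reads(sim$paths$fq1, sim$paths$fq2, tag)
  prep_wt <- prep_reads(wt$paths$fq1, wt$paths$fq2, tag)
  ann <- c("read_id", "umi", "primer_id", "side", "ext_ok")
  aln <- read_alignments(sim$paths$sam, annotations = prep[, ann])
  aln_wt <- read_alignments(wt$paths$sam, annotations = prep_wt[, ann])
  list(dir = od, ref = ref, sites = pl$sites, tag = tag, sim = sim,
       wt = wt, prep = prep, prep_wt = prep_wt, aln = aln,
       aln_wt = aln_wt)
})

## Junction fixture: all five join models planted.
fx_junctions <- function() fx_memo("junctions", function() {
  od <- file.path(tempdir(), "fx_jx")
  ref <- generate_reference(80000, 0.5, seed = 7)
  pl <- plant_sites(ref, FIX_SPACER, n_offtargets = 5,
                    mismatch_counts = c(1, 2, 3, 4, 2), seed = 2)
  ref <- pl$ref
  tag <- tag_design()
  jx <- rbind(
    junction_spec("S00", "S00", "i", 0.10),
    junction_spec("S01", "S01", "ii", 0.10),
    junction_spec("S02", "S04", "iii", 0.15),
    junction_spec("S03", "S05", "iv", 0.15),
    junction_spec("S01", "S02", "v", 0.15)
  )
  sim <- simulate_library(ref, pl$sites, tag,
                          library_params(n_fragments = 8000, seed = 11,
                                         n_junction_reads = 2000),
                          junctions = jx, out_dir = od, prefix = "sample")
  prep <- prep_reads(sim$paths$fq1, sim$paths$fq2, tag)
  ann <- c("read_id", "umi", "primer_id", "side", "ext_ok")
  aln <- read_alignments(sim$paths$sam, annotations = prep[, ann])
  jaln <- read_alignments(sim$paths$jx_sam, keep_seq = TRUE)
  list(dir = od, ref = ref, sites = pl$sites, tag = tag, jx = jx,
       sim = sim, aln = aln, jaln = jaln)
})

## Independent string reverse-complement (no Biostrings) for oracles.
oracle_rc <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## Brute-force all-positions spacer/PAM scan, mirroring the documented
## contract but written independently (plain loops, string ops only).
oracle_spacer_scan <- function(refseq, cut, spacer, window = 25,
                               max_mm = 7) {
  L <- nchar(refseq)
  hits <- list()
  for (s in seq(max(0, cut - window - 25), cut + window + 25)) {
    ## + strand candidate
    if (s >= 0 && s + 23 <= L) {
      implied <- s + 17
      if (abs(implied - cut) <= window) {
        seq20 <- substr(refseq, s + 1, s + 20)
        pam <- substr(refseq, s + 21, s + 23)
        p2 <- substr(pam, 2, 3)
        if (p2 == "GG" || p2 == "AG") {
          mm <- oracle_hamming(seq20, spacer)
          if (mm <= max_mm) {
            hits[[length(hits) + 1]] <- list(
              start = s, strand = "+", mm = mm,
              pam_rank = if (p2 == "GG") 0 else 1,
              dist = abs(implied - cut))
          }
        }
      }
    }
    ## - strand candidate
    if (s - 3 >= 0 && s + 20 <= L) {
      implied <- s + 3
      if (abs(implied - cut) <= window) {
        seq20 <- oracle_rc(substr(refseq, s + 1, s + 20))
        pam <- oracle_rc(substr(refseq, s - 2, s))
        p2 <- substr(pam, 2, 3)
        if (p2 == "GG" || p2 == "AG") {
          mm <- oracle_hamming(seq20, spacer)
          if (mm <= max_mm) {
            hits[[length(hits) + 1]] <- list(
              start = s, strand = "-", mm = mm,
              pam_rank = if (p2 == "GG") 0 else 1,
              dist = abs(implied - cut))
          }
        }
      }
    }
  }
  if (length(hits) == 0) return(NULL)
  df <- do.call(rbind, lapply(hits, as.data.frame))
  df[order(df$mm, df$pam_rank, df$dist, df$start, df$strand), ][1, ]
}

## Wrap a raw sequence string as a reference object.
as_ref <- function(seq, name = "chrT") {
  structure(list(name = name, seq = seq, length = nchar(seq)),
            class = "peac_reference")
}

## Build an alignment-table row for hand-constructed caller inputs.
aln_row <- function(read_id, start, end, strand, side, ext_ok = TRUE,
                    umi = "AAAAAAAAAA", chrom = "chrT", mapq = 60,
                    primer_id = if (identical(side, "F")) "F1" else "R2") {
  anchor <- if (strand == "+") start else end
  data.frame(read_id = read_id, chrom = chrom, start = start, end = end,
             aln_start = start, aln_end = end, strand = strand,
             mapq = mapq, cigar = paste0(end - start, "M"), umi = umi,
             qstart = 1L, qend = end - start, is_split = FALSE,
             chrom2 = NA_character_, start2 = NA_integer_,
             end2 = NA_integer_, strand2 = NA_character_,
             qstart2 = NA_integer_, anchor = anchor,
             side = side, primer_id = primer_id, ext_ok = ext_ok,
             stringsAsFactors = FALSE)
}
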