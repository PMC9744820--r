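#' Count spacer mismatches of a site match
#'
#' Mismatches are counted over the 20 spacer positions only; the degenerate
#' first PAM base never counts, and non-NGG PAMs are reported separately via
#' the `pam_variant` field of the match.
#'
#' @param match one-row data.frame from [match_spacer()] (or the site table
#'   columns), with `n_mismatch` or `mismatch_positions`.
#' @return integer mismatch count.
#' @export
count_mismatches <- function(match) {
  if (is.null(match)) stop_param("no spacer match supplied")
  if (!is.null(match$mismatch_positions)) {
    pos <- match$mismatch_positions
    if (is.list(pos)) pos <- pos[[1L]]
    length(pos)
  } else {
    as.integer(match$n_mismatch)
  }
}

#' Per-position mismatch frequency profile
#'
#' For a group of sites, the fraction of sites mismatched at each position
#' along the spacer (positions 1-20, 5' to 3') and the PAM (positions
#' 21-23). PAM positions use deviations from the expected NGG (position 21,
#' the N, is never a mismatch).
#'
#' @param matches list of one-row match data.frames, or a site data.frame
#'   with `mismatch_positions` (list column) and `pam`.
#' @param group_label label carried in the output.
#' @return list of class `peac_mismatch_profile` with `group_label`,
#'   `n_sites` and `freq` (length-23 numeric in \[0, 1\]).
#' @export
mismatch_frequency_profile <- function(matches, group_label = "sites") {
  if (is.data.frame(matches)) {
    mmpos <- matches$mismatch_positions
    pams <- matches$pam
  } else {
    mmpos <- lapply(matches, function(m) {
      p <- m$mismatch_positions
      if (is.list(p)) p[[1L]] else p
    })
    pams <- vapply(matches, function(m) as.character(m$pam), character(1))
  }
  n <- length(mmpos)
  if (n == 0L) stop_param("empty site group: no profile defined")
  counts <- numeric(23)
  for (i in seq_len(n)) {
    p <- mmpos[[i]]
    counts[p] <- counts[p] + 1
    pam <- pams[i]
    if (!is.na(pam) && nchar(pam) == 3L) {
      if (substr(pam, 2L, 2L) != "G") counts[22] <- counts[22] + 1
      if (substr(pam, 3L, 3L) != "G") counts[23] <- counts[23] + 1
    }
  }
  structure(list(group_label = group_label, n_sites = n,
                 freq = counts / n),
            class = "peac_mismatch_profile")
}

#' @export
print.peac_mismatch_profile <- function(x, ...) {
  cat(sprintf("<peac_mismatch_profile> %s (n = %d)\n", x$group_label,
              x$n_sites))
  print(round(setNames(x$freq, c(1:20, "PAM-N", "PAM-G2", "PAM-G3")), 3))
  invisible(x)
}

#' Mismatch positions falling inside the primer-binding site
#'
#' The PBS anneals to the 3' end of the nicked protospacer strand, so it
#' covers the spacer's 3'-terminal `pbs_len` positions: spacer positions
#' (21 - pbs_len)..20. Mismatches there can impair tag insertion and hence
#' detection sensitivity.
#'
#' @param match one-row match data.frame (see [count_mismatches()]).
#' @param pbs_len PBS length in bases, 1..20.
#' @return integer vector of mismatch positions inside the PBS region.
#' @export
annotate_pbs_mismatches <- function(match, pbs_len = 13L) {
  if (pbs_len < 1L || pbs_len > 20L) stop_param("pbs_len must be in 1..20")
  pos <- match$mismatch_positions
  if (is.list(pos)) pos <- pos[[1L]]
  pos <- as.integer(pos)
  pos[pos >= 21L - pbs_len & pos <= 20L]
}

#' Write a mismatch profile as TSV
#' @param profile `peac_mismatch_profile`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(position = c(1:20, "PAM-N", "PAM-G2", "PAM-G3"),
                   region = c(rep("spacer", 20), rep("PAM", 3)),
                   frequency = profile$freq)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
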