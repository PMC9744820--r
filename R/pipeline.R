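#' Load a reference from a FASTA file
#' @param path FASTA with a single sequence.
#' @return `peac_reference`.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) stop_param("expected a single-sequence FASTA")
  structure(list(name = sub("\\s.*$", "", names(x)[1]),
                 seq = as.character(x[[1]]), length = Biostrings::width(x)[1]),
            class = "peac_reference")
}

#' Write a reference as FASTA
#' @param ref `peac_reference`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_reference <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$seq)
  names(x) <- ref$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Build or validate a pipeline configuration
#'
#' A nested list mirroring the YAML config consumed by the command-line
#' entry points: simulation parameters (reference, sites, library), tag
#' design, and caller thresholds. Unspecified values take the package
#' defaults. The structure round-trips losslessly through
#' [yaml::write_yaml()].
#'
#' @param x list (e.g. from [yaml::read_yaml()]); `NULL` gives the full
#'   default config.
#' @return validated config list of class `peac_config`.
#' @export
pipeline_config <- function(x = NULL) {
  defaults <- list(
    reference = list(length = 100000L, gc = 0.5, name = "chrS"),
    spacer = "GTTCAGAGCTACGATGGTCA",
    sites = list(n_offtargets = 4L, mismatch_counts = c(1L, 2L, 3L, 4L),
                 insertion_rate = 0.3),
    tag = list(tag_seq = DEFAULT_TAG, pbs_len = 13L),
    library = list(n_fragments = 50000L, read_len = 150L, umi_len = 10L,
                   umi_spacer = "CAGT", seq_error_rate = 0,
                   random_priming_rate = 0, background_rate = 0.02,
                   pcr_duplicates = 1L, n_junction_reads = 3000L),
    call = list(window = 25L, max_wt = 0L, bidirectional_required = TRUE,
                min_ext = 4L, max_mm_primer = 1L, search_window = 25L,
                max_mm_spacer = 7L),
    transloc = list(pseudocount = 10, min_seg = 20L, tol = 5L),
    seed = 1L
  )
  cfg <- utils::modifyList(defaults, if (is.null(x)) list() else x)
  structure(cfg, class = c("peac_config", "list"))
}

config_tag <- function(cfg) {
  tag_design(tag_seq = cfg$tag$tag_seq, pbs_len = cfg$tag$pbs_len)
}

config_params <- function(cfg, seed_offset = 0L) {
  lib <- cfg$library
  library_params(
    n_fragments = lib$n_fragments, read_len = lib$read_len,
    umi_len = lib$umi_len, umi_spacer = lib$umi_spacer,
    seq_error_rate = lib$seq_error_rate,
    random_priming_rate = lib$random_priming_rate,
    background_rate = lib$background_rate,
    pcr_duplicates = lib$pcr_duplicates,
    n_junction_reads = lib$n_junction_reads,
    seed = cfg$seed + seed_offset
  )
}

#' Simulate a full fixture bundle from a configuration
#'
#' Generates the reference, plants the configured sites, simulates the
#' edited library (plus junction sub-library if configured) and a matched
#' wild-type control, and writes a manifest with the parameters and file
#' checksums. Re-running with the same config and seed reproduces every
#' file byte for byte.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory.
#' @return list with `ref`, `sites`, `sim`, `wt`, `paths`, `manifest`.
#' @export
run_simulate <- function(cfg, out_dir) {
  cfg <- pipeline_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generate_reference(cfg$reference$length, cfg$reference$gc,
                            seed = cfg$seed, name = cfg$reference$name)
  planted <- plant_sites(ref, cfg$spacer,
                         n_offtargets = cfg$sites$n_offtargets,
                         mismatch_counts = cfg$sites$mismatch_counts,
                         seed = cfg$seed + 1L,
                         insertion_rates = cfg$sites$insertion_rate)
  ref <- planted$ref
  tag <- config_tag(cfg)
  junctions <- NULL
  if (!is.null(cfg$junctions)) {
    junctions <- do.call(rbind, lapply(cfg$junctions, function(j) {
      junction_spec(j$receiver, j$donor, j$model, j$rate)
    }))
  }
  sim <- simulate_library(ref, planted$sites, tag,
                          config_params(cfg, 2L), junctions = junctions,
                          out_dir = out_dir, prefix = "sample")
  wt <- simulate_wt_control(ref, tag, config_params(cfg, 3L),
                            out_dir = out_dir, prefix = "wt")
  fa <- file.path(out_dir, "reference.fa")
  write_reference(ref, fa)
  sites_tsv <- file.path(out_dir, "planted_sites.tsv")
  st <- planted$sites
  st$mismatch_positions <- vapply(st$mismatch_positions, paste,
                                  character(1), collapse = ",")
  write.table(st, sites_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(list(reference = fa, sites = sites_tsv), sim$paths, wt$paths)
  manifest <- list(seed = cfg$seed,
                   config = unclass(cfg),
                   files = lapply(paths, function(p) {
                     unname(tools::md5sum(p))
                   }))
  mpath <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  list(ref = ref, sites = planted$sites, sim = sim, wt = wt,
       paths = paths, manifest = manifest)
}

#' Run the site caller on a simulated or external dataset
#'
#' Annotates the sample and wild-type libraries ([prep_reads()]), joins the
#' annotations onto the alignments, and calls sites ([call_sites()]).
#' Writes the site TSV/BED, per-side signal tracks, the per-criterion audit
#' log and the read rejection logs.
#'
#' @param ref `peac_reference` or FASTA path.
#' @param spacer 20-nt spacer.
#' @param tag `peac_tag_design`.
#' @param sample_fq1,sample_fq2,sample_sam sample library files.
#' @param wt_fq1,wt_fq2,wt_sam wild-type control files (mandatory: the
#'   control criterion cannot be evaluated without them).
#' @param out_dir output directory.
#' @param config a [call_config()].
#' @param min_ext,max_mm_primer,primers_used read-prep settings.
#' @return list with `sites`, `audit`, `lib_sizes` and output `paths`.
#' @export
run_call <- function(ref, spacer, tag, sample_fq1, sample_fq2, sample_sam,
                     wt_fq1, wt_fq2, wt_sam, out_dir,
                     config = call_config(), min_ext = 4L,
                     max_mm_primer = 1L, primers_used = c("F1", "R2")) {
  if (missing(wt_fq1) || missing(wt_sam) || is.null(wt_sam)) {
    stop_param("a wild-type control library is mandatory")
  }
  if (is.character(ref)) ref <- read_reference(ref)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prep_s <- prep_reads(sample_fq1, sample_fq2, tag, max_mm = max_mm_primer,
                       min_ext = min_ext, primers_used = primers_used)
  prep_w <- prep_reads(wt_fq1, wt_fq2, tag, max_mm = max_mm_primer,
                       min_ext = min_ext, primers_used = primers_used)
  ann <- c("read_id", "umi", "primer_id", "side", "ext_ok")
  aln_s <- read_alignments(sample_sam, annotations = prep_s[, ann])
  aln_w <- read_alignments(wt_sam, annotations = prep_w[, ann])
  res <- call_sites(aln_s, aln_w, ref, spacer, config)
  paths <- list()
  paths$sites <- file.path(out_dir, "sites")
  write_sites(res$sites, paths$sites)
  paths$audit <- file.path(out_dir, "audit.tsv")
  write.table(res$audit, paths$audit, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$reject_sample <- write_rejection_log(
    prep_s, file.path(out_dir, "sample_rejections.tsv"))
  ded <- deduplicate_reads(aln_s)
  for (sd in c("F", "R")) {
    p <- file.path(out_dir, paste0("signal_", sd, ".bedGraph"))
    write_signal_track(ded[!is.na(ded$side) & ded$ext_ok, , drop = FALSE],
                       ref, p, side = sd)
    paths[[paste0("track_", sd)]] <- p
  }
  c(res, list(paths = paths, dedup = ded, prep = prep_s))
}

#' Run junction calling on a junction (nested-PCR/UDiTaS-style) library
#'
#' @param junction_sam split-read alignments (SAM/BAM).
#' @param sites site table (planted sites, or the TSV written by
#'   [write_sites()] — called sites are adapted automatically).
#' @param tag `peac_tag_design`.
#' @param out_dir output directory.
#' @param pseudocount,min_seg,tol see [call_junctions()].
#' @return list with `events` and output `paths`.
#' @export
run_transloc <- function(junction_sam, sites, tag, out_dir,
                         pseudocount = 10, min_seg = 20L, tol = 5L) {
  if (is.character(sites)) sites <- read_sites_tsv(sites)
  if (!"site_id" %in% names(sites)) {
    if (!all(c("peac_id", "cut_pos", "match_strand") %in% names(sites))) {
      stop_param("site table lacks site_id or peac_id/cut_pos/match_strand",
                 " columns")
    }
    sites <- data.frame(site_id = paste0("PEAC-", sites$peac_id),
                        chrom = sites$chrom, cut = sites$cut_pos,
                        strand = sites$match_strand,
                        stringsAsFactors = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  aln <- read_alignments(junction_sam, keep_seq = TRUE)
  events <- call_junctions(aln, sites, tag, min_seg = min_seg, tol = tol,
                           pseudocount = pseudocount)
  paths <- list(events = file.path(out_dir, "events.tsv"),
                bedpe = file.path(out_dir, "events.bedpe"))
  write.table(events, paths$events, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bedpe(events, paths$bedpe)
  list(events = events, paths = paths)
}
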