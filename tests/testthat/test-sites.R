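test_that("deduplication merges same-key reads and keeps distinct UMIs", {
  a <- rbind(aln_row("r1", 100L, 400L, "+", "F", umi = "AAAAACCCCC"),
             aln_row("r2", 100L, 400L, "+", "F", umi = "AAAAACCCCC"),
             aln_row("r3", 100L, 400L, "+", "F", umi = "GGGGGTTTTT"))
  ded <- deduplicate_reads(a)
  expect_equal(nrow(ded), 2)
  expect_setequal(ded$read_id, c("r1", "r3"))
  ## highest mapq wins
  a$mapq <- c(10L, 60L, 60L)
  expect_true("r2" %in% deduplicate_reads(a)$read_id)
  ## idempotence
  expect_identical(deduplicate_reads(ded), ded)
})

test_that("deduplicated count equals the truth unique-molecule count", {
  ref <- generate_reference(40000, 0.5, seed = 3)
  pl <- plant_sites(ref, FIX_SPACER, 2, c(1, 2), seed = 4)
  tag <- tag_design()
  sim <- simulate_library(pl$ref, pl$sites, tag,
                          library_params(n_fragments = 1500, seed = 31,
                                         pcr_duplicates = 3,
                                         random_priming_rate = 0.02),
                          out_dir = tempfile())
  prep <- prep_reads(sim$paths$fq1, sim$paths$fq2, tag)
  ann <- c("read_id", "umi", "primer_id", "side", "ext_ok")
  aln <- read_alignments(sim$paths$sam, annotations = prep[, ann])
  expect_equal(nrow(aln), 4500)
  ded <- deduplicate_reads(aln)
  expect_equal(nrow(ded),
               length(unique(sim$truth$per_read$molecule_id)))
  expect_identical(deduplicate_reads(ded), ded)
})

test_that("clustering merges nearby anchors and separates distant ones", {
  near <- rbind(aln_row("r1", 100L, 400L, "+", "F"),
                aln_row("r2", 105L, 420L, "+", "F", umi = "CCCCCGGGGG"))
  cl <- cluster_cut_sites(near, window = 25)
  expect_equal(nrow(cl), 1)
  far <- rbind(aln_row("r1", 100L, 400L, "+", "F"),
               aln_row("r2", 600L, 900L, "+", "F", umi = "CCCCCGGGGG"))
  expect_equal(nrow(cluster_cut_sites(far, window = 25)), 2)
})

test_that("every planted site yields one cluster at the exact cut", {
  fx <- fx_small()
  ded <- deduplicate_reads(fx$aln)
  cl <- cluster_cut_sites(ded)
  for (cut in fx$sites$cut) {
    hit <- cl[abs(cl$cut_pos - cut) <= 2, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$cut_pos, cut)
  }
})

test_that("candidate criteria behave as specified", {
  base <- data.frame(cluster_id = 1L, chrom = "chrT", cut_pos = 500L,
                     n_reads = 5L, fwd_count = 3L, rev_count = 2L,
                     ext_fwd = 3L, ext_rev = 2L, fwd_plus = 3L,
                     fwd_minus = 0L, rev_plus = 0L, rev_minus = 2L,
                     stringsAsFactors = FALSE)
  no_wt <- empty_wt <- fx_small()$aln_wt[0, ]
  v <- apply_candidate_filters(base, no_wt)
  expect_true(all(v$crit_wt, v$crit_ext, v$crit_strand, v$pass))
  ## WT evidence at the cluster kills criterion 1
  wt <- do.call(rbind, lapply(1:5, function(i) {
    aln_row(paste0("w", i), 480L, 800L, "+", "F",
            umi = paste0(strrep("A", 9), c("A", "C", "G", "T", "N")[i]))
  }))
  v2 <- apply_candidate_filters(base, wt)
  expect_false(v2$crit_wt)
  expect_equal(v2$wt_count, 5)
  ## one-directional support fails the bidirectional reading but passes
  ## the permissive one
  uni <- base; uni$ext_rev <- 0L; uni$rev_count <- 0L
  uni$rev_minus <- 0L
  expect_false(apply_candidate_filters(uni, no_wt)$crit_ext)
  cfgp <- call_config(bidirectional_required = FALSE)
  expect_true(apply_candidate_filters(uni, no_wt, cfgp)$crit_ext)
  ## strand inconsistency fails criterion 3
  flip <- base; flip$fwd_plus <- 1L; flip$fwd_minus <- 2L
  expect_false(apply_candidate_filters(flip, no_wt)$crit_strand)
})

test_that("raising max_wt can only add passing clusters", {
  fx <- fx_small()
  ded <- deduplicate_reads(fx$aln)
  wt_ded <- deduplicate_reads(fx$aln_wt)
  cl <- cluster_cut_sites(ded)
  p0 <- apply_candidate_filters(cl, wt_ded, call_config(max_wt = 0))$pass
  p2 <- apply_candidate_filters(cl, wt_ded, call_config(max_wt = 2))$pass
  expect_true(all(p2[p0]))
})

test_that("the enrichment score is RPM-normalized extension support", {
  expect_equal(compute_peac_score(5, 0, 1e6, 1e6), 5)
  expect_equal(compute_peac_score(0, 0, 1e6, 1e6), 0)
  expect_equal(compute_peac_score(2, 3, 1e6, 2e6), 2 + 1.5)
  expect_error(compute_peac_score(2, 0, 0, 1e6), "library size")
  ## fixture: score ranks planted sites like truth tag-read counts
  fx <- fx_small()
  res <- call_sites(fx$aln, fx$aln_wt, fx$ref, FIX_SPACER)
  truth_order <- fx$sim$truth$sites$site_id[
    order(-fx$sim$truth$sites$n_ext_intact)]
  called_order <- fx$sites$site_id[
    match(res$sites$cut_pos, fx$sites$cut)]
  expect_equal(called_order, truth_order)
})

test_that("site ranking is stable and coordinate-ordered on ties", {
  s <- data.frame(chrom = "chrT", cut_pos = c(900L, 100L, 500L),
                  peac_score = c(2, 2, 7), stringsAsFactors = FALSE)
  r <- rank_sites(s)
  expect_equal(r$peac_id, 1:3)
  expect_equal(r$cut_pos, c(500L, 100L, 900L))
  one <- rank_sites(s[1, ])
  expect_equal(one$peac_id, 1L)
})

test_that("spacer matching recovers planted sites exactly", {
  fx <- fx_small()
  on <- fx$sites[1, ]
  m <- match_spacer(fx$ref, on$cut, FIX_SPACER)
  expect_equal(m$n_mismatch, 0L)
  expect_equal(m$spacer_start, on$start)
  expect_equal(m$match_strand, on$strand)
  off <- fx$sites[3, ]   # 3 planted mismatches
  m3 <- match_spacer(fx$ref, off$cut, FIX_SPACER)
  expect_equal(m3$n_mismatch, 3L)
  expect_equal(m3$mismatch_positions[[1]], off$mismatch_positions[[1]])
  ## scrambled region: no qualifying match
  far <- as_ref(strrep("AC", 300))
  expect_null(match_spacer(far, 300, FIX_SPACER, max_mm = 4))
})

test_that("spacer matching equals the brute-force oracle on random cases", {
  set.seed(17)
  for (i in 1:40) {
    ref <- generate_reference(400, 0.5, seed = 1000 + i)
    spacer <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                    collapse = "")
    if (i %% 2 == 0) {
      ## plant a mutated site near the probe cut
      pl <- tryCatch(plant_sites(ref, spacer, 0, seed = i, min_gap = 10,
                                 margin = 100),
                     error = function(e) NULL)
      if (!is.null(pl)) ref <- pl$ref
    }
    cut <- 200 + sample(-20:20, 1)
    got <- match_spacer(ref, cut, spacer, search_window = 25, max_mm = 7)
    want <- oracle_spacer_scan(ref$seq, cut, spacer, window = 25,
                               max_mm = 7)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$spacer_start, want$start)
      expect_equal(got$match_strand, as.character(want$strand))
      expect_equal(got$n_mismatch, as.integer(want$mm))
    }
  }
})

test_that("end-to-end: called sites equal planted sites, WT yields none", {
  fx <- fx_small()
  res <- call_sites(fx$aln, fx$aln_wt, fx$ref, FIX_SPACER)
  expect_setequal(res$sites$cut_pos, fx$sites$cut)
  expect_equal(nrow(res$sites), nrow(fx$sites))
  ## audit partitions every cluster
  expect_equal(sum(res$audit$pass) + sum(!res$audit$pass),
               nrow(res$audit))
  ## WT library as the sample: its own signal is its control
  res_wt <- call_sites(fx$aln_wt, fx$aln_wt, fx$ref, FIX_SPACER)
  expect_equal(nrow(res_wt$sites), 0)
})
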