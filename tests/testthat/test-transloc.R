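test_that("translocation score matches the closed form on a grid", {
  grid <- expand.grid(t = c(0, 1, 5, 10, 100), n = c(0, 1, 5, 10, 100))
  for (i in seq_len(nrow(grid))) {
    t <- grid$t[i]; n <- grid$n[i]
    expect_identical(translocation_score(t, n, 10), t / (n + t + 10))
  }
  expect_equal(translocation_score(0, 50), 0)
  expect_equal(translocation_score(10, 0, 10), 0.5)
  expect_equal(translocation_score(5, 85, 10), 0.05)
  expect_error(translocation_score(0, 0, 0), "undefined")
  expect_error(translocation_score(-1, 0), "non-negative")
})

test_that("the score is monotone in t and n and stays within [0, 1)", {
  t <- 0:50; n <- 40
  s <- translocation_score(t, n)
  expect_true(all(diff(s) > 0))
  s2 <- translocation_score(10, 0:50)
  expect_true(all(diff(s2) < 0))
  expect_true(all(s >= 0 & s < 1))
})

test_that("join geometries classify into the five models", {
  expect_equal(classify_junction(TRUE, NA, TRUE), "i")
  expect_equal(classify_junction(TRUE, NA, FALSE), "ii")
  expect_equal(classify_junction(FALSE, "upstream", FALSE), "iii")
  expect_equal(classify_junction(FALSE, "downstream", FALSE), "iv")
  expect_equal(classify_junction(FALSE, "upstream", TRUE, TRUE), "v")
  ## geometries outside the five models are never silently dropped
  expect_equal(classify_junction(FALSE, "downstream", TRUE, FALSE),
               "unassigned")
  expect_equal(classify_junction(FALSE, "upstream", TRUE, FALSE),
               "unassigned")
})

test_that("unexpected upstream forward signal is flagged with its count", {
  cl <- data.frame(cluster_id = 1:2, chrom = "chrT",
                   cut_pos = c(500L, 900L), n_reads = c(100L, 100L),
                   fwd_count = c(50L, 50L), rev_count = c(50L, 50L),
                   ext_fwd = c(50L, 50L), ext_rev = c(50L, 50L),
                   fwd_plus = c(50L, 40L), fwd_minus = c(0L, 10L),
                   rev_plus = c(0L, 0L), rev_minus = c(50L, 50L))
  got <- detect_unexpected_signals(cl)
  expect_equal(got$flagged, c(FALSE, TRUE))
  expect_equal(got$unexpected_fwd, c(0L, 10L))
})

test_that("only the model-(v) receiver shows unexpected upstream signal", {
  fx <- fx_junctions()
  ded <- deduplicate_reads(fx$aln)
  cl <- cluster_cut_sites(ded)
  fl <- detect_unexpected_signals(cl)
  v_cut <- fx$sites$cut[fx$sites$site_id == "S01"]
  site_cl <- fl[fl$cut_pos %in% fx$sites$cut, ]
  expect_equal(site_cl$cut_pos[site_cl$flagged], v_cut)
})

test_that("planted junctions are recovered, classified and scored exactly", {
  fx <- fx_junctions()
  ev <- call_junctions(fx$jaln, fx$sites, fx$tag)
  jt <- fx$sim$truth$junctions
  jr <- fx$sim$truth$junction_reads
  for (k in seq_len(nrow(jt))) {
    j <- jt[k, ]
    hit <- ev[ev$receiver_id == j$receiver & ev$donor_id == j$donor &
                ev$model == j$model, ]
    expect_equal(nrow(hit), 1)
    ## expected support: all ledger reads with this join geometry (a
    ## planted model-(i) read is indistinguishable from an ordinary
    ## tag-religation read, so both count)
    want <- if (j$model == "i") {
      sum(jr$receiver == j$receiver & jr$model %in% c("i", "normal_tag"))
    } else {
      j$n_reads
    }
    expect_equal(hit$t_reads, want)
    dcut <- fx$sites$cut[fx$sites$site_id == j$donor]
    expect_lte(abs(hit$donor_cut - dcut), 2)
    if (j$model %in% c("iii", "iv", "v")) {
      ## score equals a direct recount of truth reads through the formula
      expect_equal(hit$n_reads, j$n_normal_receiver)
      expect_equal(hit$score,
                   j$n_reads / (j$n_normal_receiver + j$n_reads + 10))
      expect_equal(hit$tag_present, j$model == "v")
    }
  }
  ## the five classes are mutually exclusive per (receiver, donor) pair
  expect_false(any(duplicated(ev[, c("receiver_id", "donor_id", "model")])))
})

test_that("hand-built reads: normal join with tag vs inverted donor join", {
  sites <- data.frame(site_id = c("R", "D"), chrom = "chrT",
                      cut = c(500L, 2000L), strand = c("+", "+"),
                      stringsAsFactors = FALSE)
  tag <- tag_design()
  mk <- function(id, split, start2, end2, strand2, gap, qs2) {
    data.frame(read_id = id, chrom = "chrT", start = 440L, end = 500L,
               aln_start = 440L, aln_end = 500L, strand = "+", mapq = 60L,
               cigar = "60M", umi = NA_character_, qstart = 1L, qend = 60L,
               seq = paste0(strrep("A", 60), gap, strrep("C", 60)),
               is_split = split, chrom2 = "chrT", start2 = start2,
               end2 = end2, strand2 = strand2, qstart2 = qs2,
               anchor = 440L, stringsAsFactors = FALSE)
  }
  ## receiver-upstream + forward tag + receiver-downstream: normal join
  normal <- mk("n1", TRUE, 500L, 560L, "+", tag$tag_seq, 82L)
  ## receiver-upstream + reversed tag + inverted donor upstream flank
  vread <- mk("v1", TRUE, 1940L, 2000L, "-", oracle_rc(tag$tag_seq), 82L)
  ev <- call_junctions(rbind(normal, vread), sites, tag)
  expect_equal(sort(ev$model), c("i", "v"))
  vrow <- ev[ev$model == "v", ]
  expect_equal(vrow$receiver_id, "R")
  expect_equal(vrow$donor_id, "D")
  expect_true(vrow$tag_present)
  expect_equal(vrow$n_reads, 1L)        # the normal join counts as n
  expect_equal(vrow$score, 1 / (1 + 1 + 10))
  expect_true(vrow$low_confidence)
  ## short second segment is ignored and audited
  shortv <- mk("s1", TRUE, 1990L, 2000L, "-", oracle_rc(tag$tag_seq), 132L)
  ev2 <- call_junctions(shortv, sites, tag)
  expect_equal(nrow(ev2), 0)
  expect_equal(unname(attr(ev2, "audit")["short_segment"]), 1L)
})
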