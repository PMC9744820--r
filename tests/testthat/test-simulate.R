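test_that("read-pair conservation: ledger covers every emitted pair", {
  fx <- fx_small()
  fq <- read_fastq(fx$sim$paths$fq1)
  expect_equal(nrow(fx$sim$truth$per_read), nrow(fq))
  expect_identical(sort(fx$sim$truth$per_read$read_id), sort(fq$read_id))
  ## per-site realized counts are recounts of the per-read ledger
  tr <- fx$sim$truth$per_read
  for (i in seq_len(nrow(fx$sim$truth$sites))) {
    sid <- fx$sim$truth$sites$site_id[i]
    expect_equal(fx$sim$truth$sites$n_pairs[i],
                 sum(tr$kind == "site" & tr$anchor_site == sid, na.rm = TRUE))
  }
})

test_that("simulation is byte-identical for a fixed seed", {
  ref <- generate_reference(30000, 0.5, seed = 3)
  pl <- plant_sites(ref, FIX_SPACER, 1, 2, seed = 4)
  tag <- tag_design()
  p <- library_params(n_fragments = 500, seed = 21,
                      random_priming_rate = 0.02)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  s1 <- simulate_library(pl$ref, pl$sites, tag, p, out_dir = d1)
  s2 <- simulate_library(pl$ref, pl$sites, tag, p, out_dir = d2)
  expect_identical(unname(tools::md5sum(s1$paths$fq1)),
                   unname(tools::md5sum(s2$paths$fq1)))
  expect_identical(unname(tools::md5sum(s1$paths$sam)),
                   unname(tools::md5sum(s2$paths$sam)))
  p3 <- library_params(n_fragments = 500, seed = 22,
                       random_priming_rate = 0.02)
  s3 <- simulate_library(pl$ref, pl$sites, tag, p3, out_dir = d3)
  expect_false(identical(unname(tools::md5sum(s1$paths$fq1)),
                         unname(tools::md5sum(s3$paths$fq1))))
})

test_that("insertion_rate 0 yields no tag-derived reads", {
  ref <- generate_reference(30000, 0.5, seed = 3)
  pl <- plant_sites(ref, FIX_SPACER, 1, 2, seed = 4, insertion_rates = 0)
  tag <- tag_design()
  sim <- simulate_library(pl$ref, pl$sites, tag,
                          library_params(n_fragments = 400, seed = 5),
                          out_dir = tempfile())
  expect_equal(sum(sim$truth$per_read$kind == "site"), 0)
  expect_equal(sum(sim$truth$per_read$ext_intact), 0)
})

test_that("full-length-only truncation gives every tag read the whole tag", {
  ref <- generate_reference(30000, 0.5, seed = 3)
  pl <- plant_sites(ref, FIX_SPACER, 1, 2, seed = 4, insertion_rates = 1)
  tag <- tag_design()
  td <- setNames(numeric(22), as.character(0:21)); td["21"] <- 1
  sim <- simulate_library(pl$ref, pl$sites, tag,
                          library_params(n_fragments = 400, seed = 5,
                                         tag_truncation_dist = td,
                                         background_rate = 0),
                          out_dir = tempfile())
  tr <- sim$truth$per_read
  expect_true(all(tr$kind == "site"))
  expect_true(all(tr$tag_len == 21))
  expect_true(all(tr$ext_intact))
  ## forward-side reads carry the tag portion the primer design expects
  fq <- read_fastq(sim$paths$fq1)
  fr <- tr$side == "F"
  expect_true(all(grepl(substr(tag$tag_seq, 2, 21),
                        fq$seq[match(tr$read_id[fr], fq$read_id)],
                        fixed = TRUE)))
})

test_that("wild-type control contains primer-matched but unverifiable pairs", {
  ref <- generate_reference(30000, 0.5, seed = 3)
  tag <- tag_design()
  p <- library_params(n_fragments = 10000, seed = 9,
                      random_priming_rate = 0.01)
  sim <- simulate_wt_control(ref, tag, p, out_dir = tempfile())
  tr <- sim$truth$per_read
  n_rp <- sum(tr$kind == "rp")
  ## ~100 expected; binomial 3 sigma
  expect_gt(n_rp, 100 - 3 * sqrt(100))
  expect_lt(n_rp, 100 + 3 * sqrt(100))
  expect_equal(sum(tr$ext_intact), 0)
  prep <- prep_reads(sim$paths$fq1, sim$paths$fq2, tag)
  m <- match(tr$read_id, prep$read_id)
  expect_gte(mean(!prep$ext_ok[m][tr$kind == "rp"]), 0.99)
  ## byte-identical on repeat
  sim2 <- simulate_wt_control(ref, tag, p, out_dir = tempfile())
  expect_identical(unname(tools::md5sum(sim$paths$fq1)),
                   unname(tools::md5sum(sim2$paths$fq1)))
})

test_that("junction specs are realized in the truth alignments", {
  fx <- fx_junctions()
  jr <- fx$sim$truth$junction_reads
  scut <- setNames(fx$sites$cut, fx$sites$site_id)
  for (k in seq_len(nrow(fx$jx))) {
    j <- fx$sim$truth$junctions[k, ]
    expect_gt(j$n_reads, 0)
    rows <- jr[jr$origin == paste0("junction:", j$junction_id), ]
    ## partner segment breakpoint sits at the donor cut
    if (j$model %in% c("iii", "v")) {
      dstrand <- fx$sites$strand[fx$sites$site_id == j$donor]
      bp <- if (dstrand == "+") rows$seg2_end else rows$seg2_start
      expect_true(all(bp == scut[j$donor]))
    } else if (j$model == "iv") {
      dstrand <- fx$sites$strand[fx$sites$site_id == j$donor]
      bp <- if (dstrand == "+") rows$seg2_start else rows$seg2_end
      expect_true(all(bp == scut[j$donor]))
    }
  }
})

test_that("junctions without sites are a consistency error", {
  ref <- generate_reference(20000, 0.5, seed = 3)
  tag <- tag_design()
  jx <- junction_spec("S00", "S01", "iii", 0.1)
  expect_error(simulate_library(ref, NULL, tag, library_params(seed = 1),
                                junctions = jx, out_dir = tempfile()),
               "empty")
})

test_that("malformed library parameters are rejected", {
  expect_error(library_params(random_priming_rate = 1.5), "rates")
  expect_error(library_params(tag_truncation_dist = rep(1, 22)), "sum")
  expect_error(library_params(pcr_duplicates = 0), "pcr_duplicates")
})
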