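tag <- tag_design()
F1 <- tag$primers[tag$primers$primer_id == "F1", ]
R2 <- tag$primers[tag$primers$primer_id == "R2", ]

test_that("UMI extraction clips UMI plus fixed spacer", {
  r2 <- paste0("ACGTACGTAC", "CAGT", "GGGTTTCCCAAA")
  got <- extract_umi(r2, umi_len = 10, umi_spacer = "CAGT")
  expect_equal(got$umi, "ACGTACGTAC")
  expect_equal(got$clipped, "GGGTTTCCCAAA")
  expect_true(is.na(got$reason))
  short <- extract_umi("ACGTACGT", umi_len = 10, umi_spacer = "CAGT")
  expect_true(is.na(short$umi))
  expect_equal(short$reason, "read_too_short")
})

test_that("primer matching finds the right primer and tolerates mismatches", {
  good <- paste0(F1$seq, "GCTAACGTACGTACGT")
  got <- match_primer(good, tag)
  expect_equal(got$primer_id, "F1")
  expect_equal(got$side, "forward")
  expect_equal(got$primer_mm, 0L)
  ## one mismatch inside the primer region still matches at max_mm = 1
  mut <- good
  substr(mut, 5, 5) <- if (substr(mut, 5, 5) == "A") "C" else "A"
  expect_equal(match_primer(mut, tag, max_mm = 1)$primer_id, "F1")
  expect_true(is.na(match_primer(mut, tag, max_mm = 0)$primer_id))
  expect_true(is.na(match_primer(strrep("T", 40), tag)$primer_id))
})

test_that("extension verification accepts tag continuation, rejects genome", {
  ok <- paste0(F1$seq, F1$expected_ext, "ACGTACGTACGT")
  bad <- paste0(F1$seq, "TTTT", "ACGTACGTACGT")
  expect_true(verify_extension(ok, "F1", tag))
  expect_false(verify_extension(bad, "F1", tag))
  ## reverse-side primer: extension is the reverse complement of the tag 5'
  okr <- paste0(R2$seq, R2$expected_ext, "ACGTACGT")
  expect_true(verify_extension(okr, "R2", tag))
  ## too-short read fails
  expect_false(verify_extension(substr(ok, 1, nchar(F1$seq) + 1), "F1", tag))
  ## no primer, no verification
  expect_false(verify_extension(ok, NA_character_, tag))
})

test_that("raising min_ext never converts a failing read to passing", {
  set.seed(42)
  reads <- paste0(F1$seq,
                  replicate(200, paste(sample(c("A", "C", "G", "T"), 10,
                                              replace = TRUE),
                                       collapse = "")))
  prev <- rep(TRUE, length(reads))
  for (me in 1:6) {
    cur <- verify_extension(reads, "F1", tag, min_ext = me)
    expect_true(all(!prev | cur | !cur))       # shape check
    expect_true(all(!(cur & !prev) | me == 1)) # no FALSE -> TRUE
    prev <- cur
  }
})

test_that("on error-free data the extension verdict equals the truth ledger", {
  fx <- fx_small()
  tr <- fx$sim$truth$per_read
  m <- match(tr$read_id, fx$prep$read_id)
  expect_false(anyNA(m))
  expect_identical(fx$prep$ext_ok[m], tr$ext_intact)
  ## extracted UMIs equal emitted UMIs for every pair
  expect_identical(fx$prep$umi[m], tr$umi)
  ## primer assignment agrees with truth for every primer-derived read
  primer_reads <- !is.na(tr$primer_id)
  expect_identical(fx$prep$primer_id[m][primer_reads],
                   tr$primer_id[primer_reads])
})

test_that("random-priming pairs are rejected and tag pairs retained", {
  fx <- fx_small()
  tr <- fx$sim$truth$per_read
  m <- match(tr$read_id, fx$prep$read_id)
  rp <- tr$kind == "rp"
  expect_gt(sum(rp), 50)
  expect_gte(mean(!fx$prep$ext_ok[m][rp]), 0.99)
  intact <- tr$ext_intact
  expect_equal(mean(fx$prep$ext_ok[m][intact]), 1.0)
})

test_that("background pairs carry no matchable primer", {
  fx <- fx_small()
  tr <- fx$sim$truth$per_read
  m <- match(tr$read_id, fx$prep$read_id)
  bg <- tr$kind == "bg"
  expect_gt(sum(bg), 20)
  expect_gte(mean(fx$prep$reject_reason[m][bg] == "no_primer",
                  na.rm = TRUE), 0.95)
})
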