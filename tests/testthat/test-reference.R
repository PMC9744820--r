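test_that("reference generation is seed-deterministic and seed-sensitive", {
  a <- generate_reference(10000, 0.5, seed = 7)
  b <- generate_reference(10000, 0.5, seed = 7)
  c <- generate_reference(10000, 0.5, seed = 8)
  expect_identical(a$seq, b$seq)
  expect_false(identical(a$seq, c$seq))
  expect_equal(nchar(a$seq), 10000)
  expect_false(grepl("[^ACGT]", a$seq))
})

test_that("base composition tracks the requested GC content", {
  ref <- generate_reference(100000, 0.40, seed = 1)
  counts <- table(strsplit(ref$seq, "")[[1]])
  gc <- (counts[["G"]] + counts[["C"]]) / 100000
  expect_gte(gc, 0.38)
  expect_lte(gc, 0.42)
  expect_equal(gc_fraction(ref), as.numeric(gc))
})

test_that("invalid reference parameters are rejected", {
  expect_error(generate_reference(0, 0.5, 1), "positive")
  expect_error(generate_reference(-10, 0.5, 1), "positive")
  expect_error(generate_reference(100, 1.2, 1), "between")
})

test_that("planting only the on-target leaves one exact spacer match", {
  ref <- generate_reference(30000, 0.5, seed = 3)
  pl <- plant_sites(ref, FIX_SPACER, n_offtargets = 0, seed = 5)
  seq <- pl$ref$seq
  n_fwd <- length(gregexpr(FIX_SPACER, seq, fixed = TRUE)[[1]])
  if (gregexpr(FIX_SPACER, seq, fixed = TRUE)[[1]][1] == -1) n_fwd <- 0
  rcq <- oracle_rc(FIX_SPACER)
  hit_rc <- gregexpr(rcq, seq, fixed = TRUE)[[1]]
  n_rev <- if (hit_rc[1] == -1) 0 else length(hit_rc)
  expect_equal(n_fwd + n_rev, 1)
  expect_equal(pl$sites$n_mismatch, 0L)
  ## PAM written as NGG on the site strand
  expect_match(pl$sites$pam, "^[ACGT]GG$")
})

test_that("planted off-target sequence differs at exactly the reported positions", {
  ref <- generate_reference(30000, 0.5, seed = 3)
  pl <- plant_sites(ref, FIX_SPACER, n_offtargets = 1,
                    mismatch_counts = 3, seed = 9)
  st <- pl$sites[2, ]
  planted <- if (st$strand == "+") {
    substr(pl$ref$seq, st$start + 1, st$start + 20)
  } else {
    oracle_rc(substr(pl$ref$seq, st$start + 1, st$start + 20))
  }
  diff_pos <- which(strsplit(planted, "")[[1]] !=
                      strsplit(FIX_SPACER, "")[[1]])
  expect_equal(oracle_hamming(planted, FIX_SPACER), 3)
  expect_equal(diff_pos, st$mismatch_positions[[1]])
})

test_that("site planting is deterministic and respects capacity limits", {
  ref <- generate_reference(40000, 0.5, seed = 3)
  a <- plant_sites(ref, FIX_SPACER, 2, c(1, 2), seed = 4)
  b <- plant_sites(ref, FIX_SPACER, 2, c(1, 2), seed = 4)
  expect_identical(a$sites$cut, b$sites$cut)
  expect_identical(a$ref$seq, b$ref$seq)
  tiny <- generate_reference(6000, 0.5, seed = 1)
  expect_error(plant_sites(tiny, FIX_SPACER, 5, rep(2, 5), seed = 1),
               "short|place")
})

test_that("cut position follows the blunt-cut geometry on both strands", {
  ref <- generate_reference(50000, 0.5, seed = 3)
  pl <- plant_sites(ref, FIX_SPACER, 6, rep(1, 6), seed = 10)
  plus <- pl$sites[pl$sites$strand == "+", ]
  minus <- pl$sites[pl$sites$strand == "-", ]
  expect_true(all(plus$cut == plus$start + 17))
  if (nrow(minus)) expect_true(all(minus$cut == minus$start + 3))
})
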