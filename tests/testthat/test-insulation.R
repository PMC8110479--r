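test_that("insulation score is zero on a uniform map and undefined at edges", {
  n <- 40
  cm <- as_cm(matrix(3, n, n), res = 1e4)
  cfg <- insulation_config(window = 5e4, resolution = 1e4, delta_span = 2e4)
  prof <- insulation_score(cm, cfg)
  w <- 5
  expect_true(all(is.na(prof$score[c(1:w, (n - w + 1):n)])))
  expect_equal(prof$score[(w + 1):(n - w)], rep(0, n - 2 * w), tolerance = 1e-12)
})

test_that("a two-domain map has its insulation minimum at the junction", {
  n <- 30
  m <- matrix(2, n, n)
  m[1:15, 1:15] <- 8
  m[16:30, 16:30] <- 8
  cfg <- insulation_config(window = 5e4, resolution = 1e4, delta_span = 2e4)
  prof <- insulation_score(as_cm(m), cfg)
  ## brute-force window means on the explicit matrix
  bf <- bf_insulation(m, 5)
  expect_equal(prof$score, bf$score, tolerance = 1e-12)
  expect_equal(which.min(prof$score), 15)  # junction bin (between 15 and 16)
})

test_that("chromosomes shorter than the window yield an empty profile", {
  cm <- as_cm(matrix(1, 8, 8), res = 1e4)
  prof <- insulation_score(cm, insulation_config(window = 1e5,
                                                 resolution = 1e4,
                                                 delta_span = 2e4))
  expect_true(all(is.na(prof$score)))
})

test_that("boundary calling respects the strength threshold", {
  ## attenuated two-domain decay maps; weaker attenuation -> weaker strength
  n <- 120
  cfg <- insulation_config(window = 1e5, resolution = 1e4, delta_span = 3e4,
                           strength_min = 0)
  strengths <- sapply(c(0.9, 0.7, 0.5, 0.3), function(beta) {
    m <- decay_matrix(n, boundaries = 60, beta = beta)
    prof <- insulation_score(as_cm(m), cfg)
    b <- call_boundaries(prof, cfg)
    b <- b[abs(b$bin - 60) <= 2, ]
    if (nrow(b)) max(b$strength) else 0
  })
  ## monotone: stronger insulation never decreases called strength
  expect_true(all(diff(strengths) > 0))

  ## threshold is inclusive at >= strength_min: candidates below are dropped
  m <- decay_matrix(n, boundaries = 60, beta = 0.5)
  prof <- insulation_score(as_cm(m), cfg)
  b_all <- call_boundaries(prof, insulation_config(1e5, 1e4, 3e4, 0))
  s <- max(b_all$strength)
  keep <- call_boundaries(prof, insulation_config(1e5, 1e4, 3e4, s))
  drop <- call_boundaries(prof, insulation_config(1e5, 1e4, 3e4, s + 1e-6))
  expect_true(any(abs(keep$bin - 60) <= 2))
  expect_false(any(abs(drop$bin - 60) <= 2))
})

test_that("boundary calls are translation-equivariant", {
  n <- 150
  cfg <- insulation_config(window = 1e5, resolution = 1e4, delta_span = 3e4)
  pos <- sapply(c(60, 75, 90), function(b0) {
    m <- decay_matrix(n, boundaries = b0, beta = 0.4)
    prof <- insulation_score(as_cm(m), cfg)
    b <- refine_boundaries(call_boundaries(prof, cfg), prof)
    b$bin[which.max(b$strength)]
  })
  ## the junction sits between two bins, so each call may land on either
  ## side of it; shifts are preserved to within that one-bin tie
  expect_true(all(abs(diff(pos) - 15) <= 1))
})

test_that("refinement snaps to the minimum and keeps ties in place", {
  n <- 60
  cfg <- insulation_config(window = 5e4, resolution = 1e4, delta_span = 2e4)
  m <- decay_matrix(n, boundaries = 30, beta = 0.4)
  prof <- insulation_score(as_cm(m), cfg)
  b <- call_boundaries(prof, cfg)
  r <- refine_boundaries(b, prof)
  i <- which.max(r$strength)
  lo <- max(1, r$bin[i] - 2); hi <- min(n, r$bin[i] + 2)
  expect_equal(prof$score[r$bin[i]], min(prof$score[lo:hi], na.rm = TRUE))
  ## already at the minimum: unchanged
  r2 <- refine_boundaries(r, prof)
  expect_equal(r2$bin, r$bin)
  ## exact tie between two minima: no move
  prof_t <- prof
  prof_t$score[] <- rep(c(1, 0, 0, 1), length.out = n)
  bt <- b[1, ]; bt$bin <- 2
  expect_equal(refine_boundaries(bt, prof_t)$bin, 2)
})

test_that("contig filtering flags boundaries over planted N gaps", {
  spec <- synthetic_spec(seed = 5, n_chromosomes = 2, total_length = 6e6,
                         depth = 0, n_gap_fraction = 0.5)
  g <- generate_genome(spec, with_sequence = TRUE)
  tb <- g$truth$boundaries
  bset <- tibble::tibble(chrom = tb$chrom, start = floor(tb$pos / 1e4) * 1e4)
  bset$end <- bset$start + 1e4
  flagged <- contig_filter(bset, g$assembly)
  gap_key <- paste(g$truth$n_gaps$chrom, floor(g$truth$n_gaps$pos / 1e4))
  expect_setequal(paste(flagged$chrom, floor(flagged$start / 1e4))[!flagged$in_contig],
                  gap_key)
})
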