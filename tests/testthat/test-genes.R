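mk_genes <- function(strands, chrom = "c1", pitch = 1000, len = 500) {
  n <- length(strands)
  tibble::tibble(gene_id = sprintf("g%03d", 1:n), chrom = chrom,
                 start = (0:(n - 1)) * pitch, end = (0:(n - 1)) * pitch + len,
                 strand = strands)
}

test_that("blocks are maximal same-strand runs that partition the genes", {
  g <- mk_genes(c("+", "+", "-", "-", "-"))
  b <- find_blocks(g)
  expect_equal(b$size, c(2, 3))
  expect_equal(b$strand, c("+", "-"))

  g1 <- mk_genes(rep("+", 7))
  expect_equal(nrow(find_blocks(g1)), 1)

  set.seed(8)
  g2 <- dplyr::bind_rows(mk_genes(sample(c("+", "-"), 40, TRUE), "c1"),
                         mk_genes(sample(c("+", "-"), 25, TRUE), "c2"))
  b2 <- find_blocks(g2)
  expect_equal(sum(b2$size), 65)
  ## adjacent blocks always switch strand
  for (cc in c("c1", "c2")) {
    s <- b2$strand[b2$chrom == cc]
    expect_true(all(s[-1] != s[-length(s)]))
  }
})

test_that("orientation-change null is Binomial(window-1, 1/2)", {
  w <- 5
  g <- mk_genes(rep(c("+", "-"), 10))
  oc <- orientation_change_stats(g, window = w)
  expect_equal(oc$observed$count[w], oc$n_windows)  # strictly alternating
  oc0 <- orientation_change_stats(mk_genes(rep("+", 12)), window = 10)
  expect_equal(oc0$observed$count[1], oc0$n_windows)  # zero changes
  expect_equal(sum(oc0$null$prob * oc0$null$changes), (10 - 1) / 2)

  ## exhaustive enumeration over all strand vectors of length w
  combos <- expand.grid(rep(list(c("+", "-")), w), stringsAsFactors = FALSE)
  changes <- apply(combos, 1, function(s) sum(s[-1] != s[-w]))
  emp <- as.numeric(table(factor(changes, levels = 0:(w - 1)))) / 2^w
  expect_equal(emp, stats::dbinom(0:(w - 1), w - 1, 0.5))
})

test_that("site calling classifies junctions and handles edge cases", {
  g <- mk_genes(c("+", "+", "-", "-", "+"), pitch = 1000, len = 500)
  b <- find_blocks(g)
  s <- call_sites(b)
  expect_equal(s$kind, c("convergent", "divergent"))
  ## gap between gene 2 end (1500) and gene 3 start (2000)
  expect_equal(s$pos[1], 1750)
  expect_false(any(s$overlap))
  expect_equal(nrow(s), nrow(b) - 1)

  expect_equal(nrow(call_sites(find_blocks(mk_genes(rep("+", 4))))), 0)

  ## overlapping blocks flag the site and use the overlap midpoint
  g2 <- mk_genes(c("+", "-"), pitch = 400, len = 500)
  s2 <- call_sites(find_blocks(g2))
  expect_true(s2$overlap)
  expect_equal(s2$pos, (500 + 400) / 2)
})

test_that("GC track computes windowed fractions with N masking", {
  asm <- genome_assembly(c(t1 = 8), Biostrings::DNAStringSet(c(t1 = "GCGCATAT")))
  gc <- gc_track(asm, window = 4)
  expect_equal(gc$value, c(1, 0))
  asm2 <- genome_assembly(c(t1 = 8),
                          Biostrings::DNAStringSet(c(t1 = "GCNNNNNN")))
  gc2 <- gc_track(asm2, window = 8)
  expect_true(is.na(gc2$value))
})

test_that("feature profiles average tracks around sites", {
  sizes <- c(c1 = 1e5)
  tr <- tibble::tibble(chrom = "c1", start = 0, end = 1e5, value = 2.5)
  sites <- tibble::tibble(chrom = "c1", pos = c(4e4, 6e4))
  fp <- feature_profile(tr, sites, flank = 1e4, window = 1000, step = 1000,
                        sizes = sizes)
  expect_equal(fp$value, rep(2.5, 20))

  ## a single site reproduces the raw windowed values around it
  set.seed(2)
  tr2 <- tibble::tibble(chrom = "c1", start = 0:99 * 1000, end = 1:100 * 1000,
                        value = stats::runif(100))
  fp2 <- feature_profile(tr2, sites[1, ], flank = 5e3, window = 1000,
                         step = 1000, sizes = sizes)
  expect_equal(fp2$value, tr2$value[36:45])

  ## sites with flanks beyond the chromosome are dropped and counted
  fp3 <- feature_profile(tr, tibble::tibble(chrom = "c1", pos = c(5e3, 5e4)),
                         flank = 1e4, window = 1000, step = 1000, sizes = sizes)
  expect_equal(attr(fp3, "n_dropped"), 1)
  expect_error(feature_profile(tr, tibble::tibble(chrom = "c1", pos = 5e3),
                               flank = 1e4, sizes = sizes), "dropped")
})

test_that("feature profiles are mirror-equivariant for stranded data", {
  sizes <- c(c1 = 5e4)
  plus <- tibble::tibble(chrom = "c1", start = c(10e3, 30e3),
                         end = c(12e3, 31e3), value = c(4, 1))
  minus <- tibble::tibble(chrom = "c1", start = 20e3, end = 22e3, value = 2)
  site <- tibble::tibble(chrom = "c1", pos = 21e3, orientation = "+")
  fwd <- feature_profile(list(plus = plus, minus = minus), site,
                         flank = 8e3, window = 500, step = 500, sizes = sizes)
  ## mirrored genome (coordinates flipped) with swapped strands
  L <- 5e4
  flip <- function(t) tibble::tibble(chrom = t$chrom, start = L - t$end,
                                     end = L - t$start, value = t$value)
  site_m <- tibble::tibble(chrom = "c1", pos = L - 21e3, orientation = "-")
  rev_p <- feature_profile(list(plus = flip(minus), minus = flip(plus)),
                           site_m, flank = 8e3, window = 500, step = 500,
                           sizes = sizes)
  expect_equal(rev_p$plus, fwd$plus, tolerance = 1e-12)
  expect_equal(rev_p$minus, fwd$minus, tolerance = 1e-12)
})

test_that("telomere profiles mirror both ends and filter short chromosomes", {
  asm <- genome_assembly(c(big = 6e6, small = 4e6))
  tr <- tibble::tibble(chrom = rep(c("big", "small"), c(600, 400)),
                       start = c(0:599, 0:399) * 1e4,
                       end = c(1:600, 1:400) * 1e4,
                       value = 1)
  tr$value[tr$chrom == "small"] <- 99  # must be excluded
  tp <- telomere_profile(tr, asm, span = 1e6, min_chrom = 5e6)
  expect_equal(tp$value, rep(1, 100))
  expect_equal(attr(tp, "n_ends"), 2)

  ## gradient track: both ends contribute the mirrored gradient
  grad <- tibble::tibble(chrom = "big", start = 0:599 * 1e4,
                         end = 1:600 * 1e4,
                         value = pmin(0:599, 599:0))
  tp2 <- telomere_profile(grad, asm, span = 1e6, min_chrom = 5e6)
  expect_true(all(diff(tp2$value) > 0))
})

test_that("track correlations behave on identity, negation and sparsity", {
  set.seed(5)
  base <- tibble::tibble(chrom = "c", start = 0:499 * 1e5, end = 1:500 * 1e5,
                         value = stats::rnorm(500))
  neg <- dplyr::mutate(base, value = -value)
  tc <- track_correlations(list(a = base, b = neg, c = base))
  expect_equal(unname(tc$r["a", "c"]), 1)
  expect_equal(unname(tc$r["a", "b"]), -1)
  short <- base[1:2, ]
  tc2 <- track_correlations(list(a = short, b = short))
  expect_true(is.na(tc2$r["a", "b"]))
})
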