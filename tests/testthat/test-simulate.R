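test_that("generators are byte-deterministic under the seed", {
  spec <- synthetic_spec(seed = 42, n_chromosomes = 2, total_length = 4e6,
                         depth = 2e4)
  g1 <- generate_genome(spec, with_sequence = TRUE)
  g2 <- generate_genome(spec, with_sequence = TRUE)
  expect_identical(as.character(g1$assembly$seq), as.character(g2$assembly$seq))
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$truth$boundaries, g2$truth$boundaries)
  expect_identical(generate_contacts(g1), generate_contacts(g2))
  e1 <- generate_expression(g1$genes, spec)
  e2 <- generate_expression(g2$genes, spec)
  expect_identical(e1$plus, e2$plus)
})

test_that("treatment removes boundaries and stripes, nothing else", {
  spec <- synthetic_spec(seed = 1, beta = 0.5)
  tr <- apply_treatment(spec)
  expect_equal(tr$beta, 1)
  expect_equal(tr$stripe_fraction, 0)
  same <- setdiff(names(spec), c("beta", "stripe_fraction"))
  expect_identical(spec[same], tr[same])
  expect_identical(apply_treatment(tr), tr)
})

test_that("block sizes follow the geometric law with the configured mean", {
  spec <- synthetic_spec(seed = 3, n_chromosomes = 4, total_length = 60e6,
                         gene_pitch = 3e3, gene_length = 1500,
                         min_block_span = 0, terminal_span = 3e4, depth = 0)
  g <- generate_genome(spec)
  bl <- find_blocks(g$genes)
  expect_gt(nrow(g$genes), 1e4)
  expect_equal(mean(bl$size), 9, tolerance = 0.05)
  ## strands alternate between adjacent blocks by construction
  expect_equal(nrow(call_sites(bl)), nrow(bl) - 4)
})

test_that("contact decay matches the configured exponent and cutoff", {
  spec <- synthetic_spec(seed = 2, beta = 1, tau = 1, stripe_fraction = 0)
  g <- generate_genome(spec)
  pairs <- generate_contacts(g)
  curve <- ps_from_pairs(pairs, g$assembly)
  fit <- fit_exponent(curve, fit_range = c(5e4, 5e5))
  expect_equal(fit$exponent, -0.4, tolerance = 0.05)
  ## beyond d_max the frequency drops by roughly the suppression factor
  below <- mean(curve$P[curve$usable & curve$s > 5e5 & curve$s < 9e5])
  above <- mean(curve$P[curve$usable & curve$s > 1.2e6 & curve$s < 2e6])
  expect_lt(above / below, 0.05)
  expect_equal(nrow(generate_contacts(g, synthetic_spec(seed = 2, depth = 0))), 0)
})

test_that("a null map (beta = tau = 1) yields almost no boundary calls", {
  spec <- synthetic_spec(seed = 4, beta = 1, tau = 1, stripe_fraction = 0)
  g <- generate_genome(spec)
  cm <- ice_balance(pairs_to_matrix(generate_contacts(g),
                                    bin_genome(g$assembly, 1e4)))
  prof <- insulation_score(cm)
  calls <- call_boundaries(prof)
  ## false-positive rate at most 1 per 100 Mb on a 40-Mb genome
  expect_lte(nrow(calls), 1)
})

test_that("fragmentation respects misjoin settings and records truth", {
  spec <- synthetic_spec(seed = 6)
  g <- generate_genome(spec)
  f0 <- fragment_assembly(g, target_n50 = 5e5, misjoin_rate = 0)
  expect_true(all(!f0$scaffolds$chimeric))
  expect_true(all(table(f0$map$scaffold) == 1))
  ## pieces tile each chromosome exactly
  for (cn in g$assembly$chroms$name) {
    pieces <- f0$map[f0$map$chrom == cn, ]
    pieces <- pieces[order(pieces$g_start), ]
    expect_equal(pieces$g_start[1], 0)
    expect_equal(max(pieces$g_end),
                 g$assembly$chroms$length[g$assembly$chroms$name == cn])
    expect_true(all(pieces$g_start[-1] == utils::head(pieces$g_end, -1)))
  }

  f1 <- fragment_assembly(g, target_n50 = 5e5, misjoin_rate = 0.1)
  expect_equal(sum(f1$scaffolds$chimeric), nrow(f1$junctions))
  expect_gt(nrow(f1$junctions), 0)

  expect_error(fragment_assembly(g, target_n50 = 1e8), "exceeds")
})

test_that("lifted pairs land on the correct scaffold coordinates", {
  spec <- synthetic_spec(seed = 7, depth = 5e3)
  g <- generate_genome(spec)
  frag <- fragment_assembly(g, target_n50 = 5e5, misjoin_rate = 0.05)
  pairs <- generate_contacts(g)
  sp <- lift_pairs(pairs, frag)
  expect_equal(nrow(sp), nrow(pairs))
  ## invert the lift and compare to a direct per-record mapping
  map <- frag$map
  back <- function(sc, pos) {
    r <- map[map$scaffold == sc & map$sc_start <= pos - 1 & pos - 1 < map$sc_end, ]
    off <- pos - 1 - r$sc_start
    if (r$strand == "+") r$g_start + off + 1 else r$g_end - off
  }
  set.seed(1)
  take <- sample(nrow(sp), 25)
  for (i in take) {
    gpos <- back(sp$chrom1[i], sp$pos1[i])
    gchr <- map$chrom[map$scaffold == sp$chrom1[i] &
                        map$sc_start <= sp$pos1[i] - 1 &
                        sp$pos1[i] - 1 < map$sc_end]
    hit <- pairs$chrom1 == gchr & pairs$pos1 == gpos |
      pairs$chrom2 == gchr & pairs$pos2 == gpos
    expect_true(any(hit))
  }
})

test_that("expression tracks are strand-faithful with the silent fraction", {
  spec <- synthetic_spec(seed = 5, n_chromosomes = 2, total_length = 4e6,
                         depth = 0, silent_fraction = 0.2)
  g <- generate_genome(spec)
  ex <- generate_expression(g$genes, spec)
  expect_true(all(ex$plus$start %in% g$genes$start[g$genes$strand == "+"]))
  expect_true(all(ex$minus$start %in% g$genes$start[g$genes$strand == "-"]))
  expect_lt(abs(mean(ex$levels$level == 0) - 0.2), 0.06)

  one <- g$genes[g$genes$strand == "+", ][1, ]
  ex1 <- generate_expression(one, spec)
  expect_equal(nrow(ex1$minus), 0)
})

test_that("the planted spacer produces the expected curve shift", {
  spec <- synthetic_spec(seed = 8, n_chromosomes = 1, total_length = 6.5e6,
                         beta = 1, tau = 1, stripe_fraction = 0,
                         trans_fraction = 0, d_max = 1.2e6, depth = 4e5,
                         spacer = c(1, 3.0e6, 0.5e6))
  g <- generate_genome(spec)
  cm <- pairs_to_matrix(generate_contacts(g), bin_genome(g$assembly, 5e4))
  ## the spacer interval itself is contact-free
  m <- dinochrom:::cm_dense_chrom(cm, "chr1")
  sp_bins <- 61:70
  expect_equal(sum(m[sp_bins, sp_bins]), 0)
  sq <- ps_domain_squares(cm, tibble::tibble(chrom = "chr1",
                                             start = c(3.0e6, 3.5e6)))
  gs <- gap_shift(sq[sq$row_domain == 1 & sq$col_domain == 3, ],
                  sq[sq$row_domain == 1 & sq$col_domain == 1, ],
                  max_shift = 1e6, step = 5e4)
  expect_lte(abs(gs$shift - 5e5), 5e4)
})
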