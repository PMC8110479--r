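test_that("bin_genome tiles chromosomes with ceiling arithmetic", {
  bt <- bin_genome(genome_assembly(c(chr1 = 26204)), 1e4)
  expect_equal(nrow(bt), 3)
  expect_equal(bt$start[3], 20000)
  expect_equal(bt$end[3], 26204)

  bt1 <- bin_genome(genome_assembly(c(chr1 = 40000)), 40000)
  expect_equal(nrow(bt1), 1)
  expect_equal(c(bt1$start, bt1$end), c(0, 40000))

  set.seed(11)
  lens <- sample(1e5:2e6, 8)
  names(lens) <- paste0("c", 1:8)
  bt8 <- bin_genome(genome_assembly(lens), 40000)
  expect_equal(nrow(bt8), sum(vapply(lens, function(L) ceiling(L / 40000), 1)))
  expect_equal(unique(bt8$chrom), names(lens))  # deterministic order

  expect_error(bin_genome(genome_assembly(c(a = 100)), 0), "resolution")
  expect_error(genome_assembly(tibble::tibble(name = character(),
                                              length = numeric())))
})

test_that("pairs_to_matrix conserves mass and reports discards", {
  asm <- genome_assembly(c(a = 1e5, b = 5e4))
  bt <- bin_genome(asm, 1e4)

  empty <- pairs_to_matrix(tibble::tibble(chrom1 = character(), pos1 = numeric(),
                                          chrom2 = character(), pos2 = numeric()),
                           bt)
  expect_equal(sum(empty$counts), 0)

  one <- pairs_to_matrix(tibble::tibble(chrom1 = "a", pos1 = 5, chrom2 = "a",
                                        pos2 = 900), bt)
  expect_equal(as.numeric(one$counts[1, 1]), 1)

  set.seed(4)
  n <- 1e4
  p <- tibble::tibble(
    chrom1 = sample(c("a", "b"), n, replace = TRUE), pos1 = sample(1.2e5, n),
    chrom2 = sample(c("a", "b", "zz"), n, replace = TRUE), pos2 = sample(9e4, n))
  cm <- pairs_to_matrix(p, bt)
  mass <- (sum(cm$counts) + sum(Matrix::diag(cm$counts))) / 2
  expect_equal(mass + cm$discards, n)
  expect_gt(cm$discards, 0)  # positions beyond length + unknown chromosome
  expect_true(Matrix::isSymmetric(cm$counts))
})

test_that("ice_balance equalises marginals and matches an IPF oracle", {
  bt2 <- bin_genome(genome_assembly(c(x = 2e4)), 1e4)
  cm2 <- ice_balance(contact_matrix(bt2, matrix(c(0, 4, 4, 0), 2)))
  expect_equal(cm2$weights[1], cm2$weights[2])

  m3 <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2), 3)
  bt3 <- bin_genome(genome_assembly(c(x = 3e4)), 1e4)
  cm3 <- ice_balance(contact_matrix(bt3, m3), tol = 1e-9)
  expect_true(cm3$converged)
  b_oracle <- ipf_balance(m3, tol = 1e-12)
  expect_equal(cm3$weights / cm3$weights[1], b_oracle / b_oracle[1],
               tolerance = 1e-6)
  marg <- as.numeric((m3 * outer(cm3$weights, cm3$weights)) %*% rep(1, 3))
  expect_lt(stats::sd(marg) / mean(marg), 1e-8)

  ## zero row masked, the rest balanced
  m0 <- rbind(cbind(m3, 0), 0)
  bt4 <- bin_genome(genome_assembly(c(x = 4e4)), 1e4)
  cm4 <- ice_balance(contact_matrix(bt4, m0))
  expect_true(is.na(cm4$weights[4]))
  expect_true(all(!is.na(cm4$weights[1:3])))

  ## weights invariant under global rescaling (up to one scalar)
  cm3b <- ice_balance(contact_matrix(bt3, 7 * m3), tol = 1e-9)
  expect_equal(cm3b$weights / cm3b$weights[1], cm3$weights / cm3$weights[1],
               tolerance = 1e-6)

  ## re-balancing a balanced matrix reproduces the weights
  again <- ice_balance(cm3, tol = 1e-9)
  expect_equal(again$weights, cm3$weights, tolerance = 1e-6)

  expect_error(contact_matrix(bt2, matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("n_gap_scan applies the consecutive-N rule at the boundary case", {
  run24 <- paste0(strrep("A", 10), strrep("N", 24), strrep("A", 10))
  run23 <- paste0(strrep("A", 10), strrep("N", 23), strrep("A", 10))
  expect_false(n_gap_scan(run24, run_min = 24))
  expect_true(n_gap_scan(run23, run_min = 24))
  expect_true(n_gap_scan(strrep("ACGT", 20), run_min = 24))
})

test_that("formats round-trip through the 0-based internal convention", {
  td <- withr::local_tempdir()
  spec <- synthetic_spec(seed = 9, n_chromosomes = 2, total_length = 4e5,
                         terminal_span = 3e4, gene_pitch = 5e3,
                         gene_length = 2e3, min_block_span = 0, depth = 1e3)
  g <- generate_genome(spec, with_sequence = TRUE)

  fa <- file.path(td, "g.fa")
  write_fasta(g$assembly, fa)
  expect_equal(as.character(read_fasta(fa)$seq), as.character(g$assembly$seq))

  ## GFF3 is 1-based: a gene written from [100, 200) must read back identically
  gff <- file.path(td, "g.gff3")
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 100,
                          end = 200, strand = "+")
  write_gff_genes(genes, gff)
  lines <- readLines(gff)
  expect_match(lines[2], "\t101\t200\t")
  back <- read_gff_genes(gff)
  expect_equal(back$start, 100)
  expect_equal(back$end, 200)

  bed <- file.path(td, "b.bed")
  bdf <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(0, 100),
                        end = c(50, 220), name = c("x", "y"),
                        score = c(1, 2), strand = c("+", "-"))
  write_bed(bdf, bed)
  expect_equal(read_bed(bed)[, c("chrom", "start", "end", "strand")],
               bdf[, c("chrom", "start", "end", "strand")])

  bg <- file.path(td, "t.bedGraph")
  tr <- tibble::tibble(chrom = "chr1", start = c(0, 100), end = c(100, 150),
                       value = c(0.25, 1.5))
  write_bedgraph(tr, bg)
  expect_equal(read_bedgraph(bg), tr)
  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t2"), bg)
  expect_error(read_bedgraph(bg), "overlap")

  pr <- file.path(td, "p.pairs")
  pairs <- generate_contacts(g)
  write_pairs(pairs, pr, g$assembly)
  expect_equal(as.data.frame(read_pairs(pr)), as.data.frame(pairs))

  cm <- ice_balance(pairs_to_matrix(pairs, bin_genome(g$assembly, 1e4)))
  write_triplet_matrix(cm, file.path(td, "m"))
  cm2 <- read_triplet_matrix(file.path(td, "m"))
  expect_equal(as.matrix(cm2$counts), as.matrix(cm$counts))
  expect_equal(cm2$weights, cm$weights)
  expect_true(cm2$balanced)
})
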