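## small two-chromosome scaffold world: 4 scaffolds of 3 bins each, the
## first two on chromosome A, the others on B
toy_scaffold_cm <- function(trans = 0) {
  n <- 12
  m <- matrix(trans, n, n)
  blockA <- 1:6; blockB <- 7:12
  fill <- function(idx) {
    for (i in idx) for (j in idx) m[i, j] <<- 10 / (1 + abs(i - j))
  }
  fill(blockA); fill(blockB)
  scf <- tibble::tibble(name = c("s1", "s2", "s3", "s4"),
                        length = rep(1.2e5, 4))
  sizes <- stats::setNames(rep(1.2e5, 4), scf$name)
  bins <- bin_genome(genome_assembly(sizes), 4e4)
  cm <- contact_matrix(bins, Matrix::Matrix(m, sparse = TRUE))
  cm$weights <- rep(1, n); cm$balanced <- TRUE
  list(cm = cm, scaffolds = scf)
}

test_that("block-diagonal maps cluster perfectly with no ambiguity", {
  tw <- toy_scaffold_cm(trans = 0.001)
  kt <- karyotype_cluster(tw$cm, tw$scaffolds, k = 2, min_scaffold_len = 1e4)
  asg <- kt$assignment
  expect_true(all(asg$status == "assigned"))
  expect_equal(asg$cluster[asg$scaffold == "s1"],
               asg$cluster[asg$scaffold == "s2"])
  expect_false(asg$cluster[asg$scaffold == "s1"] ==
                 asg$cluster[asg$scaffold == "s3"])

  expect_error(karyotype_cluster(tw$cm, tw$scaffolds, k = 10,
                                 min_scaffold_len = 1e4), "fewer scaffolds")
})

test_that("a scaffold with equal affinity to two clusters is set aside", {
  tw <- toy_scaffold_cm(trans = 0.001)
  ## add a fifth scaffold contacting both chromosomes equally
  m <- as.matrix(tw$cm$counts)
  n <- nrow(m)
  m2 <- rbind(cbind(m, 0.5), 0.5); m2[n + 1, n + 1] <- 1
  sizes <- stats::setNames(c(rep(1.2e5, 4), 4e4), c(tw$scaffolds$name, "s5"))
  bins <- bin_genome(genome_assembly(sizes), 4e4)
  cm <- contact_matrix(bins[, ], Matrix::Matrix(m2, sparse = TRUE))
  cm$weights <- rep(1, n + 1); cm$balanced <- TRUE
  scf <- tibble::tibble(name = names(sizes), length = unname(sizes))
  kt <- karyotype_cluster(cm, scf, k = 2, ambiguity_ratio = 0.5,
                          min_scaffold_len = 1e4)
  expect_equal(kt$assignment$status[kt$assignment$scaffold == "s5"],
               "ambiguous")
})

test_that("assignment partitions scaffolds into the three statuses", {
  spec <- synthetic_spec(seed = 2)
  g <- generate_genome(spec)
  frag <- fragment_assembly(g, target_n50 = 5e5, misjoin_rate = 0.05)
  sp <- lift_pairs(generate_contacts(g), frag)
  asm <- genome_assembly(stats::setNames(frag$scaffolds$length,
                                         frag$scaffolds$name))
  cm <- ice_balance(pairs_to_matrix(sp, bin_genome(asm, 4e4)))
  kt <- karyotype_cluster(cm, frag$scaffolds)
  expect_setequal(kt$assignment$scaffold, frag$scaffolds$name)
  expect_true(all(kt$assignment$status %in%
                    c("assigned", "ambiguous", "below_min_length")))
  expect_true(all(!is.na(kt$assignment$cluster[
    kt$assignment$status == "assigned"])))
})

test_that("homogeneous scaffolds pass through misjoin splitting intact", {
  tw <- toy_scaffold_cm(trans = 0.001)
  kt <- karyotype_cluster(tw$cm, tw$scaffolds, k = 2, min_scaffold_len = 1e4)
  subs <- split_misjoins(tw$cm, tw$scaffolds, kt)
  expect_equal(nrow(subs), 4)
  expect_equal(subs$start, rep(0, 4))
  expect_equal(subs$end, rep(1.2e5, 4))
})

test_that("order and orientation recovery is invariant to member shuffling", {
  md <- desk_map(1)
  cm50 <- ice_balance(pairs_to_matrix(md$pairs,
                                      bin_genome(md$genome$assembly, 5e4)))
  L <- chrom_sizes_of(md$genome$assembly)[["chr1"]]
  cuts <- seq(0, L, length.out = 8)
  members <- tibble::tibble(name = sprintf("m%02d", 1:7), chrom = "chr1",
                            start = floor(cuts[-8]), end = floor(cuts[-1]))
  oo1 <- order_orient(cm50, members)
  set.seed(99)
  oo2 <- order_orient(cm50, members[sample(7), ])
  expect_equal(oo1$name, oo2$name)
  expect_equal(oo1$orientation, oo2$orientation)
  ## members were taken in genomic order and orientation: chain equals the
  ## genomic order up to whole-chromosome reversal
  ord <- match(oo1$name, members$name)
  expect_true(all(diff(ord) == 1) || all(diff(ord) == -1))
  expect_true(all(oo1$orientation == "+") || all(oo1$orientation == "-"))

  single <- order_orient(cm50, members[3, ])
  expect_equal(single$orientation, "+")
  expect_equal(single$confidence, 0)
})

test_that("high-copy clusters are assigned to their host chromosome", {
  tw <- toy_scaffold_cm(trans = 0.001)
  m <- as.matrix(tw$cm$counts)
  n <- nrow(m)
  ## repeat scaffold contacting chromosome B (s3, s4) ten times more
  rep_row <- c(rep(0.2, 6), rep(2, 6))
  m2 <- rbind(cbind(m, rep_row), c(rep_row, 0))
  sizes <- stats::setNames(c(rep(1.2e5, 4), 4e4), c(tw$scaffolds$name, "rep1"))
  bins <- bin_genome(genome_assembly(sizes), 4e4)
  cm <- contact_matrix(bins, Matrix::Matrix(m2, sparse = TRUE))
  cm$weights <- rep(1, n + 1); cm$balanced <- TRUE
  hc <- assign_high_copy(cm, clusters = list(c1 = "rep1"),
                         chromosomes = list(A = c("s1", "s2"),
                                            B = c("s3", "s4")))
  expect_equal(hc$chrom, "B")
  expect_equal(hc$margin, 10, tolerance = 1e-6)
})

test_that("copy number is the median ratio and rescaling-invariant", {
  cov <- tibble::tibble(
    chrom = rep(c("s1", "s2", "rep1"), each = 5),
    start = rep(0:4 * 1e4, 3), end = rep(1:5 * 1e4, 3),
    value = c(rep(10, 10), rep(110, 5)))
  cn <- copy_number(cov, groups = list(r = "rep1"), reference = c("s1", "s2"))
  expect_equal(cn$copy_number, 11)
  cov2 <- dplyr::mutate(cov, value = value * 3.7)
  expect_equal(copy_number(cov2, list(r = "rep1"),
                           c("s1", "s2"))$copy_number, 11)
  expect_equal(copy_number(cov, list(r = c("s1", "s2")),
                           c("s1", "s2"))$copy_number, 1)
  cov0 <- dplyr::mutate(cov, value = 0)
  expect_error(copy_number(cov0, list(r = "rep1"), c("s1", "s2")), "median")
})
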