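## Independent brute-force oracles and shared (memoised) fixtures.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, fn(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

## brute-force insulation: mean of balanced contacts over the off-diagonal
## w x w square, NA-aware, chromosome-mean log2 normalisation
bf_insulation <- function(m, w, valid = rep(TRUE, nrow(m))) {
  n <- nrow(m)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - w < 1 || i + w > n) next
    vals <- c(); nv <- 0
    for (j in (i - w):(i - 1)) for (k in (i + 1):(i + w)) {
      if (valid[j] && valid[k]) {
        vals <- c(vals, m[j, k]); nv <- nv + 1
      }
    }
    if (nv > 0.5 * w * w) raw[i] <- mean(vals)
  }
  mu <- mean(raw, na.rm = TRUE)
  list(raw = raw, score = log2(raw / mu))
}

## plain iterative proportional fitting run to a tight tolerance
ipf_balance <- function(m, tol = 1e-10, max_iter = 10000) {
  b <- rep(1, nrow(m))
  for (it in seq_len(max_iter)) {
    s <- as.numeric(m %*% b) * b
    if (stats::sd(s) / mean(s) < tol) break
    b <- b / sqrt(s / mean(s))
  }
  b / sqrt(mean(as.numeric(m %*% b) * b))
}

bf_diag_means <- function(m) {
  n <- nrow(m)
  sapply(0:(n - 1), function(d) {
    vals <- c()
    for (i in 1:(n - d)) vals <- c(vals, m[i, i + d])
    mean(vals, na.rm = TRUE)
  })
}

## distance-decay block matrix with multiplicative attenuation at given
## boundaries (bin indices, cut after the bin)
decay_matrix <- function(n, boundaries = integer(0), beta = 0.5,
                         decay = function(d) 10 / (1 + d)) {
  m <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) {
    k <- sum(boundaries >= i & boundaries < j)
    m[i, j] <- m[j, i] <- decay(j - i) * beta^k
  }
  m
}

## wrap a dense matrix as a single-chromosome contact_matrix at `res`
as_cm <- function(m, res = 1e4, balanced = TRUE) {
  n <- nrow(m)
  bins <- bin_genome(genome_assembly(c(chrT = n * res)), res)
  cm <- contact_matrix(bins, Matrix::Matrix(m, sparse = TRUE))
  if (balanced) {
    cm$weights <- rep(1, n)
    cm$balanced <- TRUE
  }
  cm
}

## memoised desk-profile dataset: genome + balanced 10-kb matrix + profile
desk_map <- function(seed, treated = FALSE) {
  fixture(sprintf("desk_%d_%s", seed, treated), function() {
    spec <- synthetic_spec(seed = seed)
    g <- generate_genome(spec)
    use <- if (treated) apply_treatment(spec) else spec
    pairs <- generate_contacts(g, use)
    cm <- ice_balance(pairs_to_matrix(pairs, bin_genome(g$assembly, 1e4)))
    prof <- insulation_score(cm)
    list(spec = spec, genome = g, pairs = pairs, cm = cm, prof = prof)
  })
}

chrom_sizes_of <- function(assembly) {
  stats::setNames(assembly$chroms$length, assembly$chroms$name)
}
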