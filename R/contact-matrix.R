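#' Construct a binned contact matrix
#'
#' Counts are stored raw as a symmetric sparse matrix; balancing weights are
#' kept separately and applied lazily, so both raw and balanced views are
#' available from one container.
#'
#' @param bins A `bin_table` from [bin_genome()].
#' @param counts A symmetric non-negative matrix (dense or [Matrix]) with one
#'   row/column per bin.
#' @param weights Optional per-bin multiplicative balancing factors; `NA`
#'   marks masked bins.
#' @param balanced Logical flag: have weights been fitted?
#' @param discards Count of input records rejected during binning.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, counts, weights = NULL, balanced = FALSE,
                           discards = 0L) {
  n <- nrow(bins)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != n || ncol(counts) != n) {
    stop("counts must be a ", n, " x ", n, " matrix matching the bin table")
  }
  if (!Matrix::isSymmetric(counts, tol = 0)) stop("counts must be symmetric")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  counts <- methods::as(Matrix::forceSymmetric(counts, uplo = "U"),
                        "symmetricMatrix")
  if (is.null(weights)) weights <- rep(NA_real_, n)
  stopifnot(length(weights) == n)
  structure(list(bins = bins, counts = counts, weights = as.numeric(weights),
                 balanced = isTRUE(balanced), converged = NA,
                 discards = as.integer(discards)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  mass <- (sum(x$counts) + sum(Matrix::diag(x$counts))) / 2
  cat(sprintf(paste0("<contact_matrix> %d bins @ %s bp, %.4g contacts, ",
                     "balanced: %s, masked bins: %d, discarded records: %d\n"),
              nrow(x$bins), format(bin_resolution(x$bins)), mass,
              x$balanced, sum(is.na(x$weights) & x$balanced), x$discards))
  invisible(x)
}

#' Bin a stream of valid pairs into a contact matrix
#'
#' Each pair contributes one count to the (bin1, bin2) cell; pairs whose
#' position exceeds the declared chromosome length, or that reference an
#' unknown chromosome, are rejected and tallied in the `discards` field so
#' that matrix mass + discards equals the input record count.
#'
#' @param pairs A tibble of pair records with columns `chrom1`, `pos1`,
#'   `chrom2`, `pos2` (1-based positions, as in the pairs format).
#' @param bins A `bin_table` from [bin_genome()].
#' @return A raw (unbalanced) [contact_matrix()].
#' @export
pairs_to_matrix <- function(pairs, bins) {
  res <- bin_resolution(bins)
  sizes <- attr(bins, "chrom_sizes")
  off <- bin_offsets(bins)
  nb <- bins_per_chrom(bins)
  n <- nrow(bins)

  bin_of <- function(chrom, pos) {
    known <- chrom %in% names(off)
    b <- rep(NA_real_, length(pos))
    ok <- known & pos >= 1 & pos <= sizes[chrom]
    b[ok] <- off[chrom[ok]] + pmin(floor((pos[ok] - 1) / res),
                                   nb[chrom[ok]] - 1)
    b
  }
  i <- bin_of(as.character(pairs$chrom1), as.numeric(pairs$pos1))
  j <- bin_of(as.character(pairs$chrom2), as.numeric(pairs$pos2))
  keep <- !is.na(i) & !is.na(j)
  discards <- sum(!keep)
  i <- i[keep]; j <- j[keep]
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (length(lo)) {
    key <- sort(lo * n + hi)          # exact: integer-valued doubles < 2^53
    runs <- rle(key)
    m <- Matrix::sparseMatrix(i = runs$values %/% n + 1,
                              j = runs$values %% n + 1,
                              x = as.numeric(runs$lengths), dims = c(n, n),
                              symmetric = TRUE)
  } else {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, n), symmetric = TRUE)
  }
  contact_matrix(bins, m, discards = discards)
}

## symmetric sparse matrix of balanced (or raw) values; masked rows/cols zeroed
cm_values <- function(cm, balanced = cm$balanced) {
  m <- cm$counts
  if (balanced && cm$balanced) {
    w <- ifelse(is.na(cm$weights), 0, cm$weights)
    m <- Matrix::Diagonal(x = w) %*% m %*% Matrix::Diagonal(x = w)
    m <- Matrix::forceSymmetric(m, uplo = "U")
  }
  m
}

## dense per-chromosome block with NA at masked bins
cm_dense_chrom <- function(cm, chrom, balanced = cm$balanced) {
  idx <- which(cm$bins$chrom == chrom)
  m <- as.matrix(cm$counts[idx, idx, drop = FALSE])
  if (balanced && cm$balanced) {
    w <- cm$weights[idx]
    m <- m * outer(w, w)
  }
  m
}

#' Iterative-correction (ICE) balancing
#'
#' Fits per-bin multiplicative weights so that the marginals of unmasked bins
#' are equal, removing coverage-type biases. Bins with zero coverage, or whose
#' raw marginal deviates from the median by more than `mad_filter` median
#' absolute deviations, are masked before fitting.
#'
#' @param cm A [contact_matrix()].
#' @param max_iter Maximum number of iterations (default 200).
#' @param tol Convergence tolerance on the coefficient of variation of the
#'   unmasked marginals (default 1e-5).
#' @param mad_filter Low/high-coverage mask threshold in MADs (default 5);
#'   `Inf` disables the coverage filter (zero rows are always masked).
#' @return The matrix with `weights` filled in, `balanced = TRUE` and a
#'   `converged` flag (`FALSE` when `max_iter` was exhausted; no error is
#'   thrown in that case).
#' @export
ice_balance <- function(cm, max_iter = 200, tol = 1e-5, mad_filter = 5) {
  m <- cm$counts
  n <- nrow(m)
  marg <- Matrix::rowSums(m)
  mask <- marg == 0
  if (is.finite(mad_filter) && any(!mask)) {
    med <- stats::median(marg[!mask])
    s <- stats::mad(marg[!mask])
    if (s > 0) mask <- mask | abs(marg - med) > mad_filter * s
  }
  b <- ifelse(mask, 0, 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mb <- as.numeric(m %*% b) * b
    act <- !mask & mb > 0
    if (!any(act)) break
    mu <- mean(mb[act])
    cv <- stats::sd(mb[act]) / mu
    if (is.na(cv) || cv < tol) { converged <- TRUE; break }
    adj <- rep(1, n)
    adj[act] <- sqrt(mb[act] / mu)
    b <- b / adj
  }
  ## normalise so the mean balanced marginal over unmasked bins is 1
  mb <- as.numeric(m %*% b) * b
  act <- !mask & mb > 0
  if (any(act)) b <- b / sqrt(mean(mb[act]))
  out <- cm
  out$weights <- ifelse(mask | b == 0, NA_real_, b)
  out$balanced <- TRUE
  out$converged <- converged
  out
}
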