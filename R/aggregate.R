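#' Distance-decay expected model
#'
#' Mean balanced contact at each bin separation, per chromosome (default)
#' or pooled genome-wide, optionally smoothed by a 3-bin running mean in
#' log space. This is the denominator of observed/expected maps.
#'
#' @param cm A [contact_matrix()].
#' @param pooled Pool chromosomes into one genome-wide model (default
#'   `FALSE`: per-chromosome).
#' @param smooth Apply the 3-bin log-space running mean (default `TRUE`);
#'   the raw per-diagonal means are always kept alongside.
#' @return An object of class `expected_model`: tibble with `chrom`
#'   (`"genome"` when pooled), `offset` (bins), `raw`, `expected`, `n`.
#' @export
expected_by_distance <- function(cm, pooled = FALSE, smooth = TRUE) {
  per <- lapply(unique(cm$bins$chrom), function(cn) {
    m <- cm_dense_chrom(cm, cn)
    if (cm$balanced) {
      idx <- which(cm$bins$chrom == cn)
      bad <- is.na(cm$weights[idx])
      m[bad, ] <- NA; m[, bad] <- NA
    }
    d <- diag_means(m)
    tibble::tibble(chrom = cn, offset = seq_along(d$mean) - 1,
                   raw = d$mean, n = d$n)
  })
  df <- dplyr::bind_rows(per)
  if (pooled) {
    df <- dplyr::summarise(
      dplyr::group_by(df, .data$offset),
      raw = stats::weighted.mean(.data$raw, .data$n, na.rm = TRUE),
      n = sum(.data$n), .groups = "drop")
    df <- dplyr::mutate(df, chrom = "genome", .before = 1)
  }
  smooth3 <- function(x) {
    lx <- log(pmax(x, 1e-300))
    sm <- stats::filter(lx, rep(1 / 3, 3), sides = 2)
    out <- exp(as.numeric(sm))
    out[is.na(out)] <- x[is.na(out)]
    out
  }
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$chrom),
    expected = if (smooth) smooth3(.data$raw) else .data$raw)
  df <- dplyr::ungroup(df)
  df$expected[!is.finite(df$raw) | df$raw <= 0] <- NA
  structure(df, class = c("expected_model", class(df)),
            pooled = pooled, resolution = bin_resolution(cm$bins))
}

## dense per-chromosome observed/expected matrix
oe_chrom <- function(cm, expected, cn) {
  m <- cm_dense_chrom(cm, cn)
  idx <- which(cm$bins$chrom == cn)
  if (cm$balanced) {
    bad <- is.na(cm$weights[idx])
    m[bad, ] <- NA; m[, bad] <- NA
  }
  key <- if (isTRUE(attr(expected, "pooled"))) "genome" else cn
  e <- expected$expected[expected$chrom == key]
  n <- nrow(m)
  ed <- e[pmin(abs(col(m) - row(m)) + 1, length(e))]
  dim(ed) <- dim(m)
  m / ed
}

#' Aggregate observed/expected contacts around sites (pileup)
#'
#' Extracts the observed/expected submatrix centred on every site and
#' averages it elementwise across sites; the reported map is log10 of the
#' per-cell mean (a mean of per-site logs is also returned, but at finite
#' sequencing depth single-site cells are frequently empty, so the linear
#' mean is the interpretable statistic). Sites within `flank` of a
#' chromosome end are dropped and counted. Sites with an `orientation`
#' column are aligned to a canonical `+` orientation (both axes reversed
#' for `-` sites) before averaging, preserving asymmetric features. Values
#' are floored at `floor`; cells with fewer than `min_sites` contributing
#' sites are undefined.
#'
#' @param cm A balanced [contact_matrix()].
#' @param sites A tibble with `chrom` and `pos` (or a `boundary_set`).
#' @param expected An [expected_by_distance()] model (computed on the fly
#'   when `NULL`).
#' @param flank Half-width in bp (default 500 kb).
#' @param min_sites Minimal contributing sites per cell (default 10).
#' @param floor Lower floor on observed/expected before log (default 1e-4).
#' @return An object of class `hic_pileup`: `log10_oe` (log10 of the
#'   per-cell mean obs/exp), `linear_oe`, `mean_log10_oe` matrices,
#'   `n_sites`, `n_dropped`, `flank`, `resolution`.
#' @export
pileup <- function(cm, sites, expected = NULL, flank = 5e5, min_sites = 10,
                   floor = 1e-4) {
  res <- bin_resolution(cm$bins)
  f <- as.integer(round(flank / res))
  if (is.null(expected)) expected <- expected_by_distance(cm)
  if (inherits(sites, "boundary_set") ||
      (!"pos" %in% names(sites) && all(c("start", "end") %in% names(sites)))) {
    sites <- dplyr::mutate(tibble::as_tibble(sites),
                           pos = (.data$start + .data$end) / 2)
  }
  orient <- if ("orientation" %in% names(sites)) sites$orientation else
    rep("+", nrow(sites))
  k <- 2 * f + 1
  sum_log <- matrix(0, k, k); sum_lin <- matrix(0, k, k)
  cnt <- matrix(0, k, k)
  n_used <- 0; n_dropped <- 0
  for (cn in unique(sites$chrom)) {
    rows <- which(sites$chrom == cn)
    nbins <- sum(cm$bins$chrom == cn)
    if (nbins == 0) { n_dropped <- n_dropped + length(rows); next }
    oe <- NULL
    for (r in rows) {
      b <- floor(sites$pos[r] / res) + 1
      if (b - f < 1 || b + f > nbins) { n_dropped <- n_dropped + 1; next }
      if (is.null(oe)) oe <- oe_chrom(cm, expected, cn)
      sub <- oe[(b - f):(b + f), (b - f):(b + f)]
      if (orient[r] == "-") sub <- sub[k:1, k:1]
      ok <- is.finite(sub)
      sub_f <- pmax(sub, floor)
      sum_log[ok] <- sum_log[ok] + log10(sub_f[ok])
      sum_lin[ok] <- sum_lin[ok] + sub_f[ok]
      cnt[ok] <- cnt[ok] + 1
      n_used <- n_used + 1
    }
  }
  if (n_used == 0) stop("no usable sites for pileup")
  mean_log <- sum_log / cnt
  linear_oe <- sum_lin / cnt
  mean_log[cnt < min_sites] <- NA
  linear_oe[cnt < min_sites] <- NA
  structure(list(log10_oe = log10(linear_oe), linear_oe = linear_oe,
                 mean_log10_oe = mean_log,
                 n_sites = n_used, n_dropped = n_dropped,
                 flank = flank, resolution = res, min_sites = min_sites),
            class = "hic_pileup")
}

#' @export
print.hic_pileup <- function(x, ...) {
  cat(sprintf("<hic_pileup> %d x %d cells @ %s bp, %d site(s), %d dropped\n",
              nrow(x$log10_oe), ncol(x$log10_oe), format(x$resolution),
              x$n_sites, x$n_dropped))
  invisible(x)
}

#' Separation-matched boundary depletion of a pileup
#'
#' Mean observed/expected of cells whose bin pair straddles the pileup
#' centre, divided by the mean of same-separation cells lying entirely on
#' one side. Because the expected model is fitted on the full map and
#' absorbs the genome-average attenuation, this matched ratio — not the raw
#' cross-quadrant obs/exp — recovers the per-crossing contact attenuation.
#'
#' @param p A [pileup()] result.
#' @return A single ratio (1 = no insulation at the centre).
#' @export
pileup_boundary_depletion <- function(p) {
  m <- p$linear_oe
  k <- nrow(m)
  ctr <- (k + 1) / 2
  idx <- which(upper.tri(m), arr.ind = TRUE)
  d <- idx[, 2] - idx[, 1]
  cross <- idx[, 1] < ctr & idx[, 2] > ctr
  val <- m[idx]
  num <- den <- wts <- numeric(0)
  for (dd in sort(unique(d))) {
    sel <- d == dd
    a <- val[sel & cross]; b <- val[sel & !cross]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) >= 1 && length(b) >= 2) {
      num <- c(num, mean(a)); den <- c(den, mean(b))
      wts <- c(wts, min(length(a), length(b)))
    }
  }
  if (!length(num)) return(NA_real_)
  stats::weighted.mean(num / den, wts)
}

#' Compare two pileups (treated versus control)
#'
#' Elementwise log2 ratio of the linear-scale pileups; geometries must be
#' identical.
#'
#' @param a,b Two [pileup()] results on the same flank/resolution.
#' @return A matrix of log2(a/b) values.
#' @export
compare_conditions <- function(a, b) {
  if (!identical(dim(a$log10_oe), dim(b$log10_oe)) ||
      a$flank != b$flank || a$resolution != b$resolution) {
    stop("pileup geometries differ")
  }
  log2(a$linear_oe / b$linear_oe)
}
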