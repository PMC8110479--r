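#' Genome-wide contact probability versus distance, P(s)
#'
#' Computes cis contact frequency per geometric distance bin, normalised per
#' chromosome by the number of possible locus pairs at those separations and
#' pooled across chromosomes weighted by observation count, so long
#' chromosomes do not dominate.
#'
#' @param pairs A pairs tibble (1-based positions).
#' @param assembly The [genome_assembly()] the pairs refer to.
#' @param bin_ratio Geometric binning factor (> 1, default `2^(1/8)`).
#' @param s_min Smallest separation binned (default 1 kb).
#' @param min_obs Bins with fewer observations are reported but flagged
#'   unusable for fitting (default 10).
#' @return A tibble of class `scaling_curve` with `s` (bin geometric mid,
#'   bp), `P`, `n_obs`, `usable`.
#' @export
ps_from_pairs <- function(pairs, assembly, bin_ratio = 2^(1 / 8),
                          s_min = 1e3, min_obs = 10) {
  stopifnot(bin_ratio > 1)
  cis <- pairs[pairs$chrom1 == pairs$chrom2, ]
  if (nrow(cis) == 0) stop("no cis pairs")
  s <- abs(cis$pos2 - cis$pos1)
  lens <- chrom_lengths(assembly)
  s_max <- max(lens)
  edges <- s_min * bin_ratio^(0:ceiling(log(s_max / s_min, bin_ratio)))
  edges[length(edges)] <- s_max + 1
  nb <- length(edges) - 1
  keep <- s >= s_min
  bin <- findInterval(s[keep], edges, rightmost.closed = TRUE)
  chrom <- cis$chrom1[keep]
  counts <- matrix(0, nb, length(lens),
                   dimnames = list(NULL, names(lens)))
  tab <- table(factor(bin, levels = seq_len(nb)), factor(chrom, levels = names(lens)))
  counts[] <- as.numeric(tab)
  ## possible locus pairs at separation in [a, b): integral of (L - s) ds
  poss <- sapply(names(lens), function(cn) {
    L <- lens[[cn]]
    a <- pmin(edges[-length(edges)], L); b <- pmin(edges[-1], L)
    (b - a) * L - (b^2 - a^2) / 2
  })
  freq <- counts / pmax(poss, 1e-300)
  freq[poss <= 0] <- NA
  n_obs <- rowSums(counts)
  P <- rowSums(freq * counts, na.rm = TRUE) / pmax(n_obs, 1)
  out <- tibble::tibble(s = sqrt(edges[-length(edges)] * edges[-1]),
                        s_lo = edges[-length(edges)], s_hi = edges[-1],
                        P = P, n_obs = n_obs, usable = n_obs >= min_obs)
  out <- out[out$n_obs > 0 | out$s_lo < s_max, ]
  attr(out, "bin_ratio") <- bin_ratio
  class(out) <- c("scaling_curve", class(out))
  out
}

#' Contact probability from a binned matrix (per-diagonal means)
#'
#' Linear-binned counterpart of [ps_from_pairs()] computed from a
#' [contact_matrix()]; used for per-domain-square curves and cross-checks.
#'
#' @param cm A [contact_matrix()].
#' @return A `scaling_curve` tibble with `s` = separation in bp at the
#'   matrix resolution.
#' @export
ps_from_matrix <- function(cm) {
  res <- bin_resolution(cm$bins)
  per <- lapply(unique(cm$bins$chrom), function(cn) {
    m <- cm_dense_chrom(cm, cn)
    n <- nrow(m)
    if (n < 2) return(NULL)
    d <- diag_means(m)
    tibble::tibble(chrom = cn, offset = seq_along(d$mean) - 1,
                   P = d$mean, n_obs = d$n)
  })
  df <- dplyr::bind_rows(per)
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$offset),
    P = stats::weighted.mean(.data$P, .data$n_obs + 1e-12, na.rm = TRUE),
    n_obs = sum(.data$n_obs), .groups = "drop")
  out <- tibble::tibble(s = (agg$offset + 0.5) * res, offset = agg$offset,
                        P = agg$P, n_obs = agg$n_obs,
                        usable = agg$n_obs > 0)
  attr(out, "resolution") <- res
  class(out) <- c("scaling_curve", class(out))
  out
}

## per-diagonal means of a square matrix, NA-aware
diag_means <- function(m) {
  n <- nrow(m)
  idx <- col(m) - row(m)
  ok <- idx >= 0 & !is.na(m)
  sums <- tapply(m[ok], idx[ok], sum)
  cnts <- tapply(rep(1, sum(ok)), idx[ok], sum)
  mean_v <- rep(NA_real_, n); n_v <- rep(0, n)
  pos <- as.integer(names(sums)) + 1
  mean_v[pos] <- sums / cnts
  n_v[pos] <- cnts
  list(mean = mean_v, n = n_v)
}

#' Fit a power-law exponent over a distance range
#'
#' Ordinary least squares of log10 P on log10 s over usable bins inside
#' `fit_range`.
#'
#' @param curve A `scaling_curve`.
#' @param fit_range Two-element range of s (bp), default `c(5e4, 2e6)`.
#' @return A list with `exponent`, `se`, `n_bins`, `fit_range`.
#' @export
fit_exponent <- function(curve, fit_range = c(5e4, 2e6)) {
  sel <- curve$usable & curve$s >= fit_range[1] & curve$s <= fit_range[2] &
    is.finite(curve$P) & curve$P > 0
  if (sum(sel) < 3) stop("fewer than 3 usable bins in fit range")
  fit <- stats::lm(log10(P) ~ log10(s), data = curve[sel, ])
  co <- summary(fit)$coefficients
  list(exponent = unname(co[2, 1]), se = unname(co[2, 2]),
       n_bins = sum(sel), fit_range = fit_range)
}

#' Segment a scaling curve into decay regimes
#'
#' Fits a continuous piecewise-linear function with `knots` breakpoints to
#' log10 P versus log10 s by exhaustive search over breakpoint placements at
#' bin positions, minimising squared error. With two knots this separates
#' the shallow intralayer decay from the steep drop beyond the rod length.
#'
#' @param curve A `scaling_curve` with at least 10 usable bins.
#' @param knots Number of breakpoints (default 2).
#' @return An object of class `regime_fit`: `breakpoints` (bp), `slopes`
#'   (one per segment), `sse`, and the fitted points.
#' @export
segment_regimes <- function(curve, knots = 2) {
  sel <- curve$usable & is.finite(curve$P) & curve$P > 0
  x <- log10(curve$s[sel]); y <- log10(curve$P[sel])
  if (length(x) < 10) stop("need at least 10 populated bins")
  n <- length(x)
  cand <- x[2:(n - 1)]
  basis <- function(bks) {
    X <- cbind(1, x)
    for (b in bks) X <- cbind(X, pmax(x - b, 0))
    X
  }
  best <- NULL
  combs <- if (knots == 1) matrix(cand, ncol = 1) else
    t(utils::combn(cand, knots))
  for (r in seq_len(nrow(combs))) {
    bks <- combs[r, ]
    fit <- stats::lm.fit(basis(bks), y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(bks = bks, sse = sse, coef = fit$coefficients)
    }
  }
  co <- best$coef
  co[is.na(co)] <- 0
  slopes <- cumsum(co[-1])
  fitted_y <- basis(best$bks) %*% co
  structure(list(breakpoints = 10^best$bks, slopes = unname(slopes),
                 sse = best$sse,
                 points = tibble::tibble(s = 10^x, P = 10^y,
                                         fitted = as.numeric(10^fitted_y))),
            class = "regime_fit")
}

#' @export
print.regime_fit <- function(x, ...) {
  cat("<regime_fit>\n  breakpoints (bp):",
      paste(format(round(x$breakpoints)), collapse = ", "),
      "\n  slopes:", paste(round(x$slopes, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Per-domain-square P(s) curves
#'
#' The grid of domain boundaries partitions each chromosome map into
#' squares; each square's curve is the per-diagonal mean of balanced
#' entries. For squares off the main diagonal the smallest and largest s are
#' trimmed (single-cell diagonals are noisy).
#'
#' @param cm A [contact_matrix()] (typically 50-kb bins).
#' @param boundaries A `boundary_set` or tibble with `chrom` and boundary
#'   `start` positions (bp).
#' @param min_bins Squares smaller than this many bins yield no curve
#'   (default 3).
#' @return A tibble: `chrom`, `row_domain`, `col_domain`, `on_diag`, `s`
#'   (bp), `P`, `n_obs`.
#' @export
ps_domain_squares <- function(cm, boundaries, min_bins = 3) {
  res <- bin_resolution(cm$bins)
  out <- list()
  for (cn in unique(cm$bins$chrom)) {
    sub <- cm$bins[cm$bins$chrom == cn, ]
    n <- nrow(sub)
    L <- max(sub$end)
    bpos <- sort(boundaries$start[boundaries$chrom == cn])
    edges <- unique(c(0, round(bpos / res), n))
    edges <- edges[edges >= 0 & edges <= n]
    nd <- length(edges) - 1
    if (nd < 1) next
    m <- cm_dense_chrom(cm, cn)
    for (a in seq_len(nd)) {
      for (b in a:nd) {
        ri <- (edges[a] + 1):edges[a + 1]
        ci <- (edges[b] + 1):edges[b + 1]
        if (length(ri) < min_bins || length(ci) < min_bins) next
        block <- m[ri, ci, drop = FALSE]
        off <- outer(ci, ri, "-")  # col bin - row bin
        ok <- !is.na(t(block))
        sums <- tapply(t(block)[ok], off[ok], sum)
        cnts <- tapply(rep(1, sum(ok)), off[ok], sum)
        svals <- as.integer(names(sums))
        keep <- rep(TRUE, length(svals))
        if (a != b) {
          keep <- svals != min(svals) & svals != max(svals)
        } else {
          keep <- svals >= 0
        }
        if (!any(keep)) next
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = cn, row_domain = a, col_domain = b, on_diag = a == b,
          s = (svals[keep] + 0.5) * res,
          P = as.numeric(sums[keep] / cnts[keep]),
          n_obs = as.numeric(cnts[keep]))
      }
    }
  }
  res_df <- dplyr::bind_rows(out)
  attr(res_df, "resolution") <- res
  res_df
}

#' Estimate the inert gap between two domains by curve shifting
#'
#' Grid search over x-axis shifts of the inter-domain curve that best
#' overlays it on the reference intra-domain curve (squared difference of
#' log P over the overlapping support); the estimated shift is the putative
#' inert spacer size between the domains.
#'
#' @param inter_curve,ref_curve Tibbles with `s` and `P` on a common linear
#'   binning (e.g. from [ps_domain_squares()]).
#' @param max_shift Largest shift searched (bp).
#' @param step Grid step (bp); defaults to the curves' bin width. At least
#'   three s-bins must overlap for a shift to be evaluated.
#' @return A list with `shift` (bp), `residual`, `censored` (`TRUE` when the
#'   optimum sits at `max_shift`), and the residual profile.
#' @export
gap_shift <- function(inter_curve, ref_curve, max_shift = 1e6, step = NULL) {
  sdiff <- sort(unique(round(diff(sort(unique(ref_curve$s))))))
  if (is.null(step)) step <- sdiff[1]
  shifts <- seq(0, max_shift, by = step)
  resid <- rep(NA_real_, length(shifts))
  ref <- ref_curve[is.finite(ref_curve$P) & ref_curve$P > 0, ]
  inter <- inter_curve[is.finite(inter_curve$P) & inter_curve$P > 0, ]
  s0 <- if (nrow(ref)) min(ref$s) else 0
  for (si in seq_along(shifts)) {
    s_shifted <- inter$s - shifts[si]
    ## grid-align on integer multiples of the step (offsets from the first
    ## reference bin, so half-bin grid origins cannot round inconsistently)
    idx <- match(round((s_shifted - s0) / step), round((ref$s - s0) / step))
    ok <- !is.na(idx)
    if (sum(ok) < 3) next
    resid[si] <- mean((log10(inter$P[ok]) - log10(ref$P[idx[ok]]))^2)
  }
  if (all(is.na(resid))) {
    return(list(shift = NA_real_, residual = NA_real_, censored = NA,
                profile = tibble::tibble(shift = shifts, residual = resid)))
  }
  best <- which.min(resid)
  list(shift = shifts[best], residual = resid[best],
       censored = best == length(shifts),
       profile = tibble::tibble(shift = shifts, residual = resid))
}

#' Terminal versus internal domain contact enrichment
#'
#' Compares short-range contact frequency (s at most `s_max`) between the two
#' terminal domains of each chromosome and its internal domains, the
#' signature of telomeric chromatin compaction. Chromosomes with fewer than
#' three domains are excluded (no internal domain to compare against).
#' The ratio averages per-separation terminal/internal ratios over
#' separations populated in both classes, so unequal domain sizes do not
#' bias it.
#'
#' @param cm A [contact_matrix()]; balanced values are used when weights are
#'   present, raw counts otherwise.
#' @param boundaries Boundary set defining the domain grid.
#' @param s_max Separation cap in bp (default 1 Mb).
#' @return A list with `ratio`, per-class exponents, the per-separation
#'   table and the excluded chromosomes.
#' @export
terminal_vs_internal <- function(cm, boundaries, s_max = 1e6) {
  sq <- ps_domain_squares(cm, boundaries)
  sq <- sq[sq$on_diag, ]
  excluded <- character(0)
  per <- list()
  for (cn in unique(cm$bins$chrom)) {
    d <- sq[sq$chrom == cn, ]
    nd <- length(unique(d$row_domain))
    if (nd < 3) { excluded <- c(excluded, cn); next }
    last <- max(d$row_domain)
    d$class <- ifelse(d$row_domain %in% c(1, last), "terminal", "internal")
    per[[cn]] <- d
  }
  if (!length(per)) stop("no chromosome with >= 3 domains")
  all_d <- dplyr::bind_rows(per)
  agg <- dplyr::summarise(
    dplyr::group_by(all_d, .data$class, .data$s),
    P = stats::weighted.mean(.data$P, .data$n_obs, na.rm = TRUE),
    n_obs = sum(.data$n_obs), .groups = "drop")
  wide <- tidyr::pivot_wider(agg, names_from = "class",
                             values_from = c("P", "n_obs"))
  wide <- wide[wide$s <= s_max & is.finite(wide$P_terminal) &
                 is.finite(wide$P_internal) & wide$P_internal > 0, ]
  if (nrow(wide) == 0) stop("no overlapping separations at or below s_max")
  w <- pmin(wide$n_obs_terminal, wide$n_obs_internal)
  ratio <- stats::weighted.mean(wide$P_terminal / wide$P_internal, w)
  exp_of <- function(cl) {
    cur <- agg[agg$class == cl & agg$P > 0, ]
    cur$usable <- cur$n_obs >= 10
    if (sum(cur$usable) < 3) return(NA_real_)
    fit_exponent(cur, fit_range = range(cur$s[cur$usable]))$exponent
  }
  list(ratio = ratio,
       exponent_terminal = exp_of("terminal"),
       exponent_internal = exp_of("internal"),
       by_separation = wide, excluded = excluded)
}
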