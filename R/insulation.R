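#' Insulation analysis configuration
#'
#' @param window Insulation window W in bp (default 500 kb): the score at a
#'   bin averages balanced contacts crossing it within W on each side.
#' @param resolution Matrix resolution in bp (default 10 kb).
#' @param delta_span Span of the delta vector used for boundary calling
#'   (default 100 kb).
#' @param strength_min Minimal boundary strength retained (default 0.2).
#' @return A list of class `insulation_config`.
#' @export
insulation_config <- function(window = 500e3, resolution = 10e3,
                              delta_span = 100e3, strength_min = 0.2) {
  stopifnot(window %% resolution == 0, delta_span %% resolution == 0,
            window > 0, delta_span > 0)
  structure(list(window = window, resolution = resolution,
                 delta_span = delta_span, strength_min = strength_min),
            class = "insulation_config")
}

## O(1)-per-bin rectangle sums of the off-diagonal w x w square via a
## summed-area table.
rect_sums <- function(m, w) {
  n <- nrow(m)
  S <- matrix(0, n + 1, n + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum)  # S[i+1,j+1] = sum m[1:i,1:j]
  S <- t(S)
  i <- seq_len(n)
  r1 <- i - w; r2 <- i - 1    # rows (1-based)
  c1 <- i + 1; c2 <- i + w    # cols
  ok <- r1 >= 1 & c2 <= n
  out <- rep(NA_real_, n)
  ii <- which(ok)
  out[ii] <- S[cbind(r2[ii] + 1, c2[ii] + 1)] - S[cbind(r1[ii], c2[ii] + 1)] -
    S[cbind(r2[ii] + 1, c1[ii])] + S[cbind(r1[ii], c1[ii])]
  out
}

#' Insulation-score profile
#'
#' For each 10-kb (by default) bin the raw score is the mean balanced
#' contact frequency over the `w x w` square of bin pairs that straddle it
#' within the insulation window; the reported score is log2 of the raw score
#' over its chromosome mean. Bins within one window of a chromosome end, and
#' bins whose window square is more than half masked, are undefined.
#' Chromosomes shorter than `2 * window + resolution` yield no defined bins,
#' mirroring the exclusion of chromosomes too short for this analysis.
#'
#' @param cm A balanced [contact_matrix()] at `cfg$resolution`.
#' @param cfg An [insulation_config()].
#' @return A tibble of class `insulation_profile` with per-bin `raw`,
#'   `score`, and `n_valid` (defined window cells).
#' @export
insulation_score <- function(cm, cfg = insulation_config()) {
  res <- bin_resolution(cm$bins)
  if (!isTRUE(all.equal(res, cfg$resolution))) {
    stop("matrix resolution (", res, ") differs from cfg$resolution (",
         cfg$resolution, ")")
  }
  w <- as.integer(cfg$window / res)
  profs <- lapply(unique(cm$bins$chrom), function(cn) {
    sub <- cm$bins[cm$bins$chrom == cn, ]
    n <- nrow(sub)
    out <- tibble::tibble(chrom = cn, start = sub$start, end = sub$end,
                          bin_id = sub$bin_id, raw = NA_real_,
                          score = NA_real_, n_valid = NA_real_)
    if (n < 2 * w + 1) return(out)
    b <- cm_dense_chrom(cm, cn)
    idx <- which(cm$bins$chrom == cn)
    wts <- cm$weights[idx]
    valid <- if (cm$balanced) !is.na(wts) else rep(TRUE, n)
    vm <- outer(valid, valid)
    bz <- b; bz[!vm] <- 0; bz[is.na(bz)] <- 0
    sums <- rect_sums(bz, w)
    nval <- rect_sums(vm * 1, w)
    raw <- ifelse(!is.na(nval) & nval > 0.5 * w * w, sums / nval, NA_real_)
    mu <- mean(raw, na.rm = TRUE)
    out$raw <- raw
    out$n_valid <- nval
    if (is.finite(mu) && mu > 0) out$score <- log2(raw / mu)
    out
  })
  prof <- dplyr::bind_rows(profs)
  attr(prof, "config") <- cfg
  class(prof) <- c("insulation_profile", class(prof))
  prof
}

## delta vector: mean score over (i, i+ds] minus mean over [i-ds, i)
insulation_delta <- function(score, ds) {
  n <- length(score)
  delta <- rep(NA_real_, n)
  if (n < 2 * ds + 1) return(delta)
  cs <- cumsum(ifelse(is.na(score), 0, score))
  nas <- cumsum(is.na(score))
  win_sum <- function(a, b) cs[b] - ifelse(a > 1, cs[a - 1], 0)
  win_nas <- function(a, b) nas[b] - ifelse(a > 1, nas[a - 1], 0)
  i <- (ds + 1):(n - ds)
  right <- win_sum(i + 1, i + ds); rna <- win_nas(i + 1, i + ds)
  left <- win_sum(i - ds, i - 1); lna <- win_nas(i - ds, i - 1)
  d <- right / ds - left / ds
  d[rna > 0 | lna > 0] <- NA_real_
  delta[i] <- d
  delta
}

#' Call domain boundaries from an insulation profile
#'
#' Candidates are downward-to-upward zero crossings of the delta vector;
#' strength is the height difference between the nearest local maximum of
#' delta right of the crossing and the nearest local minimum left of it.
#' Candidates with strength below `cfg$strength_min` are dropped.
#'
#' @param profile An [insulation_score()] profile.
#' @param cfg The matching [insulation_config()].
#' @return A tibble of class `boundary_set`: one `resolution`-wide interval
#'   per boundary with its `strength` and `provenance = "called"`.
#' @export
call_boundaries <- function(profile, cfg = attr(profile, "config")) {
  ds <- as.integer(cfg$delta_span / cfg$resolution)
  res <- cfg$resolution
  out <- lapply(unique(profile$chrom), function(cn) {
    p <- profile[profile$chrom == cn, ]
    delta <- insulation_delta(p$score, ds)
    n <- length(delta)
    hits <- which(delta[-n] < 0 & delta[-1] >= 0)
    if (!length(hits)) return(NULL)
    recs <- lapply(hits, function(i) {
      ## nearest local min of delta to the left (monotone descent)
      j <- i
      while (j > 1 && !is.na(delta[j - 1]) && delta[j - 1] <= delta[j]) j <- j - 1
      k <- i + 1
      while (k < n && !is.na(delta[k + 1]) && delta[k + 1] >= delta[k]) k <- k + 1
      strength <- delta[k] - delta[j]
      ## boundary bin: the score minimum between the delta extrema
      span <- i:(i + 1)
      sc <- p$score[span]
      b <- if (all(is.na(sc))) i else span[which.min(sc)]
      tibble::tibble(chrom = cn, start = p$start[b], end = p$end[b],
                     bin = b, strength = strength)
    })
    dplyr::bind_rows(recs)
  })
  bs <- dplyr::bind_rows(out)
  if (nrow(bs) == 0) {
    bs <- tibble::tibble(chrom = character(), start = numeric(),
                         end = numeric(), bin = integer(),
                         strength = numeric())
  }
  bs <- bs[!is.na(bs$strength) & bs$strength >= cfg$strength_min, ]
  bs <- dplyr::distinct(bs, .data$chrom, .data$start, .keep_all = TRUE)
  bs$provenance <- rep("called", nrow(bs))
  attr(bs, "config") <- cfg
  class(bs) <- c("boundary_set", class(bs))
  bs
}

#' Snap boundary calls to the local insulation minimum
#'
#' Each boundary is moved to the bin with the minimal insulation score within
#' `max_shift` bins, the automated counterpart of correcting calls by one or
#' two bins; a boundary moves only when the minimum is unique and strictly
#' below its current score (ties keep the original position).
#'
#' @param boundaries A `boundary_set`.
#' @param profile The matching [insulation_score()] profile.
#' @param max_shift Maximal shift in bins (default 2).
#' @return The refined `boundary_set` (`provenance = "refined"` where moved).
#' @export
refine_boundaries <- function(boundaries, profile, max_shift = 2) {
  if (nrow(boundaries) == 0) return(boundaries)
  out <- boundaries
  for (r in seq_len(nrow(boundaries))) {
    p <- profile[profile$chrom == boundaries$chrom[r], ]
    b <- boundaries$bin[r]
    cand <- max(1, b - max_shift):min(nrow(p), b + max_shift)
    sc <- p$score[cand]
    if (all(is.na(sc))) next
    mn <- min(sc, na.rm = TRUE)
    winners <- cand[!is.na(sc) & sc == mn]
    if (length(winners) == 1 && winners != b &&
        (is.na(p$score[b]) || mn < p$score[b])) {
      out$bin[r] <- winners
      out$start[r] <- p$start[winners]
      out$end[r] <- p$end[winners]
      out$provenance[r] <- "refined"
    }
  }
  dplyr::arrange(out, match(.data$chrom, unique(profile$chrom)), .data$start)
}

#' Flag boundaries that lie in contiguous (N-gap-free) sequence
#'
#' The boundary interval plus `flank` on each side (30 kb total by default)
#' is scanned for runs of at least `run_min` consecutive Ns; `in_contig` is
#' `TRUE` when none is found, `NA` when sequence is unavailable (such
#' boundaries are kept, not dropped).
#'
#' @param boundaries A `boundary_set`.
#' @param assembly A [genome_assembly()] with sequence.
#' @param flank Flank on each side in bp (default 10 kb).
#' @param run_min Disqualifying N-run length (default 24).
#' @return The `boundary_set` with an `in_contig` column.
#' @export
contig_filter <- function(boundaries, assembly, flank = 10e3, run_min = 24) {
  boundaries$in_contig <- vapply(seq_len(nrow(boundaries)), function(r) {
    n_gap_scan(assembly, boundaries$chrom[r],
               boundaries$start[r] - flank, boundaries$end[r] + flank,
               run_min = run_min)
  }, NA)
  boundaries
}

#' Score boundary calls against known positions
#'
#' Utility for validation on synthetic data: matches called boundaries to
#' reference positions within `tol_bins` bins and reports recall, precision
#' and the matched pairs. When a profile is supplied, reference boundaries at
#' which the insulation delta is undefined (within `window + delta_span` of a
#' chromosome end) are excluded, since no caller can assess them there.
#'
#' @param called A `boundary_set`.
#' @param truth A tibble with `chrom` and `pos` (bp) of reference boundaries.
#' @param resolution Bin width used for matching.
#' @param tol_bins Matching tolerance in bins (default 1).
#' @param profile Optional insulation profile used to restrict `truth` to
#'   assessable positions.
#' @return A list with `recall`, `precision`, `n_truth`, `n_called`,
#'   `n_matched`.
#' @export
score_boundary_calls <- function(called, truth, resolution, tol_bins = 1,
                                 profile = NULL) {
  truth_bin <- floor(truth$pos / resolution)
  keep <- rep(TRUE, nrow(truth))
  if (!is.null(profile)) {
    cfg <- attr(profile, "config")
    ds <- cfg$delta_span / cfg$resolution
    for (r in seq_len(nrow(truth))) {
      p <- profile[profile$chrom == truth$chrom[r], ]
      b <- truth_bin[r] + 1
      lo <- b - ds; hi <- b + ds
      keep[r] <- lo >= 1 && hi <= nrow(p) && !anyNA(p$score[lo:hi])
    }
  }
  truth <- truth[keep, ]; truth_bin <- truth_bin[keep]
  called_bin <- floor(called$start / resolution)
  matched_t <- 0; matched_c <- rep(FALSE, nrow(called))
  for (r in seq_len(nrow(truth))) {
    hit <- which(called$chrom == truth$chrom[r] &
                   abs(called_bin - truth_bin[r]) <= tol_bins)
    if (length(hit)) {
      matched_t <- matched_t + 1
      matched_c[hit] <- TRUE
    }
  }
  list(recall = if (nrow(truth)) matched_t / nrow(truth) else NA_real_,
       precision = if (nrow(called)) mean(matched_c) else NA_real_,
       n_truth = nrow(truth), n_called = nrow(called),
       n_matched = matched_t)
}
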