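## Gene-orientation blocks, convergent/divergent sites, and genomic tracks
## (GC, densities, stranded expression) with feature- and telomere-centred
## profiles.

#' Find blocks of co-oriented genes
#'
#' Run-length encodes gene strands along each chromosome: a block is a
#' maximal run of consecutive same-strand genes. Adjacent blocks therefore
#' always have opposite strands, and block sizes partition the gene count.
#'
#' @param genes A gene table (`gene_id`, `chrom`, `start`, `end`, `strand`),
#'   sorted by chromosome then start (as from [read_gff_genes()]).
#' @return A tibble of class `orientation_blocks`: `chrom`, `block_id`,
#'   `size`, `strand`, `span_start` (first gene start), `span_end` (last
#'   gene end), `first_gene`.
#' @export
find_blocks <- function(genes) {
  out <- lapply(unique(genes$chrom), function(cn) {
    g <- genes[genes$chrom == cn, ]
    if (nrow(g) == 0) return(NULL)
    r <- rle(g$strand)
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    tibble::tibble(chrom = cn, block_id = seq_along(r$lengths),
                   size = r$lengths, strand = r$values,
                   span_start = g$start[starts], span_end = g$end[ends],
                   first_gene = g$gene_id[starts])
  })
  blocks <- dplyr::bind_rows(out)
  class(blocks) <- c("orientation_blocks", class(blocks))
  blocks
}

#' Block-size statistics
#'
#' @param blocks An [find_blocks()] result.
#' @return A list: `histogram` (per block size: number of blocks and genes),
#'   `cumulative` (fraction of genes in blocks of at least each size),
#'   `singleton_gene_fraction` (genes without a co-oriented neighbour) and
#'   `median_block_size` (gene-weighted median).
#' @export
block_stats <- function(blocks) {
  hist <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(blocks), .data$size),
                           n_blocks = dplyr::n(),
                           n_genes = sum(.data$size), .groups = "drop")
  hist <- dplyr::arrange(hist, .data$size)
  total <- sum(hist$n_genes)
  cum <- tibble::tibble(
    min_size = hist$size,
    gene_fraction = rev(cumsum(rev(hist$n_genes))) / total)
  half <- cum$min_size[cum$gene_fraction >= 0.5]
  list(histogram = hist, cumulative = cum,
       singleton_gene_fraction = sum(hist$n_genes[hist$size == 1]) / total,
       median_block_size = if (length(half)) max(half) else NA_real_)
}

#' Fraction of genes in blocks of at least a given size
#'
#' @param blocks An [find_blocks()] result.
#' @param min_size Minimal block size in genes.
#' @return A single fraction in `[0, 1]`.
#' @export
block_gene_fraction <- function(blocks, min_size) {
  sum(blocks$size[blocks$size >= min_size]) / sum(blocks$size)
}

#' Gene orientation-change statistics in sliding windows
#'
#' Counts strand changes among the `window - 1` neighbouring gene pairs in
#' every sliding window of `window` genes, and compares the histogram with
#' the binomial null of equal and independent gene orientation,
#' Binomial(window - 1, 1/2).
#'
#' @param genes A sorted gene table.
#' @param window Window size in genes (default 10); chromosomes with fewer
#'   genes are skipped.
#' @return A list with `observed` and `null` distribution tibbles,
#'   `tv_distance` (total variation) and `n_windows`.
#' @export
orientation_change_stats <- function(genes, window = 10) {
  stopifnot(window >= 2)
  counts <- integer(0)
  for (cn in unique(genes$chrom)) {
    st <- genes$strand[genes$chrom == cn]
    if (length(st) < window) next
    chg <- as.integer(st[-1] != st[-length(st)])
    ws <- stats::filter(chg, rep(1, window - 1), sides = 1)
    counts <- c(counts, as.integer(ws[(window - 1):length(chg)]))
  }
  if (!length(counts)) stop("no chromosome holds a full window of genes")
  k <- 0:(window - 1)
  obs <- tibble::tibble(changes = k,
                        count = as.integer(table(factor(counts, levels = k))))
  obs$prop <- obs$count / sum(obs$count)
  null <- tibble::tibble(changes = k, prob = stats::dbinom(k, window - 1, 0.5))
  list(observed = obs, null = null,
       tv_distance = sum(abs(obs$prop - null$prob)) / 2,
       n_windows = length(counts), window = window)
}

## fraction of [start, end) covered by track intervals with value >= min_value
covered_fraction <- function(track, chrom, start, end, min_value) {
  t <- track[track$chrom == chrom & track$value >= min_value, ]
  if (nrow(t) == 0 || end <= start) return(0)
  ov_start <- pmax(t$start, start); ov_end <- pmin(t$end, end)
  sum(pmax(ov_end - ov_start, 0)) / (end - start)
}

#' Call convergent and divergent sites between gene blocks
#'
#' For each pair of adjacent opposite-strand blocks the site position is the
#' midpoint of the inter-block interval (midpoint of the overlap, flagged,
#' when the blocks overlap). A `+` block followed by a `-` block is a
#' convergent site (transcription collides); the opposite order is a
#' divergent (bidirectional) site. When stranded expression is supplied, a
#' block qualifies only if at least half of its span carries coverage of at
#' least `min_expr` on its own strand, a reproducible proxy for restricting
#' to expressed blocks.
#'
#' @param blocks A [find_blocks()] result.
#' @param min_block Minimal size (genes) of both flanking blocks (default 1).
#' @param expression Optional list with `plus`/`minus` track tibbles.
#' @param min_expr Minimal qualifying coverage (default 1).
#' @return A tibble of class `site_set`: `chrom`, `pos`, `kind`,
#'   `left_block`, `right_block`, `overlap`.
#' @export
call_sites <- function(blocks, min_block = 1, expression = NULL,
                       min_expr = 1) {
  out <- lapply(unique(blocks$chrom), function(cn) {
    b <- blocks[blocks$chrom == cn, ]
    if (nrow(b) < 2) return(NULL)
    qual <- b$size >= min_block
    if (!is.null(expression)) {
      fr <- vapply(seq_len(nrow(b)), function(i) {
        tr <- if (b$strand[i] == "+") expression$plus else expression$minus
        covered_fraction(tr, cn, b$span_start[i], b$span_end[i], min_expr)
      }, numeric(1))
      qual <- qual & fr >= 0.5
    }
    i <- seq_len(nrow(b) - 1)
    ok <- qual[i] & qual[i + 1]
    if (!any(ok)) return(NULL)
    i <- i[ok]
    left_end <- b$span_end[i]; right_start <- b$span_start[i + 1]
    tibble::tibble(
      chrom = cn,
      pos = (left_end + right_start) / 2,
      kind = ifelse(b$strand[i] == "+", "convergent", "divergent"),
      left_block = b$block_id[i], right_block = b$block_id[i + 1],
      overlap = left_end > right_start)
  })
  sites <- dplyr::bind_rows(out)
  if (nrow(sites) == 0) {
    sites <- tibble::tibble(chrom = character(), pos = numeric(),
                            kind = character(), left_block = integer(),
                            right_block = integer(), overlap = logical())
  }
  class(sites) <- c("site_set", class(sites))
  sites
}

#' GC-content track in fixed windows
#'
#' Fraction of G/C among non-N bases per window; windows more than half N
#' are undefined.
#'
#' @param assembly A [genome_assembly()] with sequence.
#' @param window,step Window width and step in bp (default 10 kb tiling).
#' @return A track tibble (`chrom`, `start`, `end`, `value`).
#' @export
gc_track <- function(assembly, window = 1e4, step = window) {
  if (is.null(assembly$seq)) stop("assembly carries no sequence")
  out <- lapply(assembly$chroms$name, function(cn) {
    L <- assembly$chroms$length[assembly$chroms$name == cn]
    starts <- seq(0, max(L - 1, 0), by = step)
    ends <- pmin(starts + window, L)
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    v <- Biostrings::Views(assembly$seq[[cn]], start = starts + 1, end = ends)
    lf <- Biostrings::letterFrequency(v, letters = c("C", "G", "N"))
    width <- ends - starts
    denom <- width - lf[, "N"]
    gc <- ifelse(lf[, "N"] > 0.5 * width | denom == 0, NA_real_,
                 (lf[, "C"] + lf[, "G"]) / denom)
    tibble::tibble(chrom = cn, start = starts, end = ends, value = gc)
  })
  dplyr::bind_rows(out)
}

#' Interval-count track (gene density, repeat density)
#'
#' Counts intervals whose midpoint falls in each window.
#'
#' @param intervals A tibble with `chrom`, `start`, `end`.
#' @param assembly A [genome_assembly()] giving window extents.
#' @param window,step Window width and step (bp).
#' @return A track tibble.
#' @export
count_track <- function(intervals, assembly, window = 1e5, step = window) {
  mids <- (intervals$start + intervals$end) / 2
  out <- lapply(assembly$chroms$name, function(cn) {
    L <- assembly$chroms$length[assembly$chroms$name == cn]
    starts <- seq(0, max(L - 1, 0), by = step)
    ends <- pmin(starts + window, L)
    m <- mids[intervals$chrom == cn]
    cnt <- vapply(seq_along(starts), function(i) {
      sum(m >= starts[i] & m < ends[i])
    }, numeric(1))
    tibble::tibble(chrom = cn, start = starts, end = ends, value = cnt)
  })
  dplyr::bind_rows(out)
}

## per-chromosome run-length-encoded coverage of a track (0 outside
## intervals); widths taken from `sizes` where provided
track_rle <- function(track, sizes = NULL) {
  chroms <- unique(track$chrom)
  out <- lapply(chroms, function(cn) {
    t <- track[track$chrom == cn & !is.na(track$value), ]
    w <- if (!is.null(sizes) && cn %in% names(sizes)) sizes[[cn]] else
      max(t$end, 0)
    IRanges::coverage(IRanges::IRanges(t$start + 1, t$end),
                      weight = t$value, width = w)
  })
  stats::setNames(out, chroms)
}

#' Average a track around a set of sites
#'
#' Computes the per-offset mean of a track (or a stranded track pair) across
#' sites, in sliding windows over `±flank`. Sites carrying an `orientation`
#' column are aligned to a canonical `+` orientation by mirroring offsets
#' (and, for stranded input, swapping the strand tracks), so asymmetric
#' signals are preserved. Sites whose flank exceeds the chromosome are
#' dropped and counted.
#'
#' @param track A track tibble, or a list with `plus` and `minus` tracks for
#'   stranded data.
#' @param sites A tibble with `chrom` and `pos` (or a `boundary_set`, whose
#'   interval midpoints are used), optionally `orientation` (`+`/`-`).
#' @param flank Half-width of the profiled region (bp, default 30 kb).
#' @param window,step Sliding-window width and step (bp, default 100/100).
#' @param sizes Optional named chromosome lengths (else inferred from the
#'   track).
#' @return A tibble with `offset` (window centre relative to site) and
#'   `value` (or `plus`/`minus`); attributes `n_sites`, `n_dropped`.
#' @export
feature_profile <- function(track, sites, flank = 3e4, window = 100,
                            step = 100, sizes = NULL) {
  stranded <- is.list(track) && !is.data.frame(track)
  if (inherits(sites, "boundary_set") ||
      (!"pos" %in% names(sites) && all(c("start", "end") %in% names(sites)))) {
    sites <- dplyr::mutate(tibble::as_tibble(sites),
                           pos = (.data$start + .data$end) / 2)
  }
  if (nrow(sites) == 0) stop("no sites supplied")
  orient <- if ("orientation" %in% names(sites)) sites$orientation else
    rep("+", nrow(sites))
  rles <- if (stranded) {
    list(plus = track_rle(track$plus, sizes),
         minus = track_rle(track$minus, sizes))
  } else list(value = track_rle(track, sizes))
  chrom_len <- function(set, cn) {
    for (s in set) if (cn %in% names(s)) return(length(s[[cn]]))
    0
  }
  off_start <- seq(-flank, flank - window, by = step)
  offsets <- off_start + window / 2
  acc <- list()
  n_used <- 0; n_dropped <- 0
  for (r in seq_len(nrow(sites))) {
    cn <- sites$chrom[r]; p <- sites$pos[r]
    L <- chrom_len(rles, cn)
    if (p - flank < 0 || p + flank > L || L == 0) { n_dropped <- n_dropped + 1; next }
    mirrored <- orient[r] == "-"
    ws <- if (mirrored) p - off_start - window else p + off_start
    vals <- lapply(names(rles), function(nm) {
      rl <- rles[[nm]][[cn]]
      if (is.null(rl)) return(rep(0, length(ws)))
      IRanges::viewMeans(IRanges::Views(rl, start = round(ws) + 1,
                                        end = round(ws + window)))
    })
    names(vals) <- names(rles)
    if (stranded && mirrored) vals <- list(plus = vals$minus, minus = vals$plus)
    acc[[length(acc) + 1]] <- vals
    n_used <- n_used + 1
  }
  if (n_used == 0) stop("all sites dropped (flank exceeds chromosomes)")
  out <- tibble::tibble(offset = offsets)
  for (nm in names(acc[[1]])) {
    m <- do.call(rbind, lapply(acc, `[[`, nm))
    out[[nm]] <- colMeans(m)
  }
  attr(out, "n_sites") <- n_used
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Average a track by distance to the telomere
#'
#' Both ends of every qualifying chromosome contribute (the right end is
#' mirrored), giving the mean track value as a function of distance to the
#' chromosome end.
#'
#' @param track A track tibble.
#' @param assembly A [genome_assembly()].
#' @param span Distance from the end profiled (bp, default 2.5 Mb).
#' @param min_chrom Minimal chromosome length to qualify (default 5 Mb).
#' @param window,step Window width/step (bp, default 10 kb).
#' @return A tibble with `offset` (distance from telomere, window centre)
#'   and `value`; attribute `n_ends`.
#' @export
telomere_profile <- function(track, assembly, span = 2.5e6, min_chrom = 5e6,
                             window = 1e4, step = window) {
  sizes <- chrom_lengths(assembly)
  rles <- track_rle(track, sizes)
  qual <- names(sizes)[sizes >= min_chrom]
  qual <- intersect(qual, names(rles))
  if (!length(qual)) stop("no chromosome of at least min_chrom with track data")
  off_start <- seq(0, span - window, by = step)
  rows <- list()
  for (cn in qual) {
    L <- sizes[[cn]]; rl <- rles[[cn]]
    lv <- IRanges::viewMeans(IRanges::Views(rl, start = off_start + 1,
                                            end = pmin(off_start + window, L)))
    rv <- IRanges::viewMeans(IRanges::Views(
      rl, start = pmax(L - off_start - window, 0) + 1, end = L - off_start))
    rows[[cn]] <- rbind(lv, rv)
  }
  m <- do.call(rbind, rows)
  out <- tibble::tibble(offset = off_start + window / 2, value = colMeans(m))
  attr(out, "n_ends") <- nrow(m)
  out
}

#' Pairwise correlations between tracks on common bins
#'
#' @param tracks Named list of track tibbles on identical windows.
#' @return A list with the Pearson correlation matrix `r` and the
#'   common-bin count `n`; fewer than 3 jointly defined bins between a pair
#'   leaves that entry `NA`.
#' @export
track_correlations <- function(tracks) {
  stopifnot(length(tracks) >= 2, !is.null(names(tracks)))
  base <- tracks[[1]][, c("chrom", "start")]
  mat <- sapply(names(tracks), function(nm) {
    t <- tracks[[nm]]
    t$value[match(paste(base$chrom, base$start),
                  paste(t$chrom, t$start))]
  })
  r <- matrix(NA_real_, ncol(mat), ncol(mat),
              dimnames = list(colnames(mat), colnames(mat)))
  n <- r
  for (i in seq_len(ncol(mat))) for (j in seq_len(ncol(mat))) {
    ok <- stats::complete.cases(mat[, c(i, j)])
    n[i, j] <- sum(ok)
    if (sum(ok) >= 3) r[i, j] <- stats::cor(mat[ok, i], mat[ok, j])
  }
  list(r = r, n = n)
}
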