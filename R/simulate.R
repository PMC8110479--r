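#' Specification of a synthetic rod-chromosome dataset
#'
#' Collects every parameter of the ground-truth generators. The defaults are
#' a scaled-down "desk" profile of the biological system: 8 chromosomes /
#' 40 Mb with a shallow contact decay (exponent `alpha = -0.4`) truncated at
#' a rod-length cutoff (`d_max`, scaled to 1 Mb), contact-depleted planted
#' boundaries at convergent gene-block junctions (cross-boundary attenuation
#' `beta`), twofold telomeric compaction (`tau`) inside terminal domains,
#' alternating unidirectional gene blocks with geometric sizes (mean
#' `block_mean`), GC/gene-density gradients toward telomeres and a boundary
#' GC dip.
#'
#' @param seed Integer seed; every generator is fully deterministic given it.
#' @param n_chromosomes,total_length Karyotype size and summed length (bp).
#' @param terminal_span Span of the compacted terminal domain at each
#'   chromosome end (bp); the outermost planted boundaries sit exactly here.
#' @param block_mean Mean genes per unidirectional block (geometric law).
#' @param gene_length,gene_pitch Gene span and start-to-start spacing (bp).
#' @param min_block_span Minimal genomic span of a block (bp): a block with
#'   few genes still occupies at least this much sequence, so adjacent
#'   convergent junctions keep the several-hundred-kb spacing of real
#'   domains while gene counts per block stay geometric.
#' @param alpha Contact-decay exponent in regime II.
#' @param d_max Rod-length cutoff of the decay (bp).
#' @param tail_suppression Density multiplier beyond `d_max` (<= 0.01 keeps
#'   the regime III plateau non-zero but steeply dropped).
#' @param s_min Shortest sampled separation (bp).
#' @param beta Cross-boundary density multiplier per boundary crossed,
#'   in (0, 1]; 1 removes boundaries.
#' @param tau Density multiplier for pairs wholly inside a terminal domain.
#' @param trans_fraction Fraction of pairs that are inter-chromosomal noise.
#' @param stripe_fraction Fraction of cis pairs anchored at divergent sites
#'   (the "plus-sign" loop stripes); 0 removes stripes.
#' @param stripe_width Width (bp) over which stripe anchors are jittered
#'   around the divergent site, matching the tens-of-kb extent of anchored
#'   lines in real maps.
#' @param depth Total number of pairs to emit.
#' @param gc_base,gc_telomere_gain,gc_span GC level, its telomeric gain and
#'   the gradient span (bp).
#' @param boundary_gc_dip,gc_dip_width Depth and width (bp) of the GC dip
#'   planted at each boundary.
#' @param n_gap_len Length of an N-run planted at a fraction
#'   `n_gap_fraction` of boundaries (0 plants none).
#' @param n_gap_fraction See `n_gap_len`.
#' @param silent_fraction Fraction of genes with zero expression.
#' @param expr_meanlog,expr_sdlog Log-normal expression level parameters.
#' @param repeat_rate Repeat intervals per Mb and family.
#' @param spacer Optional `c(chrom_index, start, length)`: an inert spacer —
#'   a stretch that forms no contacts and does not count toward polymer
#'   distance — planted to exercise the inter-domain gap-shift estimator.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_chromosomes = 8, total_length = 40e6,
                           terminal_span = 500e3,
                           block_mean = 9, gene_length = 2e3, gene_pitch = 45e3,
                           min_block_span = 250e3,
                           alpha = -0.4, d_max = 1e6, tail_suppression = 0.01,
                           s_min = 1e3, beta = 0.5, tau = 2.0,
                           trans_fraction = 0.05, stripe_fraction = 0.02,
                           stripe_width = 5e4,
                           depth = 1e6,
                           gc_base = 0.46, gc_telomere_gain = 0.05,
                           gc_span = 1.25e6,
                           boundary_gc_dip = 0.05, gc_dip_width = 2e3,
                           n_gap_len = 100, n_gap_fraction = 0,
                           silent_fraction = 0.2,
                           expr_meanlog = log(5), expr_sdlog = 1,
                           repeat_rate = 20,
                           spacer = NULL) {
  spec <- as.list(environment())
  stopifnot(spec$beta > 0, spec$beta <= 1, spec$tau > 0,
            spec$trans_fraction >= 0, spec$trans_fraction < 1,
            spec$stripe_fraction >= 0, spec$stripe_fraction < 1,
            spec$n_gap_fraction >= 0, spec$n_gap_fraction <= 1,
            spec$alpha > -1, spec$s_min > 0, spec$depth >= 0,
            spec$tail_suppression >= 0, spec$tail_suppression <= 1,
            spec$d_max > spec$s_min,
            spec$terminal_span * 2 < spec$total_length / spec$n_chromosomes,
            spec$gene_length <= spec$gene_pitch)
  spec$seed <- as.integer(seed)
  class(spec) <- "synthetic_spec"
  spec
}

#' Switch a synthetic spec to the transcription-blocked condition
#'
#' Returns the spec with cross-boundary attenuation removed (`beta = 1`) and
#' divergent-site stripes disabled, all else identical (including the seed);
#' this emulates the loss of domain boundaries under transcription blockers.
#' Idempotent.
#'
#' @param spec A [synthetic_spec()].
#' @export
apply_treatment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  spec$beta <- 1
  spec$stripe_fraction <- 0
  spec
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

## geometric block sizes with mean `mean_size` (support 1, 2, ...)
rblock_sizes <- function(n, mean_size) 1L + stats::rgeom(n, 1 / mean_size)

## Alternating-strand block layout for one chromosome, built from both ends
## so that each terminal domain is a single block of span `ts` and the
## outermost junctions are convergent (+ then -).
layout_chrom_blocks <- function(L, spec) {
  ts <- spec$terminal_span
  pitch <- spec$gene_pitch
  half <- L / 2
  draw_blocks <- function(budget) {
    sizes <- integer(0); spans <- numeric(0)
    while (sum(spans) < budget) {
      sz <- rblock_sizes(8, spec$block_mean)
      sizes <- c(sizes, sz)
      spans <- c(spans, pmax(sz * pitch, spec$min_block_span))
    }
    keep <- cumsum(spans) - spans < budget
    list(sizes = sizes[keep], spans = spans[keep])
  }
  lb <- draw_blocks(half - ts)
  l_spans <- c(ts, lb$spans)
  l_sizes <- c(floor(ts / pitch), lb$sizes)
  l_end <- pmin(cumsum(l_spans), half)
  l_start <- c(0, utils::head(l_end, -1))
  keep <- l_end > l_start
  l_start <- l_start[keep]; l_end <- l_end[keep]; l_sizes <- l_sizes[keep]
  l_strand <- rep(c("+", "-"), length.out = length(l_start))

  rb <- draw_blocks(half - ts)
  r_spans <- c(ts, rb$spans)
  r_sizes <- c(floor(ts / pitch), rb$sizes)
  r_cum <- cumsum(r_spans)
  r_end <- L - c(0, utils::head(r_cum, -1))
  r_start <- pmax(L - r_cum, half)
  keep <- r_end > r_start
  r_start <- r_start[keep]; r_end <- r_end[keep]; r_sizes <- r_sizes[keep]
  r_strand <- rep(c("-", "+"), length.out = length(r_start))

  blocks <- tibble::tibble(
    start = c(l_start, rev(r_start)),
    end = c(l_end, rev(r_end)),
    strand = c(l_strand, rev(r_strand)),
    n_genes = c(l_sizes, rev(r_sizes)))
  ## truncated blocks cannot hold more genes than their span allows
  blocks$n_genes <- pmin(blocks$n_genes,
                         pmax(floor((blocks$end - blocks$start) / pitch), 1))
  ## merge the two middle blocks when the stitch leaves equal strands
  repeat {
    same <- which(blocks$strand[-1] == blocks$strand[-nrow(blocks)])
    if (!length(same)) break
    k <- same[1]
    blocks$end[k] <- blocks$end[k + 1]
    blocks$n_genes[k] <- blocks$n_genes[k] + blocks$n_genes[k + 1]
    blocks <- blocks[-(k + 1), ]
  }
  blocks
}

#' Generate a synthetic genome with ground truth
#'
#' Lays out alternating unidirectional gene blocks (terminal domains are
#' single blocks so the outermost junctions are convergent), classifies every
#' junction as convergent (planted domain boundary) or divergent, places
#' mid-chromosome-enriched repeat intervals and, optionally, synthesises
#' per-base sequence realising the telomeric GC gradient and boundary GC
#' dips. Byte-identical output for identical specs.
#'
#' @param spec A [synthetic_spec()].
#' @param with_sequence Synthesise nucleotide sequence (slower; off by
#'   default as contact-map analyses do not need it).
#' @return A list of class `synthetic_genome`: `assembly`, `genes`,
#'   `repeats`, and `truth` (planted boundaries, divergent sites, blocks,
#'   N-gap plants and the generating spec).
#' @export
generate_genome <- function(spec, with_sequence = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    mean_len <- spec$total_length / spec$n_chromosomes
    mult <- stats::runif(spec$n_chromosomes, 0.85, 1.15)
    lens <- round(mult / sum(mult) * spec$total_length / 1e3) * 1e3
    names(lens) <- sprintf("chr%d", seq_along(lens))
    if (any(lens <= 2 * spec$terminal_span)) {
      stop("infeasible spec: chromosome shorter than two terminal spans")
    }
    gene_list <- list(); block_list <- list()
    bnd_list <- list(); div_list <- list()
    for (ci in seq_along(lens)) {
      L <- lens[ci]; cn <- names(lens)[ci]
      blocks <- layout_chrom_blocks(L, spec)
      blocks$chrom <- cn
      ## junction classification between consecutive blocks
      s1 <- blocks$strand[-nrow(blocks)]; s2 <- blocks$strand[-1]
      jpos <- blocks$end[-nrow(blocks)]
      bnd_list[[cn]] <- tibble::tibble(chrom = cn,
                                       pos = jpos[s1 == "+" & s2 == "-"])
      div_list[[cn]] <- tibble::tibble(chrom = cn,
                                       pos = jpos[s1 == "-" & s2 == "+"])
      ## genes: regular pitch inside each block
      gl <- lapply(seq_len(nrow(blocks)), function(b) {
        n <- blocks$n_genes[b]
        st <- blocks$start[b] + (seq_len(n) - 1) * spec$gene_pitch +
          (spec$gene_pitch - spec$gene_length) / 2
        en <- pmin(st + spec$gene_length, blocks$end[b])
        keep <- en > st & en <= L
        tibble::tibble(chrom = cn, start = st[keep], end = en[keep],
                       strand = blocks$strand[b], block = b)
      })
      gene_list[[cn]] <- dplyr::bind_rows(gl)
      block_list[[cn]] <- blocks
    }
    genes <- dplyr::bind_rows(gene_list)
    genes <- dplyr::arrange(genes, match(.data$chrom, names(lens)),
                            .data$start)
    genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "block")]
    boundaries <- dplyr::bind_rows(bnd_list)
    div_sites <- dplyr::bind_rows(div_list)

    ## repeats: denser mid-chromosome, four families
    fams <- c(LINE = 3000, DNA = 1500, Simple = 200, Unclassified = 800)
    rep_list <- list()
    for (ci in seq_along(lens)) {
      L <- lens[ci]; cn <- names(lens)[ci]
      for (f in names(fams)) {
        n <- stats::rpois(1, spec$repeat_rate * L / 1e6)
        if (n == 0) next
        x <- stats::runif(3 * n, 0, L)
        d <- pmin(x, L - x)
        w <- 1 - 0.7 * pmax(0, 1 - d / spec$gc_span)
        x <- x[stats::runif(3 * n) < w][seq_len(n)]
        x <- x[!is.na(x)]
        rep_list[[paste(cn, f)]] <- tibble::tibble(
          chrom = cn, start = floor(x),
          end = pmin(floor(x) + fams[[f]], L), family = f)
      }
    }
    repeats <- dplyr::arrange(dplyr::bind_rows(rep_list),
                              match(.data$chrom, names(lens)), .data$start)

    ## N-gap plants at a fraction of boundaries
    gaps <- boundaries[stats::runif(nrow(boundaries)) < spec$n_gap_fraction, ]

    seq <- NULL
    if (with_sequence) {
      seqs <- character(length(lens))
      for (ci in seq_along(lens)) {
        L <- lens[ci]; cn <- names(lens)[ci]
        x <- seq_len(L) - 0.5
        d <- pmin(x, L - x)
        gc <- spec$gc_base +
          spec$gc_telomere_gain * pmax(0, 1 - d / spec$gc_span)
        for (bp in boundaries$pos[boundaries$chrom == cn]) {
          hit <- abs(x - bp) < spec$gc_dip_width / 2
          gc[hit] <- gc[hit] - spec$boundary_gc_dip
        }
        is_gc <- stats::runif(L) < gc
        half <- stats::runif(L) < 0.5
        b <- ifelse(is_gc, ifelse(half, "G", "C"), ifelse(half, "A", "T"))
        for (gp in gaps$pos[gaps$chrom == cn]) {
          i0 <- max(1, floor(gp - spec$n_gap_len / 2))
          b[i0:min(L, i0 + spec$n_gap_len - 1)] <- "N"
        }
        seqs[ci] <- paste(b, collapse = "")
      }
      seq <- Biostrings::DNAStringSet(stats::setNames(seqs, names(lens)))
    }

    structure(list(
      assembly = genome_assembly(lens, seq),
      genes = genes,
      repeats = repeats,
      truth = list(boundaries = boundaries, div_sites = div_sites,
                   blocks = dplyr::bind_rows(block_list),
                   n_gaps = gaps, spec = spec)),
      class = "synthetic_genome")
  })
}

## inverse-CDF sampler for density ~ s^alpha on [lo, hi]
rpow <- function(n, alpha, lo, hi) {
  a1 <- alpha + 1
  u <- stats::runif(n)
  (lo^a1 + u * (hi^a1 - lo^a1))^(1 / a1)
}

## integral of s^alpha over [lo, hi]
ipow <- function(alpha, lo, hi) {
  a1 <- alpha + 1
  max(0, (hi^a1 - lo^a1) / a1)
}

#' Sample a valid-pairs stream from a synthetic genome
#'
#' Cis separations follow the truncated power law `s^alpha` up to `d_max`
#' with a hard density suppression (not zero) beyond; each planted-boundary
#' crossing multiplies density by `beta`; pairs wholly inside a terminal
#' domain are enriched by `tau`; divergent sites emit anchored stripes; trans
#' pairs are uniform at the configured fraction. Sampling uses inverse-CDF
#' draws plus bounded rejection, including an `(L - s) / L` edge factor so
#' that contact probability per possible locus pair follows `s^alpha`
#' without chromosome-edge bias.
#'
#' @param genome A `synthetic_genome` from [generate_genome()].
#' @param spec Optional spec override (defaults to the genome's own, so a
#'   treated condition can reuse one genome via [apply_treatment()]).
#' @return A canonically ordered pairs tibble (1-based positions).
#' @export
generate_contacts <- function(genome, spec = genome$truth$spec) {
  stopifnot(inherits(genome, "synthetic_genome"))
  lens <- chrom_lengths(genome$assembly)
  if (spec$depth == 0) {
    return(tibble::tibble(chrom1 = character(), pos1 = numeric(),
                          strand1 = character(), chrom2 = character(),
                          pos2 = numeric(), strand2 = character()))
  }
  with_seed(spec$seed + 1L, {
    n_trans <- if (length(lens) > 1) round(spec$depth * spec$trans_fraction) else 0
    n_cis <- spec$depth - n_trans
    cis_alloc <- as.vector(stats::rmultinom(1, n_cis, lens / sum(lens)))
    out <- vector("list", length(lens) + 1)
    for (ci in seq_along(lens)) {
      m <- cis_alloc[ci]
      if (m == 0) next
      cn <- names(lens)[ci]; L <- lens[[ci]]
      sp <- spec$spacer
      has_spacer <- !is.null(sp) && sp[1] == ci
      Leff <- if (has_spacer) L - sp[3] else L
      map_pos <- function(x) {
        if (has_spacer) ifelse(x >= sp[2], x + sp[3], x) else x
      }
      bnd <- sort(genome$truth$boundaries$pos[genome$truth$boundaries$chrom == cn])
      ts <- spec$terminal_span
      m_str <- 0
      div <- genome$truth$div_sites$pos[genome$truth$div_sites$chrom == cn]
      if (spec$stripe_fraction > 0 && length(div) > 0) {
        m_str <- round(m * spec$stripe_fraction)
      }
      m_main <- m - m_str
      ## mixture weight of the suppressed tail beyond d_max
      hi <- min(spec$d_max, Leff)
      i_main <- ipow(spec$alpha, spec$s_min, hi)
      i_tail <- if (Leff > spec$d_max)
        spec$tail_suppression * ipow(spec$alpha, spec$d_max, Leff) else 0
      p_tail <- i_tail / (i_main + i_tail)
      xs <- numeric(0); ys <- numeric(0)
      rate <- 0.5
      while (length(xs) < m_main) {
        need <- m_main - length(xs)
        nb <- ceiling(need / rate * 1.25) + 100
        tail_draw <- stats::runif(nb) < p_tail
        s <- numeric(nb)
        s[!tail_draw] <- rpow(sum(!tail_draw), spec$alpha, spec$s_min, hi)
        if (any(tail_draw)) {
          s[tail_draw] <- rpow(sum(tail_draw), spec$alpha, spec$d_max, Leff)
        }
        x <- stats::runif(nb, 0, Leff - s)
        y <- x + s
        xm <- map_pos(x); ym <- map_pos(y)
        k <- findInterval(ym, bnd) - findInterval(xm, bnd)
        w <- ((Leff - s) / Leff) * spec$beta^k
        term <- (ym < ts) | (xm > L - ts)
        w <- w * ifelse(term, spec$tau, 1)
        acc <- stats::runif(nb) < w / max(spec$tau, 1)
        xs <- c(xs, xm[acc]); ys <- c(ys, ym[acc])
        rate <- max(mean(acc), 0.02)
      }
      xs <- xs[seq_len(m_main)]; ys <- ys[seq_len(m_main)]
      if (m_str > 0) {
        anchor <- sample(div, 3 * m_str, replace = TRUE) +
          stats::runif(3 * m_str, -spec$stripe_width / 2, spec$stripe_width / 2)
        ## anchored loops reach partners at uniformly varying distances up
        ## to the rod length; a power-law profile would be a pure row bias
        ## that iterative correction removes
        s <- stats::runif(3 * m_str, spec$s_min, hi)
        sgn <- sample(c(-1, 1), 3 * m_str, replace = TRUE)
        other <- anchor + sgn * s
        ok <- other >= 0 & other < L
        idx <- which(ok)[seq_len(min(m_str, sum(ok)))]
        xs <- c(xs, pmin(anchor[idx], other[idx]))
        ys <- c(ys, pmax(anchor[idx], other[idx]))
      }
      out[[ci]] <- tibble::tibble(
        chrom1 = cn, pos1 = floor(xs) + 1,
        chrom2 = cn, pos2 = pmin(floor(ys) + 1, L))
    }
    if (n_trans > 0) {
      wts <- lens / sum(lens)
      c1 <- sample(names(lens), n_trans, replace = TRUE, prob = wts)
      c2 <- sample(names(lens), n_trans, replace = TRUE, prob = wts)
      same <- c1 == c2
      while (any(same)) {
        c2[same] <- sample(names(lens), sum(same), replace = TRUE, prob = wts)
        same <- c1 == c2
      }
      out[[length(lens) + 1]] <- tibble::tibble(
        chrom1 = c1, pos1 = floor(stats::runif(n_trans, 0, lens[c1])) + 1,
        chrom2 = c2, pos2 = floor(stats::runif(n_trans, 0, lens[c2])) + 1)
    }
    pairs <- dplyr::bind_rows(out)
    pairs$strand1 <- sample(c("+", "-"), nrow(pairs), replace = TRUE)
    pairs$strand2 <- sample(c("+", "-"), nrow(pairs), replace = TRUE)
    canonical_pairs(pairs[, c("chrom1", "pos1", "strand1",
                              "chrom2", "pos2", "strand2")],
                    chrom_order = names(lens))
  })
}

#' Fragment a synthetic genome into scaffolds with planted misjoins
#'
#' Chromosomes are cut into pieces around `target_n50`; each piece receives a
#' random orientation, and a fraction `misjoin_rate` of scaffolds are
#' chimeras concatenating pieces from two different chromosomes. The truth
#' map records every piece's origin, orientation and every chimeric
#' junction, so clustering, splitting and ordering can all be scored.
#'
#' @param genome A `synthetic_genome`.
#' @param target_n50 Target scaffold size (bp); must not exceed the shortest
#'   chromosome.
#' @param misjoin_rate Fraction of scaffolds that are chimeric.
#' @param spec Spec (for the seed); defaults to the genome's.
#' @return A list of class `scaffold_set`: `scaffolds` (name, length, true
#'   majority chromosome), `map` (piece-level truth), `junctions` (chimera
#'   junction positions in scaffold coordinates).
#' @export
fragment_assembly <- function(genome, target_n50 = 5e5, misjoin_rate = 0.05,
                              spec = genome$truth$spec) {
  lens <- chrom_lengths(genome$assembly)
  if (target_n50 > min(lens)) stop("target_n50 exceeds a chromosome length")
  with_seed(spec$seed + 2L, {
    pieces <- list()
    for (cn in names(lens)) {
      L <- lens[[cn]]; pos <- 0; ps <- numeric(0)
      while (L - pos > 1.45 * target_n50) {
        step <- stats::runif(1, 0.7, 1.1) * target_n50
        ps <- c(ps, pos); pos <- pos + step
      }
      ps <- c(ps, pos)
      pieces[[cn]] <- tibble::tibble(chrom = cn,
                                     g_start = floor(ps),
                                     g_end = c(floor(ps[-1]), L))
    }
    pc <- dplyr::bind_rows(pieces)
    pc$strand <- sample(c("+", "-"), nrow(pc), replace = TRUE)
    pc <- pc[sample(nrow(pc)), ]
    n_sc_target <- nrow(pc)
    n_chim <- round(misjoin_rate * n_sc_target)
    ## pick chimera partners from different chromosomes
    used <- rep(FALSE, nrow(pc))
    chim <- list()
    for (k in seq_len(n_chim)) {
      free <- which(!used)
      if (length(free) < 2) break
      a <- free[1]
      b_cand <- free[pc$chrom[free] != pc$chrom[a]]
      if (!length(b_cand)) break
      b <- b_cand[1]
      used[c(a, b)] <- TRUE
      chim[[k]] <- c(a, b)
    }
    singles <- which(!used)
    sc_rows <- c(chim, as.list(singles))
    map <- list(); junctions <- list(); scaffolds <- list()
    for (si in seq_along(sc_rows)) {
      rows <- sc_rows[[si]]
      name <- sprintf("scf%04d", si)
      offs <- cumsum(c(0, (pc$g_end - pc$g_start)[rows]))
      map[[si]] <- tibble::tibble(
        scaffold = name,
        sc_start = offs[-length(offs)],
        sc_end = offs[-1],
        chrom = pc$chrom[rows], g_start = pc$g_start[rows],
        g_end = pc$g_end[rows], strand = pc$strand[rows])
      if (length(rows) > 1) {
        junctions[[si]] <- tibble::tibble(scaffold = name,
                                          pos = offs[2:(length(offs) - 1)])
      }
      main <- which.max(pc$g_end[rows] - pc$g_start[rows])
      scaffolds[[si]] <- tibble::tibble(
        name = name, length = offs[length(offs)],
        true_chrom = pc$chrom[rows][main], chimeric = length(rows) > 1)
    }
    structure(list(scaffolds = dplyr::bind_rows(scaffolds),
                   map = dplyr::bind_rows(map),
                   junctions = dplyr::bind_rows(junctions)),
              class = "scaffold_set")
  })
}

#' Lift genome-coordinate pairs onto scaffold coordinates
#'
#' @param pairs A pairs tibble in true-genome coordinates.
#' @param frag A `scaffold_set` from [fragment_assembly()].
#' @return The pairs tibble re-expressed on scaffolds (1-based positions).
#' @export
lift_pairs <- function(pairs, frag) {
  map <- frag$map
  lift_end <- function(chrom, pos) {
    sc <- rep(NA_character_, length(pos)); sp <- rep(NA_real_, length(pos))
    for (cn in unique(map$chrom)) {
      rows <- which(map$chrom == cn)
      rows <- rows[order(map$g_start[rows])]
      idx <- which(chrom == cn)
      if (!length(idx)) next
      p0 <- pos[idx] - 1
      fi <- findInterval(p0, map$g_start[rows])
      ok <- fi >= 1 & p0 < map$g_end[rows][pmax(fi, 1)]
      r <- rows[fi[ok]]
      off <- p0[ok] - map$g_start[r]
      fwd <- map$strand[r] == "+"
      sp[idx[ok]] <- ifelse(fwd, map$sc_start[r] + off,
                            map$sc_end[r] - 1 - off) + 1
      sc[idx[ok]] <- map$scaffold[r]
    }
    list(sc = sc, sp = sp)
  }
  e1 <- lift_end(pairs$chrom1, pairs$pos1)
  e2 <- lift_end(pairs$chrom2, pairs$pos2)
  keep <- !is.na(e1$sc) & !is.na(e2$sc)
  out <- tibble::tibble(chrom1 = e1$sc[keep], pos1 = e1$sp[keep],
                        strand1 = pairs$strand1[keep],
                        chrom2 = e2$sc[keep], pos2 = e2$sp[keep],
                        strand2 = pairs$strand2[keep])
  canonical_pairs(out, chrom_order = sort(unique(c(out$chrom1, out$chrom2))))
}

#' Generate stranded expression tracks for a gene table
#'
#' Per-gene levels are log-normal with a silent fraction; coverage is laid
#' uniformly over each gene's span on its own strand.
#'
#' @param genes A gene table.
#' @param spec A [synthetic_spec()] (seed, level distribution).
#' @return A list with `plus` and `minus` track tibbles
#'   (`chrom`, `start`, `end`, `value`) and the per-gene `levels`.
#' @export
generate_expression <- function(genes, spec) {
  with_seed(spec$seed + 3L, {
    lev <- stats::rlnorm(nrow(genes), spec$expr_meanlog, spec$expr_sdlog)
    lev[stats::runif(nrow(genes)) < spec$silent_fraction] <- 0
    levels <- dplyr::mutate(genes, level = lev)
    mk <- function(st) {
      g <- levels[levels$strand == st & levels$level > 0, ]
      dplyr::arrange(tibble::tibble(chrom = g$chrom, start = g$start,
                                    end = g$end, value = g$level),
                     .data$chrom, .data$start)
    }
    list(plus = mk("+"), minus = mk("-"), levels = levels)
  })
}
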