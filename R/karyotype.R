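## Hi-C-assisted assembly stages: chromosome clustering of scaffolds,
## misjoin splitting, ordering/orienting, high-copy placement, copy number.

## Normalise members to a tibble (name, chrom, start, end); default = whole
## matrix sequences.
as_members <- function(cm, members) {
  if (inherits(members, "scaffold_set")) members <- members$scaffolds
  if (!"chrom" %in% names(members)) {
    members <- tibble::tibble(name = members$name, chrom = members$name,
                              start = 0, end = members$length)
  }
  tibble::as_tibble(members[, c("name", "chrom", "start", "end")])
}

## list of bin-index vectors per member
member_bins <- function(cm, members) {
  lapply(seq_len(nrow(members)), function(i) {
    which(cm$bins$chrom == members$chrom[i] &
            cm$bins$start >= members$start[i] &
            cm$bins$start < members$end[i] &
            (!cm$balanced | !is.na(cm$weights)))
  })
}

## mean balanced contact between member pairs (per bin pair, zeros counted)
member_contact_means <- function(cm, bins_list) {
  nm <- length(bins_list)
  grp <- rep(NA_integer_, nrow(cm$bins))
  for (i in seq_len(nm)) grp[bins_list[[i]]] <- i
  nb <- lengths(bins_list)
  v <- methods::as(methods::as(cm_values(cm), "generalMatrix"), "TsparseMatrix")
  gi <- grp[v@i + 1]; gj <- grp[v@j + 1]
  ok <- !is.na(gi) & !is.na(gj)
  key <- (gi[ok] - 1) * nm + gj[ok]
  sums <- tapply(v@x[ok], key, sum)
  S <- matrix(0, nm, nm)
  kk <- as.integer(names(sums))
  S[cbind((kk - 1) %/% nm + 1, (kk - 1) %% nm + 1)] <- sums
  S / pmax(outer(nb, nb), 1)
}

## affinity of every member to every cluster: mean contact to the cluster's
## other members
cluster_affinities <- function(S, cl) {
  ks <- sort(unique(cl[!is.na(cl)]))
  aff <- sapply(ks, function(c2) {
    mem <- which(cl == c2)
    vapply(seq_len(nrow(S)), function(i) {
      o <- setdiff(mem, i)
      if (!length(o)) 0 else mean(S[i, o])
    }, numeric(1))
  })
  if (is.null(dim(aff))) aff <- matrix(aff, ncol = length(ks))
  colnames(aff) <- ks
  aff
}

## Newman modularity of a partition of the weighted contact graph
partition_modularity <- function(S, cl) {
  W <- sum(S) / 2
  if (W <= 0) return(NA_real_)
  d <- rowSums(S)
  sum(vapply(unique(cl), function(c2) {
    mem <- cl == c2
    sum(S[mem, mem]) / 2 / W - (sum(d[mem]) / (2 * W))^2
  }, numeric(1)))
}

## Connected components of the strong-link graph: scaffolds are joined when
## their mean contact exceeds `link_factor` times the median pairwise level
## (the trans background, since most scaffold pairs are trans). Adjacent
## sections of one chromosome always share a link two to three orders of
## magnitude above that background, so on a misjoin-free scaffold set the
## components are exactly the chromosomes.
strong_link_components <- function(S, link_factor = 50) {
  n <- nrow(S)
  bg <- stats::median(S[upper.tri(S)])
  bg <- max(bg, max(S) * 1e-9)
  A <- S > link_factor * bg
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(A[v, ] & is.na(comp)))
    }
  }
  comp
}

refine_partition <- function(S, cl, max_iter = 10) {
  for (it in seq_len(max_iter)) {
    aff <- cluster_affinities(S, cl)
    new <- as.integer(colnames(aff))[max.col(aff, ties.method = "first")]
    if (all(new == cl)) break
    cl <- new
  }
  cl
}

#' Cluster scaffolds into chromosome groups (Hi-C karyotyping)
#'
#' Scaffold-scaffold similarity is the mean balanced trans contact frequency
#' per bin pair (so scaffold length does not dominate). An average-linkage
#' dendrogram provides candidate partitions; each candidate is refined by
#' reassigning every scaffold to its maximal-affinity cluster, and, when `k`
#' is not given, the partition with maximal weighted-graph modularity is
#' kept — under a rod-length contact cutoff chromosomes are contact chains,
#' for which raw merge heights are an unreliable cut criterion. Scaffolds
#' whose second-best cluster affinity exceeds `ambiguity_ratio` times their
#' best are moved to the ambiguous set; scaffolds shorter than
#' `min_scaffold_len` never enter clustering.
#'
#' @param cm A balanced [contact_matrix()] whose sequences are scaffolds
#'   (coarse bins, 40 kb or larger recommended).
#' @param scaffolds A tibble with `name`, `length` (or a `scaffold_set`),
#'   or a members tibble with `name`, `chrom`, `start`, `end` to cluster
#'   arbitrary scaffold sections (e.g. subscaffolds after misjoin
#'   splitting).
#' @param k Number of chromosomes; `NULL` selects it by modularity.
#' @param ambiguity_ratio Second/best affinity ratio above which a scaffold
#'   is set aside (default 0.35).
#' @param min_scaffold_len Scaffolds below this length are excluded and
#'   reported separately (default 40 kb).
#' @param k_max Largest k tried during automatic selection (default 40).
#' @param linkage `"average"` (default; robust to chimeric scaffolds that
#'   bridge chromosomes) or `"single"` (exploits chain connectivity; the
#'   right choice once misjoins have been split, see
#'   [karyotype_pipeline()]). With single linkage, automatic `k` uses the
#'   largest gap in merge heights instead of the modularity scan.
#' @param method `"tree"` (hierarchical, default) or `"components"`:
#'   connected components of the strong-link graph (scaffold pairs whose
#'   mean contact exceeds `link_factor` times the median pairwise level,
#'   i.e. the trans background). Components are exact on misjoin-free
#'   scaffold sets because chromosomes are contact chains; the tree method
#'   tolerates chimeric bridges better.
#' @param link_factor Strong-link threshold for `method = "components"`
#'   (default 50; adjacency links sit two to three orders of magnitude
#'   above the trans background).
#' @return An object of class `karyotype_result` with the assignment tibble
#'   (`status` of assigned / ambiguous / below_min_length), merge heights,
#'   chosen `k`, modularity, and the `hclust` tree.
#' @export
karyotype_cluster <- function(cm, scaffolds, k = NULL, ambiguity_ratio = 0.35,
                              min_scaffold_len = 4e4, k_max = 40,
                              linkage = c("average", "single"),
                              method = c("tree", "components"),
                              link_factor = 50) {
  linkage <- match.arg(linkage)
  method <- match.arg(method)
  members <- as_members(cm, scaffolds)
  len <- members$end - members$start
  small <- members$name[len < min_scaffold_len]
  use <- members[len >= min_scaffold_len, ]
  n <- nrow(use)
  if (!is.null(k) && n < k) {
    stop("fewer scaffolds (", n, ") than requested clusters (", k, ")")
  }
  bl <- member_bins(cm, use)
  S <- member_contact_means(cm, bl)
  diag(S) <- 0
  smax <- max(S)
  if (smax <= 0) stop("no trans contacts between scaffolds")
  hc <- stats::hclust(stats::as.dist(1 - S / smax), method = linkage)
  if (method == "components" && is.null(k)) {
    ## edge-trimmed contacts for the strong-link graph: a residual misjoin
    ## stub (sub-bin remnant of a chimera) lives in the outermost bin of a
    ## member and can fake a cross-chromosome link; true adjacency spans
    ## the whole interface and survives trimming
    bl_trim <- lapply(bl, function(b) {
      tr <- if (length(b) > 5) 2L else if (length(b) > 3) 1L else 0L
      if (tr > 0) b[(1 + tr):(length(b) - tr)] else b
    })
    S_trim <- member_contact_means(cm, bl_trim)
    diag(S_trim) <- 0
    cl <- refine_partition(S, strong_link_components(S_trim, link_factor))
  } else {
    if (is.null(k)) {
      if (linkage == "single") {
        h <- hc$height
        k <- n - which.max(diff(h))
      } else {
        best <- NULL
        for (kk in 2:min(k_max, n - 1)) {
          cl_k <- refine_partition(S, stats::cutree(hc, kk))
          q <- partition_modularity(S, cl_k)
          if (is.null(best) || q > best$q + 1e-12) {
            best <- list(k = kk, cl = cl_k, q = q)
          }
        }
        k <- best$k
      }
    }
    cl <- refine_partition(S, stats::cutree(hc, k))
  }
  q <- partition_modularity(S, cl)
  ## renumber clusters consecutively
  cl <- match(cl, sort(unique(cl)))
  aff <- cluster_affinities(S, cl)
  best_a <- apply(aff, 1, max)
  second_a <- apply(aff, 1, function(r) {
    if (length(r) < 2) 0 else sort(r, decreasing = TRUE)[2]
  })
  ratio <- ifelse(best_a > 0, second_a / best_a, 1)
  status <- ifelse(ratio > ambiguity_ratio, "ambiguous", "assigned")
  assignment <- tibble::tibble(
    scaffold = c(use$name, small),
    status = c(status, rep("below_min_length", length(small))),
    cluster = c(ifelse(status == "assigned", cl, NA_integer_),
                rep(NA_integer_, length(small))),
    affinity = c(best_a, rep(NA_real_, length(small))),
    second_affinity = c(second_a, rep(NA_real_, length(small))),
    ratio = c(ratio, rep(NA_real_, length(small))))
  structure(list(assignment = assignment, k = length(unique(cl)),
                 modularity = q, heights = hc$height, tree = hc,
                 contact_means = S, members = use),
            class = "karyotype_result")
}

#' @export
print.karyotype_result <- function(x, ...) {
  tab <- table(x$assignment$status)
  cat(sprintf("<karyotype_result> k = %d (modularity %.3f); %s\n", x$k,
              x$modularity, paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Split scaffolds at chromosome-switch points (misjoin detection)
#'
#' Combines two detectors. (1) Each bin's contact affinity to every
#' chromosome cluster is computed and a scaffold is cut wherever the
#' maximal-affinity chromosome of consecutive bin runs changes; runs
#' shorter than `persistence` bins are absorbed into their neighbours, so
#' junctions in terminal bins produce no cut. (2) Independently of any
#' clustering, the scaffold's internal contact profile is scanned for
#' trans-level discontinuities — at a chimeric junction the two flanks are
#' genomically unlinked, so cross-contact drops two orders of magnitude —
#' which catches chimeras whose two chromosomes were confounded into one
#' cluster. Cut positions are refined to the bin boundary with maximal
#' signal contrast.
#'
#' @param cm A balanced [contact_matrix()] on scaffold coordinates.
#' @param scaffolds A `scaffold_set` or tibble with `name`, `length`.
#' @param karyotype A [karyotype_cluster()] result.
#' @param persistence Minimal run length in bins (default 3).
#' @return A tibble of subscaffolds: `name`, `parent`, `start`, `end`
#'   (scaffold coordinates), `cluster`, plus the cut table in
#'   `attr(, "cuts")`.
#' @export
split_misjoins <- function(cm, scaffolds, karyotype, persistence = 3) {
  if (inherits(scaffolds, "scaffold_set")) scaffolds <- scaffolds$scaffolds
  asg <- karyotype$assignment
  mem <- karyotype$members
  asg <- dplyr::left_join(asg, mem, by = c(scaffold = "name"))
  keep <- asg$status == "assigned"
  cluster_bins <- lapply(sort(unique(asg$cluster[keep])), function(c2) {
    rows <- which(keep & asg$cluster == c2)
    unlist(lapply(rows, function(r) {
      which(cm$bins$chrom == asg$chrom[r] &
              cm$bins$start >= asg$start[r] & cm$bins$start < asg$end[r] &
              (!cm$balanced | !is.na(cm$weights)))
    }))
  })
  v <- cm_values(cm)
  subs <- list(); cuts <- list()
  for (sc in scaffolds$name) {
    idx <- which(cm$bins$chrom == sc)
    L <- scaffolds$length[scaffolds$name == sc]
    if (!length(idx)) {
      subs[[sc]] <- tibble::tibble(name = paste0(sc, ".1"), parent = sc,
                                   start = 0, end = L, cluster = NA_integer_)
      next
    }
    own <- idx
    aff <- sapply(cluster_bins, function(cb) {
      cols <- setdiff(cb, own)
      if (!length(cols)) return(rep(0, length(idx)))
      Matrix::rowSums(v[idx, cols, drop = FALSE]) / length(cols)
    })
    if (is.null(dim(aff))) aff <- matrix(aff, nrow = length(idx))
    lab <- max.col(aff, ties.method = "first")
    lab[rowSums(aff) == 0] <- NA
    ## absorb short runs until every run reaches the persistence length
    repeat {
      r <- rle(lab)
      if (length(r$lengths) <= 1) break
      short <- which(r$lengths < persistence)
      if (!length(short)) break
      s <- short[which.min(r$lengths[short])]
      nb_prev <- if (s > 1) r$lengths[s - 1] else -1
      nb_next <- if (s < length(r$lengths)) r$lengths[s + 1] else -1
      take <- if (nb_prev >= nb_next) s - 1 else s + 1
      r$values[s] <- r$values[take]
      lab <- inverse.rle(r)
    }
    r <- rle(lab)
    ends_bin <- cumsum(r$lengths)
    nb <- length(lab)
    ## discontinuity scan: mean contact across each internal bin boundary
    disc_cuts <- integer(0)
    ins <- numeric(0); med <- NA_real_
    if (nb >= 2 * persistence) {
      w <- 5L
      good <- !cm$balanced | !is.na(cm$weights)
      ins <- vapply(2:nb, function(c0) {
        a <- idx[max(1, c0 - w):(c0 - 1)]; a <- a[good[a]]
        b <- idx[c0:min(nb, c0 + w - 1)]; b <- b[good[b]]
        if (!length(a) || !length(b)) return(NA_real_)
        sum(v[a, b, drop = FALSE]) / (length(a) * length(b))
      }, numeric(1))
      med <- stats::median(ins, na.rm = TRUE)
      if (is.finite(med) && med > 0) {
        low <- which(!is.na(ins) & ins < 0.25 * med)
        if (length(low)) {
          grp <- cumsum(c(1, diff(low) > 1))
          disc_cuts <- vapply(split(low, grp), function(ii) {
            ii[which.min(ins[ii])] + 1L  # boundary before bin (1-based offset)
          }, integer(1))
          disc_cuts <- disc_cuts[disc_cuts > persistence &
                                   disc_cuts <= nb - persistence + 1]
        }
      }
    }
    ## merge: keep discontinuity cuts (sharper); add affinity cuts not
    ## already explained by one. An affinity cut must itself sit at a
    ## contact discontinuity (a true junction joins genomically unlinked
    ## flanks), which rejects cuts caused by noisy affinity runs.
    aff_cuts <- ends_bin[-length(ends_bin)]
    if (length(ins) && is.finite(med) && med > 0) {
      aff_cuts <- aff_cuts[vapply(aff_cuts, function(cc) {
        win <- max(1, cc - 3):min(length(ins), cc + 3)
        min(ins[win], na.rm = TRUE) < 0.3 * med
      }, logical(1))]
    }
    aff_cuts <- aff_cuts[vapply(aff_cuts, function(cc) {
      !length(disc_cuts) || min(abs(disc_cuts - 1L - cc)) > persistence
    }, logical(1))]
    ends_bin <- sort(unique(c(nb, aff_cuts, disc_cuts - 1L)))
    r <- list(values = vapply(seq_along(ends_bin), function(si) {
      seg <- (c(0, utils::head(ends_bin, -1))[si] + 1):ends_bin[si]
      labs <- lab[seg]
      if (all(is.na(labs))) NA_integer_ else
        as.integer(names(which.max(table(labs))))
    }, integer(1)), lengths = diff(c(0, ends_bin)))
    ## refine each cut locally: place it at the bin boundary maximising the
    ## affinity contrast between the two flanking clusters (absorbed short
    ## runs can otherwise bias a cut by up to persistence - 1 bins)
    if (length(ends_bin) > 1) {
      for (ji in seq_len(length(ends_bin) - 1)) {
        la <- r$values[ji]; lb <- r$values[ji + 1]
        if (is.na(la) || is.na(lb) || la == lb) next
        c0 <- ends_bin[ji]
        lo <- max(c(1, c0 - 5, if (ji > 1) ends_bin[ji - 1] + 1 else 1))
        hi <- min(c(nb - 1, c0 + 5,
                    if (ji + 1 < length(ends_bin)) ends_bin[ji + 1] - 1 else nb - 1))
        if (hi <= lo) next
        cand <- lo:hi
        contrast <- vapply(cand, function(cc) {
          right <- if (cc < hi) (cc + 1):hi else integer(0)
          sum(aff[lo:cc, la]) - sum(aff[lo:cc, lb]) +
            sum(aff[right, lb]) - sum(aff[right, la])
        }, numeric(1))
        ends_bin[ji] <- cand[which.max(contrast)]
      }
    }
    starts_bin <- c(0, utils::head(ends_bin, -1))
    sub <- cm$bins[idx, ]
    bp_start <- sub$start[starts_bin + 1]
    bp_end <- c(sub$start[starts_bin[-1] + 1], L)
    subs[[sc]] <- tibble::tibble(
      name = paste0(sc, ".", seq_along(r$values)), parent = sc,
      start = bp_start, end = bp_end, cluster = r$values)
    if (length(r$values) > 1) {
      cuts[[sc]] <- tibble::tibble(parent = sc, pos = bp_end[-length(bp_end)])
    }
  }
  out <- dplyr::bind_rows(subs)
  attr(out, "cuts") <- dplyr::bind_rows(cuts)
  out
}

#' Full karyotyping stage: cluster, split misjoins, re-cluster
#'
#' Runs [karyotype_cluster()] on whole scaffolds, splits chimeric scaffolds
#' with [split_misjoins()], and re-clusters the resulting subscaffolds, so
#' that scaffold sections held hostage by a chimera join their true
#' chromosome.
#'
#' @inheritParams karyotype_cluster
#' @param persistence Passed to [split_misjoins()].
#' @param n_iter Split/re-cluster iterations (default 2): a chimera can
#'   contaminate the first clustering enough to hide its own junction; a
#'   second pass with the improved clusters recovers it.
#' @return A list with `initial` (whole-scaffold karyotype),
#'   `subscaffolds`, and `karyotype` (the final subscaffold-level result,
#'   clustered with single linkage once bridges are removed).
#' @export
karyotype_pipeline <- function(cm, scaffolds, k = NULL, ambiguity_ratio = 0.35,
                               min_scaffold_len = 4e4, persistence = 3,
                               n_iter = 2) {
  initial <- karyotype_cluster(cm, scaffolds, k = k,
                               ambiguity_ratio = ambiguity_ratio,
                               min_scaffold_len = min_scaffold_len)
  kt <- initial
  subs <- NULL
  for (it in seq_len(n_iter)) {
    subs <- split_misjoins(cm, scaffolds, kt, persistence = persistence)
    members <- tibble::tibble(name = subs$name, chrom = subs$parent,
                              start = subs$start, end = subs$end)
    kt <- karyotype_cluster(cm, members, k = k,
                            ambiguity_ratio = ambiguity_ratio,
                            min_scaffold_len = min_scaffold_len,
                            method = if (it == n_iter) "components" else "tree")
  }
  list(initial = initial, subscaffolds = subs, karyotype = kt)
}

## mean balanced contact between two bin-index sets
mean_contact <- function(v, idx1, idx2) {
  if (!length(idx1) || !length(idx2)) return(0)
  sum(v[idx1, idx2, drop = FALSE]) / (length(idx1) * length(idx2))
}

#' Order and orient the subscaffolds of one chromosome
#'
#' Orders members by greedy chaining on strongest mean contact followed by
#' 2-opt refinement of an adjacency-weighted log-contact score, then orients
#' each member by the contact asymmetry of its two halves toward its chain
#' neighbours. Orientation confidence is the normalised score margin
#' (`|a - b| / (a + b)`); whole-chromosome reversal is unresolvable from
#' Hi-C and left as an equivalence class.
#'
#' @param cm A balanced [contact_matrix()].
#' @param members A tibble with `name`, `chrom` (the matrix sequence the
#'   member lives on), `start`, `end` — e.g. subscaffolds from
#'   [split_misjoins()] (then `chrom` is the parent scaffold), or a
#'   `scaffold_set`-style tibble with `name` and `length`.
#' @return A tibble of class `chromosome_scaffold`: members in chain order
#'   with `orientation` and `confidence`.
#' @export
order_orient <- function(cm, members) {
  members <- as_members(cm, members)
  members <- dplyr::arrange(members, .data$name)
  nm <- nrow(members)
  v <- cm_values(cm)
  bin_sets <- member_bins(cm, members)
  if (nm == 1) {
    return(structure(tibble::tibble(name = members$name, position = 1L,
                                    orientation = "+", confidence = 0),
                     class = c("chromosome_scaffold", class(members))))
  }
  S <- matrix(0, nm, nm)
  for (i in seq_len(nm - 1)) for (j in (i + 1):nm) {
    S[i, j] <- S[j, i] <- mean_contact(v, bin_sets[[i]], bin_sets[[j]])
  }
  eps <- 1e-12
  score <- function(ord) {
    tot <- 0
    for (a in seq_len(nm - 1)) for (b in (a + 1):nm) {
      tot <- tot + log(S[ord[a], ord[b]] + eps) / (b - a)
    }
    tot
  }
  ## greedy chain from the strongest pair
  start <- which(S == max(S), arr.ind = TRUE)[1, ]
  chain <- as.integer(start)
  left <- setdiff(seq_len(nm), chain)
  while (length(left)) {
    head_s <- S[chain[1], left]
    tail_s <- S[chain[length(chain)], left]
    if (max(head_s) >= max(tail_s)) {
      pick <- left[which.max(head_s)]
      chain <- c(pick, chain)
    } else {
      pick <- left[which.max(tail_s)]
      chain <- c(chain, pick)
    }
    left <- setdiff(left, pick)
  }
  ## 2-opt refinement on the adjacency-weighted score
  best <- chain; best_score <- score(chain)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (a in seq_len(nm - 1)) for (b in (a + 1):nm) {
      cand <- best
      cand[a:b] <- rev(cand[a:b])
      sc <- score(cand)
      if (sc > best_score + 1e-9) {
        best <- cand; best_score <- sc; improved <- TRUE
      }
    }
  }
  ## canonical direction: lexicographically smallest end name first
  if (members$name[best[nm]] < members$name[best[1]]) best <- rev(best)
  ## orientation by half-contact asymmetry toward neighbours
  orient <- character(nm); conf <- numeric(nm)
  for (p in seq_len(nm)) {
    i <- best[p]
    bins_i <- bin_sets[[i]]
    h <- length(bins_i) %/% 2
    if (h == 0 || length(bins_i) < 2) { orient[p] <- "+"; conf[p] <- 0; next }
    h1 <- bins_i[seq_len(h)]
    h2 <- bins_i[(length(bins_i) - h + 1):length(bins_i)]
    nb_l <- if (p > 1) bin_sets[[best[p - 1]]] else integer(0)
    nb_r <- if (p < nm) bin_sets[[best[p + 1]]] else integer(0)
    a <- mean_contact(v, h1, nb_l) + mean_contact(v, h2, nb_r)
    b <- mean_contact(v, h2, nb_l) + mean_contact(v, h1, nb_r)
    if (a + b == 0) { orient[p] <- "+"; conf[p] <- 0; next }
    orient[p] <- if (a >= b) "+" else "-"
    conf[p] <- abs(a - b) / (a + b)
  }
  structure(tibble::tibble(name = members$name[best],
                           position = seq_len(nm),
                           orientation = orient, confidence = conf),
            class = c("chromosome_scaffold", class(members)))
}

#' Assign high-copy clusters to chromosomes
#'
#' Each set-aside cluster is placed on the chromosome with which it shows
#' the maximal mean balanced contact; the margin (best over runner-up) is
#' reported, with ties resolved deterministically toward the first
#' chromosome and flagged by `margin = 1`.
#'
#' @param cm A balanced [contact_matrix()].
#' @param clusters Named list: cluster id -> scaffold names.
#' @param chromosomes Named list: chromosome id -> scaffold names (e.g.
#'   from a [karyotype_cluster()] assignment).
#' @return A tibble with `cluster`, `chrom`, `margin`, `affinity`.
#' @export
assign_high_copy <- function(cm, clusters, chromosomes) {
  v <- cm_values(cm)
  rows <- lapply(names(clusters), function(cl) {
    idx1 <- which(cm$bins$chrom %in% clusters[[cl]])
    aff <- vapply(chromosomes, function(sc) {
      mean_contact(v, idx1, which(cm$bins$chrom %in% sc))
    }, numeric(1))
    ord <- order(aff, decreasing = TRUE)
    margin <- if (length(aff) > 1 && aff[ord[2]] > 0)
      aff[ord[1]] / aff[ord[2]] else Inf
    tibble::tibble(cluster = cl, chrom = names(chromosomes)[ord[1]],
                   margin = unname(margin), affinity = unname(aff[ord[1]]))
  })
  dplyr::bind_rows(rows)
}

#' Relative copy number from coverage
#'
#' Relative copy = median per-bin coverage of a group's sequences over the
#' median coverage of the placed (reference) sequences; invariant under
#' global coverage rescaling, and the reference level is 1 by construction.
#'
#' @param coverage A track tibble (`chrom`, `start`, `end`, `value`) of
#'   per-bin read counts on scaffold coordinates.
#' @param groups Named list: group id -> scaffold names.
#' @param reference Scaffold names making up the placed reference set.
#' @return A tibble with `group`, `copy_number`, `n_bins`.
#' @export
copy_number <- function(coverage, groups, reference) {
  ref_med <- stats::median(coverage$value[coverage$chrom %in% reference],
                           na.rm = TRUE)
  if (!is.finite(ref_med) || ref_med == 0) {
    stop("reference coverage median is zero or undefined")
  }
  rows <- lapply(names(groups), function(g) {
    vals <- coverage$value[coverage$chrom %in% groups[[g]]]
    tibble::tibble(group = g,
                   copy_number = stats::median(vals, na.rm = TRUE) / ref_med,
                   n_bins = sum(!is.na(vals)))
  })
  dplyr::bind_rows(rows)
}
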