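#' Create a genome assembly object
#'
#' A `genome_assembly` bundles an ordered chromosome table with optional
#' nucleotide sequence. All coordinates in the package are 0-based,
#' half-open; 1-based formats (GFF3, pairs) are converted at the I/O
#' boundary.
#'
#' @param chroms A data frame with columns `name` and `length` (base pairs),
#'   in the desired chromosome order, or a named numeric vector of lengths.
#' @param seq Optional [Biostrings::DNAStringSet] (or named character vector)
#'   with one entry per chromosome; widths must equal the declared lengths.
#' @return An object of class `genome_assembly` with elements `chroms`
#'   (a tibble) and `seq` (a `DNAStringSet` or `NULL`).
#' @examples
#' genome_assembly(c(chrA = 26204, chrB = 40000))
#' @export
genome_assembly <- function(chroms, seq = NULL) {
  if (is.numeric(chroms)) {
    chroms <- tibble::tibble(name = names(chroms), length = unname(chroms))
  }
  chroms <- tibble::as_tibble(chroms)
  stopifnot(all(c("name", "length") %in% names(chroms)))
  chroms$name <- as.character(chroms$name)
  chroms$length <- as.numeric(chroms$length)
  if (nrow(chroms) == 0) stop("assembly must contain at least one chromosome")
  if (anyDuplicated(chroms$name)) stop("chromosome names must be unique")
  if (any(chroms$length <= 0)) stop("chromosome lengths must be positive")
  if (!is.null(seq)) {
    if (is.character(seq)) seq <- Biostrings::DNAStringSet(seq)
    if (!all(chroms$name %in% names(seq))) {
      stop("sequence missing for chromosomes: ",
           paste(setdiff(chroms$name, names(seq)), collapse = ", "))
    }
    seq <- seq[chroms$name]
    w <- Biostrings::width(seq)
    if (!all(w == chroms$length)) {
      bad <- chroms$name[w != chroms$length]
      stop("sequence length disagrees with declared length for: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(chroms = chroms[, c("name", "length")], seq = seq),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %d chromosome(s), %.3f Mb total, sequence: %s\n",
              nrow(x$chroms), sum(x$chroms$length) / 1e6,
              if (is.null(x$seq)) "absent" else "present"))
  print(x$chroms, ...)
  invisible(x)
}

chrom_lengths <- function(assembly) {
  stats::setNames(assembly$chroms$length, assembly$chroms$name)
}

#' Tile a genome into fixed-width bins
#'
#' Each chromosome is tiled with half-open bins of width `resolution`; the
#' last bin of a chromosome may be shorter. Bin ids are 0-based and ordered
#' by the assembly's chromosome order.
#'
#' @param assembly A [genome_assembly()] (or anything accepted by it).
#' @param resolution Bin width in base pairs (> 0).
#' @return A tibble of class `bin_table` with columns `bin_id`, `chrom`,
#'   `start`, `end` and attributes `resolution` and `chrom_sizes`.
#' @examples
#' bin_genome(genome_assembly(c(chr1 = 26204)), 10000)
#' @export
bin_genome <- function(assembly, resolution) {
  if (!inherits(assembly, "genome_assembly")) assembly <- genome_assembly(assembly)
  if (length(resolution) != 1 || !is.finite(resolution) || resolution <= 0) {
    stop("resolution must be a single positive number")
  }
  resolution <- as.numeric(resolution)
  per <- lapply(seq_len(nrow(assembly$chroms)), function(i) {
    L <- assembly$chroms$length[i]
    n <- ceiling(L / resolution)
    start <- (seq_len(n) - 1) * resolution
    tibble::tibble(chrom = assembly$chroms$name[i], start = start,
                   end = pmin(start + resolution, L))
  })
  bins <- dplyr::bind_rows(per)
  bins <- tibble::add_column(bins, bin_id = seq_len(nrow(bins)) - 1L, .before = 1)
  attr(bins, "resolution") <- resolution
  attr(bins, "chrom_sizes") <- chrom_lengths(assembly)
  class(bins) <- c("bin_table", class(bins))
  bins
}

bin_resolution <- function(bins) attr(bins, "resolution")

## first bin id of each chromosome, in bin-table order
bin_offsets <- function(bins) {
  idx <- !duplicated(bins$chrom)
  stats::setNames(bins$bin_id[idx], bins$chrom[idx])
}

bins_per_chrom <- function(bins) {
  tab <- table(factor(bins$chrom, levels = unique(bins$chrom)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Scan a sequence window for runs of N
#'
#' Returns `TRUE` when the window `[start, end)` of `chrom` contains no run
#' of at least `run_min` consecutive `N` characters, the contiguity rule used
#' to decide whether a domain boundary lies inside assembled contig sequence.
#'
#' @param assembly A [genome_assembly()] carrying sequence, or a single
#'   character string (then `chrom`/`start`/`end` are ignored).
#' @param chrom,start,end Window coordinates (0-based, half-open); clipped to
#'   the chromosome.
#' @param run_min Minimal N-run length that disqualifies the window
#'   (default 24).
#' @return `TRUE`/`FALSE`, or `NA` when no sequence is available.
#' @export
n_gap_scan <- function(assembly, chrom = NULL, start = NULL, end = NULL,
                       run_min = 24) {
  if (is.character(assembly) && length(assembly) == 1) {
    s <- assembly
  } else {
    if (is.null(assembly$seq)) return(NA)
    if (!chrom %in% names(assembly$seq)) return(NA)
    L <- length(assembly$seq[[chrom]])
    start <- max(0, start); end <- min(L, end)
    if (end <= start) return(TRUE)
    s <- as.character(Biostrings::subseq(assembly$seq[[chrom]], start + 1, end))
  }
  !grepl(paste0("N{", run_min, ",}"), s)
}
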