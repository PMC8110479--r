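## Readers/writers for the interchange formats used by the pipeline.
## Internal convention everywhere: 0-based half-open intervals; conversion to
## and from the 1-based formats (FASTA-attached GFF3, pairs) happens here.

#' Read / write a genome FASTA
#'
#' @param path File path.
#' @return [read_fasta()] returns a [genome_assembly()] with sequence.
#' @export
read_fasta <- function(path) {
  seq <- Biostrings::readDNAStringSet(path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  genome_assembly(stats::setNames(Biostrings::width(seq), names(seq)), seq)
}

#' @param assembly A [genome_assembly()] with sequence.
#' @rdname read_fasta
#' @export
write_fasta <- function(assembly, path) {
  if (is.null(assembly$seq)) stop("assembly carries no sequence")
  Biostrings::writeXStringSet(assembly$seq, path, width = 70)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene`-type features and converts them to the package's 0-based
#' half-open gene table, sorted by chromosome then start (ties broken by end,
#' then id, for deterministic downstream run-length encoding).
#'
#' @param path GFF3 file path.
#' @param feature Feature type to keep (default `"gene"`).
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gff_genes <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0("gene", seq_along(gr))
  g <- tibble::tibble(
    gene_id = ids,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1,
    end = as.numeric(BiocGenerics::end(gr)),
    strand = as.character(BiocGenerics::strand(gr)))
  if (any(!g$strand %in% c("+", "-"))) stop("all genes must be stranded")
  dplyr::arrange(g, .data$chrom, .data$start, .data$end, .data$gene_id)
}

#' @param genes A gene table (see [read_gff_genes()]).
#' @param source Value for the GFF3 source column.
#' @rdname read_gff_genes
#' @export
write_gff_genes <- function(genes, path, source = "dinochrom") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, source, as.integer(genes$start + 1),
                     as.integer(genes$end), genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write BED intervals
#'
#' @param path File path.
#' @return A tibble with `chrom`, `start`, `end` and, when present in the
#'   file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble::tibble(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                        start = BiocGenerics::start(gr) - 1,
                        end = as.numeric(BiocGenerics::end(gr)))
  if (!is.null(gr$name)) out$name <- as.character(gr$name)
  if (!is.null(gr$score)) out$score <- as.numeric(gr$score)
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' @param x A tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  has <- function(col) col %in% names(x)
  cols <- list(x$chrom, format(as.integer(x$start)), format(as.integer(x$end)))
  if (has("name") || has("score") || has("strand")) {
    cols <- c(cols, list(if (has("name")) as.character(x$name) else ".",
                         if (has("score")) format(x$score) else "0",
                         if (has("strand")) x$strand else "."))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read / write a bedGraph track
#'
#' Intervals must be sorted and non-overlapping per chromosome; overlapping
#' records are rejected with the offending line numbers.
#'
#' @param path File path.
#' @return A tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- tibble::tibble(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                        start = BiocGenerics::start(gr) - 1,
                        end = as.numeric(BiocGenerics::end(gr)),
                        value = as.numeric(gr$score))
  ord <- order(match(out$chrom, unique(out$chrom)), out$start)
  ovl <- which(out$chrom[ord][-1] == out$chrom[ord][-nrow(out)] &
                 out$start[ord][-1] < out$end[ord][-nrow(out)])
  if (length(ovl)) {
    stop("overlapping bedGraph intervals at line(s): ",
         paste(utils::head(ord[ovl + 1], 10), collapse = ", "))
  }
  out[ord, ]
}

#' @param x A track tibble with `chrom`, `start`, `end`, `value`.
#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(x, path) {
  keep <- !is.na(x$value)
  writeLines(sprintf("%s\t%d\t%d\t%s", x$chrom[keep],
                     as.integer(x$start[keep]), as.integer(x$end[keep]),
                     format(x$value[keep], scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Read / write valid pairs (pairs format)
#'
#' Parses the tab-separated pairs format (header lines start with `#`);
#' positions are 1-based in file and kept 1-based in the returned tibble, as
#' pair records are consumed by [pairs_to_matrix()] which performs the
#' coordinate conversion. Records are canonically ordered (chrom1 <= chrom2
#' in assembly order, pos1 <= pos2 within a chromosome).
#'
#' @param path File path.
#' @return A tibble with `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#'   `strand2`.
#' @export
read_pairs <- function(path) {
  df <- readr::read_tsv(path, comment = "#",
                        col_names = c("readID", "chrom1", "pos1", "chrom2",
                                      "pos2", "strand1", "strand2"),
                        col_types = "ccdcdcc", progress = FALSE)
  tibble::as_tibble(df[, c("chrom1", "pos1", "strand1",
                           "chrom2", "pos2", "strand2")])
}

#' @param pairs A pairs tibble.
#' @param assembly Optional [genome_assembly()] used to emit `#chromsize`
#'   header lines.
#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path, assembly = NULL) {
  hdr <- "## pairs format v1.0"
  cols <- "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2"
  if (!is.null(assembly)) {
    hdr <- c(hdr, sprintf("#chromsize: %s %d", assembly$chroms$name,
                          as.integer(assembly$chroms$length)))
  }
  body <- sprintf(".\t%s\t%d\t%s\t%d\t%s\t%s", pairs$chrom1,
                  as.integer(pairs$pos1), pairs$chrom2, as.integer(pairs$pos2),
                  pairs$strand1, pairs$strand2)
  writeLines(c(hdr, cols, body), path)
  invisible(path)
}

## Canonical upper-triangular ordering of pair records.
canonical_pairs <- function(pairs, chrom_order = NULL) {
  if (is.null(chrom_order)) chrom_order <- unique(c(pairs$chrom1, pairs$chrom2))
  c1 <- match(pairs$chrom1, chrom_order)
  c2 <- match(pairs$chrom2, chrom_order)
  flip <- c2 < c1 | (c1 == c2 & pairs$pos2 < pairs$pos1)
  out <- pairs
  out[flip, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")] <-
    pairs[flip, c("chrom2", "pos2", "strand2", "chrom1", "pos1", "strand1")]
  dplyr::arrange(out, match(.data$chrom1, chrom_order),
                 match(.data$chrom2, chrom_order), .data$pos1, .data$pos2)
}

#' Read / write a contact matrix as plain-text triplets
#'
#' The on-disk dialect is two tab-separated files: `<prefix>.bins.tsv`
#' (bin table with a `weight` column) and `<prefix>.triplets.tsv`
#' (`bin1_id`, `bin2_id`, `count`, upper triangle only). This keeps binned
#' matrices fully text-based.
#'
#' @param prefix Path prefix for the two files.
#' @return [read_triplet_matrix()] returns a [contact_matrix()].
#' @export
read_triplet_matrix <- function(prefix) {
  bins <- readr::read_tsv(paste0(prefix, ".bins.tsv"), col_types = "icddd",
                          progress = FALSE)
  trip <- readr::read_tsv(paste0(prefix, ".triplets.tsv"), col_types = "iid",
                          progress = FALSE)
  res <- max(bins$end - bins$start)
  sizes <- tapply(bins$end, factor(bins$chrom, levels = unique(bins$chrom)), max)
  bt <- tibble::as_tibble(bins[, c("bin_id", "chrom", "start", "end")])
  attr(bt, "resolution") <- res
  attr(bt, "chrom_sizes") <- stats::setNames(as.numeric(sizes), names(sizes))
  class(bt) <- c("bin_table", class(bt))
  n <- nrow(bt)
  m <- Matrix::sparseMatrix(i = trip$bin1_id + 1, j = trip$bin2_id + 1,
                            x = trip$count, dims = c(n, n), symmetric = TRUE)
  w <- bins$weight
  contact_matrix(bt, m, weights = w, balanced = any(!is.na(w)))
}

#' @param cm A [contact_matrix()].
#' @rdname read_triplet_matrix
#' @export
write_triplet_matrix <- function(cm, prefix) {
  bins <- dplyr::mutate(tibble::as_tibble(cm$bins), weight = cm$weights)
  readr::write_tsv(bins, paste0(prefix, ".bins.tsv"), progress = FALSE)
  tu <- methods::as(Matrix::triu(methods::as(cm$counts, "generalMatrix")),
                    "TsparseMatrix")
  trip <- tibble::tibble(bin1_id = tu@i, bin2_id = tu@j, count = tu@x)
  trip <- dplyr::arrange(trip, .data$bin1_id, .data$bin2_id)
  readr::write_tsv(trip, paste0(prefix, ".triplets.tsv"), progress = FALSE)
  invisible(prefix)
}
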