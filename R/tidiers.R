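#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a karyotype result
#'
#' @param x A [karyotype_cluster()] result.
#' @param ... Unused.
#' @return The per-scaffold assignment tibble.
#' @method tidy karyotype_result
#' @export
tidy.karyotype_result <- function(x, ...) x$assignment

#' @rdname tidy.karyotype_result
#' @method glance karyotype_result
#' @export
glance.karyotype_result <- function(x, ...) {
  tab <- table(x$assignment$status)
  tibble::tibble(k = x$k,
                 n_assigned = sum(x$assignment$status == "assigned"),
                 n_ambiguous = sum(x$assignment$status == "ambiguous"),
                 n_below_min = sum(x$assignment$status == "below_min_length"),
                 max_height = max(x$heights))
}

#' Tidy a regime fit
#'
#' @param x A [segment_regimes()] result.
#' @param ... Unused.
#' @return One row per segment with its slope and bounds.
#' @method tidy regime_fit
#' @export
tidy.regime_fit <- function(x, ...) {
  bounds <- c(min(x$points$s), x$breakpoints, max(x$points$s))
  tibble::tibble(segment = seq_along(x$slopes),
                 s_from = bounds[seq_along(x$slopes)],
                 s_to = bounds[seq_along(x$slopes) + 1],
                 slope = x$slopes)
}

#' @rdname tidy.regime_fit
#' @method glance regime_fit
#' @export
glance.regime_fit <- function(x, ...) {
  tibble::tibble(n_segments = length(x$slopes),
                 n_points = nrow(x$points), sse = x$sse)
}

#' Tidy a pileup into long format
#'
#' @param x A [pileup()] result.
#' @param ... Unused.
#' @return A tibble with `offset1`, `offset2` (bp) and `log10_oe`.
#' @method tidy hic_pileup
#' @export
tidy.hic_pileup <- function(x, ...) {
  k <- nrow(x$log10_oe)
  off <- (seq_len(k) - (k + 1) / 2) * x$resolution
  tibble::tibble(offset1 = rep(off, times = k),
                 offset2 = rep(off, each = k),
                 log10_oe = as.vector(x$log10_oe))
}

#' Plot an insulation profile
#'
#' @param object An [insulation_score()] profile.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot insulation_profile
#' @export
autoplot.insulation_profile <- function(object, ...) {
  df <- object[!is.na(object$score), ]
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$score)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "insulation (log2 vs chrom mean)")
}

#' Plot a P(s) scaling curve
#'
#' @param object A `scaling_curve`.
#' @param ... Unused.
#' @return A ggplot on log-log axes.
#' @method autoplot scaling_curve
#' @export
autoplot.scaling_curve <- function(object, ...) {
  df <- object[object$usable & is.finite(object$P) & object$P > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$P)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic separation s (bp)",
                  y = "contact probability P(s)")
}

#' @rdname autoplot.scaling_curve
#' @method autoplot regime_fit
#' @export
autoplot.regime_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$P), size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::geom_vline(xintercept = object$breakpoints, linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "s (bp)", y = "P(s)")
}

#' Plot an aggregate pileup heatmap
#'
#' @param object A [pileup()] result.
#' @param ... Unused.
#' @return A ggplot raster of mean log10 observed/expected.
#' @method autoplot hic_pileup
#' @export
autoplot.hic_pileup <- function(object, ...) {
  df <- tidy.hic_pileup(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset1 / 1e3,
                                   y = .data$offset2 / 1e3,
                                   fill = .data$log10_oe)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "offset (kb)", y = "offset (kb)",
                  fill = "log10 O/E")
}

#' Plot one chromosome of a contact matrix
#'
#' @param cm A [contact_matrix()].
#' @param chrom Chromosome (sequence) name.
#' @param balanced Plot balanced values when available.
#' @return A ggplot raster of log10 contacts.
#' @export
plot_contact_map <- function(cm, chrom, balanced = cm$balanced) {
  m <- cm_dense_chrom(cm, chrom, balanced = balanced)
  res <- bin_resolution(cm$bins)
  n <- nrow(m)
  df <- tibble::tibble(x = rep(seq_len(n), times = n) * res / 1e6,
                       y = rep(seq_len(n), each = n) * res / 1e6,
                       v = log10(as.vector(m) + 1e-6))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Mb", y = "Mb", fill = "log10 contacts",
                  title = chrom)
}
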