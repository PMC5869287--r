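# ggplot2 views of the main result types.

#' Contig span versus mode coverage
#'
#' The diagnostic scatter for haplotype separation: each point is a contig;
#' a bimodal cloud around the haplotig centre and its double reveals
#' separated and collapsed contigs. Class windows are shaded.
#'
#' @param object An `hd_classes` table.
#' @param ... Unused.
#' @export
autoplot.hd_classes <- function(object, ...) {
  c0 <- attr(object, "center"); w <- attr(object, "halfwidth")
  df <- tibble::as_tibble(object) |> filter(!is.na(.data$mode))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$span,
                                   colour = .data$class)) +
    ggplot2::annotate("rect", xmin = c0 - w, xmax = c0 + w,
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "blue") +
    ggplot2::annotate("rect", xmin = 2 * c0 - w, xmax = 2 * c0 + w,
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "red") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mode coverage (fold)", y = "contig span (bp)",
                  colour = NULL)
}

#' Depth histogram plot
#'
#' @param object An `hd_coverage` histogram.
#' @param contig Optional single contig to show; default aggregates all.
#' @param ... Unused.
#' @export
autoplot.hd_coverage <- function(object, contig = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(contig)) df <- df[df$contig %in% contig, ]
  df <- df |>
    group_by(.data$depth) |>
    summarise(bases = sum(.data$bases), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$bases)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "depth (fold)", y = "bases")
}

#' Chromosomal quotient along contigs
#'
#' @param object An `hd_cq` table.
#' @param ... Unused.
#' @export
autoplot.hd_cq <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- tibble::as_tibble(object) |> filter(!is.na(.data$cq))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e3,
                                   y = pmax(.data$cq, 1e-3),
                                   colour = .data$male_specific)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = cfg$cq_threshold, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = "CQ (female/male)",
                  colour = "male-specific")
}

#' RPKM distribution with expression thresholds
#'
#' @param object An `hd_expression` table.
#' @param ... Unused.
#' @export
autoplot.hd_expression <- function(object, ...) {
  cfg <- attr(object, "config")
  thr <- attr(object, "het_threshold")
  df <- tibble::as_tibble(object) |> filter(.data$rpkm > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rpkm)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = cfg$expressed_threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = thr, linetype = 3) +
    ggplot2::labs(x = "RPKM", y = "transcripts")
}
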