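# broom-style accessors: tidy() returns the per-unit table, glance() the
# one-row model/stage summary.

#' @export
tidy.hd_classes <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.hd_classes <- function(x, ...) {
  tibble::tibble(center = attr(x, "center"), halfwidth = attr(x, "halfwidth"),
                 n_contigs = nrow(x),
                 n_separated = sum(x$class == "SEPARATED"),
                 n_collapsed = sum(x$class == "COLLAPSED"),
                 n_other = sum(x$class == "OTHER"),
                 assembly_span = attr(x, "assembly_span"),
                 separated_fraction = attr(x, "h"))
}

#' @export
tidy.hd_crosstab <- function(x, ...) tibble::as_tibble(x)

#' Derived percentage summaries of an ortholog crosstab
#'
#' Percentages are on the 0–100 scale: the share of genes found as exactly
#' two instances, the share of two-instance genes with at least one instance
#' on a SEPARATED contig, and the class shares of single-instance genes.
#' @param x An `hd_crosstab`.
#' @param ... Unused.
#' @export
glance.hd_crosstab <- function(x, ...) {
  total <- sum(x$genes_found)
  two <- x$bin == "2"
  one <- x$bin == "1"
  tibble::tibble(
    total_genes = total,
    pct_two_instance = 100 * sum(x$genes_found[two]) / total,
    pct_two_instance_touching_separated =
      100 * sum(x$genes_separated[two]) / sum(x$genes_found[two]),
    pct_one_instance_separated =
      100 * sum(x$genes_separated[one]) / sum(x$genes_found[one]),
    pct_one_instance_collapsed =
      100 * sum(x$genes_collapsed[one]) / sum(x$genes_found[one]))
}

#' @export
tidy.hd_association <- function(x, ...) {
  tb <- x$table
  tibble::tibble(instances = rep(rownames(tb), each = 2),
                 location = rep(colnames(tb), 2),
                 genes = as.vector(t(tb)))
}

#' @export
glance.hd_association <- function(x, ...) {
  tibble::tibble(odds_ratio = x$odds_ratio, p_value = x$p_value)
}

#' @export
glance.hd_pair_counts <- function(x, ...) {
  tibble::tibble(n_contig_pairs = nrow(x),
                 n_placed_pairs = attr(x, "n_placed"),
                 fraction_exactly_two = attr(x, "fraction_exactly_two"),
                 intra_contig_doubles = attr(x, "intra_contig_doubles"))
}

#' @export
glance.hd_pcs <- function(x, ...) {
  sp <- pc_span_summary(x)
  tibble::tibble(n_pcs = nrow(x),
                 n_pc_contigs = dplyr::n_distinct(c(x$contig_a, x$contig_b)),
                 pc_span = sp$pc_span, assembly_span = sp$assembly_span,
                 pc_span_fraction = sp$fraction,
                 pc_span_percent = sp$percent)
}

#' @export
tidy.hd_pc_graph <- function(x, ...) tibble::as_tibble(x$edges)

#' @export
glance.hd_pc_graph <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x$edges),
                 n_tiling = sum(x$edges$link == "TILING"),
                 n_walks = nrow(x$walks),
                 longest_walk_contigs = if (nrow(x$walks)) max(x$walks$n_contigs) else 0L,
                 longest_walk_span = if (nrow(x$walks)) max(x$walks$span) else NA_real_)
}

#' @export
glance.hd_expression <- function(x, ...) {
  tibble::tibble(n_transcripts = nrow(x),
                 total_mapped = attr(x, "total_mapped"),
                 n_expressed = attr(x, "n_expressed"),
                 mean_expressed_rpkm = attr(x, "mean_expressed_rpkm"),
                 het_threshold = attr(x, "het_threshold"),
                 n_het = attr(x, "n_het"))
}

#' @export
glance.hd_subtraction <- function(x, ...) x$report

#' @export
tidy.hd_cq <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.hd_cq <- function(x, ...) {
  tibble::tibble(n_spans = nrow(x),
                 reporting_spans = sum(!is.na(x$cq)),
                 male_specific_spans = sum(x$male_specific),
                 male_specific_fraction = sum(x$male_specific) /
                   max(1L, sum(!is.na(x$cq))))
}
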