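#' Ingest single-copy-ortholog hits against classified contigs
#'
#' Groups ortholog (e.g. BUSCO-style) hit rows into per-gene instance lists
#' and attaches each instance's contig coverage class. Accepts a tibble or a
#' TSV (`gene_id`, `contig`, `start`, `end`, optional `score`), BED
#' (name column = gene id) or GFF path; GFF's 1-based closed coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' @param hits Hit tibble or file path.
#' @param classes An `hd_classes` table from [classify_contigs()] (or any
#'   tibble with `contig` and `class` columns).
#' @param format File format when `hits` is a path: `"tsv"`, `"bed"`,
#'   `"gff"`.
#' @return An `hd_gene_instances` tibble (one row per instance, with class),
#'   carrying a per-gene summary in the `genes` attribute: instance count,
#'   class profile and the mutually exclusive `only_separated` /
#'   `only_collapsed` flags.
#' @export
ingest_gene_hits <- function(hits, classes, format = c("tsv", "bed", "gff")) {
  if (is.character(hits) && length(hits) == 1L) {
    format <- match.arg(format)
    hits <- switch(format,
      tsv = readr::read_tsv(hits, show_col_types = FALSE),
      bed = {
        df <- readr::read_tsv(hits, col_names = FALSE, show_col_types = FALSE)
        tibble::tibble(gene_id = df[[4]], contig = df[[1]],
                       start = df[[2]], end = df[[3]])
      },
      gff = {
        df <- readr::read_tsv(hits, col_names = FALSE, comment = "#",
                              show_col_types = FALSE)
        attr_id <- sub(".*(?:ID|Name)=([^;]+).*", "\\1", df[[9]])
        tibble::tibble(gene_id = attr_id, contig = df[[1]],
                       start = df[[4]] - 1, end = df[[5]]) # 1-based closed in
      })
  }
  hd_assert(all(c("gene_id", "contig", "start", "end") %in% names(hits)),
            "hits need gene_id/contig/start/end columns")
  known <- unique(classes$contig)
  bad <- setdiff(unique(hits$contig), known)
  hd_assert(length(bad) == 0,
            paste0("hits reference unknown contigs: ",
                   paste(utils::head(bad, 10), collapse = ", ")))
  inst <- tibble::as_tibble(hits) |>
    left_join(dplyr::select(tibble::as_tibble(classes), "contig", "class"),
              by = "contig")
  genes <- inst |>
    group_by(.data$gene_id) |>
    summarise(n_instances = dplyr::n(),
              n_separated = sum(.data$class == "SEPARATED"),
              n_collapsed = sum(.data$class == "COLLAPSED"),
              n_other = sum(.data$class == "OTHER"),
              .groups = "drop") |>
    mutate(only_separated = .data$n_separated == .data$n_instances,
           only_collapsed = .data$n_collapsed == .data$n_instances)
  hd_tbl(inst, "hd_gene_instances", genes = genes)
}

bin_instances <- function(n) {
  dplyr::case_when(n <= 4 ~ as.character(n), n <= 8 ~ "5-8", TRUE ~ "9+")
}

#' Ortholog instance crosstab by coverage class
#'
#' Tabulates genes by instance count (rows 1, 2, 3, 4, 5–8) against contig
#' coverage classes: genes with at least one instance on a SEPARATED /
#' COLLAPSED contig, genes with *all* instances on one class, and
#' instance-level counts per class. Derived percentage summaries (share of
#' two-instance genes, share of those touching SEPARATED contigs, class
#' shares of single-instance genes) are available through [glance()].
#'
#' @param instances An `hd_gene_instances` table from [ingest_gene_hits()].
#' @return An `hd_crosstab` tibble, one row per instance-count bin plus the
#'   underlying per-gene table in the `genes` attribute.
#' @export
instance_crosstab <- function(instances) {
  genes <- attr(instances, "genes")
  hd_assert(!is.null(genes) && nrow(genes) > 0, "empty gene instance table")
  per_bin <- genes |>
    mutate(bin = bin_instances(.data$n_instances)) |>
    group_by(.data$bin) |>
    summarise(genes_found = dplyr::n(),
              genes_separated = sum(.data$n_separated > 0),
              genes_collapsed = sum(.data$n_collapsed > 0),
              genes_only_separated = sum(.data$only_separated),
              genes_only_collapsed = sum(.data$only_collapsed),
              inst_separated = sum(.data$n_separated),
              inst_collapsed = sum(.data$n_collapsed),
              inst_other = sum(.data$n_other),
              .groups = "drop") |>
    arrange(match(.data$bin, c("1", "2", "3", "4", "5-8", "9+")))
  hd_tbl(per_bin, "hd_crosstab", genes = genes)
}

#' Build a crosstab from printed per-bin counts
#'
#' Re-ingests an already tabulated instance-by-class tally (for example the
#' published BUSCO tally of a reference assembly) so that the derived shares
#' and the association test can be recomputed from printed numbers.
#'
#' @param counts Tibble with the crosstab columns (`bin`, `genes_found`,
#'   `genes_separated`, `genes_collapsed`, `genes_only_separated`,
#'   `genes_only_collapsed`, `inst_separated`, `inst_collapsed`,
#'   `inst_other`).
#' @return An `hd_crosstab` tibble.
#' @export
crosstab_from_counts <- function(counts) {
  need <- c("bin", "genes_found", "genes_separated", "genes_collapsed",
            "genes_only_separated", "genes_only_collapsed",
            "inst_separated", "inst_collapsed", "inst_other")
  hd_assert(all(need %in% names(counts)),
            paste("counts must carry columns:", paste(need, collapse = ", ")))
  counts <- tibble::as_tibble(counts)
  counts$bin <- as.character(counts$bin)
  hd_tbl(counts[, need], "hd_crosstab", genes = NULL)
}

#' Two-by-two association table: duplication versus separation
#'
#' Rows: genes with exactly two instances vs all other genes. Columns: genes
#' with all instances on SEPARATED contigs vs not.
#'
#' @param x An `hd_crosstab`.
#' @return A 2x2 integer matrix.
#' @export
association_table <- function(x) {
  hd_assert(inherits(x, "hd_crosstab"), "x must be an hd_crosstab")
  two <- x$bin == "2"
  a <- sum(x$genes_only_separated[two])
  b <- sum(x$genes_found[two]) - a
  c_ <- sum(x$genes_only_separated[!two])
  d <- sum(x$genes_found[!two]) - c_
  matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
         dimnames = list(instances = c("exactly_2", "other"),
                         location = c("only_separated", "not")))
}

#' Fisher exact test of the duplication/separation association
#'
#' Two-sided Fisher exact test (sum of hypergeometric probabilities at or
#' below that of the observed table) of the association between a gene having
#' exactly two instances and all instances lying on haplotype-separated
#' contigs. The odds ratio is computed from the cells directly, with a 0.5
#' continuity correction when any cell is zero.
#'
#' @param x A 2x2 matrix, an `hd_crosstab`, or an `hd_gene_instances` table.
#' @return An `hd_association` list: `table`, `odds_ratio`, `p_value`.
#' @export
association_test <- function(x) {
  if (inherits(x, "hd_gene_instances")) x <- instance_crosstab(x)
  if (inherits(x, "hd_crosstab")) x <- association_table(x)
  hd_assert(is.matrix(x) && all(dim(x) == 2), "x must reduce to a 2x2 table")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    rlang::warn("a margin of the 2x2 table is zero; p = 1")
    p <- 1
  } else {
    p <- stats::fisher.test(x, alternative = "two.sided")$p.value
  }
  cc <- if (any(x == 0)) 0.5 else 0
  or <- ((x[1, 1] + cc) * (x[2, 2] + cc)) / ((x[1, 2] + cc) * (x[2, 1] + cc))
  structure(list(table = x, odds_ratio = or, p_value = p),
            class = "hd_association")
}

#' @export
print.hd_association <- function(x, ...) {
  cat("<hd_association> odds ratio ", signif(x$odds_ratio, 4),
      ", Fisher exact p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Triage genes found on only one contig of a paired contig
#'
#' A gene with a full-length instance on exactly one contig of a PC is a
#' "missing gene" candidate on the partner. Each candidate is assigned one
#' category, tested in order: `COVERAGE_ELEVATED` — mean read depth over the
#' locus at least `elevation_factor` times the host contig's mode
#' (the gene may be higher copy in the genome than the assembly);
#' `CONTIG_END` — the locus lies within `end_margin` of a contig end (the
#' cognate copy may fall in an assembly gap); `FRAGMENTARY` — the partner
#' carries a partial hit covering less than `partial_cover` of the gene
#' (suggesting allele-specific gene loss with a remnant); otherwise
#' `CLEAN_LOSS`.
#'
#' @param instances An `hd_gene_instances` table.
#' @param pcs An `hd_pcs` table.
#' @param placements Best-one `hd_placements` used for local depth.
#' @param modes Tibble with `contig` and `mode` (e.g. an `hd_classes`).
#' @param elevation_factor Depth-elevation multiplier (default 1.5).
#' @param end_margin Contig-end margin, bp (default 10,000).
#' @param partial_cover Fraction of gene length below which a hit is partial
#'   (default 0.5).
#' @return Tibble: `gene_id`, `contig`, `partner`, `category`, and the
#'   evidence values (`depth_ratio`, `end_distance`, `partner_cover`).
#' @export
triage_missing_genes <- function(instances, pcs, placements, modes,
                                 elevation_factor = 1.5,
                                 end_margin = 1e4,
                                 partial_cover = 0.5) {
  contigs <- attr(placements, "contigs")
  len <- setNames(contigs$length, contigs$contig)
  gene_len <- instances |>
    group_by(.data$gene_id) |>
    summarise(glen = max(.data$end - .data$start), .groups = "drop")
  inst <- instances |>
    left_join(gene_len, by = "gene_id") |>
    mutate(cover = (.data$end - .data$start) / .data$glen)
  mode_of <- setNames(modes$mode, modes$contig)
  paired <- isTRUE(attr(placements, "paired"))
  mean_depth <- function(cg, s, e) {
    sel <- placements$contig == cg
    if (paired) {
      ov <- interval_overlap(s, e, c(placements$start1[sel], placements$start2[sel]),
                             c(placements$end1[sel], placements$end2[sel]))
    } else {
      ov <- interval_overlap(s, e, placements$start[sel], placements$end[sel])
    }
    ov / (e - s)
  }
  out <- list()
  skipped <- 0L
  for (g in unique(inst$gene_id)) {
    gi <- inst[inst$gene_id == g, ]
    full_contigs <- unique(gi$contig[gi$cover >= partial_cover])
    on_pc <- pcs$contig_a %in% full_contigs | pcs$contig_b %in% full_contigs
    if (!any(on_pc)) { skipped <- skipped + 1L; next }
    for (e_i in which(on_pc)) {
      a <- pcs$contig_a[e_i]; b <- pcs$contig_b[e_i]
      host <- if (a %in% full_contigs) a else b
      partner <- if (host == a) b else a
      if (partner %in% full_contigs) next # present on both sides: not missing
      hrow <- gi[gi$contig == host & gi$cover >= partial_cover, ][1, ]
      depth_ratio <- mean_depth(host, hrow$start, hrow$end) / mode_of[[host]]
      end_distance <- min(hrow$start, len[[host]] - hrow$end)
      pcov <- gi$cover[gi$contig == partner]
      pcov <- if (length(pcov)) max(pcov) else 0
      category <- if (is.finite(depth_ratio) && depth_ratio >= elevation_factor) {
        "COVERAGE_ELEVATED"
      } else if (end_distance <= end_margin) {
        "CONTIG_END"
      } else if (pcov > 0) {
        "FRAGMENTARY"
      } else {
        "CLEAN_LOSS"
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        gene_id = g, contig = host, partner = partner, category = category,
        depth_ratio = depth_ratio, end_distance = end_distance,
        partner_cover = pcov)
    }
  }
  if (skipped > 0) {
    rlang::inform(paste(skipped, "gene(s) not on any PC contig: skipped"))
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(gene_id = character(0), contig = character(0),
                   partner = character(0), category = character(0),
                   depth_ratio = numeric(0), end_distance = numeric(0),
                   partner_cover = numeric(0))
}
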