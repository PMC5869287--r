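#' Expression thresholding configuration
#'
#' `expressed_threshold` is the RPKM floor for calling a transcript
#' expressed (reference value 1). Highly expressed transcripts (HET) are
#' those at or above `het_multiplier` times the mean RPKM of expressed
#' transcripts; with a mean of 32 and the default 2-fold rule the HET
#' threshold is 64. The RPKM denominator is the total of reads mapped to the
#' transcript set.
#'
#' @param expressed_threshold RPKM floor for "expressed".
#' @param het_multiplier Multiplier of the mean expressed RPKM; must
#'   exceed 1.
#' @export
expression_config <- function(expressed_threshold = 1, het_multiplier = 2) {
  hd_assert(het_multiplier > 1, "het_multiplier must exceed 1")
  structure(list(expressed_threshold = expressed_threshold,
                 het_multiplier = het_multiplier),
            class = "hd_expression_config")
}

#' Highly-expressed-transcript RPKM threshold
#'
#' @param mean_expressed_rpkm Mean RPKM of expressed transcripts.
#' @param multiplier Fold multiplier (default 2).
#' @return The HET threshold in RPKM.
#' @export
het_threshold <- function(mean_expressed_rpkm, multiplier = 2) {
  multiplier * mean_expressed_rpkm
}

#' Per-isoform RPKM quantification and thresholding
#'
#' Computes `rpkm = count * 1e9 / (length * total_mapped)` per transcript
#' isoform (no consolidation by gene; `total_mapped` is the sum of the count
#' column), flags expressed transcripts, and derives the HET threshold as
#' `het_multiplier` times the mean RPKM of expressed transcripts.
#'
#' @param counts Tibble with `transcript_id`, `length`, `count` (at most one
#'   mapping per read), e.g. from [count_reads()] or
#'   [simulate_expression_counts()].
#' @param config An [expression_config()].
#' @return An `hd_expression` tibble (`transcript_id`, `length`, `count`,
#'   `rpkm`, `expressed`, `het`) with `mean_expressed_rpkm`,
#'   `het_threshold`, `n_expressed`, `n_het` attributes (see [glance()]).
#' @export
quantify_expression <- function(counts, config = expression_config()) {
  hd_assert(all(c("transcript_id", "length", "count") %in% names(counts)),
            "counts need transcript_id/length/count columns")
  hd_assert(all(counts$count >= 0), "counts must be non-negative")
  hd_assert(all(counts$length > 0), "lengths must be positive")
  total <- sum(counts$count)
  out <- tibble::as_tibble(counts)
  if (total == 0) {
    rlang::warn("zero mapped reads: all RPKM set to 0")
    out$rpkm <- 0
  } else {
    out$rpkm <- out$count * 1e9 / (out$length * total)
  }
  out$expressed <- out$rpkm >= config$expressed_threshold
  mean_expressed <- if (any(out$expressed)) mean(out$rpkm[out$expressed]) else NA_real_
  thr <- het_threshold(mean_expressed, config$het_multiplier)
  out$het <- !is.na(thr) & out$rpkm >= thr
  hd_tbl(out, "hd_expression", total_mapped = total,
         mean_expressed_rpkm = mean_expressed, het_threshold = thr,
         n_expressed = sum(out$expressed), n_het = sum(out$het),
         config = config)
}

#' Count reads per transcript by best-one mapping
#'
#' Maps single-end reads to the transcript set keeping at most one placement
#' per read, and tallies counts per transcript isoform.
#'
#' @param reads Single-end reads tibble (`id`, `read`).
#' @param transcripts Named character vector / DNAStringSet / FASTA path.
#' @param config A [mapper_config()]; the mode is forced to `best_one`.
#' @param k Index k-mer size.
#' @return Counts tibble suitable for [quantify_expression()].
#' @export
count_reads <- function(reads, transcripts, config = mapper_config(), k = 31) {
  seqs <- as_contig_seqs(transcripts)
  config$mode <- "best_one"
  config$max_placements <- 1L
  idx <- build_index(seqs, k = k)
  pl <- map_reads(reads, idx, config)
  tibble::tibble(transcript_id = names(seqs), length = nchar(seqs)) |>
    left_join(count(pl, .data$contig, name = "count"),
              by = c(transcript_id = "contig")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Gene-family presence report
#'
#' Per family verdicts: `ABSENT` when no member is expressed; `NOMINAL` when
#' the best member RPKM sits in the nominal band
#' `[expressed_threshold, 2 * expressed_threshold)` (encoding "RPKM = 1"
#' at the default threshold); `EXPRESSED` otherwise. Members missing from
#' the expression table are treated as RPKM 0 with a warning.
#'
#' @param expression An `hd_expression` table.
#' @param families Tibble mapping `family` to `transcript_id`.
#' @return Tibble: `family`, `n_members`, `n_detected`, `max_rpkm`,
#'   `verdict`.
#' @export
family_report <- function(expression, families) {
  hd_assert(all(c("family", "transcript_id") %in% names(families)),
            "families need family/transcript_id columns")
  missing <- setdiff(families$transcript_id, expression$transcript_id)
  if (length(missing)) {
    rlang::warn(paste0(length(missing),
                       " family member(s) absent from the expression table; treated as RPKM 0"))
  }
  cfg <- attr(expression, "config") %||% expression_config()
  thr <- cfg$expressed_threshold
  tibble::as_tibble(families) |>
    left_join(dplyr::select(tibble::as_tibble(expression),
                            "transcript_id", "rpkm", "expressed"),
              by = "transcript_id") |>
    mutate(rpkm = dplyr::coalesce(.data$rpkm, 0),
           expressed = dplyr::coalesce(.data$expressed, FALSE)) |>
    group_by(.data$family) |>
    summarise(n_members = dplyr::n(),
              n_detected = sum(.data$expressed),
              max_rpkm = max(.data$rpkm),
              .groups = "drop") |>
    mutate(verdict = dplyr::case_when(
      .data$n_detected == 0 ~ "ABSENT",
      .data$max_rpkm < 2 * thr ~ "NOMINAL",
      TRUE ~ "EXPRESSED"))
}
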