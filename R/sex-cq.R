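#' Chromosomal-quotient scan configuration
#'
#' CQ is the ratio of female to male alignment counts over fixed-size tiles
#' of repeat-masked sequence; tiles with CQ below `cq_threshold` are called
#' male-specific (M-locus candidates). The `min_male` denominator floor
#' guards against 0/0 and low-count artifacts; set it to 1 to reproduce a
#' floor-less scan.
#'
#' @param span_length Tile length, bp (default 1,000).
#' @param cq_threshold Male-specificity threshold on CQ (default 0.01).
#' @param min_male Minimum male alignment count for a tile to report a CQ.
#' @export
cq_config <- function(span_length = 1000, cq_threshold = 0.01, min_male = 10) {
  hd_assert(span_length > 0, "span_length must be positive")
  hd_assert(cq_threshold > 0 && cq_threshold < 1,
            "cq_threshold must lie in (0, 1)")
  structure(list(span_length = as.integer(span_length),
                 cq_threshold = cq_threshold, min_male = min_male),
            class = "hd_cq_config")
}

#' Read a BED mask
#'
#' Minimal 0-based half-open BED reader with per-line validation.
#'
#' @param path BED file.
#' @return Tibble with `contig`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  parts <- stringr::str_split(lines, "\t")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3 || is.na(suppressWarnings(as.numeric(p[2]))) ||
        is.na(suppressWarnings(as.numeric(p[3]))) ||
        as.numeric(p[2]) >= as.numeric(p[3])) {
      rlang::abort(paste0("malformed BED record at line ", i, ": ", lines[i]))
    }
  }
  tibble::tibble(contig = vapply(parts, `[`, character(1), 1),
                 start = as.numeric(vapply(parts, `[`, character(1), 2)),
                 end = as.numeric(vapply(parts, `[`, character(1), 3)))
}

#' Hard-mask contig sequences
#'
#' Replaces masked intervals with `N` so that masked bases can neither seed
#' nor match an alignment (the all-exact counting contract then ignores
#' them entirely).
#'
#' @param contigs Named character vector / DNAStringSet / FASTA path.
#' @param mask Mask tibble (`contig`, `start`, `end`; 0-based half-open) or
#'   BED path.
#' @return Named character vector of masked sequences.
#' @export
mask_sequences <- function(contigs, mask) {
  seqs <- as_contig_seqs(contigs)
  if (is.character(mask) && length(mask) == 1L) mask <- read_bed(mask)
  hd_assert(all(mask$contig %in% names(seqs)),
            "mask references unknown contigs")
  for (i in seq_len(nrow(mask))) {
    cg <- mask$contig[i]
    hd_assert(mask$start[i] >= 0 && mask$end[i] <= nchar(seqs[[cg]]),
              "mask interval outside contig bounds")
    substr(seqs[[cg]], mask$start[i] + 1, mask$end[i]) <-
      strrep("N", mask$end[i] - mask$start[i])
  }
  seqs
}

#' Tile contigs into CQ spans
#'
#' Non-overlapping tiles from position 0; a short terminal tile is kept when
#' it is at least half a tile long. Each tile's masked fraction is computed
#' from the mask; fully masked tiles are flagged up front and never report a
#' CQ.
#'
#' @param contigs Named character vector / DNAStringSet / FASTA path, or a
#'   tibble of contig lengths (`contig`, `length`).
#' @param mask Optional mask tibble or BED path (0-based half-open).
#' @param config A [cq_config()].
#' @return Tibble of tile shells: `contig`, `start`, `end`,
#'   `masked_fraction`, `fully_masked`.
#' @export
tile_spans <- function(contigs, mask = NULL, config = cq_config()) {
  lens <- if (is.data.frame(contigs)) {
    setNames(contigs$length, contigs$contig)
  } else {
    seqs <- as_contig_seqs(contigs)
    setNames(nchar(seqs), names(seqs))
  }
  if (is.character(mask) && length(mask) == 1L) mask <- read_bed(mask)
  if (!is.null(mask)) {
    hd_assert(all(mask$contig %in% names(lens)),
              "mask references unknown contigs")
    hd_assert(all(mask$start >= 0 & mask$end <= lens[mask$contig]),
              "mask interval outside contig bounds")
  }
  sl <- config$span_length
  tiles <- purrr::map(names(lens), function(cg) {
    L <- lens[[cg]]
    starts <- seq(0, max(0, L - 1), by = sl)
    ends <- pmin(starts + sl, L)
    keep <- (ends - starts) >= sl / 2
    tibble::tibble(contig = cg, start = starts[keep], end = ends[keep])
  }) |> dplyr::bind_rows()
  mf <- numeric(nrow(tiles))
  if (!is.null(mask)) {
    for (i in seq_len(nrow(tiles))) {
      sel <- mask$contig == tiles$contig[i]
      mf[i] <- interval_overlap(tiles$start[i], tiles$end[i],
                                mask$start[sel], mask$end[sel]) /
        (tiles$end[i] - tiles$start[i])
    }
  }
  tiles$masked_fraction <- mf
  tiles$fully_masked <- mf >= 1
  tiles
}

count_starts_in_tiles <- function(tiles, placements) {
  n <- integer(nrow(tiles))
  for (cg in unique(tiles$contig)) {
    ti <- which(tiles$contig == cg)
    st <- placements$start[placements$contig == cg]
    if (!length(st)) next
    # tiles are ordered from 0; assign by start coordinate, drop starts
    # falling after the end of their assigned tile (dropped terminal tail)
    idx <- findInterval(st, tiles$start[ti])
    ok <- idx >= 1 & st < tiles$end[ti][idx]
    tab <- tabulate(idx[ok], nbins = length(ti))
    n[ti] <- n[ti] + tab
  }
  n
}

#' Chromosomal-quotient scan
#'
#' Fills CQ values for tile shells from female and male alignment counts
#' (each alignment is assigned to the tile containing its start coordinate,
#' so counts are additive across tiles). A tile reports
#' `cq = female / male` when it is not fully masked and its male count meets
#' the `min_male` floor; it is male-specific iff `cq < cq_threshold`.
#'
#' @param tiles Tile shells from [tile_spans()].
#' @param female,male Single-end `hd_placements` from all-exact mapping of
#'   the female and male read sets against the (hard-masked) contigs.
#' @param config A [cq_config()].
#' @return An `hd_cq` tibble (`contig`, `start`, `end`, `masked_fraction`,
#'   `female_count`, `male_count`, `cq`, `male_specific`) with a per-contig
#'   summary (`reporting spans`, `male_specific_fraction`) in the `summary`
#'   attribute.
#' @export
cq_scan <- function(tiles, female, male, config = cq_config()) {
  out <- tibble::as_tibble(tiles)
  out$female_count <- count_starts_in_tiles(out, female)
  out$male_count <- count_starts_in_tiles(out, male)
  reporting <- !out$fully_masked & out$male_count >= config$min_male
  out$cq <- ifelse(reporting, out$female_count / out$male_count, NA_real_)
  out$male_specific <- !is.na(out$cq) & out$cq < config$cq_threshold
  summary <- out |>
    group_by(.data$contig) |>
    summarise(n_spans = dplyr::n(),
              reporting_spans = sum(!is.na(.data$cq)),
              male_specific_spans = sum(.data$male_specific),
              male_specific_fraction =
                ifelse(.data$reporting_spans > 0,
                       .data$male_specific_spans / .data$reporting_spans, NA_real_),
              .groups = "drop")
  hd_tbl(out, "hd_cq", summary = summary, config = config)
}

#' One-call chromosomal-quotient analysis
#'
#' Hard-masks the contigs, builds an exact index, maps both sexed read sets
#' under the all-exact contract, tiles, and scans.
#'
#' @param contigs Contig sequences.
#' @param female_reads,male_reads Single-end read tibbles (`id`, `read`).
#' @param mask Optional mask (tibble or BED path).
#' @param config A [cq_config()].
#' @param k Index k-mer size.
#' @return An `hd_cq` tibble (see [cq_scan()]).
#' @export
cq_analysis <- function(contigs, female_reads, male_reads, mask = NULL,
                        config = cq_config(), k = 31) {
  seqs <- if (is.null(mask)) as_contig_seqs(contigs) else
    mask_sequences(contigs, mask)
  idx <- build_index(seqs, k = k)
  mc <- mapper_config("all_exact", max_mismatches = 0)
  fem <- map_reads(female_reads, idx, mc)
  mal <- map_reads(male_reads, idx, mc)
  cq_scan(tile_spans(seqs, mask, config), fem, mal, config)
}
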