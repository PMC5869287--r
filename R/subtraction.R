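#' Cascade host-read subtraction
#'
#' Two-stage host filter for single-end read sets: stage 1 removes reads
#' with at least one end-to-end placement on the host transcript set, stage
#' 2 maps the survivors to the host genome contigs and removes placed reads.
#' The survivors are the candidate non-host (e.g. viral) reads; the
#' remaining fraction is also the estimated downstream workload relative to
#' characterising every read. Removal stringency defaults to at most two
#' substitutions per read.
#'
#' @param reads Single-end reads tibble (`id`, `read`) or FASTQ path.
#' @param transcripts Host transcript sequences (named character /
#'   DNAStringSet / FASTA path).
#' @param genome Host genome contigs (same forms).
#' @param config A [mapper_config()]; defaults to best-one with
#'   `max_mismatches = 2`.
#' @param k Index k-mer size.
#' @return An `hd_subtraction` list: `retained` (reads tibble) and `report`
#'   (one-row tibble with exact counts and fractions per stage; fractions
#'   sum to 1 by construction).
#' @export
cascade_filter <- function(reads, transcripts, genome,
                           config = mapper_config(max_mismatches = 2),
                           k = 31) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  hd_assert(all(c("id", "read") %in% names(reads)),
            "reads must be single-end (id/read columns)")
  t_seqs <- as_contig_seqs(transcripts)
  g_seqs <- as_contig_seqs(genome)
  hd_assert(length(t_seqs) > 0 && length(g_seqs) > 0, "empty reference")
  config$mode <- "best_one"
  config$max_placements <- 1L
  total <- nrow(reads)
  s1 <- map_reads(reads, build_index(t_seqs, k = k), config)
  removed1 <- unique(s1$read_id)
  survivors <- reads[!reads$id %in% removed1, ]
  s2 <- map_reads(survivors, build_index(g_seqs, k = k), config)
  removed2 <- unique(s2$read_id)
  retained <- survivors[!survivors$id %in% removed2, ]
  report <- tibble::tibble(
    total_reads = total,
    removed_stage1 = length(removed1),
    removed_stage2 = length(removed2),
    remaining = nrow(retained),
    removed_stage1_fraction = length(removed1) / total,
    removed_stage2_fraction = length(removed2) / total,
    remaining_fraction = nrow(retained) / total,
    workload_estimate = nrow(retained) / total)
  structure(list(retained = retained, report = report),
            class = "hd_subtraction")
}

#' @export
print.hd_subtraction <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<hd_subtraction> %d reads: %.1f%% removed by transcripts, ",
                     "%.1f%% by genome, %.1f%% remaining\n"),
              r$total_reads, 100 * r$removed_stage1_fraction,
              100 * r$removed_stage2_fraction, 100 * r$remaining_fraction))
  invisible(x)
}

#' Ingest taxon assignments for retained reads
#'
#' Consumes a BLAST tabular hit table (standard 12-column `-outfmt 6`, or a
#' 4-column `query, taxon, bitscore, evalue` table) for the retained reads,
#' keeps a single best hit per query (highest bitscore; ties broken by
#' lowest e-value, then lexicographic subject), and tallies reads per taxon.
#'
#' @param hits Hit table path or tibble.
#' @param retained Retained reads tibble (`id` column) from
#'   [cascade_filter()].
#' @return List: `taxa` (tibble `taxon`, `reads`), `assignments` (per-query
#'   best hits), `unassigned` (count), `unassigned_fraction`.
#' @export
ingest_taxon_hits <- function(hits, retained) {
  if (is.character(hits) && length(hits) == 1L) {
    lines <- readLines(hits)
    lines <- lines[nzchar(lines)]
    parts <- stringr::str_split(lines, "\t")
    nf <- lengths(parts)
    bad <- which(!nf %in% c(4L, 12L))
    hd_assert(length(bad) == 0,
              paste0("malformed hit-table row at line ", bad[1], ": ",
                     if (length(bad)) lines[bad[1]] else ""))
    hits <- if (all(nf == 12L)) {
      tibble::tibble(query = vapply(parts, `[`, character(1), 1),
                     taxon = vapply(parts, `[`, character(1), 2),
                     evalue = as.numeric(vapply(parts, `[`, character(1), 11)),
                     bitscore = as.numeric(vapply(parts, `[`, character(1), 12)))
    } else {
      tibble::tibble(query = vapply(parts, `[`, character(1), 1),
                     taxon = vapply(parts, `[`, character(1), 2),
                     bitscore = as.numeric(vapply(parts, `[`, character(1), 3)),
                     evalue = as.numeric(vapply(parts, `[`, character(1), 4)))
    }
    hd_assert(!anyNA(hits$bitscore) && !anyNA(hits$evalue),
              "malformed numeric fields in hit table")
  }
  hd_assert(all(c("query", "taxon", "bitscore", "evalue") %in% names(hits)),
            "hits need query/taxon/bitscore/evalue columns")
  best <- tibble::as_tibble(hits) |>
    filter(.data$query %in% retained$id) |>
    arrange(.data$query, desc(.data$bitscore), .data$evalue, .data$taxon) |>
    distinct(.data$query, .keep_all = TRUE)
  taxa <- best |> count(.data$taxon, name = "reads") |> arrange(desc(.data$reads))
  unassigned <- sum(!retained$id %in% best$query)
  list(taxa = taxa, assignments = best, unassigned = unassigned,
       unassigned_fraction = unassigned / nrow(retained))
}
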