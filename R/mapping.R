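#' Mapper configuration
#'
#' Three reporting contracts are supported. `"best_one"` keeps a single
#' minimum-mismatch concordant placement per query with seeded random
#' tie-breaking (the default contract of end-to-end short-read aligners).
#' `"best_k"` keeps up to `max_placements` best placements after a
#' deterministic sort plus a seeded shuffle of equal-mismatch ties — the
#' "best 4" contract used to find doubly-mapping pairs. `"all_exact"` reports
#' every zero-mismatch alignment (the `-a -v 0` contract used for
#' chromosomal-quotient counting); it forces `max_mismatches = 0`.
#'
#' @param mode One of `"best_one"`, `"best_k"`, `"all_exact"`.
#' @param max_placements Placement cap for `"best_k"` (preset 4).
#' @param max_mismatches Per-mate mismatch cap (substitutions only).
#' @param fragment_bounds Concordant fragment length range, bp.
#' @param seed Integer seed driving tie-break randomness.
#' @export
mapper_config <- function(mode = c("best_one", "best_k", "all_exact"),
                          max_placements = NULL,
                          max_mismatches = 8,
                          fragment_bounds = c(100, 600),
                          seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(max_placements)) {
    max_placements <- switch(mode, best_one = 1L, best_k = 4L,
                             all_exact = .Machine$integer.max)
  }
  hd_assert(max_placements >= 1, "max_placements must be >= 1")
  if (mode == "all_exact") {
    hd_assert(max_mismatches == 0 || missing(max_mismatches),
              "all_exact requires max_mismatches = 0")
    max_mismatches <- 0L
  }
  hd_assert(length(fragment_bounds) == 2 && fragment_bounds[1] <= fragment_bounds[2],
            "fragment_bounds must be an increasing length-2 range")
  structure(list(mode = mode, max_placements = as.integer(max_placements),
                 max_mismatches = as.integer(max_mismatches),
                 fragment_bounds = fragment_bounds, seed = as.integer(seed)),
            class = "hd_mapper_config")
}

#' Build an exact k-mer index over a contig set
#'
#' Indexes every k-mer location on the forward strand of each contig (both
#' strands are searched at query time by also looking up the query's reverse
#' complement). K-mers containing non-ACGT characters — e.g. hard-masked
#' spans — are skipped, so masked sequence can never seed an alignment.
#'
#' @param contigs Named character vector, `DNAStringSet`, or FASTA path.
#' @param k K-mer size (2–31); must not exceed the shortest read to be
#'   mapped.
#' @return An `hd_index` object.
#' @export
build_index <- function(contigs, k = 31) {
  seqs <- as_contig_seqs(contigs)
  structure(list(ptr = hd_cpp_index_build(unname(seqs), as.integer(k)),
                 k = as.integer(k),
                 contigs = contig_length_tbl(seqs),
                 seqs = seqs),
            class = "hd_index")
}

#' @export
print.hd_index <- function(x, ...) {
  st <- hd_cpp_index_stats(x$ptr)
  cat("<hd_index> k=", x$k, ", ", st$n_contigs, " contigs, ",
      format(st$n_kmers, big.mark = ","), " k-mer positions\n", sep = "")
  invisible(x)
}

#' Look up a k-mer in an index
#'
#' @param index An `hd_index`.
#' @param kmer A k-length query string; its reverse complement is reported on
#'   the `-` strand.
#' @return Tibble with `contig`, `pos` (0-based forward-strand position) and
#'   `strand`.
#' @export
index_lookup <- function(index, kmer) {
  df <- hd_cpp_index_lookup(index$ptr, kmer)
  tibble::tibble(contig = index$contigs$contig[df$contig],
                 pos = df$pos, strand = df$strand)
}

reads_as_pairs <- function(reads) {
  hd_assert(is.data.frame(reads) && all(c("read1", "read2") %in% names(reads)),
            "paired mapping needs a tibble with read1/read2 columns")
  hd_assert(all(nchar(reads$read1) == nchar(reads$read1[1])) &&
              all(nchar(reads$read2) == nchar(reads$read2[1])),
            "mate length mismatch: all mates must share one read length")
  reads
}

#' Map read pairs against an index
#'
#' Candidate placements come from exact seed k-mers at fixed offsets along
#' each mate and are verified end to end with at most
#' `config$max_mismatches` substitutions per mate. Only concordant pair
#' placements are reported: both mates on one contig, FR orientation, and a
#' fragment length within `config$fragment_bounds`. Pairs with no concordant
#' placement are unmapped (absent from the table; the query count is kept in
#' the `n_query` attribute).
#'
#' @param reads A paired reads tibble (`id`, `read1`, `read2`), e.g. from
#'   [simulate_reads()] or [read_fastq()].
#' @param index An `hd_index` from [build_index()].
#' @param config A [mapper_config()].
#' @return An `hd_placements` tibble: `pair_id`, `contig`, `start1`, `end1`,
#'   `start2`, `end2`, `strand1`, `orientation` (always `"FR"`),
#'   `mismatches` (pair total), 0-based half-open coordinates. Attributes:
#'   `mode`, `paired`, `n_query`, `contigs`.
#' @export
map_pairs <- function(reads, index, config = mapper_config()) {
  reads <- reads_as_pairs(reads)
  hd_assert(inherits(index, "hd_index"), "index must come from build_index()")
  mode_code <- switch(config$mode, best_one = 1L, best_k = 2L, all_exact = 2L)
  df <- withr::with_seed(config$seed,
    hd_cpp_map_pairs(index$ptr, reads$read1, reads$read2,
                     config$max_mismatches,
                     config$fragment_bounds[1], config$fragment_bounds[2],
                     mode_code, config$max_placements))
  out <- tibble::tibble(pair_id = reads$id[df$pair],
                        contig = index$contigs$contig[df$contig],
                        start1 = df$start1, end1 = df$end1,
                        start2 = df$start2, end2 = df$end2,
                        strand1 = df$strand1, orientation = "FR",
                        mismatches = df$mismatches)
  hd_tbl(out, "hd_placements", mode = config$mode, paired = TRUE,
         n_query = nrow(reads), contigs = index$contigs, config = config)
}

#' Map single-end reads against an index
#'
#' Single-end variant of [map_pairs()], used for RNA quantification,
#' host subtraction, and all-exact chromosomal-quotient counting.
#'
#' @inheritParams map_pairs
#' @param reads A tibble with `id` and `read` columns.
#' @return An `hd_placements` tibble: `read_id`, `contig`, `start`, `end`,
#'   `strand`, `mismatches`.
#' @export
map_reads <- function(reads, index, config = mapper_config()) {
  hd_assert(is.data.frame(reads) && all(c("id", "read") %in% names(reads)),
            "single-end mapping needs a tibble with id/read columns")
  hd_assert(inherits(index, "hd_index"), "index must come from build_index()")
  mode_code <- if (config$mode == "best_one") 1L else 0L
  df <- withr::with_seed(config$seed,
    hd_cpp_map_single(index$ptr, reads$read, config$max_mismatches,
                      config$max_placements, mode_code))
  out <- tibble::tibble(read_id = reads$id[df$read],
                        contig = index$contigs$contig[df$contig],
                        start = df$start, end = df$start + nchar(reads$read[df$read]),
                        strand = df$strand, mismatches = df$mismatches)
  hd_tbl(out, "hd_placements", mode = config$mode, paired = FALSE,
         n_query = nrow(reads), contigs = index$contigs, config = config)
}
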