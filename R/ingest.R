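# Alignment interchange: SAM/BAM/PAF ingest and minimal SAM export.

cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_real_)
    m <- gregexpr("([0-9]+)([MIDNSHP=X])", cg)[[1]]
    toks <- regmatches(cg, m)[[1]]
    lens <- as.numeric(sub("[MIDNSHP=X]$", "", toks))
    ops <- sub("^[0-9]+", "", toks)
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Ingest external alignments into a placement table
#'
#' Reconstructs the internal placement table from standard alignment formats,
#' normalising all coordinates to 0-based half-open. SAM/BAM records are
#' grouped by query name in memory (any record order is accepted);
#' supplementary alignments are dropped and secondary alignments count as
#' additional placements. Paired records are matched first-in-pair to
#' second-in-pair per query name in file order. PAF ingestion yields
#' single-end placements only (PAF is already 0-based).
#'
#' @param path Alignment file.
#' @param dialect `"sam"`, `"bam"` or `"paf"`.
#' @param mode Reporting contract the file was produced under (stored as the
#'   table's `mode` attribute; default `"best_k"` so multi-placement tables
#'   are usable for paired-contig detection).
#' @return An `hd_placements` tibble (paired or single-end).
#' @export
ingest_alignments <- function(path, dialect = c("sam", "bam", "paf"),
                              mode = "best_k") {
  dialect <- match.arg(dialect)
  if (dialect == "paf") return(ingest_paf(path, mode))
  bam <- if (dialect == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    path
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  contigs <- tibble::tibble(contig = names(hdr), length = unname(as.numeric(hdr)))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "NM")
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  nm <- rec$tag$NM %||% rep(NA_integer_, length(rec$qname))
  df <- tibble::tibble(qname = rec$qname, flag = rec$flag,
                       contig = as.character(rec$rname),
                       start = rec$pos - 1,
                       width = cigar_ref_width(rec$cigar),
                       nm = as.numeric(nm))
  n_query <- dplyr::n_distinct(df$qname)
  # drop unmapped and supplementary records; secondaries stay
  df <- df[bitwAnd(df$flag, 4L) == 0L & bitwAnd(df$flag, 2048L) == 0L, ]
  df$strand <- ifelse(bitwAnd(df$flag, 16L) > 0L, "-", "+")
  paired <- any(bitwAnd(df$flag, 1L) > 0L)
  if (!paired) {
    out <- tibble::tibble(read_id = df$qname, contig = df$contig,
                          start = df$start, end = df$start + df$width,
                          strand = df$strand, mismatches = df$nm)
    return(hd_tbl(out, "hd_placements", mode = mode, paired = FALSE,
                  n_query = n_query, contigs = contigs))
  }
  df$mate <- ifelse(bitwAnd(df$flag, 64L) > 0L, 1L, 2L)
  df <- df |>
    group_by(.data$qname, .data$mate) |>
    mutate(k = row_number()) |>
    ungroup()
  m1 <- df[df$mate == 1L, ]
  m2 <- df[df$mate == 2L, ]
  j <- inner_join(m1, m2, by = c("qname", "k"), suffix = c("1", "2"))
  orientation <- dplyr::case_when(
    j$strand1 == j$strand2 ~ "FF",
    (j$strand1 == "+" & j$start1 <= j$start2) |
      (j$strand2 == "+" & j$start2 <= j$start1) ~ "FR",
    TRUE ~ "RF")
  out <- tibble::tibble(pair_id = j$qname, contig = j$contig1,
                        start1 = j$start1, end1 = j$start1 + j$width1,
                        start2 = j$start2, end2 = j$start2 + j$width2,
                        strand1 = j$strand1, orientation = orientation,
                        mismatches = j$nm1 + j$nm2)
  hd_tbl(out, "hd_placements", mode = mode, paired = TRUE,
         n_query = n_query, contigs = contigs)
}

ingest_paf <- function(path, mode) {
  cols <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "matches", "alnlen", "mapq")
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        col_select = 1:12)
  names(df) <- cols
  contigs <- df |>
    distinct(.data$tname, .data$tlen) |>
    rename(contig = "tname", length = "tlen")
  out <- tibble::tibble(read_id = df$qname, contig = df$tname,
                        start = df$tstart, end = df$tend,
                        strand = df$strand,
                        mismatches = df$alnlen - df$matches)
  hd_tbl(out, "hd_placements", mode = mode, paired = FALSE,
         n_query = dplyr::n_distinct(df$qname), contigs = contigs)
}

#' Write a placement table as SAM
#'
#' Emits minimal valid SAM (no sequence or quality fields) sufficient for
#' lossless round-tripping of a placement table: one record per mate with
#' `<len>M` CIGAR, proper pair flags, secondary flags on placements beyond
#' the first per pair, and the pair's mismatch total as an `NM` tag on the
#' first mate.
#'
#' @param placements An `hd_placements` tibble.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(placements, path) {
  contigs <- attr(placements, "contigs")
  hd_assert(!is.null(contigs), "placements lack a contigs attribute")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig, as.integer(contigs$length)))
  if (isTRUE(attr(placements, "paired"))) {
    p <- placements |> group_by(.data$pair_id) |> mutate(k = row_number()) |> ungroup()
    sec <- ifelse(p$k > 1L, 256L, 0L)
    f1 <- 1L + 2L + 64L + ifelse(p$strand1 == "-", 16L, 32L) + sec
    f2 <- 1L + 2L + 128L + ifelse(p$strand1 == "-", 32L, 16L) + sec
    tlen <- pmax(p$end1, p$end2) - pmin(p$start1, p$start2)
    r1 <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*\tNM:i:%d",
                  p$pair_id, f1, p$contig, as.integer(p$start1) + 1L,
                  as.integer(p$end1 - p$start1), as.integer(p$start2) + 1L,
                  as.integer(ifelse(p$start1 <= p$start2, tlen, -tlen)),
                  as.integer(p$mismatches))
    r2 <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*\tNM:i:0",
                  p$pair_id, f2, p$contig, as.integer(p$start2) + 1L,
                  as.integer(p$end2 - p$start2), as.integer(p$start1) + 1L,
                  as.integer(ifelse(p$start1 <= p$start2, -tlen, tlen)))
    rec <- as.vector(rbind(r1, r2))
  } else {
    p <- placements |> group_by(.data$read_id) |> mutate(k = row_number()) |> ungroup()
    f <- ifelse(p$strand == "-", 16L, 0L) + ifelse(p$k > 1L, 256L, 0L)
    rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                   p$read_id, f, p$contig, as.integer(p$start) + 1L,
                   as.integer(p$end - p$start), as.integer(p$mismatches))
  }
  writeLines(c(hdr, rec), path)
  invisible(path)
}
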