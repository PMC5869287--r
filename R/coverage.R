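#' Per-contig depth histogram
#'
#' Counts bases at each read depth per contig. Depth is a per-base pileup over
#' the aligned mate spans of concordant best-one placements (fragment gaps
#' between mates are not counted). Every contig base is accounted for, so
#' each contig's histogram sums to its span.
#'
#' @param placements An `hd_placements` table produced under the `best_one`
#'   contract ([map_pairs()] or [ingest_alignments()]).
#' @return An `hd_coverage` tibble with columns `contig`, `depth`, `bases`.
#' @export
depth_histogram <- function(placements) {
  hd_assert(inherits(placements, "hd_placements"),
            "placements must be an hd_placements table")
  hd_assert(!identical(attr(placements, "mode"), "best_k"),
            "depth histograms require best-one placements (one placement per pair)")
  contigs <- attr(placements, "contigs")
  hd_assert(!is.null(contigs), "placements lack contig lengths")
  paired <- isTRUE(attr(placements, "paired"))
  if (paired) {
    spans <- tibble::tibble(
      contig = rep(placements$contig, 2L),
      start = c(placements$start1, placements$start2),
      end = c(placements$end1, placements$end2))
  } else {
    spans <- tibble::tibble(contig = placements$contig,
                            start = placements$start, end = placements$end)
  }
  len <- setNames(contigs$length, contigs$contig)
  bad <- spans$start < 0 | spans$end > len[spans$contig]
  hd_assert(!any(bad), "placement beyond contig bounds")
  out <- lapply(contigs$contig, function(cg) {
    sel <- spans$contig == cg
    ir <- IRanges::IRanges(start = spans$start[sel] + 1L, end = spans$end[sel])
    cv <- IRanges::coverage(ir, width = len[[cg]])
    tibble::tibble(contig = cg,
                   depth = S4Vectors::runValue(cv),
                   bases = S4Vectors::runLength(cv)) |>
      group_by(.data$contig, .data$depth) |>
      summarise(bases = sum(.data$bases), .groups = "drop")
  })
  hd_tbl(dplyr::bind_rows(out), "hd_coverage", contigs = contigs)
}

# Window sum of bases at depths [max(3, d-1), d+1] for one contig histogram.
# Tied windows prefer the centre holding the most bases at the centre depth
# itself, then the smallest centre (so a uniform-depth contig reports its
# depth, not the window one below it).
mode_from_histogram <- function(depth, bases) {
  usable <- depth >= 3 & bases > 0
  if (!any(usable)) return(NA_integer_)
  dmax <- max(depth[usable])
  centers <- 4:max(4, dmax)
  win <- vapply(centers, function(d) {
    sum(bases[depth >= max(3, d - 1) & depth <= d + 1])
  }, numeric(1))
  cand <- centers[win == max(win)]
  if (length(cand) > 1L) {
    at <- vapply(cand, function(d) sum(bases[depth == d]), numeric(1))
    cand <- cand[at == max(at)]
  }
  min(cand)
}

#' Windowed mode coverage
#'
#' The per-contig depth statistic: the centre of the 3-wide depth window with
#' the most bases, sliding from the minimum window 3x–5x upward (so the
#' lowest reportable mode is 4x). Bases below 3x depth are never counted;
#' contigs with no bases at 3x or more have an undefined mode (`NA`). Tied
#' windows resolve to the centre holding the most bases at the centre depth
#' itself, then to the smallest centre — so a uniformly covered contig
#' reports its own depth.
#'
#' @param profile An `hd_coverage` histogram from [depth_histogram()], or any
#'   tibble with `contig`, `depth`, `bases` columns.
#' @return Tibble with `contig`, `span`, `mode`.
#' @export
mode_coverage <- function(profile) {
  hd_assert(all(c("contig", "depth", "bases") %in% names(profile)),
            "profile needs contig/depth/bases columns")
  hd_assert(nrow(profile) > 0, "empty histogram")
  profile |>
    group_by(.data$contig) |>
    summarise(span = sum(.data$bases),
              mode = mode_from_histogram(.data$depth, .data$bases),
              .groups = "drop")
}

#' Coverage class windows
#'
#' Defines the haplotype-separated and allele-collapsed mode-coverage
#' windows. With the reference defaults (centre 18, halfwidth 6) the
#' SEPARATED window is the closed interval \[12, 24\] and the COLLAPSED
#' window \[30, 42\]; anything else (including undefined modes) is OTHER.
#' `"auto"` estimation sets the centre to the span-weighted modal mode over
#' contigs and the halfwidth to `round(centre / 3)`.
#'
#' @param center Primary (haplotig) mode centre, fold coverage.
#' @param halfwidth Window halfwidth, fold coverage; must satisfy
#'   `halfwidth < center / 2` so the two windows cannot overlap.
#' @param estimation `"fixed"` or `"auto"`.
#' @export
coverage_classes <- function(center = 18, halfwidth = 6,
                             estimation = c("fixed", "auto")) {
  estimation <- match.arg(estimation)
  hd_assert(halfwidth < center, "halfwidth must be smaller than center")
  if (halfwidth >= center / 2) {
    rlang::warn("halfwidth >= center/2: class windows overlap; SEPARATED takes precedence")
  }
  structure(list(center = center, halfwidth = halfwidth,
                 estimation = estimation),
            class = "hd_coverage_classes")
}

#' Classify contigs by mode coverage
#'
#' Assigns each contig to SEPARATED (mode within `center +- halfwidth`),
#' COLLAPSED (within `2*center +- halfwidth`) or OTHER, and computes the
#' separated span fraction `h` = (bases on SEPARATED contigs) / (bases on
#' contigs with a defined mode). Window bounds are closed; membership is
#' tested SEPARATED before COLLAPSED.
#'
#' @param profile An `hd_coverage` histogram, or a tibble with `contig`,
#'   `span`, `mode` columns (e.g. from [mode_coverage()]).
#' @param classes A [coverage_classes()].
#' @return An `hd_classes` tibble (`contig`, `span`, `mode`, `class`) with
#'   attributes `center`, `halfwidth`, `h`, `assembly_span`.
#' @export
classify_contigs <- function(profile, classes = coverage_classes()) {
  modes <- if (all(c("span", "mode") %in% names(profile))) {
    tibble::as_tibble(profile)
  } else {
    mode_coverage(profile)
  }
  c0 <- classes$center
  w <- classes$halfwidth
  if (classes$estimation == "auto") {
    hd_assert(nrow(modes) >= 2, "auto class estimation needs at least 2 contigs")
    wt <- modes |>
      filter(!is.na(.data$mode)) |>
      group_by(.data$mode) |>
      summarise(span = sum(.data$span), .groups = "drop") |>
      arrange(desc(.data$span), .data$mode)
    c0 <- wt$mode[1]
    w <- round(c0 / 3)
  }
  cls <- dplyr::case_when(
    is.na(modes$mode) ~ "OTHER",
    modes$mode >= c0 - w & modes$mode <= c0 + w ~ "SEPARATED",
    modes$mode >= 2 * c0 - w & modes$mode <= 2 * c0 + w ~ "COLLAPSED",
    TRUE ~ "OTHER")
  out <- modes
  out$class <- cls
  defined <- !is.na(out$mode)
  h <- sum(out$span[cls == "SEPARATED"]) / sum(out$span[defined])
  hd_tbl(out, "hd_classes", center = c0, halfwidth = w, h = h,
         assembly_span = sum(out$span))
}

#' Genome size under the haplotype-separation model
#'
#' If a fraction `h` of assembled bases sits in haplotype-separated contigs
#' (each such base present twice, once per haplotype) and the rest is a
#' collapsed single-copy consensus, the haploid genome size is
#' `S * (h/2 + (1 - h))`. With the reference value `h = 0.9582` the haploid
#' fraction is 0.5209, i.e. the genome is 52% of the assembly span.
#'
#' @param S Assembly span in bp, or an `hd_classes` object (in which case
#'   `h` is taken from it).
#' @param h Fraction of assembled bases in the SEPARATED class.
#' @return A one-row `hd_genome_size` tibble: `assembly_span`,
#'   `separated_fraction`, `haploid_fraction`, `genome_size`.
#' @export
estimate_genome_size <- function(S, h = NULL) {
  if (inherits(S, "hd_classes")) {
    h <- h %||% attr(S, "h")
    S <- attr(S, "assembly_span")
  }
  hd_assert(h >= 0 && h <= 1, "h must lie in [0, 1]")
  hf <- h / 2 + (1 - h)
  hd_tbl(tibble::tibble(assembly_span = S, separated_fraction = h,
                        haploid_fraction = hf, genome_size = S * hf),
         "hd_genome_size")
}

#' Assembly span statistics
#'
#' N50 is the length of the shortest contig in the smallest set of longest
#' contigs spanning at least half the assembly; NG50 uses a supplied genome
#' size G as the total instead, and is undefined (NA) when `G > 2 * span`.
#'
#' @param lengths Positive contig lengths (or an `hd_classes` object, whose
#'   `span` column is used).
#' @param genome_size Optional putative genome size G for NG50.
#' @return One-row tibble: `n_contigs`, `span`, `n50`, `ng50`.
#' @export
assembly_stats <- function(lengths, genome_size = NULL) {
  if (inherits(lengths, "hd_classes")) lengths <- lengths$span
  hd_assert(length(lengths) > 0, "empty contig set")
  hd_assert(all(lengths > 0), "contig lengths must be positive")
  sl <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(sl)
  n50 <- sl[which(cs >= sum(sl) / 2)[1]]
  ng50 <- NA_real_
  if (!is.null(genome_size)) {
    if (genome_size <= 2 * sum(sl) && any(cs >= genome_size / 2)) {
      ng50 <- sl[which(cs >= genome_size / 2)[1]]
    } else {
      rlang::warn("NG50 undefined: G exceeds twice the assembly span")
    }
  }
  tibble::tibble(n_contigs = length(lengths), span = sum(lengths),
                 n50 = n50, ng50 = ng50)
}
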