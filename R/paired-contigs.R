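#' Paired-contig detection configuration
#'
#' Exactly one of `min_shared_pairs` (absolute threshold; fidelity default
#' 10,000 read pairs) or `density_threshold` (pairs per kb of the smaller
#' contig; default option for genomes far below Gbp scale) is active:
#' supplying `density_threshold` deactivates the absolute threshold.
#'
#' @param min_shared_pairs Absolute doubly-mapped pair threshold.
#' @param density_threshold Pairs per kb of the smaller contig of a pair.
#' @param anchor_k K-mer size of the intra-pair anchor alignment.
#' @param max_anchor_gap Maximum gap (bp) bridged between chained anchors.
#' @param min_extension Minimum extension (bp) beyond the partner alignment
#'   for an edge to count as TILING in walk construction.
#' @export
pc_config <- function(min_shared_pairs = 10000,
                      density_threshold = NULL,
                      anchor_k = 21,
                      max_anchor_gap = 500,
                      min_extension = 1000) {
  hd_assert(is.null(density_threshold) || density_threshold > 0,
            "density_threshold must be positive")
  hd_assert(min_shared_pairs >= 1, "min_shared_pairs must be >= 1")
  structure(list(min_shared_pairs = min_shared_pairs,
                 density_threshold = density_threshold,
                 anchor_k = as.integer(anchor_k),
                 max_anchor_gap = max_anchor_gap,
                 min_extension = min_extension),
            class = "hd_pc_config")
}

#' Doubly-mapped pair counts per contig pair
#'
#' A read pair contributes to a contig pair's shared count iff it has exactly
#' two concordant placements and they lie on two distinct contigs. Pairs with
#' two placements on a single contig are tallied separately
#' (`intra_contig_doubles` attribute) and never feed paired-contig counts.
#' The fraction of placed pairs mapping exactly twice — the quantity that was
#' about 15% on the reference assembly — is kept in the
#' `fraction_exactly_two` attribute, and the full placement-multiplicity
#' tally in `multiplicity`.
#'
#' @param placements An `hd_placements` table produced under the `best_k`
#'   contract (the "best 4" mapping); a `best_one` table is rejected since a
#'   single placement per pair cannot reveal double mapping.
#' @return An `hd_pair_counts` tibble: `contig_a`, `contig_b` (lexicographic
#'   order), `shared_pairs`.
#' @export
doubly_mapped <- function(placements) {
  hd_assert(inherits(placements, "hd_placements") &&
              isTRUE(attr(placements, "paired")),
            "doubly_mapped() needs paired placements")
  hd_assert(!identical(attr(placements, "mode"), "best_one"),
            "placements were produced under best_one: insufficient multiplicity for paired-contig detection")
  mult <- placements |> count(.data$pair_id, name = "n_placements")
  two <- mult$pair_id[mult$n_placements == 2L]
  sub <- placements[placements$pair_id %in% two, ]
  per_pair <- sub |>
    group_by(.data$pair_id) |>
    summarise(contig_a = min(.data$contig), contig_b = max(.data$contig),
              .groups = "drop")
  intra <- sum(per_pair$contig_a == per_pair$contig_b)
  cross <- per_pair |>
    filter(.data$contig_a != .data$contig_b) |>
    count(.data$contig_a, .data$contig_b, name = "shared_pairs") |>
    arrange(desc(.data$shared_pairs))
  hd_tbl(cross, "hd_pair_counts",
         contigs = attr(placements, "contigs"),
         n_placed = nrow(mult),
         fraction_exactly_two = length(two) / nrow(mult),
         intra_contig_doubles = intra,
         multiplicity = count(mult, .data$n_placements, name = "pairs"))
}

#' Detect paired contigs
#'
#' Keeps contig pairs whose doubly-mapped shared count meets the configured
#' threshold — absolute (`min_shared_pairs`, boundary inclusive) or scaled
#' (`density_threshold` pairs per kb of the smaller contig).
#'
#' @param counts An `hd_pair_counts` table from [doubly_mapped()].
#' @param config A [pc_config()].
#' @return An `hd_pcs` tibble (`contig_a`, `contig_b`, `shared_pairs`,
#'   `threshold`) with a per-contig PC-membership tibble in the `membership`
#'   attribute.
#' @export
detect_pcs <- function(counts, config = pc_config()) {
  contigs <- attr(counts, "contigs")
  if (!is.null(config$density_threshold)) {
    hd_assert(!is.null(contigs), "density threshold needs contig lengths")
    len <- setNames(contigs$length, contigs$contig)
    thr <- config$density_threshold *
      pmin(len[counts$contig_a], len[counts$contig_b]) / 1000
  } else {
    thr <- rep(config$min_shared_pairs, nrow(counts))
  }
  pcs <- counts
  pcs$threshold <- as.numeric(thr)
  pcs <- pcs |> filter(.data$shared_pairs >= .data$threshold)
  membership <- tibble::tibble(contig = c(pcs$contig_a, pcs$contig_b)) |>
    count(.data$contig, name = "n_pcs")
  hd_tbl(pcs, "hd_pcs", contigs = contigs, membership = membership,
         config = config)
}

#' Share of assembly span incorporated in paired contigs
#'
#' @param pcs An `hd_pcs` table (or any tibble with `contig_a`/`contig_b`).
#' @param contigs Tibble of all contigs with `contig` and `length` columns;
#'   defaults to the lengths carried by `pcs`.
#' @return One-row tibble: `pc_span`, `assembly_span`, `fraction`, `percent`
#'   (percent rounded to the nearest integer).
#' @export
pc_span_summary <- function(pcs, contigs = NULL) {
  contigs <- contigs %||% attr(pcs, "contigs")
  hd_assert(!is.null(contigs), "contig lengths required")
  members <- unique(c(pcs$contig_a, pcs$contig_b))
  pc_span <- sum(contigs$length[contigs$contig %in% members])
  total <- sum(contigs$length)
  tibble::tibble(pc_span = pc_span, assembly_span = total,
                 fraction = pc_span / total,
                 percent = round(100 * pc_span / total))
}

# Longest strictly-increasing subsequence (indices) of y, O(n log n).
lis_indices <- function(y) {
  n <- length(y)
  if (n == 0L) return(integer(0))
  tails <- numeric(0)      # smallest tail value per LIS length
  tails_idx <- integer(0)  # index of that tail
  parent <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(y[i] - 0.5, tails) + 1L # first tail >= y[i]
    parent[i] <- if (j > 1L) tails_idx[j - 1L] else 0L
    tails[j] <- y[i]
    tails_idx[j] <- i
    length(tails) <- j_max <- max(length(tails), j)
  }
  # backtrack from the last tail
  out <- integer(0)
  i <- tails_idx[length(tails_idx)]
  while (i > 0L) {
    out <- c(i, out)
    i <- parent[i]
  }
  out
}

#' Anchor-based alignment of a contig pair
#'
#' Estimates intra-pair similarity without full dynamic programming: k-mers
#' unique within each contig and shared between the two serve as anchors; the
#' longest colinear anchor chain (per strand) is extended gap-free between
#' consecutive anchors when both contigs advance by the same distance (at
#' most `max_anchor_gap`), with mismatches counted column-wise in the
#' extension. Unequal advances break the chain and contribute unaligned
#' sequence. Identity is matched columns over aligned columns; `aligned_bases`
#' is the merged chain footprint.
#'
#' @param seq_a,seq_b Contig sequences (character).
#' @param config A [pc_config()] (anchor k-mer size and gap cap).
#' @return An `hd_pc_alignment` list: `aligned_bases`, `identity`, `strand`,
#'   `n_anchors`, footprint and extension intervals on both contigs
#'   (0-based half-open, B in forward coordinates).
#' @export
intra_pc_alignment <- function(seq_a, seq_b, config = pc_config()) {
  k <- config$anchor_k
  hd_assert(nchar(seq_a) >= k && nchar(seq_b) >= k,
            "contig shorter than the anchor k-mer size")
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  anc <- hd_cpp_anchors(seq_a, seq_b, k)
  len_a <- nchar(seq_a); len_b <- nchar(seq_b)
  empty <- function(strand) {
    structure(list(aligned_bases = 0, identity = NA_real_, strand = strand,
                   n_anchors = 0L,
                   footprint_a = tibble::tibble(start = numeric(0), end = numeric(0)),
                   footprint_b = tibble::tibble(start = numeric(0), end = numeric(0)),
                   extension_a = tibble::tibble(start = 0, end = len_a),
                   extension_b = tibble::tibble(start = 0, end = len_b)),
              class = "hd_pc_alignment")
  }
  if (nrow(anc) == 0L) return(empty("+"))
  strand <- if (sum(anc$strand == "+") >= sum(anc$strand == "-")) "+" else "-"
  anc <- anc[anc$strand == strand, ]
  b_work <- seq_b
  if (strand == "-") {
    b_work <- revcomp(seq_b)
    anc$posB <- len_b - k - anc$posB # coordinates on the reverse complement
  }
  anc <- anc[order(anc$posA, anc$posB), ]
  keep <- lis_indices(anc$posB)
  pa <- anc$posA[keep]; pb <- anc$posB[keep]
  # chain and extend
  seg_s <- pa[1]; seg_sb <- pb[1]
  seg_e <- pa[1] + k
  mism <- 0
  chains <- list()
  close_chain <- function(s, e, sb, mm) {
    tibble::tibble(start_a = s, end_a = e, start_b = sb, end_b = sb + (e - s),
                   mismatches = mm)
  }
  for (i in seq_along(pa)[-1]) {
    shift_a <- pa[i] - (seg_e - k)      # distance from previous anchor start
    gap_a <- pa[i] - seg_e              # gap after previous anchor end
    gap_b <- pb[i] - (seg_sb + (seg_e - seg_s) - k) - k
    if (gap_a == gap_b && gap_a <= config$max_anchor_gap) {
      if (gap_a > 0) {
        ga <- substr(seq_a, seg_e + 1, seg_e + gap_a)
        gb <- substr(b_work, seg_sb + (seg_e - seg_s) + 1,
                     seg_sb + (seg_e - seg_s) + gap_b)
        mism <- mism + hd_cpp_count_mismatch(ga, gb)
      }
      seg_e <- pa[i] + k
    } else {
      chains[[length(chains) + 1L]] <- close_chain(seg_s, seg_e, seg_sb, mism)
      seg_s <- pa[i]; seg_sb <- pb[i]; seg_e <- pa[i] + k; mism <- 0
    }
  }
  chains[[length(chains) + 1L]] <- close_chain(seg_s, seg_e, seg_sb, mism)
  ch <- dplyr::bind_rows(chains)
  aligned <- sum(ch$end_a - ch$start_a)
  identity <- 1 - sum(ch$mismatches) / aligned
  fp_a <- merge_intervals(ch$start_a, ch$end_a)
  fp_b_work <- merge_intervals(ch$start_b, ch$end_b)
  fp_b <- if (strand == "-") {
    tibble::tibble(start = len_b - rev(fp_b_work$end),
                   end = len_b - rev(fp_b_work$start))
  } else {
    fp_b_work
  }
  complement <- function(fp, len) {
    bounds <- c(0, as.vector(rbind(fp$start, fp$end)), len)
    s <- bounds[seq(1, length(bounds), by = 2)]
    e <- bounds[seq(2, length(bounds), by = 2)]
    keep <- e > s
    tibble::tibble(start = s[keep], end = e[keep])
  }
  structure(list(aligned_bases = aligned, identity = identity, strand = strand,
                 n_anchors = length(pa),
                 footprint_a = fp_a, footprint_b = fp_b,
                 extension_a = complement(fp_a, len_a),
                 extension_b = complement(fp_b, len_b)),
            class = "hd_pc_alignment")
}

#' Align every detected paired contig
#'
#' @param pcs An `hd_pcs` table.
#' @param contigs Named character vector of contig sequences (or
#'   `hd_assembly`).
#' @param config A [pc_config()].
#' @return The `pcs` tibble extended with `aligned_bases`, `identity`,
#'   `aligned_fraction` (of the smaller contig), `strand` and the four
#'   end-extension widths used for walk construction.
#' @export
pc_alignments <- function(pcs, contigs, config = pc_config()) {
  if (inherits(contigs, "hd_assembly")) contigs <- contigs$contigs
  seqs <- as_contig_seqs(contigs)
  res <- purrr::map(seq_len(nrow(pcs)), function(i) {
    al <- intra_pc_alignment(seqs[[pcs$contig_a[i]]], seqs[[pcs$contig_b[i]]],
                             config)
    la <- nchar(seqs[[pcs$contig_a[i]]]); lb <- nchar(seqs[[pcs$contig_b[i]]])
    fp_a <- al$footprint_a; fp_b <- al$footprint_b
    tibble::tibble(
      aligned_bases = al$aligned_bases, identity = al$identity,
      aligned_fraction = al$aligned_bases / min(la, lb),
      strand = al$strand,
      ext_a_left = if (nrow(fp_a)) min(fp_a$start) else la,
      ext_a_right = if (nrow(fp_a)) la - max(fp_a$end) else la,
      ext_b_left = if (nrow(fp_b)) min(fp_b$start) else lb,
      ext_b_right = if (nrow(fp_b)) lb - max(fp_b$end) else lb)
  })
  out <- dplyr::bind_cols(tibble::as_tibble(pcs), dplyr::bind_rows(res))
  hd_tbl(out, "hd_pc_alignments", contigs = attr(pcs, "contigs"),
         config = config)
}

#' Paired-contig graph and walks
#'
#' Builds the graph whose nodes are contigs and edges detected PCs, annotates
#' each edge TILING (each contig extends beyond the partner alignment on
#' opposite ends, by at least `min_extension`) or CONTAINED, and extracts
#' walks: maximal simple paths over TILING edges, greedily grown from the
#' highest shared-count edge (each contig joins at most one walk, so no walk
#' repeats a contig).
#'
#' @param alignments An `hd_pc_alignments` table from [pc_alignments()].
#' @param config A [pc_config()].
#' @return An `hd_pc_graph` list: `edges` (with `link` annotation) and
#'   `walks` (walk id, contigs, PC count, summed span).
#' @export
build_walks <- function(alignments, config = pc_config()) {
  m <- config$min_extension
  strand_flip <- alignments$strand == "-"
  # strand-normalised extensions of contig B
  bl <- ifelse(strand_flip, alignments$ext_b_right, alignments$ext_b_left)
  br <- ifelse(strand_flip, alignments$ext_b_left, alignments$ext_b_right)
  tiling <- (alignments$ext_a_left >= m & br >= m &
               alignments$ext_a_right < m & bl < m) |
    (alignments$ext_a_right >= m & bl >= m &
       alignments$ext_a_left < m & br < m)
  edges <- tibble::as_tibble(alignments)
  edges$link <- ifelse(tiling, "TILING", "CONTAINED")
  contigs <- attr(alignments, "contigs")
  len <- if (!is.null(contigs)) setNames(contigs$length, contigs$contig) else NULL
  te <- edges |> filter(.data$link == "TILING") |> arrange(desc(.data$shared_pairs))
  used_contig <- character(0)
  used_edge <- rep(FALSE, nrow(te))
  walks <- list()
  neighbours <- function(node, banned) {
    cand <- which(!used_edge &
                    (te$contig_a == node | te$contig_b == node))
    other <- ifelse(te$contig_a[cand] == node, te$contig_b[cand], te$contig_a[cand])
    ok <- !(other %in% banned) & !(other %in% used_contig)
    list(edge = cand[ok], other = other[ok])
  }
  for (i in seq_len(nrow(te))) {
    if (used_edge[i]) next
    a <- te$contig_a[i]; b <- te$contig_b[i]
    if (a %in% used_contig || b %in% used_contig) next
    path <- c(a, b)
    used_edge[i] <- TRUE
    n_edges <- 1L
    repeat { # extend at the tail
      nb <- neighbours(path[length(path)], path)
      if (length(nb$edge) == 0L) break
      used_edge[nb$edge[1]] <- TRUE
      path <- c(path, nb$other[1])
      n_edges <- n_edges + 1L
    }
    repeat { # extend at the head
      nb <- neighbours(path[1], path)
      if (length(nb$edge) == 0L) break
      used_edge[nb$edge[1]] <- TRUE
      path <- c(nb$other[1], path)
      n_edges <- n_edges + 1L
    }
    used_contig <- c(used_contig, path)
    walks[[length(walks) + 1L]] <- tibble::tibble(
      walk = length(walks) + 1L,
      contigs = list(path),
      n_contigs = length(path),
      n_pcs = n_edges,
      span = if (is.null(len)) NA_real_ else sum(len[path]))
  }
  walks <- if (length(walks)) dplyr::bind_rows(walks) else
    tibble::tibble(walk = integer(0), contigs = list(), n_contigs = integer(0),
                   n_pcs = integer(0), span = numeric(0))
  structure(list(edges = edges, walks = walks, contigs = contigs),
            class = "hd_pc_graph")
}

#' @export
print.hd_pc_graph <- function(x, ...) {
  cat("<hd_pc_graph> ", nrow(x$edges), " PC edges (",
      sum(x$edges$link == "TILING"), " tiling), ", nrow(x$walks),
      " walk(s)\n", sep = "")
  invisible(x)
}
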