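#' Specification for a synthetic diploid genome
#'
#' Bundles the parameters of the diploid-genome simulator. The defaults model
#' a mosquito-cell-line-like genome: ~5.7% heterozygous sites overall, with
#' 80% of the haploid span diverged beyond the 2% threshold at which a
#' long-read assembler emits both haplotypes as separate contigs, and the
#' remainder lowly diverged so that it is assembled as a single collapsed
#' consensus.
#'
#' The haploid genome is a grid of loci of `locus_length` bases. Each locus is
#' assigned a divergence; loci above `separation_divergence` are the
#' "separated" mosaic. Divergences are drawn so that the genome-wide expected
#' substitution fraction equals `heterozygosity_target`: separated loci get a
#' uniform divergence centred on the value that balances the target, collapsed
#' loci a uniform divergence with mean `collapsed_divergence`.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp; must be a multiple of
#'   `locus_length`.
#' @param locus_length Locus granularity of the separation mosaic, bp.
#' @param heterozygosity_target Genome-wide substitution fraction between the
#'   two haplotypes; must lie in `[0, 0.25)`.
#' @param separation_divergence Divergence above which the emulated assembler
#'   separates the haplotypes of a locus (default 0.02).
#' @param separated_fraction Fraction of loci drawn above
#'   `separation_divergence`.
#' @param collapsed_divergence Mean divergence of collapsed (low-divergence)
#'   loci.
#' @param gene_count Number of genes placed on the genome (one per locus,
#'   non-overlapping).
#' @param gene_length Gene length in bp.
#' @param gene_loss_rate Per-allele probability that a gene copy is lost.
#' @param partial_loss_prob Given a loss, probability that it is partial
#'   (a fragment of the allele remains detectable).
#' @param m_locus_length Length of the male-limited locus appended to
#'   haplotype A of chromosome 1; `0` disables it.
#' @param seed Mandatory integer seed; identical specs and seeds reproduce
#'   byte-identical genomes.
#' @return A list of class `hd_genome_spec`.
#' @export
genome_sim_spec <- function(n_chromosomes = 2,
                            chrom_length = 5e5,
                            locus_length = 1e4,
                            heterozygosity_target = 0.057,
                            separation_divergence = 0.02,
                            separated_fraction = 0.8,
                            collapsed_divergence = 0.005,
                            gene_count = 100,
                            gene_length = 1500,
                            gene_loss_rate = 0.05,
                            partial_loss_prob = 0.3,
                            m_locus_length = 20000,
                            seed = 1L) {
  hd_assert(heterozygosity_target >= 0 && heterozygosity_target < 0.25,
            "heterozygosity_target must lie in [0, 0.25)")
  hd_assert(separation_divergence > 0, "separation_divergence must be > 0")
  hd_assert(chrom_length %% locus_length == 0,
            "chrom_length must be a multiple of locus_length")
  hd_assert(separated_fraction >= 0 && separated_fraction <= 1,
            "separated_fraction must lie in [0, 1]")
  hd_assert(gene_length < locus_length,
            "gene_length must be smaller than locus_length")
  hd_assert(!is.null(seed) && is.finite(seed), "seed is mandatory")
  spec <- list(n_chromosomes = as.integer(n_chromosomes),
               chrom_length = as.integer(chrom_length),
               locus_length = as.integer(locus_length),
               heterozygosity_target = heterozygosity_target,
               separation_divergence = separation_divergence,
               separated_fraction = separated_fraction,
               collapsed_divergence = collapsed_divergence,
               gene_count = as.integer(gene_count),
               gene_length = as.integer(gene_length),
               gene_loss_rate = gene_loss_rate,
               partial_loss_prob = partial_loss_prob,
               m_locus_length = as.integer(m_locus_length),
               seed = as.integer(seed))
  structure(spec, class = "hd_genome_spec")
}

# Per-locus divergence draws balancing the genome-wide target.
draw_divergences <- function(spec, n_loci) {
  f <- spec$separated_fraction
  het <- spec$heterozygosity_target
  sep <- spec$separation_divergence
  if (het == 0) {
    return(list(divergence = rep(0, n_loci), separated = rep(FALSE, n_loci)))
  }
  n_sep <- round(f * n_loci)
  separated <- rep(FALSE, n_loci)
  if (n_sep > 0) separated[sample.int(n_loci, n_sep)] <- TRUE
  d <- numeric(n_loci)
  if (n_sep > 0) {
    d_lo_mean <- min(spec$collapsed_divergence, 0.9 * sep)
    mean_hi <- (het - (1 - f) * d_lo_mean) / f
    hd_assert(mean_hi > 1.05 * sep,
              paste("heterozygosity_target too low to place",
                    "separated loci above separation_divergence"))
    lo <- min(1.25 * sep, mean_hi)
    hi <- 2 * mean_hi - lo
    d[separated] <- runif(n_sep, lo, hi)
  }
  if (n_sep < n_loci) {
    d_lo_mean <- if (n_sep > 0) {
      min(spec$collapsed_divergence, 0.9 * sep)
    } else {
      hd_assert(het < sep,
                "heterozygosity_target must stay below separation_divergence when separated_fraction = 0")
      het
    }
    d[!separated] <- runif(n_loci - n_sep, 0, min(2 * d_lo_mean, 0.95 * sep))
  }
  list(divergence = d, separated = separated)
}

# Substitute n random positions of a locus string with a different base.
mutate_locus <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  L <- nchar(seq)
  pos <- sample.int(L, min(n_sub, L))
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a diploid genome with a heterozygosity mosaic
#'
#' Haplotype A of each chromosome is uniform random sequence; haplotype B is
#' derived locus by locus by substituting a binomial number of sites at the
#' locus divergence, so that the realised genome-wide substitution fraction
#' matches the spec's heterozygosity target. Genes are placed one per locus,
#' non-overlapping, on both haplotypes, and each allele is independently lost
#' at the spec's loss rate (losses are recorded in the truth table; the
#' underlying sequence stays positionally aligned). When enabled, a unique
#' male-limited locus (`m_locus`) is appended to haplotype A of chromosome 1
#' so that all other coordinates remain aligned between the haplotypes.
#'
#' @param spec A [genome_sim_spec()].
#' @return An object of class `hd_genome`: a list with haplotype sequences
#'   (`hap_a`, `hap_b`, named character vectors per chromosome), a `loci`
#'   truth tibble (divergence targets and realised values, separation flag),
#'   a `genes` truth tibble (per-allele presence and retained extent), and an
#'   `m_locus` row (or `NULL`).
#' @export
simulate_diploid_genome <- function(spec) {
  hd_assert(inherits(spec, "hd_genome_spec"), "spec must be a genome_sim_spec()")
  withr::with_seed(spec$seed, {
    loci_per_chrom <- spec$chrom_length %/% spec$locus_length
    n_loci <- spec$n_chromosomes * loci_per_chrom
    dv <- draw_divergences(spec, n_loci)
    loci <- tibble::tibble(
      chrom = rep(paste0("chr", seq_len(spec$n_chromosomes)), each = loci_per_chrom),
      locus = rep(seq_len(loci_per_chrom), times = spec$n_chromosomes),
      start = (rep(seq_len(loci_per_chrom), times = spec$n_chromosomes) - 1) *
        spec$locus_length,
      end = rep(seq_len(loci_per_chrom), times = spec$n_chromosomes) *
        spec$locus_length,
      divergence_target = dv$divergence,
      separated = dv$separated
    )
    hap_a <- hap_b <- setNames(character(spec$n_chromosomes),
                               paste0("chr", seq_len(spec$n_chromosomes)))
    realised <- numeric(nrow(loci))
    for (ch in names(hap_a)) {
      a_loci <- character(loci_per_chrom)
      b_loci <- character(loci_per_chrom)
      idx <- which(loci$chrom == ch)
      for (j in seq_len(loci_per_chrom)) {
        a <- random_dna(spec$locus_length)
        d <- loci$divergence_target[idx[j]]
        n_sub <- rbinom(1L, spec$locus_length, d)
        b <- mutate_locus(a, n_sub)
        realised[idx[j]] <- hd_cpp_count_mismatch(a, b) / spec$locus_length
        a_loci[j] <- a
        b_loci[j] <- b
      }
      hap_a[[ch]] <- paste(a_loci, collapse = "")
      hap_b[[ch]] <- paste(b_loci, collapse = "")
    }
    loci$divergence_realised <- realised

    # gene placement: one gene per locus, sampled without replacement
    hd_assert(spec$gene_count <= n_loci,
              paste0("gene placement failed: gene_count (", spec$gene_count,
                     ") exceeds the number of loci (", n_loci,
                     "); enlarge the genome or reduce gene_count"))
    genes <- NULL
    if (spec$gene_count > 0) {
      gl <- loci[sort(sample.int(n_loci, spec$gene_count)), ]
      offs <- floor(runif(spec$gene_count, 0,
                          spec$locus_length - spec$gene_length + 1))
      loss_a <- runif(spec$gene_count) < spec$gene_loss_rate
      loss_b <- runif(spec$gene_count) < spec$gene_loss_rate
      extent <- function(lost) {
        ifelse(!lost, 1,
               ifelse(runif(length(lost)) < spec$partial_loss_prob,
                      runif(length(lost), 0.1, 0.45), 0))
      }
      genes <- tibble::tibble(
        gene_id = sprintf("gene%04d", seq_len(spec$gene_count)),
        chrom = gl$chrom, locus = gl$locus,
        start = gl$start + offs,
        end = gl$start + offs + spec$gene_length,
        extent_a = extent(loss_a),
        extent_b = extent(loss_b)
      )
      genes$present_a <- genes$extent_a > 0
      genes$present_b <- genes$extent_b > 0
    }

    m_locus <- NULL
    if (spec$m_locus_length > 0) {
      m_seq <- random_dna(spec$m_locus_length)
      hap_a[["chr1"]] <- paste0(hap_a[["chr1"]], m_seq)
      m_locus <- tibble::tibble(chrom = "chr1", hap = "A",
                                start = spec$chrom_length,
                                end = spec$chrom_length + spec$m_locus_length)
    }

    structure(list(spec = spec, hap_a = hap_a, hap_b = hap_b, loci = loci,
                   genes = genes, m_locus = m_locus),
              class = "hd_genome")
  })
}

#' @export
print.hd_genome <- function(x, ...) {
  cat("<hd_genome> ", x$spec$n_chromosomes, " chromosome(s), ",
      format(x$spec$chrom_length, big.mark = ","), " bp each; realised heterozygosity ",
      sprintf("%.4f", realized_heterozygosity(x)), "\n", sep = "")
  invisible(x)
}

#' Realised substitution fraction between the two haplotypes
#'
#' @param genome An `hd_genome`.
#' @return Genome-wide fraction of mismatched columns (m_locus excluded).
#' @export
realized_heterozygosity <- function(genome) {
  with(genome$loci, sum(divergence_realised * (end - start)) / sum(end - start))
}

#' Emulate assembler behaviour on a synthetic diploid genome
#'
#' Mirrors the two-class emission rule of a haplotype-aware long-read
#' assembler: each maximal run of consecutive loci whose divergence exceeds
#' the separation threshold is emitted as two contigs (one per haplotype,
#' recorded as a counterpart pair), while runs at or below the threshold are
#' emitted as a single contig equal to haplotype A, standing in for the
#' two-allele consensus. Contig names are deterministic
#' (`<chrom>_r<run>` with `_A`/`_B` suffixes for separated runs).
#'
#' @param genome An `hd_genome` from [simulate_diploid_genome()].
#' @return An object of class `hd_assembly`: list with `contigs` (named
#'   character vector), `contig_truth` (tibble: contig, chrom, run, hap,
#'   start/end in chromosome coordinates, truth class) and `pc_truth`
#'   (tibble of haplotype counterpart pairs with their mean divergence).
#' @export
simulate_assembly <- function(genome) {
  hd_assert(inherits(genome, "hd_genome"), "genome must come from simulate_diploid_genome()")
  spec <- genome$spec
  loci <- genome$loci
  contigs <- character(0)
  truth <- list()
  pc_truth <- list()
  for (ch in unique(loci$chrom)) {
    lc <- loci[loci$chrom == ch, ]
    run_id <- cumsum(c(TRUE, diff(lc$separated) != 0))
    for (r in unique(run_id)) {
      rows <- lc[run_id == r, ]
      s <- min(rows$start); e <- max(rows$end)
      sep <- rows$separated[1]
      # the male-limited locus rides on the terminal run of chr1 haplotype A
      a_end <- e
      if (!is.null(genome$m_locus) && ch == "chr1" && e == spec$chrom_length) {
        a_end <- e + spec$m_locus_length
      }
      base <- paste0(ch, "_r", sprintf("%02d", r))
      if (sep) {
        na <- paste0(base, "_A"); nb <- paste0(base, "_B")
        contigs[[na]] <- substr(genome$hap_a[[ch]], s + 1, a_end)
        contigs[[nb]] <- substr(genome$hap_b[[ch]], s + 1, e)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          contig = c(na, nb), chrom = ch, run = r, hap = c("A", "B"),
          start = s, end = c(a_end, e), class = "SEPARATED")
        pc_truth[[length(pc_truth) + 1L]] <- tibble::tibble(
          contig_a = na, contig_b = nb, chrom = ch, run = r,
          start = s, end = e,
          mean_divergence = weighted.mean(rows$divergence_realised,
                                          rows$end - rows$start))
      } else {
        contigs[[base]] <- substr(genome$hap_a[[ch]], s + 1, a_end)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          contig = base, chrom = ch, run = r, hap = NA_character_,
          start = s, end = a_end, class = "COLLAPSED")
      }
    }
  }
  contig_truth <- dplyr::bind_rows(truth)
  pc_truth <- if (length(pc_truth)) dplyr::bind_rows(pc_truth) else
    tibble::tibble(contig_a = character(0), contig_b = character(0),
                   chrom = character(0), run = integer(0),
                   start = numeric(0), end = numeric(0),
                   mean_divergence = numeric(0))
  m_locus_contig <- NULL
  if (!is.null(genome$m_locus)) {
    host <- contig_truth[contig_truth$chrom == "chr1" &
                           contig_truth$end > spec$chrom_length &
                           (is.na(contig_truth$hap) | contig_truth$hap == "A"), ]
    m_locus_contig <- tibble::tibble(
      contig = host$contig[1],
      start = spec$chrom_length - host$start[1],
      end = spec$chrom_length - host$start[1] + spec$m_locus_length)
  }
  structure(list(contigs = contigs, contig_truth = contig_truth,
                 pc_truth = pc_truth, m_locus_contig = m_locus_contig,
                 genome = genome),
            class = "hd_assembly")
}

#' @export
print.hd_assembly <- function(x, ...) {
  cat("<hd_assembly> ", length(x$contigs), " contigs, ",
      format(sum(nchar(x$contigs)), big.mark = ","), " bp (",
      sum(x$contig_truth$class == "SEPARATED"), " separated, ",
      sum(x$contig_truth$class == "COLLAPSED"), " collapsed)\n", sep = "")
  invisible(x)
}

#' Truth-derived ortholog hit table for a synthetic assembly
#'
#' Projects the simulated gene truth onto assembly contigs, emulating the hit
#' table a homology search would produce: an allele in a separated run yields
#' an instance on that haplotype's contig, alleles in collapsed runs yield a
#' single merged instance on the collapsed contig, and partially lost alleles
#' yield proportionally truncated hits. The `score` column carries the
#' fraction of the gene covered by the hit.
#'
#' @param assembly An `hd_assembly`.
#' @return Tibble with columns `gene_id`, `contig`, `start`, `end`, `score`
#'   (0-based half-open contig coordinates).
#' @export
simulate_gene_hits <- function(assembly) {
  genome <- assembly$genome
  genes <- genome$genes
  hd_assert(!is.null(genes), "the genome was simulated without genes")
  truth <- assembly$contig_truth
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    host <- truth[truth$chrom == g$chrom & truth$start <= g$start &
                    truth$end >= g$end, ]
    sep <- host$class[1] == "SEPARATED"
    emit <- function(contig, extent) {
      if (extent <= 0) return(NULL)
      s <- g$start - host$start[1]
      tibble::tibble(gene_id = g$gene_id, contig = contig,
                     start = s, end = s + round(extent * (g$end - g$start)),
                     score = extent)
    }
    if (sep) {
      ca <- host$contig[host$hap == "A"]; cb <- host$contig[host$hap == "B"]
      rows[[length(rows) + 1L]] <- emit(ca, g$extent_a)
      rows[[length(rows) + 1L]] <- emit(cb, g$extent_b)
    } else {
      # both alleles co-locate on the collapsed contig: one merged instance
      rows[[length(rows) + 1L]] <- emit(host$contig[1],
                                        max(g$extent_a, g$extent_b))
    }
  }
  dplyr::bind_rows(rows)
}

#' Expected doubly-mapped read pairs for truth contig pairs
#'
#' For each truth haplotype-counterpart pair, estimates the expected number
#' of read pairs that map concordantly to *both* contigs under the mapper's
#' seed-and-verify contract: a mate reaches the counterpart contig when it
#' stays within the per-mate mismatch cap *and* at least one of its seed
#' k-mers (placed every `k` bases plus one flush with the read end) is free
#' of mismatches. The per-mate probability is estimated by Monte Carlo at
#' each locus's realised divergence (plus the sequencing error rate), with
#' mates independent; the draw is internally seeded so the estimate is
#' reproducible.
#'
#' @param assembly An `hd_assembly`.
#' @param read_spec A [read_sim_spec()] describing the read set.
#' @param config A [mapper_config()] supplying the per-mate mismatch cap.
#' @param k Seed k-mer size used by the mapper index.
#' @param nsim Monte Carlo draws per divergence value.
#' @return The assembly's `pc_truth` tibble with an `expected_shared_pairs`
#'   column.
#' @export
expected_shared_pairs <- function(assembly, read_spec, config, k = 31,
                                  nsim = 2000) {
  loci <- assembly$genome$loci
  rl <- read_spec$read_length
  pairs_per_bp <- read_spec$depth_total / (2 * rl)
  offs <- seq(0, rl - k, by = k)
  if (offs[length(offs)] != rl - k) offs <- c(offs, rl - k)
  p_detect <- function(d) {
    # P(mate maps: <= max_mismatches and at least one clean seed window)
    mism <- matrix(runif(nsim * rl) < d, nsim)
    mm_ok <- rowSums(mism) <= config$max_mismatches
    clean <- rep(FALSE, nsim)
    for (o in offs) {
      clean <- clean | rowSums(mism[, (o + 1):(o + k), drop = FALSE]) == 0
    }
    mean(mm_ok & clean)
  }
  pt <- assembly$pc_truth
  withr::with_seed(1L, {
    cache <- new.env(parent = emptyenv())
    p_cached <- function(d) {
      key <- sprintf("%.4f", d)
      if (is.null(cache[[key]])) cache[[key]] <- p_detect(d)
      cache[[key]]
    }
    p_own <- p_cached(read_spec$error_rate)
    exp_shared <- numeric(nrow(pt))
    for (i in seq_len(nrow(pt))) {
      rows <- loci[loci$chrom == pt$chrom[i] & loci$start >= pt$start[i] &
                     loci$end <= pt$end[i], ]
      d_eff <- pmin(1, rows$divergence_realised + read_spec$error_rate)
      p_pair <- vapply(d_eff, p_cached, numeric(1))^2 * p_own^2
      # pairs_per_bp is per haploid-coordinate base, i.e. it already counts
      # fragments from both haplotypes of the run
      exp_shared[i] <- sum((rows$end - rows$start) * pairs_per_bp * p_pair)
    }
  })
  pt$expected_shared_pairs <- exp_shared
  pt
}
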