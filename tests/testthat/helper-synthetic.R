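# Shared synthetic fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

tiny_genome <- function() {
  memo("tiny_genome", function() {
    simulate_diploid_genome(genome_sim_spec(
      n_chromosomes = 1, chrom_length = 2e5, gene_count = 12,
      gene_loss_rate = 0.2, m_locus_length = 10000, seed = 42))
  })
}

tiny_assembly <- function() {
  memo("tiny_assembly", function() simulate_assembly(tiny_genome()))
}

tiny_reads <- function() {
  memo("tiny_reads", function() {
    simulate_reads(tiny_genome(), read_sim_spec(seed = 7))
  })
}

tiny_index <- function() {
  memo("tiny_index", function() build_index(tiny_assembly()$contigs))
}

tiny_best1 <- function() {
  memo("tiny_best1", function() {
    map_pairs(tiny_reads(), tiny_index(), mapper_config("best_one", seed = 11))
  })
}

tiny_best4 <- function() {
  memo("tiny_best4", function() {
    map_pairs(tiny_reads(), tiny_index(), mapper_config("best_k", seed = 12))
  })
}

# Independent column-mismatch counter (oracle; avoids the package's C++ one).
oracle_mismatch <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Exhaustive windowed-mode oracle over a depth histogram: best 3-wide window
# with centres from 4 up; ties prefer the most bases at the centre depth,
# then the smallest centre.
oracle_mode <- function(depth, bases) {
  keep <- depth >= 3 & bases > 0
  if (!any(keep)) return(NA_integer_)
  cand <- integer(0); best_s <- -1
  for (d in 4:(max(depth[keep]) + 1)) {
    s <- sum(bases[depth >= max(3, d - 1) & depth <= d + 1])
    if (s > best_s) { best_s <- s; cand <- d }
    else if (s == best_s) cand <- c(cand, d)
  }
  at <- vapply(cand, function(d) sum(bases[depth == d]), numeric(1))
  min(cand[at == max(at)])
}

# Two-sided Fisher exact p by explicit enumeration over tables with the
# observed margins (hypergeometric weights from factorials).
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lp <- function(a) {
    lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
  }
  as <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lp(as))
  p_obs <- exp(lp(m[1, 1]))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Build an hd_placements tibble by hand for table-level tests.
fake_placements <- function(df, contigs, mode = "best_k", paired = TRUE) {
  haplodiag:::hd_tbl(df, "hd_placements", mode = mode, paired = paired,
                     n_query = dplyr::n_distinct(
                       if (paired) df$pair_id else df$read_id),
                     contigs = contigs)
}

# Paper-scale study conditions: ~1 Mb haploid diploid genome, 5.7%
# heterozygosity, 80% of the span separated, 36x total depth. Shared by the
# parameter-recovery acceptance checks.
big_genome <- function() {
  memo("big_genome", function() {
    simulate_diploid_genome(genome_sim_spec(
      n_chromosomes = 2, chrom_length = 5e5, gene_count = 100,
      m_locus_length = 0, seed = 1042))
  })
}

big_assembly <- function() {
  memo("big_assembly", function() simulate_assembly(big_genome()))
}

big_read_spec <- function() read_sim_spec(depth_total = 36, seed = 1043)

big_reads <- function() {
  memo("big_reads", function() simulate_reads(big_genome(), big_read_spec()))
}

big_index <- function() {
  memo("big_index", function() build_index(big_assembly()$contigs))
}

big_best1 <- function() {
  memo("big_best1", function() {
    map_pairs(big_reads(), big_index(), mapper_config("best_one", seed = 1044))
  })
}

big_best4 <- function() {
  memo("big_best4", function() {
    map_pairs(big_reads(), big_index(), mapper_config("best_k", seed = 1045))
  })
}
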