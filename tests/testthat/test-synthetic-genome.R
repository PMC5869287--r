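test_that("zero heterozygosity yields identical haplotypes outside the m-locus", {
  g <- simulate_diploid_genome(genome_sim_spec(
    n_chromosomes = 1, chrom_length = 5e4, heterozygosity_target = 0,
    gene_count = 0, m_locus_length = 5000, seed = 1))
  expect_identical(substr(g$hap_a[["chr1"]], 1, 5e4), g$hap_b[["chr1"]])
  expect_equal(nchar(g$hap_a[["chr1"]]), 5.5e4) # m-locus appended to A
  expect_true(all(g$loci$divergence_realised == 0))
})

test_that("realised substitution fraction matches the heterozygosity target", {
  g <- simulate_diploid_genome(genome_sim_spec(
    n_chromosomes = 1, chrom_length = 1e6, heterozygosity_target = 0.057,
    gene_count = 0, m_locus_length = 0, seed = 3))
  # oracle: count mismatched columns between the emitted haplotypes
  frac <- oracle_mismatch(g$hap_a[["chr1"]], g$hap_b[["chr1"]]) / 1e6
  expect_gte(frac, 0.051)
  expect_lte(frac, 0.063)
  expect_equal(frac, realized_heterozygosity(g), tolerance = 1e-9)
})

test_that("allele losses follow the configured rate", {
  g <- simulate_diploid_genome(genome_sim_spec(
    n_chromosomes = 2, chrom_length = 1e6, gene_count = 200,
    gene_loss_rate = 0.1, m_locus_length = 0, seed = 5))
  lost <- sum(g$genes$extent_a < 1) + sum(g$genes$extent_b < 1)
  expected <- 0.1 * 400
  sd3 <- 3 * sqrt(400 * 0.1 * 0.9)
  expect_gte(lost, expected - sd3)
  expect_lte(lost, expected + sd3)
})

test_that("identical specs and seeds reproduce identical genomes and reads", {
  spec <- genome_sim_spec(n_chromosomes = 1, chrom_length = 5e4,
                          gene_count = 5, seed = 9)
  g1 <- simulate_diploid_genome(spec)
  g2 <- simulate_diploid_genome(spec)
  expect_identical(g1$hap_a, g2$hap_a)
  expect_identical(g1$hap_b, g2$hap_b)
  expect_identical(g1$genes, g2$genes)
  rs <- read_sim_spec(seed = 4)
  expect_identical(simulate_reads(g1, rs), simulate_reads(g2, rs))
})

test_that("gene placement failure names the constraint", {
  expect_error(
    simulate_diploid_genome(genome_sim_spec(
      n_chromosomes = 1, chrom_length = 5e4, gene_count = 10, seed = 1)),
    "gene placement failed")
})

test_that("assembler emulation follows the two-class emission rule", {
  # all loci at divergence zero: one collapsed contig per chromosome
  g0 <- simulate_diploid_genome(genome_sim_spec(
    n_chromosomes = 1, chrom_length = 1e5, heterozygosity_target = 0,
    gene_count = 0, m_locus_length = 0, seed = 2))
  a0 <- simulate_assembly(g0)
  expect_true(all(a0$contig_truth$class == "COLLAPSED"))
  expect_equal(nrow(a0$pc_truth), 0)
  expect_equal(sum(nchar(a0$contigs)), 1e5)

  # full separation: every contig separated, span about twice the haploid span
  g1 <- simulate_diploid_genome(genome_sim_spec(
    n_chromosomes = 1, chrom_length = 1e5, separated_fraction = 1,
    gene_count = 0, m_locus_length = 0, seed = 2))
  a1 <- simulate_assembly(g1)
  expect_true(all(a1$contig_truth$class == "SEPARATED"))
  expect_equal(sum(nchar(a1$contigs)), 2e5)

  # mixed: contig span = haploid * (1 + h) with h from the truth intervals
  a <- tiny_assembly()
  loci <- tiny_genome()$loci
  h_span <- sum(loci$end[loci$separated] - loci$start[loci$separated])
  haploid <- 2e5
  expected <- haploid * (1 + h_span / haploid) + 1e4 # + m-locus on hap A
  expect_equal(sum(nchar(a$contigs)), expected)
})

test_that("truth tables are internally consistent", {
  a <- tiny_assembly()
  g <- tiny_genome()
  spec <- g$spec
  # every truth pair spans loci above the separation threshold, collapsed
  # contigs only loci at or below it
  for (i in seq_len(nrow(a$pc_truth))) {
    rows <- g$loci[g$loci$start >= a$pc_truth$start[i] &
                     g$loci$end <= a$pc_truth$end[i], ]
    expect_true(all(rows$divergence_target > spec$separation_divergence))
  }
  col <- a$contig_truth[a$contig_truth$class == "COLLAPSED", ]
  for (i in seq_len(nrow(col))) {
    rows <- g$loci[g$loci$start >= col$start[i] & g$loci$end <= col$end[i], ]
    expect_true(all(rows$divergence_target <= spec$separation_divergence))
  }
  # separated contigs come in counterpart pairs listed in pc_truth
  sep <- a$contig_truth$contig[a$contig_truth$class == "SEPARATED"]
  expect_setequal(sep, c(a$pc_truth$contig_a, a$pc_truth$contig_b))
})
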