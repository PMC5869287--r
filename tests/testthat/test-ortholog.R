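two_class_tbl <- function() {
  tibble::tibble(contig = c("s1", "s2", "k1", "o1"),
                 class = c("SEPARATED", "SEPARATED", "COLLAPSED", "OTHER"))
}

test_that("gene hits group into instances with class profiles", {
  hits <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g3", "g4", "g5"),
    contig  = c("s1", "s2", "k1", "s1", "k1", "o1", "s2", "o1"),
    start = 0, end = 100)
  inst <- ingest_gene_hits(hits, two_class_tbl())
  genes <- attr(inst, "genes")
  expect_equal(genes$n_instances[genes$gene_id == "g1"], 2)
  expect_true(genes$only_separated[genes$gene_id == "g1"])
  expect_false(genes$only_separated[genes$gene_id == "g3"])
  expect_true(genes$only_collapsed[genes$gene_id == "g2"])
  # hand tally of the profile
  expect_equal(genes$n_separated, c(2, 0, 1, 1, 0))
  expect_equal(genes$n_collapsed, c(0, 1, 1, 0, 0))
  expect_equal(genes$n_other, c(0, 0, 1, 0, 1))
  expect_error(ingest_gene_hits(
    tibble::tibble(gene_id = "g", contig = "nope", start = 0, end = 1),
    two_class_tbl()), "unknown contigs")
})

test_that("GFF rows convert from 1-based closed to 0-based half-open", {
  gff <- withr::local_tempfile(fileext = ".gff")
  writeLines("s1\tsrc\tgene\t101\t200\t.\t+\t.\tID=gX", gff)
  inst <- ingest_gene_hits(gff, two_class_tbl(), format = "gff")
  expect_equal(inst$start, 100)
  expect_equal(inst$end, 200)
  expect_equal(inst$gene_id, "gX")
})

test_that("the crosstab reproduces printed-tally shares", {
  counts <- readr::read_tsv(
    system.file("extdata", "c636_busco_class_counts.tsv",
                package = "haplodiag"),
    show_col_types = FALSE)
  xt <- crosstab_from_counts(counts)
  g <- glance(xt)
  expect_equal(g$total_genes, 2624)
  expect_equal(round(g$pct_two_instance), 64)
  expect_equal(round(g$pct_two_instance_touching_separated, 1), 99.6)
  expect_equal(round(g$pct_one_instance_separated), 85)
  expect_equal(round(g$pct_one_instance_collapsed), 14)
  tb <- association_table(xt)
  expect_equal(unname(as.vector(t(tb))), c(1600, 68, 816, 140))
})

test_that("crosstab row sums and instance totals are conserved", {
  inst <- ingest_gene_hits(simulate_gene_hits(tiny_assembly()),
                           classify_contigs(depth_histogram(tiny_best1())))
  xt <- instance_crosstab(inst)
  expect_equal(sum(xt$genes_found), dplyr::n_distinct(inst$gene_id))
  expect_equal(sum(xt$inst_separated + xt$inst_collapsed + xt$inst_other),
               nrow(inst))
  # all-single-instance table has a zero two-instance share
  one <- ingest_gene_hits(
    tibble::tibble(gene_id = c("a", "b"), contig = "s1", start = 0, end = 10),
    two_class_tbl())
  expect_equal(glance(instance_crosstab(one))$pct_two_instance, 0)
})

test_that("Fisher association matches enumeration and handles degeneracy", {
  bal <- association_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(bal$p_value, 1)
  big <- association_test(matrix(c(1600, 68, 816, 140), 2, byrow = TRUE))
  expect_lt(big$p_value, 0.01)
  expect_warning(association_test(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
                 "margin")
  # random tables with margins <= 60 against the enumeration oracle
  withr::with_seed(12, {
    for (i in 1:150) {
      m <- matrix(sample(0:30, 4, replace = TRUE), 2)
      if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
      got <- association_test(m)$p_value
      expect_equal(got, oracle_fisher_p(m), tolerance = 1e-12)
    }
  })
})

test_that("odds ratio uses cells with continuity correction on zeros", {
  a <- association_test(matrix(c(20, 5, 4, 10), 2, byrow = TRUE))
  expect_equal(a$odds_ratio, (20 * 10) / (5 * 4))
  z <- suppressWarnings(association_test(matrix(c(20, 0, 4, 10), 2, byrow = TRUE)))
  expect_equal(z$odds_ratio, (20.5 * 10.5) / (0.5 * 4.5))
})

test_that("missing-gene triage categorises by evidence", {
  contigs <- tibble::tibble(contig = c("A", "B"), length = c(5e4, 5e4))
  pcs <- haplodiag:::hd_tbl(
    tibble::tibble(contig_a = "A", contig_b = "B", shared_pairs = 1e4),
    "hd_pcs", contigs = contigs)
  modes <- tibble::tibble(contig = c("A", "B"), mode = c(18, 18))
  classes <- tibble::tibble(contig = c("A", "B"), class = "SEPARATED")
  # uniform 18x depth over contig A via 18 stacked full-length placements
  pl <- fake_placements(
    tibble::tibble(read_id = sprintf("r%02d", 1:18), contig = "A",
                   start = 0, end = 5e4, strand = "+", mismatches = 0),
    contigs, mode = "best_one", paired = FALSE)
  mk_inst <- function(hits) ingest_gene_hits(hits, classes)
  # clean loss: mid-contig, normal depth, no partner hit
  t1 <- triage_missing_genes(
    mk_inst(tibble::tibble(gene_id = "g", contig = "A",
                           start = 2e4, end = 2.15e4)),
    pcs, pl, modes)
  expect_equal(t1$category, "CLEAN_LOSS")
  # fragmentary: partner carries a partial hit (< 50% of gene length)
  t2 <- triage_missing_genes(
    mk_inst(tibble::tibble(gene_id = "g", contig = c("A", "B"),
                           start = 2e4, end = c(2.15e4, 2.05e4))),
    pcs, pl, modes)
  expect_equal(t2$category, "FRAGMENTARY")
  # contig end: locus 1 kb from the terminus
  t3 <- triage_missing_genes(
    mk_inst(tibble::tibble(gene_id = "g", contig = "A",
                           start = 1000, end = 2500)),
    pcs, pl, modes)
  expect_equal(t3$category, "CONTIG_END")
  # elevated coverage: depth 2x the contig mode
  pl2 <- fake_placements(
    tibble::tibble(read_id = sprintf("r%02d", 1:36), contig = "A",
                   start = 0, end = 5e4, strand = "+", mismatches = 0),
    contigs, mode = "best_one", paired = FALSE)
  t4 <- triage_missing_genes(
    mk_inst(tibble::tibble(gene_id = "g", contig = "A",
                           start = 2e4, end = 2.15e4)),
    pcs, pl2, modes)
  expect_equal(t4$category, "COVERAGE_ELEVATED")
  # genes off every PC are skipped with a message
  expect_message(
    out <- triage_missing_genes(
      mk_inst(tibble::tibble(gene_id = "g", contig = "A",
                             start = 2e4, end = 2.15e4)),
      haplodiag:::hd_tbl(tibble::tibble(contig_a = character(0),
                                        contig_b = character(0),
                                        shared_pairs = numeric(0)),
                         "hd_pcs", contigs = contigs),
      pl, modes),
    "skipped")
  expect_equal(nrow(out), 0)
})

test_that("simulated allele losses are recovered as losses", {
  inst <- ingest_gene_hits(simulate_gene_hits(tiny_assembly()),
                           classify_contigs(depth_histogram(tiny_best1())))
  genes <- tiny_genome()$genes
  loci <- tiny_genome()$loci
  sep_locus <- loci$separated[match(genes$locus, loci$locus)]
  truth_lost <- genes$gene_id[sep_locus &
                                ((genes$extent_a < 1) != (genes$extent_b < 1))]
  tri <- suppressMessages(triage_missing_genes(
    inst, detect_pcs(doubly_mapped(tiny_best4()),
                     pc_config(density_threshold = 4.5)),
    tiny_best1(), classify_contigs(depth_histogram(tiny_best1()))))
  found <- tri$gene_id[tri$category %in% c("CLEAN_LOSS", "FRAGMENTARY",
                                           "CONTIG_END")]
  expect_true(all(truth_lost %in% found))
})
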