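make_counts_fixture <- function() {
  contigs <- tibble::tibble(contig = c("A", "B", "C"),
                            length = c(2e4, 2e4, 1e4))
  df <- tibble::tibble(
    pair_id = c("p1", "p1", "p2", "p2", "p3", "p3", "p4", "p5", "p5", "p5"),
    contig  = c("A",  "B",  "A",  "B",  "A",  "A",  "C",  "A",  "B",  "C"),
    start1 = 0, end1 = 150, start2 = 200, end2 = 350,
    strand1 = "+", orientation = "FR", mismatches = 0)
  fake_placements(df, contigs)
}

test_that("doubly-mapped accounting isolates cross-contig double placements", {
  dm <- doubly_mapped(make_counts_fixture())
  expect_equal(nrow(dm), 1)
  expect_equal(dm$contig_a, "A")
  expect_equal(dm$contig_b, "B")
  expect_equal(dm$shared_pairs, 2)            # p1 and p2
  expect_equal(attr(dm, "intra_contig_doubles"), 1) # p3 on A twice
  expect_equal(attr(dm, "fraction_exactly_two"), 3 / 5)
  # conservation: multiplicity tally covers every placed pair
  expect_equal(sum(attr(dm, "multiplicity")$pairs), attr(dm, "n_placed"))
  # best-one tables are rejected
  b1 <- fake_placements(tibble::as_tibble(make_counts_fixture()),
                        attr(make_counts_fixture(), "contigs"),
                        mode = "best_one")
  expect_error(doubly_mapped(b1), "insufficient multiplicity")
})

test_that("doubly-mapped counts equal brute-force enumeration on mapped data", {
  dm <- doubly_mapped(tiny_best4())
  tab <- table(tiny_best4()$pair_id)
  two_ids <- names(tab[tab == 2])
  oracle <- list()
  for (id in two_ids) {
    cg <- sort(tiny_best4()$contig[tiny_best4()$pair_id == id])
    if (cg[1] != cg[2]) {
      key <- paste(cg, collapse = "|")
      oracle[[key]] <- (oracle[[key]] %||% 0) + 1
    }
  }
  got <- setNames(dm$shared_pairs, paste(dm$contig_a, dm$contig_b, sep = "|"))
  expect_mapequal(as.list(got), oracle)
})

test_that("PC detection respects absolute and scaled thresholds", {
  contigs <- tibble::tibble(contig = c("A", "B"), length = c(2e6, 2e6))
  mk <- function(n) {
    haplodiag:::hd_tbl(
      tibble::tibble(contig_a = "A", contig_b = "B", shared_pairs = n),
      "hd_pair_counts", contigs = contigs)
  }
  expect_equal(nrow(detect_pcs(mk(10000), pc_config())), 1)   # boundary holds
  expect_equal(nrow(detect_pcs(mk(9999), pc_config())), 0)
  # density threshold: 4.5 pairs/kb over the 2 Mb smaller contig = 9000
  expect_equal(nrow(detect_pcs(mk(9000),
                               pc_config(density_threshold = 4.5))), 1)
  expect_equal(nrow(detect_pcs(mk(8999),
                               pc_config(density_threshold = 4.5))), 0)
  # symmetry under pair order
  sw <- haplodiag:::hd_tbl(
    tibble::tibble(contig_a = "B", contig_b = "A", shared_pairs = 10000),
    "hd_pair_counts", contigs = contigs)
  expect_equal(nrow(detect_pcs(sw, pc_config())), 1)
})

test_that("anchor alignment recovers identity from truth divergence", {
  withr::with_seed(23, {
    a <- paste(sample(c("A", "C", "G", "T"), 3e4, replace = TRUE), collapse = "")
  })
  # identical contigs
  al0 <- intra_pc_alignment(a, a)
  expect_gte(al0$aligned_bases / 3e4, 0.999)
  expect_equal(al0$identity, 1)
  # 5% substituted copy (reverse complemented to exercise strand handling)
  withr::with_seed(24, {
    b <- haplodiag:::mutate_locus(a, rbinom(1, 3e4, 0.05))
  })
  d_truth <- oracle_mismatch(a, b) / 3e4
  al <- intra_pc_alignment(
    a, as.character(Biostrings::reverseComplement(Biostrings::DNAString(b))))
  expect_equal(al$strand, "-")
  expect_lt(abs(al$identity - (1 - d_truth)), 0.01)
  expect_gte(al$aligned_bases / 3e4, 0.95)
  # unrelated contigs share no anchors
  withr::with_seed(25, {
    z <- paste(sample(c("A", "C", "G", "T"), 3e4, replace = TRUE), collapse = "")
  })
  expect_equal(intra_pc_alignment(a, z)$aligned_bases, 0)
  expect_error(intra_pc_alignment("ACGT", a), "shorter than")
})

staggered_fixture <- function() {
  # one 90 kb haplotype region; haplotype A split at thirds, B offset by half
  withr::with_seed(31, {
    hap_a <- paste(sample(c("A", "C", "G", "T"), 9e4, replace = TRUE),
                   collapse = "")
    hap_b <- haplodiag:::mutate_locus(hap_a, rbinom(1, 9e4, 0.05))
  })
  contigs <- c(A1 = substr(hap_a, 1, 3e4), A2 = substr(hap_a, 3e4 + 1, 6e4),
               A3 = substr(hap_a, 6e4 + 1, 9e4),
               B1 = substr(hap_b, 1, 1.5e4), B2 = substr(hap_b, 1.5e4 + 1, 4.5e4),
               B3 = substr(hap_b, 4.5e4 + 1, 7.5e4),
               B4 = substr(hap_b, 7.5e4 + 1, 9e4))
  contigs
}

test_that("tiling edges chain into walks spanning the truth region", {
  contigs <- staggered_fixture()
  lens <- tibble::tibble(contig = names(contigs), length = nchar(contigs))
  overlaps <- tibble::tibble(
    contig_a = c("A1", "A1", "A2", "A2", "A3", "A3"),
    contig_b = c("B1", "B2", "B2", "B3", "B3", "B4"),
    shared_pairs = c(500, 600, 650, 700, 750, 400))
  pcs <- haplodiag:::hd_tbl(overlaps, "hd_pcs", contigs = lens)
  aln <- pc_alignments(pcs, contigs, pc_config(min_extension = 2000))
  graph <- build_walks(aln, pc_config(min_extension = 2000))
  # terminal B contigs are contained in their A partners; the four staggered
  # overlaps tile
  expect_equal(sum(graph$edges$link == "TILING"), 4)
  expect_setequal(
    graph$edges$contig_b[graph$edges$link == "CONTAINED"], c("B1", "B4"))
  expect_equal(nrow(graph$walks), 1)
  expect_equal(graph$walks$n_contigs, 5) # B2-A1 ... A3-B3 chain
  expect_equal(graph$walks$n_pcs, 4)
  # walk span within 10% of the truth span of the tiled contigs (150 kb)
  expect_lt(abs(graph$walks$span - 1.5e5) / 1.5e5, 0.1)
})

test_that("star graphs yield simple walks through the hub at most once", {
  withr::with_seed(33, {
    hub <- paste(sample(c("A", "C", "G", "T"), 4e4, replace = TRUE), collapse = "")
  })
  # leaves overlap opposite halves of the hub
  contigs <- c(H = substr(hub, 1e4 + 1, 3e4),
               L1 = substr(hub, 1, 2e4), L2 = substr(hub, 2e4 + 1, 4e4),
               L3 = substr(hub, 1, 2e4 - 500))
  lens <- tibble::tibble(contig = names(contigs), length = nchar(contigs))
  pcs <- haplodiag:::hd_tbl(
    tibble::tibble(contig_a = c("H", "H", "H"),
                   contig_b = c("L1", "L2", "L3"),
                   shared_pairs = c(900, 800, 700)),
    "hd_pcs", contigs = lens)
  aln <- pc_alignments(pcs, contigs, pc_config(min_extension = 400))
  graph <- build_walks(aln, pc_config(min_extension = 400))
  for (i in seq_len(nrow(graph$walks))) {
    path <- graph$walks$contigs[[i]]
    expect_equal(anyDuplicated(path), 0)
    expect_lte(sum(path == "H"), 1)
    expect_lte(graph$walks$n_pcs[i], 2)
  }
})
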