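test_that("k-mer index enumerates forward positions and both strands", {
  idx <- build_index(c(ctg = "ACGTACGT"), k = 4)
  expect_equal(haplodiag:::hd_cpp_index_stats(idx$ptr)$n_kmers, 5)
  hits <- index_lookup(idx, "CGTA")
  expect_equal(sort(hits$pos[hits$strand == "+"]), 1)
  # reverse-complement query reported on the opposite strand
  idx2 <- build_index(c(ctg = "AACCGGTT"), k = 4)
  h <- index_lookup(idx2, "AACC")
  expect_equal(h$pos[h$strand == "+"], 0)
  expect_equal(h$pos[h$strand == "-"], 4) # revcomp(AACC) = GGTT at 4
  expect_error(build_index(c(a = "ACGT", a = "ACGT")))
})

test_that("sampled reference k-mers look up their true origin", {
  a <- tiny_assembly()
  idx <- build_index(a$contigs, k = 21)
  withr::with_seed(3, {
    for (i in 1:50) {
      cg <- sample(names(a$contigs), 1)
      pos <- sample.int(nchar(a$contigs[[cg]]) - 21, 1)
      km <- substr(a$contigs[[cg]], pos + 1, pos + 21)
      hits <- index_lookup(idx, km)
      expect_true(any(hits$contig == cg & hits$pos == pos & hits$strand == "+"))
    }
  })
})

test_that("best-one placements of error-free reads match read-name truth", {
  g <- simulate_diploid_genome(genome_sim_spec(
    n_chromosomes = 1, chrom_length = 5e4, heterozygosity_target = 0,
    gene_count = 0, m_locus_length = 0, seed = 21))
  a <- simulate_assembly(g) # single collapsed contig = haplotype A
  r <- simulate_reads(g, read_sim_spec(error_rate = 0, depth_total = 4, seed = 5))
  pl <- map_pairs(r, build_index(a$contigs), mapper_config("best_one", seed = 1))
  tr <- parse_read_names(pl$pair_id)
  frag_start <- pmin(pl$start1, pl$start2)
  expect_equal(frag_start, tr$start)
  expect_equal(pmax(pl$end1, pl$end2) - frag_start, tr$frag_len)
  expect_true(all(pl$mismatches == 0))
  # mapped fraction of error-free reads
  expect_gte(dplyr::n_distinct(pl$pair_id) / nrow(r), 0.99)
})

test_that("a verbatim two-copy locus yields exactly two best-k placements", {
  withr::with_seed(11, {
    shared <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                    collapse = "")
    flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")
    contigs <- c(c1 = paste0(flank(3000), shared, flank(3000)),
                 c2 = paste0(flank(2500), shared, flank(3500)))
  })
  idx <- build_index(contigs)
  r1 <- substr(shared, 101, 250)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(shared, 301, 450))))
  reads <- tibble::tibble(id = "p1", read1 = r1, read2 = r2)
  pl <- map_pairs(reads, idx, mapper_config("best_k", seed = 2))
  expect_equal(nrow(pl), 2)
  expect_setequal(pl$contig, c("c1", "c2"))
  # the same pair under best_one keeps a single deterministic tie-break
  b1a <- map_pairs(reads, idx, mapper_config("best_one", seed = 7))
  b1b <- map_pairs(reads, idx, mapper_config("best_one", seed = 7))
  expect_equal(nrow(b1a), 1)
  expect_identical(b1a, b1b)
})

test_that("pairs sharing no k-mer with the reference stay unmapped", {
  idx <- build_index(c(ctg = strrep("ACGT", 1000)))
  reads <- tibble::tibble(id = "p1", read1 = strrep("A", 150),
                          read2 = strrep("C", 150))
  pl <- map_pairs(reads, idx, mapper_config("best_one"))
  expect_equal(nrow(pl), 0)
  expect_equal(attr(pl, "n_query"), 1)
})

test_that("all-exact single-end mapping equals brute-force substring search", {
  withr::with_seed(19, {
    base <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
    # duplicate a block to force multi-mapping
    ref <- c(r1 = paste0(base, substr(base, 2001, 4000)))
    reads <- tibble::tibble(
      id = sprintf("s%03d", 1:80),
      read = vapply(1:80, function(i) {
        s <- sample.int(nchar(ref[[1]]) - 150, 1)
        rd <- substr(ref[[1]], s + 1, s + 150)
        if (i %% 2 == 0)
          rd <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
        rd
      }, character(1)))
  })
  pl <- map_reads(reads, build_index(ref), mapper_config("all_exact"))
  subject <- Biostrings::DNAString(ref[[1]])
  for (i in seq_len(nrow(reads))) {
    fwd <- Biostrings::start(Biostrings::matchPattern(reads$read[i], subject)) - 1
    rev <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(reads$read[i])),
      subject)) - 1
    got <- pl[pl$read_id == reads$id[i], ]
    expect_setequal(got$start[got$strand == "+"], fwd)
    expect_setequal(got$start[got$strand == "-"], rev)
  }
})

test_that("mate length mismatch and invalid configs error", {
  expect_error(mapper_config("all_exact", max_mismatches = 2), "all_exact")
  idx <- build_index(c(ctg = strrep("ACGT", 100)))
  expect_error(
    map_pairs(tibble::tibble(id = c("a", "b"),
                             read1 = c(strrep("A", 150), strrep("A", 100)),
                             read2 = c(strrep("C", 150), strrep("C", 150))),
              idx, mapper_config()),
    "mate length")
})
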