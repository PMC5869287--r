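test_that("depth histograms follow per-base overlap arithmetic", {
  contigs <- tibble::tibble(contig = "c1", length = 100)
  one <- fake_placements(
    tibble::tibble(read_id = "r1", contig = "c1", start = 0, end = 100,
                   strand = "+", mismatches = 0),
    contigs, mode = "best_one", paired = FALSE)
  h1 <- depth_histogram(one)
  expect_equal(h1$depth, 1)
  expect_equal(h1$bases, 100)

  two <- fake_placements(
    tibble::tibble(read_id = c("r1", "r2"), contig = "c1",
                   start = c(0, 40), end = c(60, 100),
                   strand = "+", mismatches = 0),
    contigs, mode = "best_one", paired = FALSE)
  h2 <- depth_histogram(two)
  expect_equal(h2$bases[h2$depth == 1], 80)
  expect_equal(h2$bases[h2$depth == 2], 20)

  # random fixture versus brute-force per-base counting
  withr::with_seed(5, {
    n <- 60
    s <- sample.int(180, n) - 1
    e <- pmin(200, s + sample(10:40, n, replace = TRUE))
    df <- tibble::tibble(read_id = sprintf("r%02d", 1:n), contig = "cx",
                         start = s, end = e, strand = "+", mismatches = 0)
  })
  px <- fake_placements(df, tibble::tibble(contig = "cx", length = 200),
                        mode = "best_one", paired = FALSE)
  hx <- depth_histogram(px)
  depth_vec <- integer(200)
  for (i in seq_len(nrow(df))) {
    span <- (df$start[i] + 1):df$end[i]
    depth_vec[span] <- depth_vec[span] + 1L
  }
  oracle <- table(depth_vec)
  for (d in as.integer(names(oracle))) {
    expect_equal(hx$bases[hx$depth == d], unname(oracle[as.character(d)]))
  }
  expect_error(depth_histogram(fake_placements(
    tibble::tibble(read_id = "r", contig = "c1", start = 50, end = 150,
                   strand = "+", mismatches = 0),
    contigs, mode = "best_one", paired = FALSE)), "beyond contig bounds")
})

test_that("windowed mode coverage matches the printed rule and an exhaustive oracle", {
  h <- tibble::tibble(contig = "c", depth = c(3, 4, 5, 30),
                      bases = c(10, 20, 10, 5))
  expect_equal(mode_coverage(h)$mode, 4)
  # uniform depth reports itself
  hu <- tibble::tibble(contig = "c", depth = 18, bases = 1e4)
  expect_equal(mode_coverage(hu)$mode, 18)
  # all bases below 3x: undefined
  hl <- tibble::tibble(contig = "c", depth = c(0, 1, 2), bases = c(5, 5, 5))
  expect_true(is.na(mode_coverage(hl)$mode))
  # random histograms versus exhaustive scan
  withr::with_seed(8, {
    for (i in 1:200) {
      depth <- sort(sample(0:60, sample(3:12, 1)))
      bases <- sample(0:50, length(depth), replace = TRUE)
      if (all(bases[depth >= 3] == 0)) next
      ht <- tibble::tibble(contig = "c", depth = depth, bases = bases)
      expect_equal(mode_coverage(ht)$mode, oracle_mode(depth, bases))
    }
  })
})

test_that("contig classification uses closed windows and computes h", {
  prof <- tibble::tibble(contig = c("A", "B", "C", "D"),
                         span = c(100, 200, 50, 80),
                         mode = c(18, 36, 70, 24))
  cl <- classify_contigs(prof, coverage_classes(18, 6))
  expect_equal(cl$class, c("SEPARATED", "COLLAPSED", "OTHER", "SEPARATED"))
  expect_equal(attr(cl, "h"), (100 + 80) / 430)
  # boundary modes 12, 24, 30, 42 fall inside their windows
  edge <- classify_contigs(
    tibble::tibble(contig = c("a", "b", "c", "d"), span = 1,
                   mode = c(12, 24, 30, 42)),
    coverage_classes(18, 6))
  expect_equal(edge$class,
               c("SEPARATED", "SEPARATED", "COLLAPSED", "COLLAPSED"))
  expect_error(classify_contigs(prof[1, ], coverage_classes(estimation = "auto")),
               "at least 2")
  # auto estimation recovers the span-weighted modal centre
  auto <- classify_contigs(
    tibble::tibble(contig = letters[1:5], span = c(100, 120, 90, 10, 10),
                   mode = c(18, 18, 17, 36, 70)),
    coverage_classes(estimation = "auto"))
  expect_equal(attr(auto, "center"), 18)
  expect_equal(attr(auto, "halfwidth"), 6)
})

test_that("the genome-size model reproduces the separation arithmetic", {
  gs <- estimate_genome_size(2.25e9, 0.9582)
  expect_equal(gs$haploid_fraction, 0.5209)
  expect_equal(round(100 * gs$haploid_fraction), 52)
  expect_equal(estimate_genome_size(100, 0)$haploid_fraction, 1)
  expect_equal(estimate_genome_size(100, 1)$haploid_fraction, 0.5)
  expect_error(estimate_genome_size(100, 1.2))
})

test_that("N50 and NG50 follow the cumulative-span definition", {
  expect_equal(assembly_stats(10)$n50, 10)
  st <- assembly_stats(c(5, 4, 3, 2, 1), genome_size = 8)
  expect_equal(st$n50, 4)   # 5+4 = 9 >= 15/2
  expect_equal(st$ng50, 5)  # 5 >= 8/2
  expect_error(assembly_stats(numeric(0)))
  expect_warning(assembly_stats(c(5, 4), genome_size = 100), "NG50")
})
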