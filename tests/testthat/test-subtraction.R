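subtraction_refs <- function() {
  memo("subtraction_refs", function() {
    withr::with_seed(41, {
      tx <- setNames(vapply(1:5, function(i) paste(
        sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = ""),
        character(1)), sprintf("tx%d", 1:5))
      gn <- setNames(paste(sample(c("A", "C", "G", "T"), 5e4, replace = TRUE),
                           collapse = ""), "ctg1")
    })
    list(tx = tx, gn = gn)
  })
}

reads_from <- function(seqs, n, prefix, seed) {
  withr::with_seed(seed, {
    src <- sample(seq_along(seqs), n, replace = TRUE)
    s <- vapply(src, function(i) sample.int(nchar(seqs[[i]]) - 150, 1),
                integer(1))
    tibble::tibble(id = sprintf("%s%04d", prefix, seq_len(n)),
                   read = substring(seqs[src], s + 1, s + 150))
  })
}

test_that("reads drawn from the references are removed completely", {
  r <- subtraction_refs()
  tx_reads <- reads_from(r$tx, 300, "t", 1)
  sub <- cascade_filter(tx_reads, r$tx, r$gn)
  expect_equal(sub$report$remaining, 0)
  expect_equal(sub$report$removed_stage1, 300)
})

test_that("an 85/15 host/foreign mix leaves close to 15% with exact accounting", {
  r <- subtraction_refs()
  host <- dplyr::bind_rows(reads_from(r$tx, 300, "ht", 2),
                           reads_from(r$gn, 1400, "hg", 3))
  mix <- dplyr::bind_rows(host, random_reads(300, seed = 4))
  sub <- cascade_filter(mix, r$tx, r$gn)
  expect_lt(abs(sub$report$remaining_fraction - 0.15), 0.01)
  # exact integer conservation across stages
  expect_equal(sub$report$removed_stage1 + sub$report$removed_stage2 +
                 sub$report$remaining, sub$report$total_reads)
  expect_equal(sub$report$removed_stage1_fraction +
                 sub$report$removed_stage2_fraction +
                 sub$report$remaining_fraction, 1)
  # every retained read is foreign by truth label
  expect_true(all(grepl("^foreign", sub$retained$id)))
})

test_that("stage order changes the split but not the retained set", {
  r <- subtraction_refs()
  mix <- dplyr::bind_rows(reads_from(r$tx, 200, "ht", 5),
                          reads_from(r$gn, 600, "hg", 6),
                          random_reads(200, seed = 7))
  ab <- cascade_filter(mix, r$tx, r$gn)
  ba <- cascade_filter(mix, r$gn, r$tx)
  expect_setequal(ab$retained$id, ba$retained$id)
  expect_false(ab$report$removed_stage1 == ba$report$removed_stage1)
})

test_that("growing a reference never increases the remaining fraction", {
  r <- subtraction_refs()
  withr::with_seed(44, {
    extra <- setNames(paste(sample(c("A", "C", "G", "T"), 2e4, replace = TRUE),
                            collapse = ""), "ctg2")
  })
  mix <- dplyr::bind_rows(reads_from(r$gn, 500, "hg", 8),
                          reads_from(c(r$gn, extra), 300, "hx", 9),
                          random_reads(150, seed = 10))
  base <- cascade_filter(mix, r$tx, r$gn)
  grown <- cascade_filter(mix, r$tx, c(r$gn, extra))
  expect_lte(grown$report$remaining_fraction, base$report$remaining_fraction)
})

test_that("taxon ingestion keeps a single best hit per query", {
  retained <- tibble::tibble(id = sprintf("q%02d", 1:6))
  hits <- tibble::tibble(
    query = c("q01", "q01", "q02", "q02", "q03", "q03", "q04"),
    taxon = c("zika", "host", "flavi", "zika", "b", "a", "zika"),
    bitscore = c(50, 40, 60, 60, 70, 70, 90),
    evalue = c(1e-10, 1e-8, 1e-12, 1e-11, 1e-9, 1e-9, 1e-20))
  out <- ingest_taxon_hits(hits, retained)
  a <- setNames(out$assignments$taxon, out$assignments$query)
  expect_equal(unname(a["q01"]), "zika")   # bitscore wins
  expect_equal(unname(a["q02"]), "flavi")  # e-value breaks the tie
  expect_equal(unname(a["q03"]), "a")      # lexicographic fallback
  expect_equal(out$unassigned, 2)
  expect_equal(out$taxa$reads[out$taxa$taxon == "zika"], 2)
  # no rows: everything unassigned
  none <- ingest_taxon_hits(hits[0, ], retained)
  expect_equal(none$unassigned, 6)
  # malformed file rows error with the line number
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q01\tzika\t50\t1e-10", "broken row"), f)
  expect_error(ingest_taxon_hits(f, retained), "line 2")
})

test_that("spike-in recovery: per-taxon counts equal surviving foreign best hits", {
  r <- subtraction_refs()
  mix <- dplyr::bind_rows(reads_from(r$gn, 400, "hg", 11),
                          random_reads(100, seed = 12))
  sub <- cascade_filter(mix, r$tx, r$gn)
  foreign <- sub$retained$id
  hits <- tibble::tibble(query = foreign,
                         taxon = rep(c("zika", "phage"),
                                     length.out = length(foreign)),
                         bitscore = 100, evalue = 1e-30)
  out <- ingest_taxon_hits(hits, sub$retained)
  expect_equal(sum(out$taxa$reads), length(foreign))
  expect_equal(out$taxa$reads[out$taxa$taxon == "zika"],
               sum(hits$taxon == "zika"))
  expect_equal(out$unassigned, 0)
})
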