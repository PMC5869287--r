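#' Simulate transcript read counts with a long-tailed RPKM distribution
#'
#' Per-transcript abundances are drawn log-normally; integer counts are each
#' transcript's read share (abundance times length) of the library. When
#' `total_reads` is `NULL` the library size is calibrated so that the mean
#' RPKM of *expressed* transcripts (RPKM at or above `expressed_threshold`)
#' approaches `mean_rpkm_target`: deeper libraries pull more low-abundance
#' transcripts over the threshold and so lower the mean. Because RPKM sums to
#' `1e9 / sum(length)` over a fully expressed set, targets below that floor
#' are unattainable for a given transcript set (a warning is raised). A
#' configurable zero-inflation set models silent gene families (all members
#' at count 0).
#'
#' @param transcripts Transcript lengths: a named numeric vector, a tibble
#'   with `transcript_id` and `length` columns, or a `DNAStringSet`.
#' @param mean_rpkm_target Target mean RPKM of expressed transcripts
#'   (used when `total_reads` is `NULL`).
#' @param sdlog Log-normal shape parameter of the abundance law.
#' @param zero_inflated Character vector of transcript ids forced to zero.
#' @param total_reads Library size (reads); `NULL` calibrates it against
#'   `mean_rpkm_target`.
#' @param expressed_threshold RPKM floor defining "expressed".
#' @param seed Integer seed; identical seeds reproduce identical tables.
#' @return A tibble with `transcript_id`, `length`, `count`.
#' @export
simulate_expression_counts <- function(transcripts,
                                       mean_rpkm_target = 32,
                                       sdlog = 1.6,
                                       zero_inflated = character(0),
                                       total_reads = NULL,
                                       expressed_threshold = 1,
                                       seed = 1L) {
  tr <- as_transcript_lengths(transcripts)
  hd_assert(nrow(tr) > 0, "transcripts must be non-empty")
  withr::with_seed(seed, {
    a <- rlnorm(nrow(tr), meanlog = 0, sdlog = sdlog)
    a[tr$transcript_id %in% zero_inflated] <- 0
    if (all(a == 0)) {
      return(tibble::tibble(transcript_id = tr$transcript_id,
                            length = tr$length, count = 0))
    }
    # read share of each transcript: abundance times length
    w <- a * tr$length / sum(a * tr$length)
    mean_expressed <- function(t) {
      count <- round(t * w)
      total <- sum(count)
      if (total == 0) return(Inf)
      rpkm <- count * 1e9 / (tr$length * total)
      ex <- rpkm >= expressed_threshold
      if (!any(ex)) return(Inf)
      mean(rpkm[ex])
    }
    t_use <- total_reads
    if (is.null(t_use)) {
      # Calibrate library size: deeper libraries pull more low-abundance
      # transcripts over the expressed threshold, lowering the mean.  The
      # floor (everything expressed) is ~1e9 / sum(lengths); targets below
      # it are unattainable for this transcript set.
      f <- function(lt) mean_expressed(exp(lt)) - mean_rpkm_target
      lo <- log(10); hi <- log(1e9)
      if (f(hi) > 0) {
        t_use <- exp(hi)
        rlang::warn(paste0("mean_rpkm_target ", mean_rpkm_target,
                           " is below the attainable floor ",
                           signif(mean_expressed(exp(hi)), 3),
                           " for this transcript set; using the deepest library"))
      } else if (f(lo) < 0) {
        t_use <- exp(lo)
      } else {
        t_use <- exp(uniroot(f, c(lo, hi))$root)
      }
    }
    tibble::tibble(transcript_id = tr$transcript_id, length = tr$length,
                   count = round(t_use * w))
  })
}

as_transcript_lengths <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    return(tibble::tibble(transcript_id = names(x), length = Biostrings::width(x)))
  }
  if (is.data.frame(x)) {
    hd_assert(all(c("transcript_id", "length") %in% names(x)),
              "transcript tibble needs transcript_id and length columns")
    return(tibble::as_tibble(x[, c("transcript_id", "length")]))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(tibble::tibble(transcript_id = names(x), length = as.numeric(x)))
  }
  if (is.character(x) && !is.null(names(x))) {
    return(tibble::tibble(transcript_id = names(x), length = nchar(x)))
  }
  rlang::abort("cannot interpret transcripts input")
}

#' Transcript sequences for simulated genes
#'
#' Extracts the haplotype-A sequence of every simulated gene, giving a
#' transcript set matched to the synthetic genome (used by the expression and
#' host-subtraction stages).
#'
#' @param genome An `hd_genome` with genes.
#' @return Named character vector of transcript sequences.
#' @export
transcript_sequences <- function(genome) {
  genes <- genome$genes
  hd_assert(!is.null(genes), "the genome was simulated without genes")
  seqs <- vapply(seq_len(nrow(genes)), function(i) {
    substr(genome$hap_a[[genes$chrom[i]]], genes$start[i] + 1, genes$end[i])
  }, character(1))
  setNames(seqs, genes$gene_id)
}
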