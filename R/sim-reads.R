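#' Specification for synthetic short reads
#'
#' Defaults follow a standard 2 x 150 bp paired-end layout. The default
#' fragment length is 350 bp so that mates never overlap; set 270 bp to match
#' a tight-insert library. `depth_total` is fold coverage relative to the
#' *haploid* genome span: fragments are drawn from both haplotypes in equal
#' proportion, so each haplotype receives `depth_total / 2` and a collapsed
#' (single-contig) representation of a locus attracts the full `depth_total`.
#'
#' @param read_length Read length, bp.
#' @param fragment_length_mean,fragment_length_sd Fragment length draw (bp).
#' @param depth_total Fold coverage over the haploid genome span.
#' @param error_rate Per-base substitution error rate.
#' @param layout `"PAIRED"` or `"SINGLE"`.
#' @param sex `"MALE"`, `"FEMALE"` or `"NONE"`. `FEMALE` excludes the
#'   male-limited locus from the fragment source; `MALE` (and `NONE`)
#'   include it when the genome carries one.
#' @param seed Mandatory integer seed.
#' @export
read_sim_spec <- function(read_length = 150,
                          fragment_length_mean = 350,
                          fragment_length_sd = 30,
                          depth_total = 36,
                          error_rate = 0.005,
                          layout = c("PAIRED", "SINGLE"),
                          sex = c("NONE", "MALE", "FEMALE"),
                          seed = 1L) {
  layout <- match.arg(layout)
  sex <- match.arg(sex)
  hd_assert(depth_total > 0, "depth_total must be > 0")
  hd_assert(layout == "SINGLE" || fragment_length_mean >= 2 * read_length,
            "fragment_length_mean must be at least twice read_length (no mate-overlap handling)")
  structure(list(read_length = as.integer(read_length),
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 depth_total = depth_total, error_rate = error_rate,
                 layout = layout, sex = sex, seed = as.integer(seed)),
            class = "hd_read_spec")
}

# Substitution errors on a character vector of reads, at `rate` per base.
add_read_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n_err <- rbinom(length(reads), nchar(reads), rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  reads
}

#' Simulate a short-read set from a diploid genome
#'
#' Fragments are drawn uniformly from both haplotypes in proportion to their
#' lengths. Paired layout emits mates in FR orientation (mate 1 from a random
#' fragment strand). Truth is encoded in the read name with the fixed grammar
#' `p<idx>:<chrom>:<hap>:<start>:<fraglen>:<mate1strand>` (0-based fragment
#' start on the forward strand of the source haplotype).
#'
#' @param genome An `hd_genome`.
#' @param spec A [read_sim_spec()].
#' @return An `hd_reads` tibble with columns `id`, `read1`, `read2` (paired)
#'   or `id`, `read` (single), plus the spec as an attribute.
#' @export
simulate_reads <- function(genome, spec) {
  hd_assert(inherits(genome, "hd_genome"), "genome must be an hd_genome")
  hd_assert(inherits(spec, "hd_read_spec"), "spec must be a read_sim_spec()")
  gspec <- genome$spec
  withr::with_seed(spec$seed, {
    src <- list()
    for (ch in names(genome$hap_a)) {
      a <- genome$hap_a[[ch]]
      if (spec$sex == "FEMALE" && !is.null(genome$m_locus) &&
          ch == genome$m_locus$chrom[1]) {
        a <- substr(a, 1, gspec$chrom_length) # drop the appended m_locus
      }
      src[[paste0(ch, ":A")]] <- a
      src[[paste0(ch, ":B")]] <- genome$hap_b[[ch]]
    }
    src_len <- vapply(src, nchar, integer(1))
    haploid_span <- as.numeric(gspec$n_chromosomes) * gspec$chrom_length
    rl <- spec$read_length
    paired <- spec$layout == "PAIRED"
    yield <- if (paired) 2 * rl else rl
    n_frag <- round(spec$depth_total * haploid_span / yield)
    fl <- if (paired) {
      pmax(2 * rl, round(rnorm(n_frag, spec$fragment_length_mean,
                               spec$fragment_length_sd)))
    } else {
      rep(rl, n_frag)
    }
    hd_assert(max(fl) <= min(src_len),
              "fragment longer than the shortest chromosome")
    si <- sample.int(length(src), n_frag, replace = TRUE, prob = src_len)
    start <- floor(runif(n_frag) * (src_len[si] - fl + 1))
    frags <- character(n_frag)
    for (k in seq_along(src)) {
      sel <- si == k
      if (any(sel)) {
        frags[sel] <- substring(src[[k]], start[sel] + 1, start[sel] + fl[sel])
      }
    }
    ch_hap <- strsplit(names(src)[si], ":", fixed = TRUE)
    s1 <- sample(c("+", "-"), n_frag, replace = TRUE)
    ids <- sprintf("p%07d:%s:%s:%d:%d:%s", seq_len(n_frag),
                   vapply(ch_hap, `[`, character(1), 1),
                   vapply(ch_hap, `[`, character(1), 2),
                   as.integer(start), as.integer(fl), s1)
    if (paired) {
      left <- substr(frags, 1, rl)
      right <- revcomp(substring(frags, fl - rl + 1, fl))
      read1 <- ifelse(s1 == "+", left, right)
      read2 <- ifelse(s1 == "+", right, left)
      out <- tibble::tibble(id = ids,
                            read1 = add_read_errors(read1, spec$error_rate),
                            read2 = add_read_errors(read2, spec$error_rate))
    } else {
      rd <- ifelse(s1 == "+", frags, revcomp(frags))
      out <- tibble::tibble(id = ids, read = add_read_errors(rd, spec$error_rate))
    }
    hd_tbl(out, "hd_reads", read_spec = spec)
  })
}

#' Decode read-name truth
#'
#' @param ids Character vector of simulated read names.
#' @return Tibble with `id`, `chrom`, `hap`, `start`, `frag_len`,
#'   `mate1_strand`.
#' @export
parse_read_names <- function(ids) {
  parts <- stringr::str_split_fixed(ids, stringr::fixed(":"), 6)
  tibble::tibble(id = ids, chrom = parts[, 2], hap = parts[, 3],
                 start = as.numeric(parts[, 4]),
                 frag_len = as.numeric(parts[, 5]),
                 mate1_strand = parts[, 6])
}

#' Random (non-host) reads
#'
#' Uniform random sequence, used as the foreign component of subtraction
#' mixes.
#'
#' @param n Number of reads.
#' @param read_length Read length, bp.
#' @param seed Integer seed.
#' @param prefix Read-name prefix.
#' @export
random_reads <- function(n, read_length = 150, seed = 1L, prefix = "foreign") {
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("%s%07d", prefix, seq_len(n)),
      read = vapply(seq_len(n), function(i) random_dna(read_length),
                    character(1)))
  })
}

#' Write reads to FASTQ
#'
#' Paired tibbles (`read1`/`read2`) are written to two files; `path2` is
#' derived from `path` (`_1`/`_2` infix) when not given. Quality strings are
#' constant (`I`); the simulator does not model base qualities.
#'
#' @param reads An `hd_reads` tibble (or any tibble with `id` and `read`
#'   or `read1`/`read2` columns).
#' @param path Output FASTQ path (mate 1 for paired data).
#' @param path2 Mate-2 path for paired data.
#' @return The written path(s), invisibly.
#' @export
write_fastq <- function(reads, path, path2 = NULL) {
  write_one <- function(seqs, ids, p) {
    x <- Biostrings::DNAStringSet(setNames(seqs, ids))
    q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, p, format = "fastq", qualities = q)
    p
  }
  if ("read" %in% names(reads)) {
    return(invisible(write_one(reads$read, reads$id, path)))
  }
  if (is.null(path2)) {
    path2 <- sub("(\\.[^.]+)$", "_2\\1", path)
    path <- sub("(\\.[^.]+)$", "_1\\1", path)
  }
  write_one(reads$read1, reads$id, path)
  write_one(reads$read2, reads$id, path2)
  invisible(c(path, path2))
}

#' Read FASTQ into a reads tibble
#'
#' @param path FASTQ path (mate 1 for paired input).
#' @param path2 Optional mate-2 FASTQ.
#' @return A tibble with `id` and `read` (or `read1`/`read2`) columns.
#' @export
read_fastq <- function(path, path2 = NULL) {
  r1 <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(r1))
  if (is.null(path2)) {
    return(tibble::tibble(id = ids, read = unname(as.character(r1))))
  }
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  hd_assert(length(r1) == length(r2), "mate FASTQ files differ in length")
  tibble::tibble(id = ids, read1 = unname(as.character(r1)),
                 read2 = unname(as.character(r2)))
}
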