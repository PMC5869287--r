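# Internal helpers shared across modules.

hd_assert <- function(cond, msg, class = "haplodiag_error") {
  if (!isTRUE(cond)) rlang::abort(msg, class = class)
  invisible(TRUE)
}

# Uniform random DNA as a single character string.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Reverse complement for a character vector of sequences.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Coerce contig input (named character vector, DNAStringSet, or FASTA path)
# to an uppercase named character vector.
as_contig_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "DNAStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  hd_assert(is.character(x) && length(x) >= 1L,
            "contigs must be a named character vector, DNAStringSet, or FASTA path")
  hd_assert(!is.null(names(x)) && !anyDuplicated(names(x)),
            "contigs must carry unique names")
  toupper(x)
}

contig_length_tbl <- function(seqs) {
  tibble::tibble(contig = names(seqs), length = unname(nchar(seqs)))
}

# Attribute-preserving class constructor for result tibbles.
hd_tbl <- function(x, subclass, ...) {
  x <- tibble::as_tibble(x)
  extra <- list(...)
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  class(x) <- c(subclass, class(x))
  x
}

#' @export
print.hd_tbl <- function(x, ...) {
  NextMethod()
  invisible(x)
}

# Merge a list of 0-based half-open intervals given as a two-column matrix.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# Total overlap between one interval [s, e) and a set of intervals.
interval_overlap <- function(s, e, starts, ends) {
  if (length(starts) == 0L) return(0)
  sum(pmax(0, pmin(e, ends) - pmax(s, starts)))
}
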