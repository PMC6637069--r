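#' Split a haplotype into dense SNP subsequences by genomic distance
#'
#' SNPs cluster along chromosomes; runs of SNPs whose consecutive genomic
#' distances stay below a threshold r form the dense subsequences the chaos
#' analysis operates on. The sequence is cut between consecutive SNPs i and
#' i+1 exactly when `position[i+1] - position[i] >= r`, so within every
#' subsequence all consecutive distances are strictly less than r. The
#' slices tile the parent: they are disjoint, ordered, and their
#' concatenation restores the full haplotype.
#'
#' @param seq An [allele_seq] with genomic positions.
#' @param r Distance threshold in bp (default 30000).
#' @return A list of `subsequence` objects, each with elements `start`,
#'   `end` (1-based inclusive indices into the parent) and `seq` (the
#'   [allele_seq] slice, positions retained).
#' @export
split_by_distance <- function(seq, r = 30000) {
  pos <- positions(seq)
  if (is.null(pos)) stop("sequence has no genomic positions", call. = FALSE)
  stopifnot(r > 0)
  n <- length(seq)
  if (n == 0L) return(list())
  cuts <- which(diff(pos) >= r)          # cut after these indices
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  mapply(function(s, e) {
    structure(list(start = s, end = e, seq = seq[s:e]), class = "subsequence")
  }, starts, ends, SIMPLIFY = FALSE)
}

#' @export
print.subsequence <- function(x, ...) {
  cat(sprintf("subsequence [%d, %d] (%d SNPs)\n", x$start, x$end,
              length(x$seq)))
  invisible(x)
}

#' Keep subsequences longer than a minimum length
#'
#' The length filter is strict: a subsequence of exactly `thr` SNPs is
#' dropped. The counts before and after filtering are attached so callers
#' can report them per chromosome.
#'
#' @param subs List of `subsequence` objects from [split_by_distance()].
#' @param thr Minimum length threshold (default 800; strictly greater
#'   than).
#' @return The kept subsequences, in order, with attributes `n_total` and
#'   `n_kept`.
#' @export
filter_min_length <- function(subs, thr = 800) {
  stopifnot(thr >= 0)
  keep <- vapply(subs, function(s) length(s$seq) > thr, logical(1))
  structure(subs[keep], n_total = length(subs), n_kept = sum(keep))
}
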