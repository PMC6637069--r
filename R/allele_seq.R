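#' Binary allele sequences
#'
#' An `allele_seq` is the package's representation of a haplotype (or a
#' haplotype subsequence): an ordered vector of alleles over \{0, 1, gap\},
#' optionally annotated with strictly increasing 1-based genomic positions
#' and a chromosome label. Gaps mark sites whose allele is unknown
#' (uncovered or ambiguous in an assembly) and are stored as `NA`.
#'
#' @param alleles Alleles as an integer/numeric vector of 0/1 with `NA` for
#'   gaps, a character vector of `"0"`, `"1"`, `"-"`, or a single string such
#'   as `"0110-01"`.
#' @param positions Optional integer vector of genomic coordinates (1-based,
#'   strictly increasing), one per allele.
#' @param chrom Optional chromosome label (single string).
#' @return An object of class `allele_seq`: an integer vector of 0/1/`NA`
#'   with attributes `positions` and `chrom`.
#' @examples
#' h <- allele_seq("01101-0", positions = c(100, 130, 161, 190, 220, 251, 280))
#' h
#' gap_positions(h)
#' @export
allele_seq <- function(alleles, positions = NULL, chrom = NA_character_) {
  a <- parse_alleles(alleles)
  if (!is.null(positions)) {
    positions <- as.integer(positions)
    if (length(positions) != length(a))
      stop("'positions' must have one entry per allele", call. = FALSE)
    if (length(positions) > 1L && any(diff(positions) <= 0L))
      stop("'positions' must be strictly increasing", call. = FALSE)
  }
  structure(a, positions = positions, chrom = as.character(chrom)[1L],
            class = "allele_seq")
}

parse_alleles <- function(alleles) {
  if (inherits(alleles, "allele_seq")) return(unclass_alleles(alleles))
  if (is.character(alleles)) {
    if (length(alleles) == 1L && (nchar(alleles) > 1L || alleles %in% c("", "0", "1", "-")))
      alleles <- strsplit(alleles, "", fixed = TRUE)[[1L]]
    bad <- !(alleles %in% c("0", "1", "-"))
    if (any(bad))
      stop("unknown allele symbol(s): ",
           paste(unique(alleles[bad]), collapse = ", "), call. = FALSE)
    a <- rep(NA_integer_, length(alleles))
    a[alleles == "0"] <- 0L
    a[alleles == "1"] <- 1L
  } else {
    a <- as.integer(alleles)
    if (any(!is.na(a) & !(a %in% c(0L, 1L))))
      stop("alleles must be 0, 1 or gap", call. = FALSE)
  }
  a
}

unclass_alleles <- function(x) {
  a <- unclass(x)
  attributes(a) <- NULL
  as.integer(a)
}

#' @export
print.allele_seq <- function(x, ...) {
  n <- length(x)
  cat(sprintf("allele_seq: %d sites, %d gaps", n, sum(is.na(x))))
  if (!is.na(chrom(x))) cat(", chrom ", chrom(x), sep = "")
  if (!is.null(positions(x)) && n > 0L)
    cat(sprintf(", span %d-%d", positions(x)[1L], positions(x)[n]))
  cat("\n")
  shown <- min(n, 60L)
  if (n > 0L)
    cat("  ", paste0(as.character(x)[seq_len(shown)], collapse = ""),
        if (n > shown) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.character.allele_seq <- function(x, ...) {
  a <- unclass_alleles(x)
  ifelse(is.na(a), "-", as.character(a))
}

#' @export
`[.allele_seq` <- function(x, i) {
  allele_seq(unclass_alleles(x)[i],
             positions = if (!is.null(positions(x))) positions(x)[i],
             chrom = chrom(x))
}

#' Accessors for allele sequences
#'
#' @param x An [allele_seq].
#' @return `positions()` the genomic coordinates (or `NULL`), `chrom()` the
#'   chromosome label, `gap_positions()` the indices of gap sites,
#'   `allele_string()` the sequence as a single `"01-"` string.
#' @export
positions <- function(x) attr(x, "positions", exact = TRUE)

#' @rdname positions
#' @export
chrom <- function(x) attr(x, "chrom", exact = TRUE)

#' @rdname positions
#' @export
gap_positions <- function(x) which(is.na(unclass_alleles(x)))

#' @rdname positions
#' @export
allele_string <- function(x) paste0(as.character.allele_seq(x), collapse = "")

has_gaps <- function(x) anyNA(unclass_alleles(x))
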