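#' Read a haplotype table
#'
#' The on-disk haplotype format is a TSV with header columns `chrom`,
#' `position`, `allele` (allele one of `0`, `1`, `-`); lines starting with
#' `#` are comments. Positions must be strictly increasing (1-based,
#' VCF-style coordinates).
#'
#' @param path Path to the TSV file.
#' @return An [allele_seq] with positions and chromosome label. An empty
#'   file (or one with only comments/header) yields an empty sequence.
#' @export
read_haplotype_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(allele_seq(integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(fields[[1L]][1L]), "chrom")) {
    fields <- fields[-1L]; lineno <- lineno[-1L]
  }
  if (length(fields) == 0L) return(allele_seq(integer(0)))
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed row(s) (need chrom, position, allele) at line(s): ",
         paste(lineno[nf < 3L], collapse = ", "), call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  al <- vapply(fields, `[[`, "", 3L)
  if (anyNA(pos))
    stop("non-numeric position at line(s): ",
         paste(lineno[is.na(pos)], collapse = ", "), call. = FALSE)
  bad <- !(al %in% c("0", "1", "-"))
  if (any(bad))
    stop("unknown allele symbol at line(s): ",
         paste(lineno[bad], collapse = ", "), call. = FALSE)
  if (length(pos) > 1L && any(diff(pos) <= 0L)) {
    at <- which(diff(pos) <= 0L)[1L] + 1L
    stop("positions not strictly increasing at line ", lineno[at], call. = FALSE)
  }
  allele_seq(al, positions = pos, chrom = chrom[1L])
}

#' @rdname read_haplotype_table
#' @param seq An [allele_seq] to write; sequences without positions get
#'   consecutive 1-based indices.
#' @export
write_haplotype_table <- function(seq, path) {
  a <- as.character.allele_seq(seq)
  pos <- positions(seq) %||% seq_along(a)
  ch <- chrom(seq); if (is.null(ch) || is.na(ch)) ch <- "chrU"
  df <- data.frame(chrom = rep(ch, length(a)), position = pos, allele = a)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the two phased haplotypes of a sample from a VCF
#'
#' Keeps biallelic SNVs whose genotype for `sample` is phased and
#' heterozygous (`0|1` or `1|0`): those are the haplotype-defining sites.
#' Haplotype 1 takes the left genotype allele and haplotype 2 the right;
#' the REF allele is coded 0 and the ALT allele 1. Homozygous, unphased,
#' missing, multi-allelic and indel records are skipped and the skipped
#' count is reported via `message()`.
#'
#' @param path Path to a VCF file (uncompressed or bgzipped).
#' @param sample Sample name; must be present in the VCF.
#' @return A list with elements `h1` and `h2` ([allele_seq]s on the same
#'   positions) and `n_skipped`.
#' @export
read_phased_vcf <- function(path, sample) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (!(sample %in% colnames(gt)))
    stop("sample '", sample, "' not present in VCF (has: ",
         paste(colnames(gt), collapse = ", "), ")", call. = FALSE)
  fix <- vcfR::getFIX(vcf)
  g <- gt[, sample]
  is_snv <- !is.na(fix[, "REF"]) & !is.na(fix[, "ALT"]) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  phased_het <- !is.na(g) & g %in% c("0|1", "1|0")
  keep <- is_snv & phased_het
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    message("read_phased_vcf: skipped ", n_skipped,
            " record(s) (non-SNV, unphased, missing or homozygous)")
  if (!any(keep)) {
    warning("no phased heterozygous SNVs for sample '", sample, "'")
    return(list(h1 = allele_seq(integer(0)), h2 = allele_seq(integer(0)),
                n_skipped = n_skipped))
  }
  pos <- as.integer(fix[keep, "POS"])
  ch <- fix[keep, "CHROM"][1L]
  left <- as.integer(substr(g[keep], 1L, 1L))
  right <- as.integer(substr(g[keep], 3L, 3L))
  list(h1 = allele_seq(left, positions = pos, chrom = ch),
       h2 = allele_seq(right, positions = pos, chrom = ch),
       n_skipped = n_skipped)
}

#' Fragment-matrix text files
#'
#' One read per line: the 1-based start column, a tab, and the read's
#' allele string over `0`, `1`, `-` (internal gaps allowed). Comment lines
#' start with `#`.
#'
#' @param path File path.
#' @param n_sites Total number of SNP columns; defaults to the largest
#'   column touched by any read.
#' @return `read_fragment_matrix()`: a `fragment_matrix` (integer matrix,
#'   `NA` = gap).
#' @export
read_fragment_matrix <- function(path, n_sites = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    mat <- matrix(NA_integer_, 0L, n_sites %||% 0L)
    return(structure(mat, class = c("fragment_matrix", "matrix")))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  starts <- as.integer(vapply(parts, `[[`, "", 1L))
  reads <- vapply(parts, `[[`, "", 2L)
  ends <- starts + nchar(reads) - 1L
  N <- n_sites %||% max(ends)
  mat <- matrix(NA_integer_, length(reads), N)
  for (i in seq_along(reads)) {
    sym <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    mat[i, starts[i]:ends[i]] <- ifelse(sym == "-", NA_integer_, as.integer(sym))
  }
  structure(mat, starts = starts, class = c("fragment_matrix", "matrix"))
}

#' @rdname read_fragment_matrix
#' @param frags A `fragment_matrix`.
#' @export
write_fragment_matrix <- function(frags, path) {
  lines <- character(nrow(frags))
  for (i in seq_len(nrow(frags))) {
    row <- frags[i, ]
    cov <- which(!is.na(row))
    if (length(cov) == 0L) stop("read ", i, " covers no site", call. = FALSE)
    span <- cov[1L]:cov[length(cov)]
    sym <- ifelse(is.na(row[span]), "-", as.character(row[span]))
    lines[i] <- paste0(cov[1L], "\t", paste0(sym, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Per-column read coverage of a fragment matrix
#'
#' Coverage of a SNP column is the number of reads whose window covers it,
#' i.e. the count of non-gap entries in that column.
#'
#' @param frags A `fragment_matrix`.
#' @return Integer vector of length `ncol(frags)`.
#' @export
column_coverage <- function(frags) {
  if (nrow(frags) == 0L) return(rep(0L, ncol(frags)))
  as.integer(colSums(!is.na(frags)))
}

#' Majority-vote consensus haplotypes with gaps at ambiguous columns
#'
#' Given a partition of the reads into the two haplotype groups, each
#' column of each group is called by majority vote over its non-gap
#' entries. Columns with zero coverage in a group, or with an exact tie,
#' are emitted as gaps: calling them is deferred to the phase-space
#' gap-filling stage rather than guessed.
#'
#' @param frags A `fragment_matrix` (M reads x N sites).
#' @param partition Integer vector of length M over \{1, 2\} assigning each
#'   read to a haplotype. The partition is an input (simulation truth or an
#'   external assembler's output); this package does not compute one.
#' @return A list with [allele_seq]s `h1` and `h2`, both of length N.
#' @export
consensus_with_gaps <- function(frags, partition) {
  stopifnot(length(partition) == nrow(frags), all(partition %in% c(1L, 2L)))
  call_group <- function(sub) {
    if (nrow(sub) == 0L) return(rep(NA_integer_, ncol(frags)))
    ones <- colSums(sub == 1L, na.rm = TRUE)
    zeros <- colSums(sub == 0L, na.rm = TRUE)
    out <- rep(NA_integer_, ncol(sub))
    out[ones > zeros] <- 1L
    out[zeros > ones] <- 0L
    out  # ties (incl. zero coverage) stay NA
  }
  list(h1 = allele_seq(call_group(frags[partition == 1L, , drop = FALSE])),
       h2 = allele_seq(call_group(frags[partition == 2L, , drop = FALSE])))
}
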