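#' Published chromosome-1 surrogate-test reference table
#'
#' Surrogate-test summary statistics for the 38 dense SNP subsequences of
#' the chromosome 1 haplotype of the NA12878 reference individual:
#' correlation dimension of each original coordinate series, the min/max
#' envelope over 10 phase-randomized surrogates, and the Eckmann largest
#' Lyapunov exponent. These published values serve as a worked example for
#' the chaotic classification rule ([envelope_rejected()] +
#' [classify_chaotic()]): applying it to the table flags 28 of the 38
#' subsequences (about 74 percent) as chaotic.
#'
#' @return A `data.frame` with columns `id`, `d2_original`, `d2_surr_min`,
#'   `d2_surr_max`, `lle`.
#' @examples
#' ref <- chr1_surrogate_reference()
#' flags <- classify_chaotic(
#'   envelope_rejected(ref$d2_original, ref$d2_surr_min, ref$d2_surr_max),
#'   ref$lle)
#' 100 * mean(flags)
#' @export
chr1_surrogate_reference <- function() {
  path <- system.file("extdata", "chr1_surrogate_reference.tsv",
                      package = "hapcgr", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
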