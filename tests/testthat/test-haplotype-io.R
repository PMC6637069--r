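test_that("haplotype tables round-trip bit-exactly and reject malformed input", {
  h <- make_clustered_haplotype(seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(h, path)
  back <- read_haplotype_table(path)
  expect_identical(pa(back), pa(h))
  expect_identical(positions(back), positions(h))
  expect_identical(chrom(back), chrom(h))

  # second write of the re-read sequence is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(back, path2)
  expect_identical(readLines(path), readLines(path2))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# just a comment"), empty)
  expect_length(read_haplotype_table(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tallele", "chr1\t10\t0", "chr1\t5\t1"), bad)
  expect_error(read_haplotype_table(bad), "strictly increasing at line 3")

  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tposition\tallele", "chr1\t10\t2"), bad2)
  expect_error(read_haplotype_table(bad2), "allele symbol at line")
})

test_that("gaps survive the table round trip", {
  h <- allele_seq("01-0-1", positions = c(5, 9, 14, 20, 33, 47), chrom = "chr9")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(h, path)
  expect_identical(allele_string(read_haplotype_table(path)), "01-0-1")
})

test_that("phased VCF extraction keeps only phased heterozygous SNVs", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path)
  res <- suppressMessages(read_phased_vcf(path, "NA00001"))
  # kept: 100 (0|1), 200 (1|0), 600 (0|1); skipped: hom 1|1, unphased 0/1, indel
  expect_identical(positions(res$h1), c(100L, 200L, 600L))
  expect_identical(pa(res$h1), c(0L, 1L, 0L))
  expect_identical(pa(res$h2), c(1L, 0L, 1L))
  expect_identical(res$n_skipped, 3L)
  expect_error(suppressMessages(read_phased_vcf(path, "nope")), "not present")
})

test_that("fragment matrix text IO round-trips and coverage counts non-gap entries", {
  h1 <- gen_random_binary(0.5, 30, seed = 1)
  h2 <- allele_seq(1L - pa(h1))
  fm <- gen_fragment_matrix(h1, h2, read_len = 6, err_rate = 0.1,
                            target_coverage = 3, seed = 8)
  path <- withr::local_tempfile(fileext = ".txt")
  write_fragment_matrix(fm, path)
  back <- read_fragment_matrix(path, n_sites = 30)
  expect_identical(unname(unclass(back)[, ]), unname(unclass(fm)[, ]))
  expect_identical(column_coverage(back), as.integer(colSums(!is.na(fm))))
})

test_that("consensus applies the majority / tie-to-gap / zero-coverage rules", {
  # columns: majority 1, majority 0, tie, uncovered-by-group-1
  m <- rbind(c(1L, 0L, 0L, NA),
             c(1L, 0L, 1L, NA),
             c(0L, NA, NA, NA),
             c(NA, 1L, 1L, 1L))
  frags <- structure(m, class = c("fragment_matrix", "matrix"))
  cons <- consensus_with_gaps(frags, partition = c(1L, 1L, 1L, 2L))
  expect_identical(pa(cons$h1), c(1L, 0L, NA, NA))
  expect_identical(pa(cons$h2), c(NA, 1L, 1L, 1L))
})
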