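# shared fixture builders; everything is generated in code at test time

pa <- function(x) hapcgr:::parse_alleles(x)

# haplotype with known cluster structure for IO / extraction tests
make_clustered_haplotype <- function(seed = 1L, n_clusters = 3L,
                                     cluster_sizes = c(5L, 9L)) {
  pos <- gen_snp_positions(n_clusters, cluster_sizes,
                           within_gap = c(10L, 200L),
                           between_gap = c(30000L, 40000L), seed = seed)
  al <- gen_random_binary(0.5, length(pos), seed = seed + 17L)
  allele_seq(pa(al), positions = pos, chrom = "chrT")
}

# minimal phased VCF written as text (synthetic records)
write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tNA00001",
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0|1",
    "chr1\t200\t.\tC\tT\t50\tPASS\t.\tGT\t1|0",
    "chr1\t300\t.\tG\tA\t50\tPASS\t.\tGT\t1|1",
    "chr1\t400\t.\tT\tC\t50\tPASS\t.\tGT\t0/1",
    "chr1\t500\t.\tA\tAT\t50\tPASS\t.\tGT\t0|1",
    "chr1\t600\t.\tG\tC\t50\tPASS\t.\tGT\t0|1"
  ), path)
  path
}
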