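test_that("chaotic map generator matches hand iteration and is seed-deterministic", {
  s <- gen_chaotic_binary("logistic", n = 3, burn_in = 0, x0 = 0.3)
  expect_equal(attr(s, "orbit"), c(0.84, 0.5376, 0.99434496), tolerance = 1e-12)
  expect_identical(allele_string(s), "111")

  expect_length(gen_chaotic_binary("logistic", n = 0, seed = 1), 0L)
  expect_error(gen_chaotic_binary("logistic", n = -1, seed = 1), "non-negative")

  a <- gen_chaotic_binary("logistic", 500, seed = 42)
  b <- gen_chaotic_binary("logistic", 500, seed = 42)
  expect_identical(pa(a), pa(b))
  expect_identical(attr(a, "orbit"), attr(b, "orbit"))

  # symbol balance follows the symmetric invariant density
  long <- gen_chaotic_binary("logistic", 10000, seed = 7)
  expect_lt(abs(mean(pa(long)) - 0.5), 0.05)

  # tent and henon orbits stay on their attractors
  expect_true(all(attr(gen_chaotic_binary("tent", 200, seed = 3), "orbit") <= 1))
  h <- gen_chaotic_binary("henon", 200, seed = 3)
  expect_true(all(abs(attr(h, "orbit")) < 1.5))
})

test_that("Bernoulli generator respects p and the seed contract", {
  expect_identical(allele_string(gen_random_binary(0, 5, seed = 1)), "00000")
  expect_identical(allele_string(gen_random_binary(1, 3, seed = 1)), "111")
  expect_error(gen_random_binary(1.2, 5, seed = 1), "probability")
  expect_lt(abs(mean(pa(gen_random_binary(0.3, 10000, seed = 5))) - 0.3), 0.02)
  expect_identical(pa(gen_random_binary(0.5, 100, seed = 9)),
                   pa(gen_random_binary(0.5, 100, seed = 9)))
})

test_that("Markov generator produces persistent runs", {
  s <- pa(gen_markov_binary(5000, p_stay = 0.9, seed = 2))
  expect_gt(mean(s[-1] == s[-length(s)]), 0.85)
  s2 <- pa(gen_markov_binary(5000, p_stay = 0.5, seed = 2))
  expect_lt(abs(mean(s2[-1] == s2[-length(s2)]) - 0.5), 0.05)
})

test_that("SNP position generator yields the constructed cluster structure", {
  pos <- gen_snp_positions(1, 3, within_gap = 10, between_gap = 30000, seed = 1)
  expect_identical(as.integer(pos), c(1000L, 1010L, 1020L))

  expect_length(gen_snp_positions(0, 3, 10, 30000, seed = 1), 0L)
  expect_error(gen_snp_positions(2, 3, within_gap = c(10, 40000),
                                 between_gap = 30000, seed = 1), "below")

  for (seed in 1:5) {
    pos <- gen_snp_positions(4, c(3, 8), within_gap = c(50, 29000),
                             between_gap = c(30000, 50000), seed = seed)
    expect_true(all(diff(pos) > 0))
    sizes <- attr(pos, "cluster_sizes")
    bounds <- cumsum(sizes)
    gaps <- diff(pos)
    between <- gaps[bounds[-length(bounds)]]
    within <- gaps[-bounds[-length(bounds)]]
    expect_true(all(between >= 30000))
    expect_true(all(within < 30000))
    # the distance rule recovers exactly the constructed clusters
    h <- allele_seq(rep(0L, length(pos)), positions = pos)
    subs <- split_by_distance(h, r = 30000)
    expect_length(subs, 4L)
    expect_identical(vapply(subs, function(s) length(s$seq), integer(1)),
                     as.integer(sizes))
  }
})

test_that("binomial cascade masses are exact and refine consistently", {
  cm <- gen_cascade_measure(0.5, 3)
  expect_equal(cm$cell_masses, rep(0.125, 8))
  cm2 <- gen_cascade_measure(0.7, 1)
  expect_equal(cm2$cell_masses, c(0.7, 0.3))
  expect_error(gen_cascade_measure(1.2, 3), "inside")
  expect_error(gen_cascade_measure(0.7, 0), "depth")

  d9 <- gen_cascade_measure(0.7, 9)$cell_masses
  d10 <- gen_cascade_measure(0.7, 10)$cell_masses
  expect_equal(sum(d10), 1, tolerance = 1e-12)
  # depth-10 masses refine depth-9 masses by (p, 1-p)
  expect_equal(d10[seq(1, length(d10), by = 2)], 0.7 * d9, tolerance = 1e-14)
  expect_equal(d10[seq(2, length(d10), by = 2)], 0.3 * d9, tolerance = 1e-14)

  pts <- sample_cascade_points(gen_cascade_measure(0.7, 10), 100, seed = 3)
  expect_true(all(pts >= 0 & pts <= 1))
  expect_identical(pts, sample_cascade_points(gen_cascade_measure(0.7, 10),
                                              100, seed = 3))
})

test_that("fragment simulator reproduces parents without error and leaves gaps elsewhere", {
  h1 <- gen_random_binary(0.5, 40, seed = 1)
  h2 <- allele_seq(1L - pa(h1))
  fm <- gen_fragment_matrix(h1, h2, n_reads = 1, read_len = 40,
                            err_rate = 0, seed = 5)
  expect_identical(as.integer(fm[1, ]), pa(if (attr(fm, "parents") == 1) h1 else h2))

  fm0 <- gen_fragment_matrix(h1, h2, n_reads = 0, read_len = 10, seed = 1)
  expect_identical(column_coverage(fm0), rep(0L, 40))
  expect_error(gen_fragment_matrix(h1, h2, n_reads = 5, read_len = 99),
               "between 1 and")

  # error-free consensus with the true partition recovers both parents
  fm5 <- gen_fragment_matrix(h1, h2, read_len = 8, err_rate = 0,
                             target_coverage = 5, seed = 11)
  cons <- consensus_with_gaps(fm5, attr(fm5, "parents"))
  cov1 <- column_coverage(fm5[attr(fm5, "parents") == 1L, , drop = FALSE])
  cov2 <- column_coverage(fm5[attr(fm5, "parents") == 2L, , drop = FALSE])
  got1 <- pa(cons$h1); got2 <- pa(cons$h2)
  expect_true(all(got1[!is.na(got1)] == pa(h1)[!is.na(got1)]))
  expect_true(all(got2[!is.na(got2)] == pa(h2)[!is.na(got2)]))
  expect_true(all(is.na(got1[cov1 == 0L])))

  # low coverage leaves zero-coverage columns
  fml <- gen_fragment_matrix(h1, h2, read_len = 4, err_rate = 0,
                             target_coverage = 0.5, seed = 2)
  expect_gt(sum(column_coverage(fml) == 0L), 0L)
})
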