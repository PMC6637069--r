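test_that("corruption blanks the rounded fraction of distinct positions", {
  h <- gen_random_binary(0.5, 800, seed = 1)
  cr <- corrupt_with_gaps(h, 0.10, seed = 2)
  expect_length(cr$mask, 80L)
  expect_identical(gap_positions(cr$seq), cr$mask)
  expect_identical(pa(cr$seq)[-cr$mask], pa(h)[-cr$mask])

  cr0 <- corrupt_with_gaps(h, 0, seed = 2)
  expect_length(cr0$mask, 0L)
  expect_identical(pa(cr0$seq), pa(h))
  cr1 <- corrupt_with_gaps(h, 1, seed = 2)
  expect_true(all(is.na(pa(cr1$seq))))
  expect_error(corrupt_with_gaps(cr1$seq, 0.1), "already contains")
  # identical seed, identical mask
  expect_identical(corrupt_with_gaps(h, 0.1, seed = 9)$mask,
                   corrupt_with_gaps(h, 0.1, seed = 9)$mask)
})

test_that("gap coordinates initialize from flanking neighbors", {
  mid <- initialize_gap_coordinates(
    coordinate_series(c(0.2, NA, 0.6), defined = c(TRUE, FALSE, TRUE)))
  expect_equal(mid$values, c(0.2, 0.4, 0.6))
  lead <- initialize_gap_coordinates(
    coordinate_series(c(NA, 0.3, 0.5), defined = c(FALSE, TRUE, TRUE)))
  expect_equal(lead$values[1L], 0.3)
  run <- initialize_gap_coordinates(
    coordinate_series(c(0.2, NA, NA, 0.6),
                      defined = c(TRUE, FALSE, FALSE, TRUE)))
  expect_equal(run$values, c(0.2, 0.4, 0.4, 0.6))
  expect_identical(attr(run, "gap_indices"), c(2L, 3L))
  expect_error(initialize_gap_coordinates(
    coordinate_series(c(NA, NA), defined = c(FALSE, FALSE))), "degenerate")
})

test_that("local projection is idempotent on data already on an affine subspace", {
  lin <- seq(0, 1, length.out = 200)
  out <- local_projection_fill(coordinate_series(lin), 50:60,
                               gap_fill_config(embed = embedding_params(1, 2)))
  expect_equal(out$values, lin, tolerance = 1e-12)
})

test_that("local projection reduces gap-position error on a noisy limit cycle", {
  set.seed(51)
  n <- 2000
  truth <- 0.5 + 0.4 * sin(2 * pi * (1:n) / 100)
  noisy <- truth + rnorm(n, 0, 0.05)
  mask <- sort(sample(n, 200))
  vals <- noisy; vals[mask] <- NA
  ini <- initialize_gap_coordinates(
    coordinate_series(vals, defined = !is.na(vals)))
  rmse_init <- sqrt(mean((ini$values[mask] - truth[mask])^2))
  ref <- suppressMessages(local_projection_fill(ini, mask, gap_fill_config()))
  rmse_lp <- sqrt(mean((ref$values[mask] - truth[mask])^2))
  expect_lt(rmse_lp, rmse_init)
})

test_that("thresholding decodes the midpoint rule with the boundary at zero", {
  expect_identical(threshold_to_alleles(c(0.5, 0.49, 0.51)), c(0L, 0L, 1L))
  expect_warning(out <- threshold_to_alleles(c(-0.2, 1.3)), "clamped")
  expect_identical(out, c(0L, 1L))
})

test_that("reconstruction rates are plain proportions over mask and sequence", {
  orig <- allele_seq("0101010101")
  perfect <- reconstruction_rate(orig, orig, c(2L, 5L))
  expect_equal(perfect$rate_gaps, 1)
  expect_equal(perfect$rate_overall, 1)

  flipped <- pa(orig); flipped[1L] <- 1L
  rr <- reconstruction_rate(orig, allele_seq(flipped), 1L)
  expect_equal(rr$rate_gaps, 0)
  expect_equal(rr$rate_overall, 0.9)

  threequarters <- pa(allele_seq(strrep("0", 40)))
  threequarters[1L] <- 1L
  rr2 <- reconstruction_rate(allele_seq(strrep("0", 40)),
                             allele_seq(threequarters), c(1L, 2L, 3L, 4L))
  expect_equal(rr2$rate_gaps, 0.75)
  expect_error(reconstruction_rate(orig, allele_seq("01"), 1L), "length")
})

test_that("the full fill pipeline never alters non-gap alleles and is deterministic", {
  for (seed in c(3L, 4L)) {
    h <- gen_markov_binary(600, 0.9, seed = seed)
    cr <- corrupt_with_gaps(h, 0.1, seed = seed + 100L)
    res <- suppressWarnings(suppressMessages(fill_gaps(cr$seq)))
    expect_identical(gap_positions(res$filled), integer(0))
    expect_identical(pa(res$filled)[-cr$mask], pa(h)[-cr$mask])
    res2 <- suppressWarnings(suppressMessages(fill_gaps(cr$seq)))
    expect_identical(pa(res$filled), pa(res2$filled))
    expect_identical(res$cs, res2$cs)
  }
})

test_that("constant sequences are recovered exactly", {
  for (sym in c("0", "1")) {
    h <- allele_seq(strrep(sym, 300))
    cr <- corrupt_with_gaps(h, 0.1, seed = 6)
    res <- suppressWarnings(suppressMessages(fill_gaps(cr$seq)))
    expect_identical(allele_string(res$filled), strrep(sym, 300))
    rr <- reconstruction_rate(h, res$filled, cr$mask)
    expect_equal(rr$rate_gaps, 1)
  }
})

test_that("persistent Markov haplotypes are recovered far above the majority baseline", {
  # neighbor-correlated alleles (the linkage-disequilibrium-like regime the
  # method targets) are where phase-space imputation pays off
  rates <- vapply(1:6, function(sd) {
    h <- gen_markov_binary(800, 0.9, seed = sd)
    cr <- corrupt_with_gaps(h, 0.1, seed = 500L + sd)
    res <- suppressWarnings(suppressMessages(fill_gaps(cr$seq)))
    a <- pa(h)
    maj <- as.integer(mean(a[-cr$mask]) > 0.5)
    c(rate = reconstruction_rate(h, res$filled, cr$mask)$rate_gaps,
      base = mean(a[cr$mask] == maj))
  }, numeric(2))
  expect_gt(mean(rates["rate", ]) - mean(rates["base", ]), 0.10)
})

test_that("fill on i.i.d. fair-coin input hovers at chance (no structure to exploit)", {
  rates <- vapply(1:6, function(sd) {
    h <- gen_random_binary(0.5, 600, seed = sd)
    cr <- corrupt_with_gaps(h, 0.1, seed = 700L + sd)
    res <- suppressWarnings(suppressMessages(fill_gaps(cr$seq)))
    reconstruction_rate(h, res$filled, cr$mask)$rate_gaps
  }, numeric(1))
  expect_gt(mean(rates), 0.35)
  expect_lt(mean(rates), 0.65)
})
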