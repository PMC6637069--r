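test_that("correlation sum counts admissible pairs under the Heaviside kernel", {
  two <- matrix(c(0, 1), ncol = 1)
  expect_equal(as.numeric(correlation_sum(two, radii = 2)), 1)
  expect_equal(as.numeric(correlation_sum(two, radii = 0.5)), 0)

  three <- matrix(c(0, 1, 2), ncol = 1)
  expect_equal(as.numeric(correlation_sum(three, radii = 1.5)), 2 / 3)
  # saturation: a radius beyond every pair distance gives exactly 1
  expect_equal(as.numeric(correlation_sum(three, radii = 10)), 1)

  # monotone non-decreasing in r; invariant under point permutation (w = 0)
  set.seed(31)
  Y <- matrix(runif(200), ncol = 2)
  r <- radii_grid(hapcgr:::pairwise_distances(Y, 0L))
  C <- correlation_sum(Y, r)
  expect_true(all(diff(C) >= 0))
  Cp <- correlation_sum(Y[sample(nrow(Y)), ], r)
  expect_equal(as.numeric(C), as.numeric(Cp))

  # Theiler window drops temporally close pairs from the normalization
  expect_error(correlation_sum(two, radii = 1, theiler = 5), "Theiler")
})

test_that("D2 recovers an exact power law to machine precision", {
  r <- exp(seq(log(0.01), log(1), length.out = 24))
  est <- estimate_correlation_dimension(r, r^1.5)
  expect_equal(est$D2, 1.5, tolerance = 1e-12)
  expect_false(est$low_confidence)
})

test_that("D2 of uniform samples matches the geometric dimension", {
  set.seed(32)
  Y1 <- matrix(runif(2000), ncol = 1)
  d1 <- hapcgr:::pairwise_distances(Y1, 0L)
  r1 <- radii_grid(d1)
  e1 <- estimate_correlation_dimension(r1, correlation_sum(Y1, r1))
  expect_gt(e1$D2, 0.9); expect_lt(e1$D2, 1.1)

  Y2 <- matrix(runif(4000), ncol = 2)
  d2 <- hapcgr:::pairwise_distances(Y2, 0L)
  r2 <- radii_grid(d2)
  e2 <- estimate_correlation_dimension(r2, correlation_sum(Y2, r2))
  expect_gt(e2$D2, 1.8); expect_lt(e2$D2, 2.1)
})

test_that("Eckmann exponent matches analytic values on canonical systems", {
  # logistic map: lambda = ln 2 (modest length keeps the unit suite fast;
  # the acceptance suite re-runs this at n = 5000)
  orb <- attr(gen_chaotic_binary("logistic", 2000, seed = 7), "orbit")
  ly <- lyapunov_eckmann(orb, embed = embedding_params(1, 1))
  expect_lt(abs(ly$lle - log(2)), 0.1)
  expect_identical(ly$lle, ly$spectrum[1L])

  # limit cycle: largest exponent is not positive
  sn <- sin(2 * pi * (1:3000) / 100)
  ly2 <- lyapunov_eckmann(sn, embed = embedding_params(25, 2))
  expect_lt(ly2$lle, 0.05)
  expect_true(!is.unsorted(rev(ly2$spectrum)))

  expect_error(lyapunov_eckmann(rnorm(30), embed = embedding_params(1, 2)),
               "too short")
})

test_that("surrogates preserve the amplitude spectrum, mean and variance", {
  for (len in c(128L, 255L)) {  # even and odd lengths
    x <- cgr_encode_binary(gen_random_binary(0.5, len, seed = len))$values
    surr <- generate_surrogates(x, n = 5, seed = 99)
    amp <- Mod(stats::fft(x))
    for (s in surr) {
      expect_lt(max(abs(Mod(stats::fft(s)) - amp)), 1e-8)
      expect_lt(abs(mean(s) - mean(x)), 1e-10)
      expect_equal(stats::var(s), stats::var(x), tolerance = 1e-8)
      expect_true(all(abs(Im(s)) == 0))
    }
    # distinct seeds give distinct phase draws
    s1 <- generate_surrogates(x, n = 1, seed = 1)[[1L]]
    s2 <- generate_surrogates(x, n = 1, seed = 2)[[1L]]
    expect_gt(max(abs(s1 - s2)), 1e-8)
  }
  const <- rep(0.4, 64)
  expect_equal(generate_surrogates(const, n = 2, seed = 1)[[1L]], const)
})

test_that("envelope rule rejects on or outside the surrogate range and sorts inverted bounds", {
  ref <- chr1_surrogate_reference()
  rej <- envelope_rejected(ref$d2_original, ref$d2_surr_min, ref$d2_surr_max)
  # below the envelope
  expect_true(rej[ref$id == "S1"])
  # strictly inside
  expect_false(rej[ref$id == "S23"])
  expect_false(rej[ref$id == "S10"])
  # boundary equality counts as rejection
  expect_true(rej[ref$id == "S26"])
  expect_true(rej[ref$id == "S37"])
  # inverted bounds (min > max) are sorted before comparison
  expect_true(rej[ref$id == "S3"])
  expect_true(envelope_rejected(0.1, 0.5, 0.2))
  expect_false(envelope_rejected(0.3, 0.5, 0.2))
})

test_that("chaotic classification requires both rejection and a positive exponent", {
  ref <- chr1_surrogate_reference()
  rej <- envelope_rejected(ref$d2_original, ref$d2_surr_min, ref$d2_surr_max)
  flags <- classify_chaotic(rej, ref$lle)
  expect_true(flags[ref$id == "S1"])    # rejected, LLE > 0
  expect_false(flags[ref$id == "S4"])   # rejected, LLE < 0
  expect_false(flags[ref$id == "S23"])  # not rejected despite LLE > 0
})

test_that("surrogate test evaluates all surrogates on the original's grid", {
  x <- cgr_encode_binary(gen_markov_binary(600, 0.9, seed = 5))$values
  st <- suppressMessages(surrogate_test(x, n = 6, seed = 11))
  expect_length(st$d2_surrogates, 6L)
  expect_identical(st$d2_min, min(st$d2_surrogates))
  expect_identical(st$d2_max, max(st$d2_surrogates))
  expect_identical(st$rejected,
                   envelope_rejected(st$d2_original, st$d2_min, st$d2_max))
  # identical seed reproduces the identical result
  st2 <- suppressMessages(surrogate_test(x, n = 6, seed = 11))
  expect_identical(st$d2_surrogates, st2$d2_surrogates)
})

test_that("chaos report returns one typed row per subsequence, even when empty", {
  empty <- chaos_report(list())
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty),
                   c("id", "length", "tau", "m", "d2_original", "d2_surr_min",
                     "d2_surr_max", "lle", "is_chaotic"))
  h <- gen_markov_binary(450, 0.9, seed = 8)
  subs <- list(structure(list(start = 1L, end = 450L, seq = h),
                         class = "subsequence"))
  rep1 <- suppressMessages(chaos_report(subs, n_surrogates = 4L, seed = 3))
  expect_identical(nrow(rep1), 1L)
  expect_identical(rep1$length, 450L)
  expect_identical(rep1$is_chaotic, rep1$lle > 0 &&
                     envelope_rejected(rep1$d2_original, rep1$d2_surr_min,
                                       rep1$d2_surr_max))
})
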