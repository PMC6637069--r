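#' Pairwise maximum-norm distances of delay vectors
#'
#' Distances for all admissible pairs (i < j with |i - j| > theiler); the
#' Theiler window removes temporally correlated pairs from the correlation
#' sum. Maximum norm is used throughout the correlation-dimension code.
#'
#' @param vectors Delay-vector matrix (rows = points).
#' @param theiler Theiler exclusion window (0 = only i = j excluded).
#' @return Numeric vector of pair distances.
#' @keywords internal
pairwise_distances <- function(vectors, theiler = 0L) {
  n <- nrow(vectors)
  m <- ncol(vectors)
  theiler <- as.integer(theiler)
  if (n - theiler < 2L) return(numeric(0))
  out <- vector("list", n - 1L - theiler)
  k <- 0L
  for (lag in (theiler + 1L):(n - 1L)) {
    idx <- seq_len(n - lag)
    d <- abs(vectors[idx, 1L] - vectors[idx + lag, 1L])
    if (m > 1L) for (j in 2L:m)
      d <- pmax(d, abs(vectors[idx, j] - vectors[idx + lag, j]))
    k <- k + 1L
    out[[k]] <- d
  }
  unlist(out, use.names = FALSE)
}

#' Correlation sum C(r) of an embedded point set
#'
#' C(r) is the fraction of admissible point pairs closer than r (Heaviside
#' kernel, maximum norm). Normalization is over the admissible-pair count,
#' which reduces to 2 / (N (N - 1)) of the raw pair sum when `theiler = 0`.
#'
#' @param vectors Delay-vector matrix (>= 2 rows).
#' @param radii Positive, sorted radius grid.
#' @param theiler Theiler window (pairs with |i - j| <= theiler excluded).
#' @return Numeric vector C(r) with attribute `n_pairs`.
#' @export
correlation_sum <- function(vectors, radii, theiler = 0L) {
  if (is.vector(vectors)) vectors <- matrix(vectors, ncol = 1L)
  stopifnot(nrow(vectors) >= 2L, all(radii > 0), !is.unsorted(radii))
  d <- pairwise_distances(vectors, theiler)
  if (length(d) == 0L)
    stop("no admissible pairs: Theiler window too wide for this series",
         call. = FALSE)
  C <- vapply(radii, function(r) sum(d < r), numeric(1)) / length(d)
  attr(C, "n_pairs") <- length(d)
  C
}

#' Log-spaced radius grid from the pairwise-distance distribution
#'
#' @param dists Pair distances.
#' @param n Number of radii (default 24).
#' @param probs Quantile range anchoring the grid (default 1st and 99th
#'   percentile).
#' @return Sorted radius vector.
#' @export
radii_grid <- function(dists, n = 24L, probs = c(0.01, 0.99)) {
  qs <- stats::quantile(dists, probs, names = FALSE)
  pos <- dists[dists > 0]
  if (length(pos) == 0L) stop("all pair distances are zero", call. = FALSE)
  if (qs[1L] <= 0) qs[1L] <- min(pos)
  if (qs[2L] <= qs[1L]) qs[2L] <- max(pos) * (1 + 1e-9)
  exp(seq(log(qs[1L]), log(qs[2L]), length.out = n))
}

#' Correlation-dimension estimate from a C(r) grid
#'
#' D2 is the slope of log C(r) against log r over the linear scaling
#' region, located between the depopulated small-r end (no pairs) and the
#' saturated large-r end (C ~ 1). The scaling region is found as the
#' longest contiguous run of local slopes whose deviation from the run
#' mean stays below `slope_tol`; D2 is then the least-squares slope over
#' that run. If no run of at least `min_points` radii qualifies, the fit
#' uses all unsaturated radii and the result carries
#' `low_confidence = TRUE`.
#'
#' @param radii Radius grid.
#' @param corr_sum C(r) values on that grid.
#' @param slope_tol Maximum deviation of a local slope from the run mean.
#' @param min_points Minimum radii in an acceptable scaling region.
#' @param saturation C(r) above this is treated as saturated.
#' @return A `corr_dim` object: `radii`, `corr_sum`, `fit_range` (radius
#'   interval used), `D2`, `slope_stderr`, `low_confidence`.
#' @export
estimate_correlation_dimension <- function(radii, corr_sum, slope_tol = 0.3,
                                           min_points = 5L,
                                           saturation = 0.999) {
  keep <- which(corr_sum > 0 & corr_sum <= saturation)
  if (length(keep) < 3L) {
    # degenerate: fall back to any informative radii
    keep <- which(corr_sum > 0)
    keep <- keep[cumsum(c(TRUE, diff(corr_sum[keep]) != 0)) > 0]
  }
  if (length(keep) < 2L)
    stop("correlation sum is uninformative on this radius grid", call. = FALSE)
  lr <- log(radii[keep]); lc <- log(corr_sum[keep])
  sl <- diff(lc) / diff(lr)
  best <- NULL
  ns <- length(sl)
  min_sl <- max(1L, min_points - 1L)
  if (ns >= min_sl) {
    for (i in seq_len(ns - min_sl + 1L)) {
      for (j in (i + min_sl - 1L):ns) {
        dev <- max(abs(sl[i:j] - mean(sl[i:j])))
        if (dev < slope_tol) {
          len <- j - i + 1L
          if (is.null(best) || len > best$len ||
              (len == best$len && dev < best$dev))
            best <- list(i = i, j = j, len = len, dev = dev)
        }
      }
    }
  }
  low_confidence <- is.null(best)
  if (low_confidence) {
    pts <- seq_along(keep)
  } else {
    pts <- best$i:(best$j + 1L)
  }
  fit <- stats::lm.fit(cbind(1, lr[pts]), lc[pts])
  D2 <- unname(fit$coefficients[2L])
  res <- fit$residuals
  dfree <- length(pts) - 2L
  se <- if (dfree > 0) {
    sxx <- sum((lr[pts] - mean(lr[pts]))^2)
    sqrt(sum(res^2) / dfree / sxx)
  } else NA_real_
  structure(list(radii = radii, corr_sum = as.numeric(corr_sum),
                 fit_range = range(radii[keep][pts]), D2 = D2,
                 slope_stderr = se, low_confidence = low_confidence),
            class = "corr_dim")
}

#' @export
print.corr_dim <- function(x, ...) {
  cat(sprintf("correlation dimension D2 = %.4f (se %.4f%s), fit on r in [%.3g, %.3g]\n",
              x$D2, x$slope_stderr,
              if (x$low_confidence) ", LOW CONFIDENCE" else "",
              x$fit_range[1L], x$fit_range[2L]))
  invisible(x)
}

#' Correlation dimension of a series (Grassberger-Procaccia)
#'
#' Convenience wrapper: embeds the series, builds the radius grid from the
#' pairwise-distance distribution, computes the correlation sum and
#' estimates D2.
#'
#' @param series Numeric vector or scalar [coordinate_series].
#' @param embed An [embedding_params]; `NULL` selects one automatically.
#' @param theiler Theiler window; default = the embedding delay.
#' @param n_radii Number of radii in the grid.
#' @param radii Optional explicit radius grid (overrides `n_radii`); used
#'   to evaluate surrogates on the identical grid as their original.
#' @param ... Passed to [estimate_correlation_dimension()].
#' @return A `corr_dim` object (with the embedding attached).
#' @export
corr_dim <- function(series, embed = NULL, theiler = NULL, n_radii = 24L,
                     radii = NULL, ...) {
  x <- as_series(series)
  if (is.null(embed)) embed <- select_embedding(x)
  if (is.null(theiler)) theiler <- embed$delay
  Y <- delay_embed(x, embed)
  d <- pairwise_distances(Y, theiler)
  if (length(d) == 0L || all(d == 0))
    stop("degenerate point set: no positive pair distances", call. = FALSE)
  if (is.null(radii)) radii <- radii_grid(d, n = n_radii)
  C <- vapply(radii, function(r) sum(d < r), numeric(1)) / length(d)
  out <- estimate_correlation_dimension(radii, C, ...)
  out$embed <- embed
  out
}

#' Lyapunov spectrum by Eckmann's local-Jacobian method
#'
#' Reconstructs the phase space, fits a local linear map at each
#' evaluation point by least squares from the offsets of its neighbors to
#' the offsets of their images `tau2` steps ahead, and accumulates the
#' Jacobian product along the trajectory with repeated QR decompositions
#' (the numerically stable realization of the eigenvalue prescription for
#' the transposed-product matrix). Exponents are averaged over all
#' evaluation points and reported per iteration step.
#'
#' @param series Numeric vector or scalar [coordinate_series].
#' @param embed An [embedding_params]; `NULL` selects one automatically.
#' @param tau2 Iteration step of the fitted map (default 1).
#' @param min_neighbors Minimum neighborhood size; default 2 (m + 1).
#' @param eps_frac Initial neighborhood radius as a quantile of the
#'   pairwise distances (default 0.05); grown by `eps_factor` until enough
#'   neighbors are found.
#' @param eps_factor Growth factor for the neighborhood radius.
#' @param ridge Tikhonov regularization added to the normal equations of
#'   the local fit (stabilizes rank-deficient neighborhoods, e.g. on limit
#'   cycles).
#' @return A `lyapunov` object: `spectrum` (sorted descending), `lle`, and
#'   the configuration used.
#' @export
lyapunov_eckmann <- function(series, embed = NULL, tau2 = 1L,
                             min_neighbors = NULL, eps_frac = 0.05,
                             eps_factor = 1.3, ridge = 1e-8) {
  x <- as_series(series)
  if (is.null(embed)) embed <- select_embedding(x)
  m <- embed$dimension
  if (is.null(min_neighbors)) min_neighbors <- 2L * (m + 1L)
  Y <- delay_embed(x, embed)
  ne <- nrow(Y)
  tau2 <- as.integer(tau2)
  if (ne <= min_neighbors * 10L)
    stop("series too short for a stable Lyapunov estimate", call. = FALSE)
  # initial neighborhood radius from a deterministic subsample of pair distances
  samp <- if (ne > 1200L) unique(as.integer(round(seq(1L, ne, length.out = 1200L)))) else seq_len(ne)
  d0 <- pairwise_distances(Y[samp, , drop = FALSE], 0L)
  eps0 <- stats::quantile(d0[d0 > 0], eps_frac, names = FALSE)
  evals <- seq(1L, ne - tau2, by = tau2)
  Qmat <- diag(1, m)
  logsum <- numeric(m)
  used <- 0L
  cand <- seq_len(ne - tau2)
  for (j in evals) {
    dj <- abs(Y[cand, 1L] - Y[j, 1L])
    if (m > 1L) for (c2 in 2L:m) dj <- pmax(dj, abs(Y[cand, c2] - Y[j, c2]))
    dj[j] <- Inf
    eps <- eps0
    nb <- which(dj <= eps)
    while (length(nb) < min_neighbors && eps < max(dj[is.finite(dj)])) {
      eps <- eps * eps_factor
      nb <- which(dj <= eps)
    }
    if (length(nb) < min_neighbors) next
    A <- Y[nb, , drop = FALSE] - matrix(Y[j, ], length(nb), m, byrow = TRUE)
    B <- Y[nb + tau2, , drop = FALSE] -
      matrix(Y[j + tau2, ], length(nb), m, byrow = TRUE)
    G <- crossprod(A)
    lam <- ridge * mean(diag(G))
    if (!is.finite(lam) || lam <= 0) lam <- ridge
    DFt <- solve(G + diag(lam, m), crossprod(A, B))  # maps offsets forward
    DF <- t(DFt)
    M <- DF %*% Qmat
    qrd <- qr(M)
    R <- qr.R(qrd)
    dg <- diag(R)
    sgn <- ifelse(dg >= 0, 1, -1)
    Qmat <- qr.Q(qrd) %*% diag(sgn, m)
    logsum <- logsum + log(pmax(abs(dg), 1e-300))
    used <- used + 1L
  }
  if (used == 0L)
    stop("degenerate attractor: no evaluation point had enough neighbors",
         call. = FALSE)
  spectrum <- sort(logsum / (used * tau2), decreasing = TRUE)
  structure(list(spectrum = spectrum, lle = spectrum[1L],
                 config = list(embed = embed, tau2 = tau2,
                               min_neighbors = min_neighbors,
                               eps0 = eps0, n_evaluations = used)),
            class = "lyapunov")
}

#' @export
print.lyapunov <- function(x, ...) {
  cat(sprintf("Eckmann Lyapunov spectrum (m = %d): %s; LLE = %.4f\n",
              length(x$spectrum),
              paste(sprintf("%.4f", x$spectrum), collapse = ", "), x$lle))
  invisible(x)
}

#' Phase-randomized (Fourier) surrogate series
#'
#' Each surrogate keeps the original amplitude spectrum (hence mean,
#' variance and autocorrelation) but replaces the phases of the positive
#' frequencies by i.i.d. uniform draws, enforcing conjugate symmetry so
#' the inverse transform is real; the zero-frequency and Nyquist
#' components are kept real. Surrogates realize the null hypothesis of a
#' linear Gaussian stochastic process with the same spectrum.
#'
#' @param series Numeric vector or scalar [coordinate_series] (length
#'   >= 8).
#' @param n Number of surrogates (default 10).
#' @param seed Integer seed.
#' @return List of numeric surrogate series.
#' @export
generate_surrogates <- function(series, n = 10L, seed = NULL) {
  x <- as_series(series)
  len <- length(x)
  if (len < 8L) stop("series too short for surrogate generation", call. = FALSE)
  X <- stats::fft(x)
  half <- if (len %% 2L == 0L) len / 2L else (len - 1L) / 2L
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ph <- stats::runif(half - if (len %% 2L == 0L) 1L else 0L, 0, 2 * pi)
      Xs <- X
      pos <- 2L:(if (len %% 2L == 0L) half else half + 1L)
      rot <- exp(1i * ph)
      Xs[pos] <- abs(X[pos]) * rot
      Xs[len + 2L - pos] <- Conj(Xs[pos])
      if (len %% 2L == 0L) Xs[half + 1L] <- abs(X[half + 1L]) * sample(c(-1, 1), 1L)
      Xs[1L] <- X[1L]
      Re(stats::fft(Xs, inverse = TRUE)) / len
    })
  })
}

#' Surrogate data test on the correlation dimension
#'
#' Computes D2 for the original series and for `n` phase-randomized
#' surrogates under identical settings (same delay, dimension, radius grid
#' and Theiler window), then applies the min/max envelope rule: the
#' stochastic null hypothesis is rejected when the original D2 falls on or
#' outside the surrogate envelope (boundary equality counts as rejection;
#' inverted bounds are sorted before comparison).
#'
#' @param series Numeric vector or scalar [coordinate_series].
#' @param n Number of surrogates (default 10).
#' @param seed Integer seed for the surrogate phases.
#' @param embed An [embedding_params]; `NULL` selects one from the
#'   original series.
#' @param ... Passed to [corr_dim()] (e.g. `slope_tol`, `n_radii`).
#' @return A `surrogate_test` object: `d2_original`, `d2_surrogates`,
#'   `d2_min`, `d2_max`, `rejected`, `embed`.
#' @export
surrogate_test <- function(series, n = 10L, seed = NULL, embed = NULL, ...) {
  x <- as_series(series)
  if (is.null(embed)) embed <- select_embedding(x)
  cd <- corr_dim(x, embed = embed, ...)
  surr <- generate_surrogates(x, n = n, seed = seed)
  d2s <- vapply(surr, function(s)
    corr_dim(s, embed = embed, radii = cd$radii, ...)$D2, numeric(1))
  lo <- min(d2s); hi <- max(d2s)
  structure(list(n_surrogates = n, d2_original = cd$D2, d2_surrogates = d2s,
                 d2_min = lo, d2_max = hi,
                 rejected = envelope_rejected(cd$D2, lo, hi),
                 embed = embed, corr_dim = cd),
            class = "surrogate_test")
}

#' @export
print.surrogate_test <- function(x, ...) {
  cat(sprintf("surrogate test: D2 = %.5f vs envelope [%.5f, %.5f] (%d surrogates) -> %s\n",
              x$d2_original, x$d2_min, x$d2_max, x$n_surrogates,
              if (x$rejected) "null REJECTED" else "null not rejected"))
  invisible(x)
}

#' Envelope rejection rule
#'
#' Vectorized form of the surrogate-test decision: the null is rejected
#' when the original statistic is less than or equal to the envelope
#' minimum or greater than or equal to the envelope maximum. Bounds are
#' sorted first, so an inverted (min > max) pair is handled.
#'
#' @param original Original-series statistic(s).
#' @param surr_min,surr_max Envelope bounds.
#' @return Logical vector.
#' @export
envelope_rejected <- function(original, surr_min, surr_max) {
  lo <- pmin(surr_min, surr_max)
  hi <- pmax(surr_min, surr_max)
  original <= lo | original >= hi
}

#' Chaotic classification of a subsequence
#'
#' A series is classified chaotic when the surrogate test rejects the
#' stochastic null AND its largest Lyapunov exponent is positive
#' (sensitivity to initial conditions confirmed).
#'
#' @param test A `surrogate_test` result (or logical `rejected` flag).
#' @param lyap A `lyapunov` result (or numeric LLE).
#' @return Logical flag.
#' @export
classify_chaotic <- function(test, lyap) {
  rejected <- if (inherits(test, "surrogate_test")) test$rejected else as.logical(test)
  lle <- if (inherits(lyap, "lyapunov")) lyap$lle else as.numeric(lyap)
  rejected & lle > 0
}

#' Full chaos diagnosis of one binary sequence
#'
#' CGR-encodes a gap-free binary sequence, selects embedding parameters,
#' runs the surrogate test on the correlation dimension and the Eckmann
#' Lyapunov estimate, and returns one report row.
#'
#' @param seq Gap-free binary [allele_seq].
#' @param n_surrogates Number of surrogates.
#' @param seed Integer seed (surrogate phases).
#' @param id Label used in the report row.
#' @param ... Passed to [corr_dim()].
#' @return One-row `data.frame`: id, length, tau, m, d2_original,
#'   d2_surr_min, d2_surr_max, lle, is_chaotic.
#' @export
diagnose_sequence <- function(seq, n_surrogates = 10L, seed = NULL,
                              id = "S1", ...) {
  x <- cgr_encode_binary(seq)$values
  embed <- select_embedding(x)
  st <- surrogate_test(x, n = n_surrogates, seed = seed, embed = embed, ...)
  ly <- lyapunov_eckmann(x, embed = embed)
  data.frame(id = id, length = length(x), tau = embed$delay,
             m = embed$dimension, d2_original = st$d2_original,
             d2_surr_min = st$d2_min, d2_surr_max = st$d2_max,
             lle = ly$lle, is_chaotic = classify_chaotic(st, ly),
             stringsAsFactors = FALSE)
}

#' Chaos report for a set of subsequences
#'
#' @param subs List of `subsequence` objects (from [split_by_distance()] /
#'   [filter_min_length()]).
#' @param n_surrogates Number of surrogates per subsequence.
#' @param seed Integer seed; each subsequence gets a derived sub-seed.
#' @param ... Passed to [diagnose_sequence()].
#' @return `data.frame` with one row per subsequence (empty but correctly
#'   typed when `subs` is empty).
#' @export
chaos_report <- function(subs, n_surrogates = 10L, seed = NULL, ...) {
  if (length(subs) == 0L) {
    return(data.frame(id = character(0), length = integer(0),
                      tau = integer(0), m = integer(0),
                      d2_original = numeric(0), d2_surr_min = numeric(0),
                      d2_surr_max = numeric(0), lle = numeric(0),
                      is_chaotic = logical(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(subs), function(i) {
    sub_seed <- if (is.null(seed)) NULL else (as.integer(seed) + i) %% .Machine$integer.max
    diagnose_sequence(subs[[i]]$seq, n_surrogates = n_surrogates,
                      seed = sub_seed, id = paste0("S", i), ...)
  })
  do.call(rbind, rows)
}
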