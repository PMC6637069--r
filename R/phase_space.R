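#' Embedding parameters for phase-space reconstruction
#'
#' @param delay Time delay tau (samples, >= 1).
#' @param dimension Embedding dimension m (>= 1).
#' @return An `embedding_params` object.
#' @export
embedding_params <- function(delay = 1L, dimension = 2L) {
  delay <- as.integer(delay); dimension <- as.integer(dimension)
  stopifnot(delay >= 1L, dimension >= 1L)
  structure(list(delay = delay, dimension = dimension),
            class = "embedding_params")
}

#' @export
print.embedding_params <- function(x, ...) {
  cat(sprintf("embedding: delay tau = %d, dimension m = %d\n",
              x$delay, x$dimension))
  invisible(x)
}

#' Takens delay embedding
#'
#' Builds the delay-vector matrix Y[t] = (x[t], x[t+tau], ...,
#' x[t+(m-1)tau]) of a scalar series; the number of rows is exactly
#' N - (m-1) tau.
#'
#' @param series Numeric vector (or a scalar [coordinate_series]).
#' @param params An [embedding_params], or `delay`/`dimension` given
#'   directly.
#' @param delay,dimension Alternative to `params`.
#' @return Numeric matrix with one delay vector per row.
#' @export
delay_embed <- function(series, params = NULL, delay = NULL, dimension = NULL) {
  x <- as_series(series)
  if (!is.null(params)) { delay <- params$delay; dimension <- params$dimension }
  m <- as.integer(dimension); tau <- as.integer(delay)
  stopifnot(m >= 1L, tau >= 1L)
  n <- length(x)
  ne <- n - (m - 1L) * tau
  if (ne < 1L)
    stop("series too short to embed: need length > (m-1)*tau", call. = FALSE)
  out <- matrix(0, ne, m)
  for (j in seq_len(m)) out[, j] <- x[seq_len(ne) + (j - 1L) * tau]
  out
}

as_series <- function(x) {
  if (inherits(x, "coordinate_series")) {
    if (is.matrix(x$values))
      stop("expected a scalar series, got a 2-D coordinate series", call. = FALSE)
    if (!all(x$defined))
      stop("series has undefined entries; fill or initialize them first",
           call. = FALSE)
    return(x$values)
  }
  as.numeric(x)
}

#' Average mutual information and delay selection
#'
#' AMI(k) is the mutual information (in nats) between x[t] and x[t+k],
#' estimated from an equal-width 2-D histogram. The embedding delay is
#' chosen as the first local minimum of AMI over k = 1..`max_lag`; if no
#' local minimum exists the fallback delay 1 is used and reported via
#' `message()`.
#'
#' @param series Numeric vector or scalar [coordinate_series].
#' @param max_lag Largest lag examined (default 50, capped to n/4).
#' @param n_bins Histogram bins per axis; default `ceiling(sqrt(n))` capped
#'   at 32 (a denser grid leaves the joint histogram too sparse for the
#'   bias-corrected estimator at attainable series lengths).
#' @return A list with `lags` (0..max_lag), `ami`, and the selected
#'   `delay`.
#' @export
average_mutual_information <- function(series, max_lag = 50L, n_bins = NULL) {
  x <- as_series(series)
  n <- length(x)
  max_lag <- as.integer(min(max_lag, max(1L, n %/% 4L)))
  if (n <= max_lag + 1L) stop("series too short for 'max_lag'", call. = FALSE)
  if (is.null(n_bins)) n_bins <- min(32L, ceiling(sqrt(n)))
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    warning("constant series: AMI is identically zero; delay set to 1")
    return(list(lags = 0:max_lag, ami = rep(0, max_lag + 1L), delay = 1L))
  }
  bins <- pmin(pmax(1L, as.integer(ceiling((x - rng[1L]) / diff(rng) * n_bins))),
               n_bins)
  ami <- vapply(0:max_lag, function(k) {
    a <- bins[seq_len(n - k)]
    b <- bins[seq_len(n - k) + k]
    tab <- table(a, b) / (n - k)
    px <- rowSums(tab); py <- colSums(tab)
    nz <- tab > 0
    mi <- sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
    # Miller-Madow bias correction of the plug-in estimator
    bias <- (sum(nz) - sum(px > 0) - sum(py > 0) + 1) / (2 * (n - k))
    max(mi - bias, 0)
  }, numeric(1))
  delay <- NA_integer_
  for (k in seq_len(max_lag - 1L)) {
    if (ami[k + 1L] < ami[k] && ami[k + 1L] <= ami[k + 2L]) { delay <- k; break }
  }
  if (is.na(delay)) {
    message("AMI has no local minimum within max_lag = ", max_lag,
            "; falling back to delay 1")
    delay <- 1L
  }
  list(lags = 0:max_lag, ami = ami, delay = delay)
}

#' False nearest neighbors and embedding-dimension selection
#'
#' Kennel-style criterion: for each trial dimension m, each point's nearest
#' neighbor in the m-dimensional embedding is re-examined after appending
#' the (m+1)-th delay coordinate. A neighbor is false if the extra
#' coordinate separates the pair by more than `Rtol` times their
#' m-dimensional distance (ratio test) or if the (m+1)-dimensional distance
#' exceeds `Atol` times the series' standard deviation (attractor-size
#' test). The selected dimension is the smallest m whose false-neighbor
#' fraction drops below `threshold`; otherwise `m_max` is used and reported
#' via `message()`.
#'
#' @param series Numeric vector or scalar [coordinate_series].
#' @param delay Embedding delay tau.
#' @param m_max Largest dimension examined.
#' @param Rtol,Atol Kennel test thresholds (defaults 10 and 2).
#' @param threshold Acceptable false-neighbor fraction (default 0.01).
#' @return A list with `dimensions`, `fnn_fraction`, and the selected
#'   `dimension`.
#' @export
false_nearest_neighbors <- function(series, delay = 1L, m_max = 8L,
                                    Rtol = 10, Atol = 2, threshold = 0.01) {
  x <- as_series(series)
  tau <- as.integer(delay)
  m_max <- as.integer(m_max)
  n <- length(x)
  sdx <- stats::sd(x)
  if (!is.finite(sdx) || sdx == 0)
    stop("degenerate input: constant series cannot be embedded", call. = FALSE)
  if (n < (m_max - 1L) * tau + 2L)
    stop("series too short to examine dimensions up to m_max", call. = FALSE)
  frac <- rep(NA_real_, m_max)
  for (m in seq_len(m_max)) {
    # embed at m but keep only points whose (m+1)-th coordinate exists
    ne <- n - m * tau
    if (ne < 2L) break
    Y <- matrix(0, ne, m)
    for (j in seq_len(m)) Y[, j] <- x[seq_len(ne) + (j - 1L) * tau]
    nxt <- x[seq_len(ne) + m * tau]
    d2 <- as.matrix(stats::dist(Y))
    diag(d2) <- Inf
    nn <- max.col(-d2, ties.method = "first")
    dm <- d2[cbind(seq_len(ne), nn)]
    extra <- abs(nxt - nxt[nn])
    dm1 <- sqrt(dm^2 + extra^2)
    # floor on the denominator guards exact recurrences (e.g. noise-free
    # periodic data), whose ~1e-15 distances would blow up the ratio test
    false_nb <- (extra > Rtol * pmax(dm, 1e-8 * sdx)) | (dm1 / sdx > Atol)
    frac[m] <- mean(false_nb)
  }
  ok <- which(!is.na(frac) & frac < threshold)
  if (length(ok) > 0L) {
    dimension <- ok[1L]
  } else {
    message("FNN fraction never dropped below ", threshold,
            "; falling back to m_max = ", m_max)
    dimension <- m_max
  }
  list(dimensions = seq_len(m_max), fnn_fraction = frac, dimension = dimension)
}

#' Automatic embedding selection (AMI delay + FNN dimension)
#'
#' @inheritParams average_mutual_information
#' @inheritParams false_nearest_neighbors
#' @return An [embedding_params] with attributes `ami` and `fnn` holding
#'   the full selection diagnostics.
#' @export
select_embedding <- function(series, max_lag = 50L, m_max = 8L,
                             Rtol = 10, Atol = 2, threshold = 0.01) {
  ami <- average_mutual_information(series, max_lag = max_lag)
  fnn <- false_nearest_neighbors(series, delay = ami$delay, m_max = m_max,
                                 Rtol = Rtol, Atol = Atol,
                                 threshold = threshold)
  out <- embedding_params(delay = ami$delay, dimension = fnn$dimension)
  attr(out, "ami") <- ami
  attr(out, "fnn") <- fnn
  out
}
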