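#' Partition sum of a measure over a fixed-size box grid
#'
#' Covers \[0, 1\]^d with boxes of side eps anchored at 0 (half-open
#' \[a, a + eps), the last box closed) and sums mu(B)^q over occupied
#' boxes only, where mu(B) is the fraction of total point mass in box B.
#' Restricting to occupied boxes keeps negative-q moments finite.
#'
#' @param points Numeric vector (1-D) or matrix (rows = points) in
#'   \[0, 1\]^d.
#' @param eps Box side, a dyadic fraction 2^-k.
#' @param q Moment order (any real).
#' @param weights Optional non-negative point masses (default: equal). A
#'   weighted point set evaluates a measure (e.g. cascade cell centers with
#'   cell masses) exactly.
#' @return The partition sum Z_eps(q); for q = 0 this is the occupied-box
#'   count.
#' @export
box_partition_sum <- function(points, eps, q, weights = NULL) {
  mu <- box_masses(points, eps, weights)
  sum(mu^q)
}

box_masses <- function(points, eps, weights = NULL) {
  if (is.vector(points)) points <- matrix(points, ncol = 1L)
  n <- nrow(points)
  if (n == 0L) stop("empty point set", call. = FALSE)
  stopifnot(eps > 0, eps <= 1)
  nbox <- as.integer(round(1 / eps))
  idx <- pmin(floor(points / eps), nbox - 1L)  # last box closed at 1
  cell <- idx[, 1L]
  if (ncol(points) > 1L)
    for (j in 2L:ncol(points)) cell <- cell * nbox + idx[, j]
  w <- if (is.null(weights)) rep(1 / n, n) else weights / sum(weights)
  mu <- rowsum(w, cell)
  mu <- mu[mu > 0]
  mu
}

#' Mass exponents tau(q) by box-counting regression
#'
#' For each q, tau(q) is the least-squares slope of ln Z_eps(q) against
#' ln eps across the box-size grid. The q = 1 entropy sums
#' (sum mu ln mu per eps) are returned alongside for the information
#' dimension.
#'
#' @param points Points in \[0, 1\]^d (vector or matrix).
#' @param q_grid Moment orders (default -5..5 step 0.25).
#' @param eps_grid Box sides (default 2^-(1:8)).
#' @param weights Optional point masses.
#' @return A list: `q`, `eps`, `tau`, `log_Z` (q x eps matrix),
#'   `entropy_slope` (the Eq-11 information dimension), `degenerate`
#'   (TRUE when a single box is occupied at every eps, giving a width-zero
#'   spectrum).
#' @export
mass_exponents <- function(points, q_grid = default_q_grid(),
                           eps_grid = 2^-(1:8), weights = NULL) {
  stopifnot(length(eps_grid) >= 4L)
  mus <- lapply(eps_grid, function(e) box_masses(points, e, weights))
  degenerate <- all(vapply(mus, length, integer(1)) == 1L)
  log_eps <- log(eps_grid)
  log_Z <- vapply(seq_along(eps_grid), function(i) {
    vapply(q_grid, function(q) log(sum(mus[[i]]^q)), numeric(1))
  }, numeric(length(q_grid)))
  log_Z <- matrix(log_Z, nrow = length(q_grid))
  X <- cbind(1, log_eps)
  tau <- apply(log_Z, 1L, function(y) stats::lm.fit(X, y)$coefficients[2L])
  ent <- vapply(mus, function(mu) sum(mu * log(mu)), numeric(1))
  entropy_slope <- stats::lm.fit(X, ent)$coefficients[2L]
  list(q = q_grid, eps = eps_grid, tau = unname(tau), log_Z = log_Z,
       entropy_slope = unname(entropy_slope), degenerate = degenerate)
}

default_q_grid <- function() {
  # moments beyond |q| ~ 5 are dominated by single extreme boxes at
  # attainable sample sizes; 0.25 steps keep the tau derivative stable
  seq(-5, 5, by = 0.25)
}

#' Generalized (Renyi) dimensions D_q
#'
#' D_q = tau(q) / (q - 1) away from q = 1; at q = 1 the information
#' dimension is taken from the direct entropy-sum regression
#' (slope of sum mu ln mu against ln eps).
#'
#' @param me Result of [mass_exponents()].
#' @return Numeric vector D_q on the q grid.
#' @export
generalized_dimensions <- function(me) {
  q <- me$q
  D <- ifelse(abs(q - 1) < 1e-9, me$entropy_slope, me$tau / (q - 1))
  unname(D)
}

#' Singularity spectrum f(alpha)
#'
#' alpha(q) = d tau / d q by central finite differences (one-sided at the
#' grid ends) and f(alpha) = q alpha(q) - tau(q). The spectrum width
#' max(alpha) - min(alpha) quantifies multifractality strength: a narrow
#' spectrum indicates a monofractal (weakly multifractal) measure.
#'
#' @param me Result of [mass_exponents()].
#' @return A list: `alpha`, `f_alpha`, `width`.
#' @export
singularity_spectrum <- function(me) {
  q <- me$q; tau <- me$tau
  k <- length(q)
  stopifnot(k >= 3L)
  alpha <- numeric(k)
  alpha[1L] <- (tau[2L] - tau[1L]) / (q[2L] - q[1L])
  alpha[k] <- (tau[k] - tau[k - 1L]) / (q[k] - q[k - 1L])
  alpha[2:(k - 1L)] <- (tau[3:k] - tau[1:(k - 2L)]) / (q[3:k] - q[1:(k - 2L)])
  f <- q * alpha - tau
  list(alpha = alpha, f_alpha = f, width = max(alpha) - min(alpha))
}

#' Full multifractal spectrum of a point set or weighted measure
#'
#' Runs the fixed-size box-counting analysis end to end: partition sums,
#' mass exponents, generalized dimensions and the singularity spectrum.
#'
#' @inheritParams mass_exponents
#' @return An `mf_spectrum` object with fields `q`, `eps`, `tau`, `D_q`,
#'   `alpha`, `f_alpha`, `width`, `degenerate`.
#' @examples
#' cm <- gen_cascade_measure(0.7, 10)
#' sp <- multifractal_spectrum(cm$cell_centers, weights = cm$cell_masses)
#' sp$width
#' @export
multifractal_spectrum <- function(points, q_grid = default_q_grid(),
                                  eps_grid = 2^-(1:8), weights = NULL) {
  me <- mass_exponents(points, q_grid, eps_grid, weights)
  D <- generalized_dimensions(me)
  ss <- singularity_spectrum(me)
  structure(list(q = me$q, eps = me$eps, tau = me$tau, D_q = D,
                 alpha = ss$alpha, f_alpha = ss$f_alpha,
                 width = if (me$degenerate) 0 else ss$width,
                 degenerate = me$degenerate),
            class = "mf_spectrum")
}

#' @export
print.mf_spectrum <- function(x, ...) {
  cat(sprintf("multifractal spectrum: q in [%g, %g], D_0 = %.3f, D_2 = %.3f, width = %.3f%s\n",
              min(x$q), max(x$q), x$D_q[which.min(abs(x$q))],
              x$D_q[which.min(abs(x$q - 2))], x$width,
              if (x$degenerate) " (degenerate: single occupied box)" else ""))
  invisible(x)
}

#' @rdname multifractal_spectrum
#' @param spectrum An `mf_spectrum`.
#' @param path Output TSV path (columns q, tau, D_q, alpha, f_alpha).
#' @export
write_mf_spectrum <- function(spectrum, path) {
  df <- data.frame(q = spectrum$q, tau = spectrum$tau, D_q = spectrum$D_q,
                   alpha = spectrum$alpha, f_alpha = spectrum$f_alpha)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
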