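#' Seeded generators for synthetic haplotype-like data
#'
#' These generators produce every kind of input the analysis and imputation
#' pipelines consume: binary sequences from deterministic chaotic maps and
#' from stochastic null models, clustered SNP genomic positions, binomial
#' multiplicative cascade measures with closed-form multifractal spectra,
#' and simulated sequencing fragment matrices. All of them are fully
#' deterministic given their `seed`.
#'
#' @name synthetic-data
NULL

# Local RNG scope: generators never disturb the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
              suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(as.integer(seed))
  }
  expr
}

#' Binary sequences from deterministic chaotic maps
#'
#' Iterates a chaotic map, discards `burn_in` transient iterates, and
#' symbolizes each subsequent state at threshold 0.5 (state <= 0.5 becomes
#' allele 0, otherwise 1). The raw real-valued orbit is attached as
#' attribute `"orbit"` so chaos metrics can be evaluated directly on the
#' continuous states. For `"henon"` the orbit is the x coordinate and the
#' full (x, y) path is attached as `"orbit_xy"`.
#'
#' @param kind `"logistic"` (x <- r x (1 - x), default r = 4), `"tent"`
#'   (x <- a min(x, 1 - x), default a = 2), or `"henon"`
#'   (x <- 1 - a x^2 + y; y <- b x, default a = 1.4, b = 0.3).
#' @param n Number of symbols to emit (may be 0).
#' @param seed Integer seed; draws the initial condition when `x0` is `NULL`.
#' @param map_params Named list of map parameters overriding the defaults.
#' @param burn_in Iterates discarded before emission (default 1000, enough
#'   to land on the attractor).
#' @param x0 Optional explicit initial condition (for `"henon"` a length-2
#'   vector).
#' @return An [allele_seq] with attributes `orbit` (and `orbit_xy`).
#' @examples
#' s <- gen_chaotic_binary("logistic", n = 3, burn_in = 0, x0 = 0.3)
#' attr(s, "orbit")   # 0.84 0.5376 0.99434...
#' allele_string(s)   # "111"
#' @export
gen_chaotic_binary <- function(kind = c("logistic", "tent", "henon"),
                               n, seed = NULL, map_params = list(),
                               burn_in = 1000L, x0 = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("'n' must be a non-negative integer", call. = FALSE)
  burn_in <- as.integer(burn_in)
  stopifnot(burn_in >= 0L)
  with_seed(seed, {
    orbit_xy <- NULL
    if (kind == "henon") {
      a <- map_params$a %||% 1.4
      b <- map_params$b %||% 0.3
      st <- if (is.null(x0)) c(stats::runif(1, -0.1, 0.1), stats::runif(1, -0.1, 0.1)) else x0
      total <- burn_in + n
      xs <- numeric(n); ys <- numeric(n)
      for (i in seq_len(total)) {
        st <- c(1 - a * st[1L]^2 + st[2L], b * st[1L])
        if (i > burn_in) { xs[i - burn_in] <- st[1L]; ys[i - burn_in] <- st[2L] }
      }
      orbit <- xs
      orbit_xy <- cbind(x = xs, y = ys)
    } else {
      f <- switch(kind,
        logistic = { r <- map_params$r %||% 4;   function(x) r * x * (1 - x) },
        tent     = { a <- map_params$a %||% 2;   function(x) a * pmin(x, 1 - x) })
      # keep the draw away from fixed points / the endpoints of [0,1]
      x <- if (is.null(x0)) stats::runif(1, 0.05, 0.95) else x0
      for (i in seq_len(burn_in)) x <- f(x)
      orbit <- numeric(n)
      for (i in seq_len(n)) { x <- f(x); orbit[i] <- x }
    }
    out <- allele_seq(as.integer(orbit > 0.5))
    attr(out, "orbit") <- orbit
    if (!is.null(orbit_xy)) attr(out, "orbit_xy") <- orbit_xy
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' I.i.d. Bernoulli binary sequences
#'
#' @param p Success (allele 1) probability in \[0, 1\].
#' @param n Number of symbols.
#' @param seed Integer seed.
#' @return An [allele_seq].
#' @export
gen_random_binary <- function(p, n, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a probability in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("'n' must be a non-negative integer", call. = FALSE)
  with_seed(seed, allele_seq(stats::rbinom(n, 1L, p)))
}

#' Persistent two-state Markov binary sequences
#'
#' A symmetric two-state Markov chain with stay probability `p_stay`
#' emulates the neighbor correlation (linkage-disequilibrium-like
#' persistence) of real haplotype alleles; `p_stay = 0.5` degenerates to a
#' fair coin.
#'
#' @param n Number of symbols.
#' @param p_stay Probability of repeating the previous allele.
#' @param seed Integer seed.
#' @return An [allele_seq].
#' @export
gen_markov_binary <- function(n, p_stay = 0.9, seed = NULL) {
  stopifnot(p_stay >= 0, p_stay <= 1)
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("'n' must be a non-negative integer", call. = FALSE)
  with_seed(seed, {
    if (n == 0L) return(allele_seq(integer(0)))
    stay <- stats::runif(n) < p_stay
    s <- integer(n)
    s[1L] <- stats::rbinom(1L, 1L, 0.5)
    for (i in seq_len(n - 1L) + 1L) s[i] <- if (stay[i]) s[i - 1L] else 1L - s[i - 1L]
    allele_seq(s)
  })
}

#' Clustered SNP genomic positions
#'
#' Builds strictly increasing positions forming exactly `n_clusters` dense
#' runs: consecutive within-cluster distances are drawn from `within_gap`
#' and distances between the last SNP of one cluster and the first of the
#' next from `between_gap`. With a distance threshold r equal to
#' `min(between_gap)`, [split_by_distance()] recovers the clusters exactly.
#'
#' @param n_clusters Number of clusters (may be 0).
#' @param cluster_sizes Length-2 range (or single value) of SNPs per cluster.
#' @param within_gap Length-2 range (or single value) of within-cluster
#'   distances in bp; its maximum must be below `min(between_gap)`.
#' @param between_gap Length-2 range (or single value) of between-cluster
#'   distances in bp.
#' @param seed Integer seed.
#' @param start First genomic coordinate.
#' @return Integer vector of positions with attribute `cluster_sizes`.
#' @export
gen_snp_positions <- function(n_clusters, cluster_sizes, within_gap,
                              between_gap, seed = NULL, start = 1000L) {
  rng <- function(r) { r <- as.integer(r); if (length(r) == 1L) c(r, r) else range(r) }
  n_clusters <- as.integer(n_clusters)
  stopifnot(n_clusters >= 0L)
  cs <- rng(cluster_sizes); wg <- rng(within_gap); bg <- rng(between_gap)
  if (cs[1L] < 1L) stop("cluster sizes must be >= 1", call. = FALSE)
  if (wg[1L] < 1L) stop("within-cluster distances must be >= 1", call. = FALSE)
  if (wg[2L] >= bg[1L])
    stop("max within-cluster distance must be below min between-cluster distance",
         call. = FALSE)
  # draw from a range without sample()'s scalar-x surprise
  rdraw <- function(lohi, n) lohi[1L] + sample.int(lohi[2L] - lohi[1L] + 1L,
                                                   n, replace = TRUE) - 1L
  with_seed(seed, {
    sizes <- if (n_clusters > 0L) rdraw(cs, n_clusters) else integer(0)
    pos <- integer(0)
    cur <- as.integer(start)
    for (k in seq_len(n_clusters)) {
      if (k > 1L) cur <- pos[length(pos)] + rdraw(bg, 1L)
      p <- cur
      if (sizes[k] > 1L)
        p <- cur + c(0L, cumsum(rdraw(wg, sizes[k] - 1L)))
      pos <- c(pos, p)
    }
    structure(pos, cluster_sizes = sizes)
  })
}

#' Binomial multiplicative cascade measures
#'
#' Recursively splits the mass of \[0, 1\] over dyadic halves in proportions
#' (p, 1 - p) down to `depth` levels, yielding 2^depth cell masses. The
#' cascade is the standard closed-form multifractal test object: its mass
#' exponent is tau(q) = -log2(p^q + (1-p)^q) (see [cascade_tau_exact()]),
#' with singularity exponents spanning \[-log2(max(p,1-p)),
#' -log2(min(p,1-p))\].
#'
#' @param p Left-half weight in (0, 1); `p = 0.5` gives the uniform measure.
#' @param depth Number of dyadic refinement levels (>= 1).
#' @return An object of class `cascade_measure` with elements `p`, `depth`,
#'   `cell_masses` (summing to 1), and `cell_centers`.
#' @export
gen_cascade_measure <- function(p, depth) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("'depth' must be >= 1", call. = FALSE)
  m <- 1
  for (k in seq_len(depth)) m <- as.vector(rbind(p * m, (1 - p) * m))
  eps <- 2^(-depth)
  centers <- (seq_along(m) - 0.5) * eps
  structure(list(p = p, depth = depth, cell_masses = m, cell_centers = centers),
            class = "cascade_measure")
}

#' @export
print.cascade_measure <- function(x, ...) {
  cat(sprintf("binomial cascade: p = %g, depth = %d, %d cells (mass sum %.12f)\n",
              x$p, x$depth, length(x$cell_masses), sum(x$cell_masses)))
  invisible(x)
}

#' @rdname gen_cascade_measure
#' @param q Real moment order(s).
#' @return `cascade_tau_exact()`: the analytic mass exponent
#'   tau(q) = -log2(p^q + (1-p)^q) of the cascade.
#' @export
cascade_tau_exact <- function(p, q) -log2(p^q + (1 - p)^q)

#' @rdname gen_cascade_measure
#' @param measure A `cascade_measure`.
#' @param n Number of points to sample.
#' @param seed Integer seed.
#' @return `sample_cascade_points()`: `n` points in \[0, 1\] drawn
#'   proportionally to cell mass (uniform within a cell).
#' @export
sample_cascade_points <- function(measure, n, seed = NULL) {
  stopifnot(inherits(measure, "cascade_measure"))
  with_seed(seed, {
    eps <- 2^(-measure$depth)
    cell <- sample.int(length(measure$cell_masses), n, replace = TRUE,
                       prob = measure$cell_masses)
    (cell - 1L) * eps + stats::runif(n) * eps
  })
}

#' Simulated sequencing fragment matrices
#'
#' Emulates single-individual-haplotyping input: each read copies a
#' contiguous window from one of the two parent haplotypes, flips each
#' copied allele independently with probability `err_rate`, and leaves gaps
#' outside its window. Reads pick their parent fairly (1/2 each) and their
#' start uniformly. Low coverage (few/short reads) produces zero-coverage
#' columns, the ambiguous positions the gap-filling stage targets.
#'
#' @param h1,h2 Gap-free parent [allele_seq]s of equal length.
#' @param n_reads Number of reads; alternatively give `target_coverage`.
#' @param read_len Read length in SNP sites.
#' @param err_rate Per-allele flip probability.
#' @param target_coverage If `n_reads` is missing, the mean per-column
#'   coverage to aim for (`n_reads = round(target_coverage * N / read_len)`).
#' @param seed Integer seed.
#' @return A `fragment_matrix`: integer matrix (reads x sites, `NA` = gap)
#'   with attributes `parents` and `starts` recording the simulation truth.
#' @export
gen_fragment_matrix <- function(h1, h2, n_reads = NULL, read_len,
                                err_rate = 0, target_coverage = NULL,
                                seed = NULL) {
  a1 <- parse_alleles(h1); a2 <- parse_alleles(h2)
  if (length(a1) != length(a2)) stop("parent haplotypes differ in length", call. = FALSE)
  if (anyNA(a1) || anyNA(a2)) stop("parent haplotypes must be gap-free", call. = FALSE)
  N <- length(a1)
  read_len <- as.integer(read_len)
  if (read_len < 1L || read_len > N)
    stop("'read_len' must be between 1 and the haplotype length", call. = FALSE)
  if (is.null(n_reads)) {
    if (is.null(target_coverage)) stop("give 'n_reads' or 'target_coverage'", call. = FALSE)
    n_reads <- max(0L, as.integer(round(target_coverage * N / read_len)))
  }
  n_reads <- as.integer(n_reads)
  with_seed(seed, {
    mat <- matrix(NA_integer_, nrow = n_reads, ncol = N)
    parents <- integer(n_reads); starts <- integer(n_reads)
    H <- rbind(a1, a2)
    for (i in seq_len(n_reads)) {
      parents[i] <- sample(1:2, 1L)
      starts[i] <- sample.int(N - read_len + 1L, 1L)
      idx <- starts[i]:(starts[i] + read_len - 1L)
      alleles <- H[parents[i], idx]
      flip <- stats::runif(read_len) < err_rate
      mat[i, idx] <- ifelse(flip, 1L - alleles, alleles)
    }
    structure(mat, parents = parents, starts = starts,
              class = c("fragment_matrix", "matrix"))
  })
}
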