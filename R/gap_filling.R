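#' Configuration for phase-space gap filling
#'
#' @param gap_fraction Fraction of sites corrupted to gaps when a gap-free
#'   sequence is corrupted for evaluation (default 0.10).
#' @param lp_half_window Half-window N of the local-projection
#'   neighborhood: each projected point uses the 2N + 1 temporally
#'   consecutive embedded points centered on it (default 10).
#' @param embed An [embedding_params] or `NULL` for automatic selection on
#'   the initialized coordinate series.
#' @param manifold_rank Rank Q of the local affine subspace the embedded
#'   points are projected onto (default 1, the locally fitted curve).
#' @param n_iterations Local-projection sweeps (default 3; more sweeps
#'   over-smooth binary-derived series).
#' @param threshold Allele decision threshold on the projected coordinate
#'   (default 0.5; values <= threshold decode to allele 0).
#' @param seed Integer seed (used by [corrupt_with_gaps()]).
#' @return A `gap_fill_config` list.
#' @export
gap_fill_config <- function(gap_fraction = 0.10, lp_half_window = 10L,
                            embed = NULL, manifold_rank = 1L,
                            n_iterations = 3L, threshold = 0.5,
                            seed = NULL) {
  stopifnot(gap_fraction >= 0, gap_fraction <= 1, lp_half_window >= 1L,
            manifold_rank >= 1L, manifold_rank < 2L * lp_half_window + 1L,
            n_iterations >= 1L)
  structure(list(gap_fraction = gap_fraction,
                 lp_half_window = as.integer(lp_half_window), embed = embed,
                 manifold_rank = as.integer(manifold_rank),
                 n_iterations = as.integer(n_iterations),
                 threshold = threshold, seed = seed),
            class = "gap_fill_config")
}

#' Corrupt a gap-free sequence with gaps at random positions
#'
#' Replaces `round(fraction * length)` distinct uniformly drawn positions
#' by gaps, emulating uncovered/ambiguous assembly sites with known truth.
#'
#' @param seq Gap-free [allele_seq].
#' @param fraction Fraction of positions to blank (default 0.10).
#' @param seed Integer seed.
#' @return A list: `seq` (corrupted [allele_seq]) and `mask` (sorted gap
#'   indices).
#' @export
corrupt_with_gaps <- function(seq, fraction = 0.10, seed = NULL) {
  a <- parse_alleles(seq)
  if (anyNA(a)) stop("sequence already contains gaps", call. = FALSE)
  stopifnot(fraction >= 0, fraction <= 1)
  n <- length(a)
  k <- round(fraction * n)
  mask <- with_seed(seed, sort(sample.int(n, k)))
  a[mask] <- NA_integer_
  list(seq = allele_seq(a, positions = positions(seq), chrom = chrom(seq)),
       mask = mask)
}

#' Initialize undefined coordinates from their defined neighbors
#'
#' Every undefined entry of the series receives the mean of the nearest
#' defined value on each side; a whole run of gaps receives the mean of
#' its two flanking defined values, and runs touching a boundary copy the
#' single available flank.
#'
#' @param coords A [coordinate_series] with at least one defined entry.
#' @return A fully defined [coordinate_series]; the original gap indices
#'   are kept in attribute `gap_indices`.
#' @export
initialize_gap_coordinates <- function(coords) {
  stopifnot(inherits(coords, "coordinate_series"))
  v <- coords$values
  def <- coords$defined & !is.na(v)
  if (!any(def))
    stop("degenerate input: no defined coordinates to initialize from",
         call. = FALSE)
  gaps <- which(!def)
  if (length(gaps) > 0L) {
    didx <- which(def)
    for (run in split(gaps, cumsum(c(1L, diff(gaps) != 1L)))) {
      left <- didx[didx < run[1L]]
      right <- didx[didx > run[length(run)]]
      lv <- if (length(left)) v[max(left)] else NA_real_
      rv <- if (length(right)) v[min(right)] else NA_real_
      fill <- mean(c(lv, rv), na.rm = TRUE)
      v[run] <- fill
    }
  }
  out <- coordinate_series(v, defined = rep(TRUE, length(v)),
                           alphabet = coords$alphabet,
                           vertex_map = coords$vertex_map)
  attr(out, "gap_indices") <- gaps
  out
}

#' Refine gap coordinates by local projection in phase space
#'
#' Standard local-projection noise reduction restricted to gap sites: the
#' (initialized) series is delay-embedded; every embedded point whose
#' window covers a gap index is projected onto the best rank-Q affine
#' subspace (principal directions) of the 2N + 1 temporally consecutive
#' embedded points centered on it (windows near the series ends are
#' truncated symmetrically). Only coordinates at gap indices are written
#' back, averaging when several embedded windows update the same index;
#' the sweep is repeated `n_iterations` times. Coordinates at non-gap
#' indices are never modified.
#'
#' @param coords Fully defined [coordinate_series] (after
#'   [initialize_gap_coordinates()]).
#' @param gap_indices Indices to refine.
#' @param config A [gap_fill_config].
#' @return The refined [coordinate_series].
#' @export
local_projection_fill <- function(coords, gap_indices,
                                  config = gap_fill_config()) {
  stopifnot(inherits(coords, "coordinate_series"), all(coords$defined))
  x <- coords$values
  if (length(gap_indices) == 0L) return(coords)
  embed <- config$embed
  if (is.null(embed)) embed <- robust_embedding(x)
  m <- embed$dimension; tau <- embed$delay
  N <- config$lp_half_window
  Q <- config$manifold_rank
  n <- length(x)
  for (iter in seq_len(config$n_iterations)) {
    Y <- delay_embed(x, embed)
    ne <- nrow(Y)
    # embedded rows whose window covers a gap index
    rows <- unique(unlist(lapply(gap_indices, function(g) {
      t <- g - (0:(m - 1L)) * tau
      t[t >= 1L & t <= ne]
    })))
    rows <- sort(rows)
    upd_sum <- numeric(n)
    upd_cnt <- integer(n)
    for (t in rows) {
      half <- min(N, t - 1L, ne - t)
      if (half < 1L) next  # not enough context at the series boundary
      w <- (t - half):(t + half)
      W <- Y[w, , drop = FALSE]
      ctr <- colMeans(W)
      Wc <- sweep(W, 2L, ctr)
      if (sum(Wc^2) < 1e-24) {
        proj <- ctr  # locally constant: project to the centroid
      } else {
        sv <- svd(Wc, nu = 0L, nv = min(Q, m))
        V <- sv$v
        off <- Y[t, ] - ctr
        proj <- ctr + as.vector(V %*% crossprod(V, off))
      }
      covered <- t + (0:(m - 1L)) * tau
      hit <- covered %in% gap_indices
      if (any(hit)) {
        upd_sum[covered[hit]] <- upd_sum[covered[hit]] + proj[which(hit)]
        upd_cnt[covered[hit]] <- upd_cnt[covered[hit]] + 1L
      }
    }
    touched <- upd_cnt > 0L
    x[touched] <- upd_sum[touched] / upd_cnt[touched]
  }
  out <- coordinate_series(x, alphabet = coords$alphabet,
                           vertex_map = coords$vertex_map)
  attr(out, "gap_indices") <- gap_indices
  attr(out, "embed") <- embed
  out
}

# embedding selection that degrades gracefully on near-degenerate series
robust_embedding <- function(x) {
  tryCatch(select_embedding(x),
           error = function(e) {
             message("automatic embedding failed (", conditionMessage(e),
                     "); using tau = 1, m = 2")
             embedding_params(1L, 2L)
           })
}

#' Decode projected coordinates to alleles by thresholding
#'
#' h(i) = 0 when cs(i) <= threshold, else 1. The most significant binary
#' digit of a chaos-game coordinate is the current symbol, so the midpoint
#' 0.5 is the natural decision boundary; the boundary itself decodes to 0.
#' Values outside \[0, 1\] are clamped with a warning.
#'
#' @param cs Numeric coordinate values.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer vector of alleles.
#' @export
threshold_to_alleles <- function(cs, threshold = 0.5) {
  if (any(cs < 0 | cs > 1)) {
    warning("projected coordinates outside [0, 1] were clamped")
    cs <- pmin(pmax(cs, 0), 1)
  }
  as.integer(cs > threshold)
}

#' Reconstruction rates of a filled haplotype
#'
#' @param original Gap-free truth [allele_seq].
#' @param filled Reconstructed [allele_seq] of the same length.
#' @param mask Indices that were gaps before filling.
#' @return A list: `rate_gaps` (fraction of gap positions recovered; 1
#'   when the mask is empty, vacuously) and `rate_overall` (fraction
#'   correct over the whole sequence).
#' @export
reconstruction_rate <- function(original, filled, mask) {
  a <- parse_alleles(original); b <- parse_alleles(filled)
  if (length(a) != length(b)) stop("sequences differ in length", call. = FALSE)
  if (anyNA(a)) stop("'original' must be gap-free", call. = FALSE)
  rate_gaps <- if (length(mask) == 0L) 1 else mean(a[mask] == b[mask], na.rm = FALSE)
  rate_overall <- if (length(a) == 0L) 1 else mean(a == b)
  list(rate_gaps = rate_gaps, rate_overall = rate_overall)
}

#' Fill the gaps of a binary haplotype via phase-space local projection
#'
#' End-to-end applied method: encode the gapped sequence with the
#' restart-on-gap chaos game, initialize gap coordinates from their
#' flanking neighbors, refine them by iterated local projection in the
#' reconstructed phase space, and decode the refined gap coordinates back
#' to alleles by thresholding. Non-gap alleles pass through untouched.
#'
#' @param seq An [allele_seq] with gaps (a gap-free sequence is returned
#'   unchanged).
#' @param config A [gap_fill_config].
#' @return A `gap_fill_result`: `filled` ([allele_seq], gap-free), `mask`
#'   (the gap indices), `cs` (projected coordinate values at the gaps),
#'   `h` (decoded alleles at the gaps), `embed`.
#' @export
fill_gaps <- function(seq, config = gap_fill_config()) {
  a <- parse_alleles(seq)
  mask <- which(is.na(a))
  if (length(mask) == 0L) {
    return(structure(list(filled = allele_seq(a, positions = positions(seq),
                                              chrom = chrom(seq)),
                          mask = integer(0), cs = numeric(0), h = integer(0),
                          embed = NULL),
                     class = "gap_fill_result"))
  }
  if (length(mask) == length(a))
    stop("sequence is all gaps; nothing to project from", call. = FALSE)
  coords <- cgr_encode_with_gaps(a)
  init <- initialize_gap_coordinates(coords)
  refined <- local_projection_fill(init, mask, config)
  cs <- refined$values[mask]
  h <- threshold_to_alleles(cs, config$threshold)
  a[mask] <- h
  structure(list(filled = allele_seq(a, positions = positions(seq),
                                     chrom = chrom(seq)),
                 mask = mask, cs = cs, h = h,
                 embed = attr(refined, "embed")),
            class = "gap_fill_result")
}

#' @export
print.gap_fill_result <- function(x, ...) {
  cat(sprintf("gap fill: %d of %d sites imputed\n", length(x$mask),
              length(x$filled)))
  invisible(x)
}
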