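#' Coordinate series produced by the chaos game map
#'
#' The chaos game representation (CGR) maps a symbol sequence into the unit
#' interval (binary alphabet) or the unit square (DNA alphabet) by the
#' iterative midpoint rule b[i] = 0.5 * (b[i-1] + v[i]), started from the
#' center, where v[i] is the vertex assigned to the i-th symbol. A
#' `coordinate_series` holds the emitted points b[1..n] (the virtual seed
#' b[0] = 0.5 is not emitted, so the series has exactly one value per input
#' symbol), a `defined` mask that is `FALSE` at gap positions, and the
#' vertex map used.
#'
#' @param values Numeric vector (binary CGR) or two-column matrix (DNA CGR).
#' @param defined Logical mask, `FALSE` where the input symbol was a gap.
#' @param alphabet `"binary"` or `"dna"`.
#' @param vertex_map Named vector/matrix of vertex coordinates per symbol.
#' @return An object of class `coordinate_series`.
#' @export
coordinate_series <- function(values, defined = NULL,
                              alphabet = c("binary", "dna"),
                              vertex_map = NULL) {
  alphabet <- match.arg(alphabet)
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (is.null(defined)) defined <- rep(TRUE, n)
  stopifnot(length(defined) == n)
  structure(list(values = values, defined = defined, alphabet = alphabet,
                 vertex_map = vertex_map),
            class = "coordinate_series")
}

#' @export
print.coordinate_series <- function(x, ...) {
  n <- if (is.matrix(x$values)) nrow(x$values) else length(x$values)
  cat(sprintf("coordinate_series (%s CGR): %d points, %d undefined\n",
              x$alphabet, n, sum(!x$defined)))
  invisible(x)
}

#' @export
length.coordinate_series <- function(x) {
  if (is.matrix(x$values)) nrow(x$values) else length(x$values)
}

#' Encode a gap-free binary sequence as a CGR coordinate series
#'
#' Vertices are 0 and 1 on the unit segment; the first point falls halfway
#' between the center 0.5 and the first symbol's vertex, and each later
#' point halfway between its predecessor and the current vertex. With a
#' two-letter alphabet the square of the classical DNA chaos game
#' degenerates to a segment, so the series is scalar.
#'
#' @param seq An [allele_seq] (or anything `allele_seq()` accepts) without
#'   gaps. Use [cgr_encode_with_gaps()] for gapped input.
#' @return A [coordinate_series] with values in (0, 1).
#' @examples
#' cgr_encode_binary("1")$values   # 0.75
#' cgr_encode_binary("00")$values  # 0.25 0.125
#' @seealso [cgr_decode_binary()], [cgr_encode_with_gaps()]
#' @export
cgr_encode_binary <- function(seq) {
  a <- parse_alleles(seq)
  if (anyNA(a))
    stop("sequence contains gaps; use cgr_encode_with_gaps()", call. = FALSE)
  vals <- cgr_forward(a)
  coordinate_series(vals, alphabet = "binary", vertex_map = c(`0` = 0, `1` = 1))
}

# midpoint recursion from seed 0.5; exact for dyadic arithmetic
cgr_forward <- function(v, seed = 0.5) {
  n <- length(v)
  if (n == 0L) return(numeric(0))
  as.numeric(stats::filter(0.5 * v, 0.5, method = "recursive", init = seed))
}

#' Decode a binary CGR coordinate series back to alleles
#'
#' Inverts the midpoint rule: v[i] = 2 b[i] - b[i-1] with b[0] = 0.5. The
#' inversion is exact (each coordinate's leading binary digit is the most
#' recent symbol) as long as floating point resolves the 2^-n contraction,
#' i.e. for runs of up to about 50 symbols.
#'
#' @param coords A fully defined binary [coordinate_series].
#' @param tol Maximum distance of a recovered vertex from \{0, 1\} before
#'   the series is declared corrupt.
#' @return An [allele_seq].
#' @export
cgr_decode_binary <- function(coords, tol = 1e-6) {
  stopifnot(inherits(coords, "coordinate_series"))
  if (coords$alphabet != "binary")
    stop("binary decoder applied to a non-binary series", call. = FALSE)
  if (!all(coords$defined))
    stop("series has undefined entries; decoding requires a full series",
         call. = FALSE)
  b <- coords$values
  v <- 2 * b - c(0.5, b[-length(b)])
  if (length(v) && max(pmin(abs(v), abs(v - 1))) > tol)
    stop("corrupt coordinate series: recovered vertices are not near {0,1}",
         call. = FALSE)
  allele_seq(as.integer(round(v)))
}

#' Encode a DNA sequence as a 2-D CGR coordinate series
#'
#' @param seq Character string or vector over \{A, C, G, T\}.
#' @param vertex_map 4 x 2 matrix of vertex coordinates with rownames
#'   A, C, G, T. The default places A, C, G, T at the corners
#'   (0,0), (0,1), (1,1), (1,0) of the unit square.
#' @return A [coordinate_series] with a two-column `values` matrix.
#' @export
cgr_encode_dna <- function(seq, vertex_map = NULL) {
  if (is.null(vertex_map)) {
    vertex_map <- rbind(A = c(0, 0), C = c(0, 1), G = c(1, 1), T = c(1, 0))
  }
  stopifnot(is.matrix(vertex_map), ncol(vertex_map) == 2,
            all(c("A", "C", "G", "T") %in% rownames(vertex_map)))
  if (length(seq) == 1L) seq <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (length(seq) == 0L)
    return(coordinate_series(matrix(numeric(0), 0, 2), alphabet = "dna",
                             vertex_map = vertex_map))
  bad <- !(seq %in% rownames(vertex_map))
  if (any(bad))
    stop("unknown base(s): ", paste(unique(seq[bad]), collapse = ", "),
         call. = FALSE)
  vx <- vertex_map[seq, 1L]
  vy <- vertex_map[seq, 2L]
  vals <- cbind(x = cgr_forward(vx), y = cgr_forward(vy))
  coordinate_series(vals, alphabet = "dna", vertex_map = vertex_map)
}

#' Encode a gapped binary sequence, restarting the chaos game after gaps
#'
#' Gap positions are emitted as undefined (masked) coordinates so that
#' series indices stay aligned with sequence indices. The first non-gap
#' symbol after a gap run is mapped from the center of the segment again,
#' i.e. b = 0.5 * (0.5 + v), after which the ordinary recursion resumes;
#' a coordinate after a gap run therefore depends only on symbols after the
#' run. Gap-free input reproduces [cgr_encode_binary()] exactly.
#'
#' @param seq An [allele_seq] possibly containing gaps.
#' @return A [coordinate_series] with `defined = FALSE` at gap indices.
#' @export
cgr_encode_with_gaps <- function(seq) {
  a <- parse_alleles(seq)
  n <- length(a)
  vals <- rep(NA_real_, n)
  defined <- !is.na(a)
  prev <- 0.5
  for (i in seq_len(n)) {
    if (is.na(a[i])) {
      prev <- 0.5  # restart: next symbol maps from the center
    } else {
      prev <- 0.5 * (prev + a[i])
      vals[i] <- prev
    }
  }
  coordinate_series(vals, defined = defined, alphabet = "binary",
                    vertex_map = c(`0` = 0, `1` = 1))
}

#' Export a coordinate series as a two-column table
#'
#' @param coords A [coordinate_series].
#' @param path Output TSV path (columns: index, value; DNA series get x, y).
#' @return The path, invisibly.
#' @export
write_coordinate_series <- function(coords, path) {
  stopifnot(inherits(coords, "coordinate_series"))
  if (is.matrix(coords$values)) {
    df <- data.frame(index = seq_len(nrow(coords$values)),
                     x = coords$values[, 1L], y = coords$values[, 2L])
  } else {
    df <- data.frame(index = seq_along(coords$values), value = coords$values)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
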