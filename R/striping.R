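# Striped layout: the stripe interval Q and the rearrangement of
# quantized scores into (q, lane) order with sentinel padding, so that
# the diagonal DP dependency becomes a single end-of-row lane shift.

#' Lane geometry of a warp-wide vector
#'
#' A warp of `S_warp` threads, each operating on `alpha` packed
#' sublanes, behaves as a flat vector of `S_warp * alpha` lanes. The
#' hardware scheme uses `alpha = 4` (8-bit quads) for MSV/SSV and
#' `alpha = 2` (16-bit pairs) for Viterbi; any positive integers are
#' accepted so tests can use tiny warps.
#'
#' @param S_warp Threads per warp (default 32).
#' @param alpha Sublanes per thread.
#' @return Object of class `lane_geometry` with fields `S_warp`,
#'   `alpha`, `lanes`.
#' @export
lane_geometry <- function(S_warp = 32L, alpha = 4L) {
  S_warp <- as.integer(S_warp); alpha <- as.integer(alpha)
  stopifnot(S_warp >= 1, alpha >= 1)
  structure(list(S_warp = S_warp, alpha = alpha,
                 lanes = S_warp * alpha),
            class = "lane_geometry")
}

#' @export
print.lane_geometry <- function(x, ...) {
  cat(sprintf("<lane_geometry %d threads x %d sublanes = %d lanes>\n",
              x$S_warp, x$alpha, x$lanes))
  invisible(x)
}

#' Stripe interval Q
#'
#' `Q = max((L - 1) %/% (alpha * S_warp) + 1, 2)`: the number of
#' inner-loop iterations needed per DP row when `L` model states are
#' spread over `alpha * S_warp` lanes, floored at 2.
#'
#' @param L Model length (states), >= 1.
#' @param alpha Sublanes per thread.
#' @param S_warp Threads per warp.
#' @return Integer stripe interval.
#' @export
compute_q <- function(L, alpha, S_warp) {
  stopifnot(L >= 1, alpha >= 1, S_warp >= 1)
  max((as.integer(L) - 1L) %/% (as.integer(alpha) * as.integer(S_warp)) + 1L,
      2L)
}

# state k (1-based) <-> grid cell: lane l = (k-1) %/% Q, stripe q =
# (k-1) %% Q, i.e. k = l*Q + q + 1. Cells with k > L hold the sentinel.
state_of_cell <- function(q, lane, Q) lane * Q + q + 1L

# Stripe a single L-vector into a Q x lanes integer matrix.
stripe_vector <- function(v, Q, lanes, sentinel) {
  L <- length(v)
  g <- matrix(sentinel, Q, lanes)
  k <- seq_len(L)
  g[cbind((k - 1L) %% Q + 1L, (k - 1L) %/% Q + 1L)] <- v
  mode(g) <- "integer"
  g
}

unstripe_vector <- function(g, L) {
  Q <- nrow(g)
  k <- seq_len(L)
  g[cbind((k - 1L) %% Q + 1L, (k - 1L) %/% Q + 1L)]
}

#' Rearrange quantized scores into the striped (q, lane) layout
#'
#' Every residue symbol gets its own `Q x lanes` emission grid; grid
#' cells beyond state `L` are padded with the sentinel, so enlarging
#' the geometry never changes downstream filter scores.
#'
#' @param scores A `quantized_scores` (see [quantize()]).
#' @param geometry A [lane_geometry()].
#' @return Object of class `striped_profile` with fields `geometry`,
#'   `Q`, `L`, `width`, `scale`, `bias`, `sentinel` and `emissions`
#'   (3-d array `Q x lanes x 21`).
#' @export
stripe <- function(scores, geometry = lane_geometry()) {
  stopifnot(inherits(scores, "quantized_scores"),
            inherits(geometry, "lane_geometry"))
  L <- scores$L
  Q <- compute_q(L, geometry$alpha, geometry$S_warp)
  nsym <- ncol(scores$values)
  em <- array(scores$sentinel, dim = c(Q, geometry$lanes, nsym))
  for (s in seq_len(nsym))
    em[, , s] <- stripe_vector(scores$values[, s], Q, geometry$lanes,
                               scores$sentinel)
  structure(list(geometry = geometry, Q = Q, L = L,
                 width = scores$width, scale = scores$scale,
                 bias = scores$bias, sentinel = scores$sentinel,
                 emissions = em),
            class = "striped_profile")
}

#' @export
print.striped_profile <- function(x, ...) {
  cat(sprintf("<striped_profile %s, L = %d, Q = %d, lanes = %d, %d padded cells/grid>\n",
              x$width, x$L, x$Q, x$geometry$lanes,
              x$Q * x$geometry$lanes - x$L))
  invisible(x)
}

#' Invert the striped layout
#'
#' Recovers the `quantized_scores` that [stripe()] was given; padded
#' cells never appear in the output.
#'
#' @param sp A `striped_profile`.
#' @return A `quantized_scores`.
#' @export
unstripe <- function(sp) {
  stopifnot(inherits(sp, "striped_profile"))
  nsym <- dim(sp$emissions)[3]
  vals <- vapply(seq_len(nsym),
                 function(s) unstripe_vector(sp$emissions[, , s], sp$L),
                 integer(sp$L))
  vals <- matrix(as.integer(vals), sp$L, nsym)
  structure(list(width = sp$width, scale = sp$scale, bias = sp$bias,
                 sentinel = sp$sentinel, L = sp$L, values = vals),
            class = "quantized_scores")
}

#' Dump a striped grid as TSV (debug aid)
#'
#' @param grid A `Q x lanes` matrix (one symbol's emission grid or a
#'   DP row history).
#' @param path Output path.
#' @export
dump_striped_grid <- function(grid, path) {
  write.table(grid, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
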