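# Warp-wide vector primitives: saturating per-sublane arithmetic, the
# closed-cycle lane reorder and the max-reduction. The 32-thread warp
# with packed sublanes is flattened to a single `lanes`-wide vector;
# only the flat striped order is semantically meaningful.

WIDTH_RANGE <- list("8u" = c(0L, 255L), "16s" = c(-32768L, 32767L))

# internal clamped ops on bare integer vectors (shared with the filters)
clamp_w <- function(x, width) {
  r <- WIDTH_RANGE[[width]]
  pmin.int(pmax.int(x, r[1]), r[2])
}
sat_add_vec <- function(a, b, width) clamp_w(a + b, width)
sat_sub_vec <- function(a, b, width) clamp_w(a - b, width)

#' Construct a lane row
#'
#' One DP row as a flat vector of `lanes` integers in striped lane
#' order, under saturating 8-bit-unsigned or 16-bit-signed semantics.
#'
#' @param values Integer vector of length `geometry$lanes`.
#' @param geometry A [lane_geometry()].
#' @param width `"8u"` or `"16s"`.
#' @return Object of class `lane_row`.
#' @export
lane_row <- function(values, geometry = lane_geometry(), width = "8u") {
  values <- as.integer(values)
  stopifnot(width %in% names(WIDTH_RANGE),
            length(values) == geometry$lanes)
  r <- WIDTH_RANGE[[width]]
  if (any(values < r[1] | values > r[2]))
    stop(sprintf("values outside representable %s range [%d, %d]",
                 width, r[1], r[2]), call. = FALSE)
  structure(list(values = values, geometry = geometry, width = width),
            class = "lane_row")
}

#' @export
print.lane_row <- function(x, ...) {
  cat(sprintf("<lane_row %s, %d lanes> ", x$width, x$geometry$lanes))
  cat(head(x$values, 16), if (x$geometry$lanes > 16) "...", "\n")
  invisible(x)
}

check_rows <- function(a, b) {
  if (!identical(a$width, b$width) ||
      !identical(a$geometry$lanes, b$geometry$lanes))
    stop("lane_row geometry/width mismatch", call. = FALSE)
}

#' Saturating per-sublane addition
#'
#' `a + b` clamped per lane to `[0, 255]` (8u) or `[-32768, 32767]`
#' (16s) instead of wrapping.
#'
#' @param a,b `lane_row`s of matching geometry and width.
#' @return A `lane_row`.
#' @export
sat_add <- function(a, b) {
  check_rows(a, b)
  lane_row(sat_add_vec(a$values, b$values, a$width), a$geometry, a$width)
}

#' Saturating per-sublane subtraction
#' @inheritParams sat_add
#' @return A `lane_row`.
#' @export
sat_sub <- function(a, b) {
  check_rows(a, b)
  lane_row(sat_sub_vec(a$values, b$values, a$width), a$geometry, a$width)
}

#' Per-sublane maximum
#' @inheritParams sat_add
#' @return A `lane_row`.
#' @export
vmax <- function(a, b) {
  check_rows(a, b)
  lane_row(pmax.int(a$values, b$values), a$geometry, a$width)
}

#' Closed-cycle lane reorder
#'
#' The one-lane shift applied at the last stripe iteration `q = Q - 1`:
#' `out[1] = sentinel`, `out[l] = in[l - 1]` for `l >= 2`. The wrapped
#' last lane is discarded and the sentinel (-Inf representation: 0 for
#' the MSV scheme, the 0x80 byte pattern for a signed-byte scheme,
#' -32768 for 16s) is shifted in. On a striped DP row this places state
#' `k` where the diagonal recurrence for the next row expects state
#' `k - 1`.
#'
#' @param x A `lane_row`.
#' @param sentinel Integer shifted into lane 1.
#' @param ... Unused.
#' @return A `lane_row`.
#' @export
reorder.lane_row <- function(x, sentinel, ...) {
  lane_row(reorder_vec(x$values, sentinel), x$geometry, x$width)
}

reorder_vec <- function(v, sentinel) {
  c(as.integer(sentinel), v[-length(v)])
}

#' Warp-wide max-reduction
#'
#' The maximum over all sublanes of a row (the value the butterfly
#' shuffle / quad-lane maximizing sequence broadcasts to every thread).
#'
#' @param row A `lane_row`.
#' @return Integer scalar.
#' @export
max_reduce <- function(row) max(row$values)
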