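# The three filter scoring kernels on the striped lane layout:
# SSV (single ungapped segment), MSV (multiple ungapped segments with
# the J rejoin state) in the 8-bit unsigned offset scheme, and the full
# Plan-7 Viterbi filter in 16-bit signed arithmetic with Lazy-F
# evaluation of the Delete-Delete recursion.
#
# Scoring scheme (normative for this package; the naive oracles in
# oracle.R implement the identical per-cell operation DAG):
#  * 8u: path scores live at an unsigned offset `base`; 0 is the floor
#    and the -Inf sentinel. Emissions are applied as
#    sat_sub(sat_add(cell, B), C_e) with per-symbol byte costs
#    C_e = B - (v - bias) (255 for the sentinel), so a -Inf emission
#    floors the cell exactly.
#  * N and C self-loops are free in MSV/SSV; the J loop is charged
#    c_loop per residue. The Viterbi filter charges t_loop on N, J and
#    C alike.
#  * The E state is fed from Match states only.

#' Per-stage filter constants
#'
#' Special-state transition costs of the multi-segment / Plan-7 models,
#' quantized to the stage's integer scheme. Defaults follow the
#' length-dependent parameterization used by hmmsearch-style pipelines:
#' `tloop = log2(len / (len + 3))`, `tmove = log2(3 / (len + 3))`
#' (recomputed per target sequence), uniform entry
#' `tbm = log2(2 / (L * (L + 1)))`, and `tec = tej = -1` bit (the E
#' state splits its exit evenly between J and C).
#'
#' @param stage `"ssv"`, `"msv"` or `"vit"`.
#' @param L Model length.
#' @param seq_len Target sequence length (drives `tloop`/`tmove`).
#' @param scale Units per bit; defaults to the stage's quantization
#'   default (3/ln 2 for 8u, 16 for 16s).
#' @param base Integer score offset representing 0 bits (default 190
#'   for 8u, 12000 for 16s).
#' @param tloop,tmove,tbm,tec,tej Optional overrides in bits (<= 0).
#' @return Object of class `filter_constants`. For 8u stages the
#'   quantized entries are nonnegative byte costs `c_loop`, `c_move`,
#'   `c_bm`, `c_ec`; for 16s they are nonpositive deltas `t_loop`,
#'   `t_move`, `t_bm`, `t_ec`, `t_ej` (sentinel -32768 for -Inf).
#' @export
filter_constants <- function(stage = c("msv", "ssv", "vit"), L, seq_len,
                             scale = NULL, base = NULL,
                             tloop = NULL, tmove = NULL, tbm = NULL,
                             tec = NULL, tej = NULL) {
  stage <- match.arg(stage)
  width <- if (stage == "vit") "16s" else "8u"
  if (is.null(scale)) scale <- if (width == "8u") 3 / log(2) else 16
  if (is.null(base))  base  <- if (width == "8u") 190L else 12000L
  if (is.null(tloop)) tloop <- if (seq_len > 0) log2(seq_len / (seq_len + 3)) else -Inf
  if (is.null(tmove)) tmove <- log2(3 / (seq_len + 3))
  if (is.null(tbm))   tbm   <- log2(2 / (L * (L + 1)))
  if (is.null(tec))   tec   <- -1
  if (is.null(tej))   tej   <- tec
  out <- list(stage = stage, width = width, scale = scale,
              base = as.integer(base),
              bits = list(tloop = tloop, tmove = tmove, tbm = tbm,
                          tec = tec, tej = tej))
  if (width == "8u") {
    cost <- function(t) as.integer(min(255, max(0, round(-scale * t))))
    out$c_loop <- cost(tloop); out$c_move <- cost(tmove)
    out$c_bm <- cost(tbm); out$c_ec <- cost(tec)
  } else {
    d16 <- function(t) if (!is.finite(t)) -32768L else
      as.integer(min(0, max(-32767, round(scale * t))))
    out$t_loop <- d16(tloop); out$t_move <- d16(tmove)
    out$t_bm <- d16(tbm); out$t_ec <- d16(tec); out$t_ej <- d16(tej)
  }
  structure(out, class = "filter_constants")
}

#' @export
print.filter_constants <- function(x, ...) {
  cat(sprintf("<filter_constants %s (%s), base = %d, scale = %.4g>\n",
              x$stage, x$width, x$base, x$scale))
  invisible(x)
}

# 8u emission handling: add-bias B then subtract per-symbol cost C.
# B = max finite quantized value minus quantization bias (clamped >= 0);
# C = B - (v - bias) for finite values, 255 at sentinel cells, so a
# sentinel emission floors a cell exactly (sat_add caps at 255, then
# subtracting 255 gives 0). Works identically on an L x 21 score matrix
# and on a striped Q x lanes x 21 array (padded cells are sentinels).
msv_bias_costs <- function(values, sentinel, bias) {
  fin <- values != sentinel
  B <- if (any(fin)) max(0L, max(values[fin]) - bias) else 0L
  C <- B - (values - bias)
  C[!fin] <- 255L
  C <- pmin.int(pmax.int(C, 0L), 255L)
  C <- array(as.integer(C), dim = dim(values))
  list(B = as.integer(B), C = C)
}

new_filter_record <- function(seq_id, stage, raw, base, scale, sentinel,
                              saturated, threshold, lazy_passes = NA_integer_) {
  bits <- if (raw == sentinel) -Inf else (raw - base) / scale
  structure(list(seq_id = seq_id, stage = stage,
                 raw_score = as.integer(raw), real_score = bits,
                 saturated = saturated,
                 passed = saturated || bits >= threshold,
                 lazy_passes = lazy_passes),
            class = "filter_record")
}

#' @export
print.filter_record <- function(x, ...) {
  cat(sprintf("<filter_record %s '%s': raw = %d, %.2f bits%s, %s>\n",
              toupper(x$stage), x$seq_id, x$raw_score, x$real_score,
              if (x$saturated) " (saturated)" else "",
              if (x$passed) "PASS" else "fail"))
  invisible(x)
}

# shared 8u row sweep for SSV/MSV: one DP row over Q stripes.
# Returns list(M = new Q x lanes matrix, xE = row maximum).
msv_row_sweep <- function(M_prev, Cx, B, xB_entry, Q, lanes) {
  mpv <- reorder_vec(M_prev[Q, ], 0L)
  xEv <- integer(lanes)
  M_new <- M_prev
  for (q in seq_len(Q)) {
    sv <- pmax.int(mpv, xB_entry)
    sv <- pmin.int(sv + B, 255L)           # sat_add bias
    sv <- pmax.int(sv - Cx[q, ], 0L)       # sat_sub cost
    xEv <- pmax.int(xEv, sv)
    mpv <- M_prev[q, ]
    M_new[q, ] <- sv
  }
  list(M = M_new, xE = max(xEv))
}

#' SSV filter score (striped engine)
#'
#' Best single ungapped diagonal segment under the SSV model, on the
#' striped 8-bit unsigned scheme. Empty sequences legally score at the
#' floor.
#'
#' @param seq A `digitized_seq`.
#' @param sp A `striped_profile` of width `"8u"` (see [stripe()]).
#' @param c A `filter_constants` for stage `"ssv"`, or `NULL` to derive
#'   per-sequence defaults.
#' @param threshold Pass threshold in bits (default `-Inf`: everything
#'   passes). A saturated score always passes (it is a lower bound).
#' @return A `filter_record`.
#' @export
ssv_score <- function(seq, sp, c = NULL, threshold = -Inf) {
  stopifnot(inherits(sp, "striped_profile"), sp$width == "8u")
  if (is.null(c)) c <- filter_constants("ssv", sp$L, seq$length,
                                        scale = sp$scale)
  bc <- msv_bias_costs(sp$emissions, sp$sentinel, sp$bias)
  Q <- sp$Q; lanes <- sp$geometry$lanes
  xB_entry <- max(0L, max(0L, c$base - c$c_move) - c$c_bm)
  M_prev <- matrix(0L, Q, lanes)
  xE_glob <- 0L; saturated <- FALSE
  for (x in seq$residues) {
    Cx <- matrix(bc$C[, , x + 1L], Q, lanes)
    sw <- msv_row_sweep(M_prev, Cx, bc$B, xB_entry, Q, lanes)
    M_prev <- sw$M
    if (sw$xE >= 255L - bc$B) saturated <- TRUE
    if (sw$xE > xE_glob) xE_glob <- sw$xE
  }
  raw <- max(0L, max(0L, xE_glob - c$c_ec) - c$c_move)
  new_filter_record(seq$id, "ssv", raw, c$base, c$scale, 0L,
                    saturated, threshold)
}

#' MSV filter score (striped engine)
#'
#' Multiple ungapped segment score: the SSV row sweep plus per-row
#' special-state updates `xJ <- max(xJ - c_loop, xE - c_ec)` and
#' `xB <- max(base, xJ) - c_move`, the J state allowing high-scoring
#' segments to chain. One lane reorder per row satisfies the diagonal
#' dependency.
#'
#' @inheritParams ssv_score
#' @param c A `filter_constants` for stage `"msv"`, or `NULL`.
#' @return A `filter_record`.
#' @export
msv_score <- function(seq, sp, c = NULL, threshold = -Inf) {
  stopifnot(inherits(sp, "striped_profile"), sp$width == "8u")
  if (is.null(c)) c <- filter_constants("msv", sp$L, seq$length,
                                        scale = sp$scale)
  bc <- msv_bias_costs(sp$emissions, sp$sentinel, sp$bias)
  Q <- sp$Q; lanes <- sp$geometry$lanes
  M_prev <- matrix(0L, Q, lanes)
  xJ <- 0L
  xB <- max(0L, c$base - c$c_move)
  xC <- 0L
  saturated <- FALSE
  for (x in seq$residues) {
    xB_entry <- max(0L, xB - c$c_bm)
    Cx <- matrix(bc$C[, , x + 1L], Q, lanes)
    sw <- msv_row_sweep(M_prev, Cx, bc$B, xB_entry, Q, lanes)
    M_prev <- sw$M
    if (sw$xE >= 255L - bc$B) saturated <- TRUE
    xEJ <- max(0L, sw$xE - c$c_ec)
    xJ <- max(max(0L, xJ - c$c_loop), xEJ)
    xC <- max(xC, xEJ)                       # C self-loop is free
    xB <- max(0L, max(c$base, xJ) - c$c_move)
  }
  raw <- max(0L, xC - c$c_move)
  new_filter_record(seq$id, "msv", raw, c$base, c$scale, 0L,
                    saturated, threshold)
}

## ---------------------------------------------------------------------
## Viterbi

#' Quantize the full core model (emissions + transitions) to 16s
#'
#' @param model A `profile_hmm` with transitions.
#' @param scale Units per bit (default 16).
#' @param bias Emission bias (default 0).
#' @return Object of class `quantized_core`: the 16s emission
#'   `quantized_scores` plus an `L x 7` integer transition matrix on
#'   the same scale.
#' @export
quantize_core <- function(model, scale = NULL, bias = NULL) {
  stopifnot(inherits(model, "profile_hmm"))
  if (is.null(model$transitions))
    stop("Viterbi quantization needs a model with transitions", call. = FALSE)
  em <- quantize(model, "16s", scale, bias)
  tr <- quantize_matrix(model$transitions, "16s", em$scale, 0L)
  structure(list(emissions = em, transitions = tr, L = model$L,
                 scale = em$scale, bias = em$bias, sentinel = -32768L),
            class = "quantized_core")
}

#' @export
print.quantized_core <- function(x, ...) {
  cat(sprintf("<quantized_core L = %d, scale = %.4g>\n", x$L, x$scale))
  invisible(x)
}

#' Build the striped Viterbi profile
#'
#' Emissions and all transition score vectors quantized to 16-bit
#' signed units and rearranged into the striped layout. Transition
#' grids are aligned the way the inner loop consumes them:
#' destination-aligned `MM`, `IM`, `DM` grids hold, at the cell of
#' state `k`, the transition out of state `k - 1` (sentinel at
#' `k = 1`); `MI`, `II` are aligned to `k`; source-aligned `MD`, `DD`
#' feed the Delete carry towards `k + 1`.
#'
#' @param x A `profile_hmm` with transitions, or a `quantized_core`.
#' @param geometry A [lane_geometry()] (default 32 threads x 2
#'   sublanes = 64 lanes).
#' @param scale,bias Passed to [quantize_core()] when `x` is a model.
#' @return A `striped_profile` of width `"16s"` with a `transitions`
#'   list of striped grids.
#' @export
striped_viterbi_profile <- function(x, geometry = lane_geometry(32L, 2L),
                                    scale = NULL, bias = NULL) {
  qc <- if (inherits(x, "quantized_core")) x
        else quantize_core(x, scale, bias)
  sp <- stripe(qc$emissions, geometry)
  L <- qc$L; Q <- sp$Q; lanes <- geometry$lanes
  sent <- -32768L
  tr <- qc$transitions
  dest <- function(col) stripe_vector(c(sent, tr[-L, col]), Q, lanes, sent)
  here <- function(col) stripe_vector(tr[, col], Q, lanes, sent)
  sp$transitions <- list(
    MM = dest("MM"), IM = dest("IM"), DM = dest("DM"),
    MI = here("MI"), II = here("II"),
    MD = here("MD"), DD = here("DD"))
  sp
}

sat16 <- function(x) pmin.int(pmax.int(x, -32768L), 32767L)

#' Plan-7 Viterbi filter score (striped engine with Lazy-F)
#'
#' Full Match/Insert/Delete filter score in saturating 16-bit signed
#' arithmetic. Insert emissions are scored at 0. The sequential
#' Delete-Delete recursion is evaluated lazily: an initial within-
#' stripe pass produces a candidate Delete row plus a carry register,
#' then reorder-and-propagate passes run only until a full pass changes
#' nothing, at which point the row equals the strict sequential
#' recursion (a hard cap of `lanes` passes guards against bugs).
#'
#' @param seq A `digitized_seq`.
#' @param sp A `striped_profile` from [striped_viterbi_profile()].
#' @param c A `filter_constants` for stage `"vit"`, or `NULL`.
#' @param threshold Pass threshold in bits.
#' @return A `filter_record`; field `lazy_passes` holds the maximum
#'   number of Lazy-F check passes used on any row.
#' @export
viterbi_score <- function(seq, sp, c = NULL, threshold = -Inf) {
  stopifnot(inherits(sp, "striped_profile"), sp$width == "16s",
            !is.null(sp$transitions))
  if (is.null(c)) c <- filter_constants("vit", sp$L, seq$length,
                                        scale = sp$scale)
  Q <- sp$Q; lanes <- sp$geometry$lanes
  sent <- -32768L
  tr <- sp$transitions
  M_prev <- matrix(sent, Q, lanes)
  I_prev <- matrix(sent, Q, lanes)
  D_prev <- matrix(sent, Q, lanes)
  xN <- c$base; xJ <- sent; xC <- sent
  xB <- sat16(xN + c$t_move)
  saturated <- FALSE; max_passes <- 0L
  for (x in seq$residues) {
    Ex <- matrix(sp$emissions[, , x + 1L], Q, lanes)
    xBe <- sat16(xB + c$t_bm)
    mpv <- reorder_vec(M_prev[Q, ], sent)
    ipv <- reorder_vec(I_prev[Q, ], sent)
    dpv <- reorder_vec(D_prev[Q, ], sent)
    dcv <- rep(sent, lanes)
    xEv <- rep(sent, lanes)
    M_new <- M_prev; I_new <- I_prev; D_new <- D_prev
    for (q in seq_len(Q)) {
      sv <- pmax.int(rep(xBe, lanes), sat16(mpv + tr$MM[q, ]))
      sv <- pmax.int(sv, sat16(ipv + tr$IM[q, ]))
      sv <- pmax.int(sv, sat16(dpv + tr$DM[q, ]))
      sv <- sat16(sv + Ex[q, ])
      xEv <- pmax.int(xEv, sv)
      mpv <- M_prev[q, ]; ipv <- I_prev[q, ]; dpv <- D_prev[q, ]
      M_new[q, ] <- sv
      D_new[q, ] <- dcv
      dcv <- pmax.int(sat16(sv + tr$MD[q, ]), sat16(dcv + tr$DD[q, ]))
      I_new[q, ] <- pmax.int(sat16(mpv + tr$MI[q, ]), sat16(ipv + tr$II[q, ]))
    }
    # Lazy-F: one unconditional merge pass folds the end-of-row carry
    # into the candidate Delete row across the lane boundary; check
    # passes then repeat only while a full pass still changes the row.
    dcv <- reorder_vec(dcv, sent)
    for (q in seq_len(Q)) {
      D_new[q, ] <- pmax.int(D_new[q, ], dcv)
      dcv <- sat16(D_new[q, ] + tr$DD[q, ])
    }
    passes <- 0L
    repeat {
      dcv <- reorder_vec(dcv, sent)
      changed <- FALSE
      for (q in seq_len(Q)) {
        nd <- pmax.int(D_new[q, ], dcv)
        if (!changed && any(nd != D_new[q, ])) changed <- TRUE
        D_new[q, ] <- nd
        dcv <- sat16(nd + tr$DD[q, ])
      }
      passes <- passes + 1L
      if (!changed) break
      if (passes > lanes)
        stop("internal error: Lazy-F failed to converge", call. = FALSE)
    }
    if (passes > max_passes) max_passes <- passes
    M_prev <- M_new; I_prev <- I_new; D_prev <- D_new
    xE <- max(xEv)
    if (xE >= 32767L) saturated <- TRUE
    xJ <- max(sat16(xJ + c$t_loop), sat16(xE + c$t_ej))
    xC <- max(sat16(xC + c$t_loop), sat16(xE + c$t_ec))
    xN <- sat16(xN + c$t_loop)
    xB <- max(sat16(xN + c$t_move), sat16(xJ + c$t_move))
  }
  raw <- if (xC == sent) sent else sat16(xC + c$t_move)
  new_filter_record(seq$id, "vit", raw, c$base, c$scale, sent,
                    saturated, threshold, lazy_passes = max_passes)
}
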