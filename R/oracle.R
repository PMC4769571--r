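# Naive, obviously-correct sequential DP implementations of the three
# filters on the same quantized integers as the striped engine. In
# saturating mode every operation clamps exactly where the engine
# clamps (saturation is not associative, so the clipping order is part
# of the contract); the Delete recursion runs as a strict sequential
# k-loop. In unsaturated mode scores are plain numerics with -Inf and
# no clamping, which is the mode the SSV <= MSV dominance argument
# lives in.

# emission deltas relative to the path offset: finite -> v - bias as a
# saturated two-op add (8u) or plain add (16s); sentinel -> floor.
msv_apply_emission <- function(sv, Ccol, B) {
  sv <- pmin.int(sv + B, 255L)
  pmax.int(sv - Ccol, 0L)
}

#' Naive SSV score
#'
#' Full `O(L * len)` two-loop DP over the single-ungapped-segment
#' model, sequential over states, no striping.
#'
#' @param seq A `digitized_seq`.
#' @param scores A `quantized_scores` of width `"8u"` (same integers
#'   the engine stripes).
#' @param c A `filter_constants` for stage `"ssv"`.
#' @param saturating If `TRUE` (default), reproduce the engine's
#'   per-operation 8-bit clamping and return the raw integer score; if
#'   `FALSE`, compute in unbounded arithmetic with `-Inf` sentinels and
#'   return a numeric (possibly `-Inf`) score in the same integer
#'   units.
#' @return Raw score (integer, or numeric when `saturating = FALSE`).
#' @export
naive_ssv <- function(seq, scores, c, saturating = TRUE) {
  stopifnot(inherits(scores, "quantized_scores"), scores$width == "8u")
  L <- scores$L
  if (saturating) {
    bc <- msv_bias_costs(scores$values, scores$sentinel, scores$bias)
    xBe <- max(0L, max(0L, c$base - c$c_move) - c$c_bm)
    M <- integer(L); xE <- 0L
    for (x in seq$residues) {
      mp <- c(0L, M[-L])[seq_len(L)]
      sv <- msv_apply_emission(pmax.int(mp, xBe), bc$C[, x + 1L], bc$B)
      xE <- max(xE, sv)
      M <- sv
    }
    max(0L, max(0L, xE - c$c_ec) - c$c_move)
  } else {
    d <- msv_delta(scores)
    xBe <- c$base - c$c_move - c$c_bm
    M <- rep(-Inf, L); xE <- -Inf
    for (x in seq$residues) {
      mp <- c(-Inf, M[-L])[seq_len(L)]
      sv <- pmax(mp, xBe) + d[, x + 1L]
      xE <- max(xE, sv)
      M <- sv
    }
    xE - c$c_ec - c$c_move
  }
}

# unsaturated emission deltas (numeric, -Inf at sentinels)
msv_delta <- function(scores) {
  d <- scores$values - scores$bias
  d[scores$values == scores$sentinel] <- -Inf
  d
}

#' Naive MSV score
#'
#' As [naive_ssv()] plus the sequential special-state updates after
#' each row: `xJ <- max(xJ - c_loop, xE - c_ec)`,
#' `xB <- max(base, xJ) - c_move`, with the running best exit tracked
#' by a free-looping C state.
#'
#' @inheritParams naive_ssv
#' @param c A `filter_constants` for stage `"msv"`.
#' @return Raw score as in [naive_ssv()].
#' @export
naive_msv <- function(seq, scores, c, saturating = TRUE) {
  stopifnot(inherits(scores, "quantized_scores"), scores$width == "8u")
  L <- scores$L
  if (saturating) {
    bc <- msv_bias_costs(scores$values, scores$sentinel, scores$bias)
    M <- integer(L); xJ <- 0L; xC <- 0L
    xB <- max(0L, c$base - c$c_move)
    for (x in seq$residues) {
      xBe <- max(0L, xB - c$c_bm)
      mp <- c(0L, M[-L])[seq_len(L)]
      sv <- msv_apply_emission(pmax.int(mp, xBe), bc$C[, x + 1L], bc$B)
      M <- sv
      xE <- max(sv)
      xEJ <- max(0L, xE - c$c_ec)
      xJ <- max(max(0L, xJ - c$c_loop), xEJ)
      xC <- max(xC, xEJ)
      xB <- max(0L, max(c$base, xJ) - c$c_move)
    }
    max(0L, xC - c$c_move)
  } else {
    d <- msv_delta(scores)
    M <- rep(-Inf, L); xJ <- -Inf; xC <- -Inf
    xB <- c$base - c$c_move
    for (x in seq$residues) {
      xBe <- xB - c$c_bm
      mp <- c(-Inf, M[-L])[seq_len(L)]
      sv <- pmax(mp, xBe) + d[, x + 1L]
      M <- sv
      xEJ <- max(sv) - c$c_ec
      xJ <- max(xJ - c$c_loop, xEJ)
      xC <- max(xC, xEJ)
      xB <- max(c$base, xJ) - c$c_move
    }
    xC - c$c_move
  }
}

#' Naive Plan-7 Viterbi filter score
#'
#' Strictly sequential DP: Match/Insert recursions over the previous
#' row and, crucially, the Delete state evaluated by the sequential
#' `k = 2..L` recursion `D[k] = max(M[k-1] + tMD, D[k-1] + tDD)` —
#' the reference the engine's Lazy-F evaluation must match bit-exactly.
#'
#' @param seq A `digitized_seq`.
#' @param qc A `quantized_core` (see [quantize_core()]).
#' @param c A `filter_constants` for stage `"vit"`.
#' @param saturating As in [naive_ssv()].
#' @return Raw score (integer, or numeric when `saturating = FALSE`).
#' @export
naive_viterbi <- function(seq, qc, c, saturating = TRUE) {
  stopifnot(inherits(qc, "quantized_core"))
  L <- qc$L
  sent <- -32768L
  if (saturating) {
    em <- qc$emissions$values
    tr <- qc$transitions
    add <- function(a, b) pmin.int(pmax.int(a + b, -32768L), 32767L)
    neg <- sent
  } else {
    em <- qc$emissions$values + 0      # numeric; engine adds 16s values as-is
    em[qc$emissions$values == sent] <- -Inf
    tr <- qc$transitions
    tr <- ifelse(tr == sent, -Inf, tr)
    add <- function(a, b) a + b
    neg <- -Inf
    c <- unsat_constants(c)
  }
  tMMd <- c(neg, tr[-L, "MM"]); tIMd <- c(neg, tr[-L, "IM"])
  tDMd <- c(neg, tr[-L, "DM"])
  tMI <- tr[, "MI"]; tII <- tr[, "II"]
  tMDs <- tr[, "MD"]; tDDs <- tr[, "DD"]
  M <- rep(neg, L); I <- rep(neg, L); D <- rep(neg, L)
  xN <- c$base; xJ <- neg; xC <- neg
  xB <- add(xN, c$t_move)
  for (x in seq$residues) {
    xBe <- add(xB, c$t_bm)
    mp <- c(neg, M[-L])[seq_len(L)]
    ip <- c(neg, I[-L])[seq_len(L)]
    dp <- c(neg, D[-L])[seq_len(L)]
    sv <- pmax(rep(xBe, L), add(mp, tMMd), add(ip, tIMd), add(dp, tDMd))
    sv <- add(sv, em[, x + 1L])
    I <- pmax(add(M, tMI), add(I, tII))
    Dn <- rep(neg, L)
    if (L >= 2) for (k in 2:L)
      Dn[k] <- max(add(sv[k - 1L], tMDs[k - 1L]), add(Dn[k - 1L], tDDs[k - 1L]))
    M <- sv; D <- Dn
    xE <- max(sv)
    xJ <- max(add(xJ, c$t_loop), add(xE, c$t_ej))
    xC <- max(add(xC, c$t_loop), add(xE, c$t_ec))
    xN <- add(xN, c$t_loop)
    xB <- max(add(xN, c$t_move), add(xJ, c$t_move))
  }
  if (saturating) {
    if (xC == sent) sent else add(xC, c$t_move)
  } else xC + c$t_move
}

# map 16s sentinel constants to -Inf for unsaturated mode
unsat_constants <- function(c) {
  for (f in c("t_loop", "t_move", "t_bm", "t_ec", "t_ej"))
    if (c[[f]] == -32768L) c[[f]] <- -Inf
  c
}
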