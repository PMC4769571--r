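# Shared fixtures and independent brute-force oracles for the suite.

# A random (model, sequence, geometry) triple under a fixed seed.
rand_case <- function(i, L_range = c(3, 200), len_range = c(0, 300),
                      p_neginf = 0.03, dd_range = c(0.1, 0.5),
                      warps = c(4, 8, 16, 32), alphas = c(1, 2, 4)) {
  withr::with_seed(90000 + i, {
    L <- sample(L_range[1]:L_range[2], 1)
    len <- sample(len_range[1]:len_range[2], 1)
    geom <- lane_geometry(sample(warps, 1), sample(alphas, 1))
    list(L = L, len = len, geom = geom)
  })
}

rand_seq <- function(len, seed) {
  if (len == 0)
    return(structure(list(id = "empty", residues = integer(0), length = 0L),
                     class = "digitized_seq"))
  gen_sequences(1, len, len, seed = seed)[[1]]
}

# -Inf-aware numeric view of quantized emission values
delta_view <- function(qs) {
  d <- qs$values - qs$bias
  d[qs$values == qs$sentinel] <- -Inf
  d
}

# Brute-force enumeration of all segment sets under the multi-segment
# ungapped model (single_segment = TRUE restricts to the SSV model),
# in unbounded arithmetic. Independent of the DP recurrences: scores
# are summed per explicit segment placement.
enum_msv <- function(seq, qs, c, single_segment = FALSE) {
  L <- qs$L; len <- seq$length; x <- seq$residues
  d <- delta_view(qs)
  segs <- list()
  for (a in seq_len(len)) for (k in seq_len(L)) {
    mmax <- min(len - a, L - k) + 1L
    for (mlen in seq_len(mmax)) {
      E <- sum(d[cbind(k:(k + mlen - 1L), x[a:(a + mlen - 1L)] + 1L)])
      segs[[length(segs) + 1L]] <- list(a = a, b = a + mlen - 1L, E = E)
    }
  }
  best <- -Inf
  score_set <- function(set) {
    m <- length(set)
    gaps <- if (m > 1) sum(vapply(seq_len(m - 1), function(j)
      set[[j + 1]]$a - set[[j]]$b - 1L, numeric(1))) else 0
    c$base - m * (c$c_bm + c$c_ec) - m * c$c_move - c$c_move +
      sum(vapply(set, `[[`, numeric(1), "E")) - gaps * c$c_loop
  }
  grow <- function(set, from) {
    if (length(set)) best <<- max(best, score_set(set))
    if (single_segment && length(set) >= 1) return()
    for (si in seq_along(segs)) {
      sg <- segs[[si]]
      if (sg$a > from) grow(c(set, list(sg)), sg$b)
    }
  }
  grow(list(), 0L)
  best
}

# Exhaustive Plan-7 path enumeration (multi-domain, unbounded
# arithmetic): recursive walk over every legal state path, no
# memoization — the oracle of the Viterbi oracle for tiny instances.
enum_viterbi <- function(seq, qc, c) {
  L <- qc$L; len <- seq$length; x <- seq$residues
  em <- qc$emissions$values + 0
  em[qc$emissions$values == -32768L] <- -Inf
  tr <- ifelse(qc$transitions == -32768L, -Inf, qc$transitions)
  cc <- c
  for (f in c("t_loop", "t_move", "t_bm", "t_ec", "t_ej"))
    if (cc[[f]] == -32768L) cc[[f]] <- -Inf
  best <- -Inf
  finish <- function(i, s) {
    best <<- max(best, s + cc$t_ec + (len - i) * cc$t_loop + cc$t_move)
    for (g in 0:(len - i))
      from_B(i + g, s + cc$t_ej + g * cc$t_loop + cc$t_move)
  }
  from_B <- function(i, s) {
    if (i >= len || !is.finite(s)) return()
    for (k in seq_len(L))
      core(i + 1L, k, "M", s + cc$t_bm + em[k, x[i + 1L] + 1L])
  }
  core <- function(i, k, st, s) {
    if (!is.finite(s)) return()
    if (st == "M") {
      finish(i, s)
      if (k < L && i < len)
        core(i + 1L, k + 1L, "M", s + tr[k, "MM"] + em[k + 1L, x[i + 1L] + 1L])
      if (i < len) core(i + 1L, k, "I", s + tr[k, "MI"])
      if (k < L) core(i, k + 1L, "D", s + tr[k, "MD"])
    } else if (st == "I") {
      if (k < L && i < len)
        core(i + 1L, k + 1L, "M", s + tr[k, "IM"] + em[k + 1L, x[i + 1L] + 1L])
      if (i < len) core(i + 1L, k, "I", s + tr[k, "II"])
    } else {
      if (k < L && i < len)
        core(i + 1L, k + 1L, "M", s + tr[k, "DM"] + em[k + 1L, x[i + 1L] + 1L])
      if (k < L) core(i, k + 1L, "D", s + tr[k, "DD"])
    }
  }
  for (a in 0:len) from_B(a, c$base + a * cc$t_loop + cc$t_move)
  best
}

# Hand-specified 2-state core model with small integer scores (scale 1,
# bias 0) for the worked Viterbi example.
tiny_worked_model <- function() {
  em <- matrix(0, 2, 20)
  em[1, 1] <- 5    # state 1 emits A at +5
  em[2, 2] <- 4    # state 2 emits C at +4
  profile_model("tiny", em, transitions = cbind(
    MM = c(-1, 0), MI = c(-4, -4), MD = c(-5, -5),
    IM = c(-2, -2), II = c(-6, -6), DM = c(-3, -3), DD = c(-2, -2)))
}

tiny_worked_constants <- function(len)
  filter_constants("vit", L = 2, seq_len = len, scale = 1, base = 100L,
                   tloop = -2, tmove = -1, tbm = -3, tec = -1, tej = -1)
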