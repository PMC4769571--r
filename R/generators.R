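# Synthetic fixture generators: random sequence databases, random
# profile models with a consensus motif, and motif planting. All are
# deterministic under an explicit seed.

#' Generate random protein sequences
#'
#' Residues are i.i.d. uniform over the 20 standard amino acids;
#' lengths uniform on `[len_min, len_max]`.
#'
#' @param n Number of sequences (>= 0).
#' @param len_min,len_max Length range (inclusive).
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @param prefix Id prefix.
#' @return List of `digitized_seq`.
#' @export
gen_sequences <- function(n, len_min = 50L, len_max = 300L, seed = 1L,
                          prefix = "seq") {
  len_min <- as.integer(len_min); len_max <- as.integer(len_max)
  stopifnot(n >= 0, len_min >= 0, len_max >= len_min)
  if (n == 0) return(list())
  withr::with_seed(as.integer(seed), {
    lens <- len_min + sample.int(len_max - len_min + 1L, n, replace = TRUE) - 1L
    lapply(seq_len(n), function(i)
      structure(list(id = sprintf("%s%04d", prefix, i),
                     residues = sample(0:19, lens[i], replace = TRUE),
                     length = lens[i]),
                class = "digitized_seq"))
  })
}

#' Generate a random profile model
#'
#' Each state gets a random consensus residue whose match emission is
#' `motif_strength` bits; off-consensus emissions are uniform on
#' `bg_range` bits (with probability `p_neginf`, `-Inf` instead).
#' Core transitions are drawn from realistic ranges; `dd_range` is the
#' Delete self-continuation probability range — push it towards 1 to
#' build models with strong D-D chains.
#'
#' @param L Model length (>= 1).
#' @param seed RNG seed.
#' @param motif_strength Consensus match emission, bits.
#' @param bg_range Off-consensus emission range, bits.
#' @param p_neginf Probability an off-consensus emission is `-Inf`.
#' @param dd_range Range of the D -> D probability.
#' @param name Model name.
#' @return A `profile_hmm` with an extra `consensus` field (codes
#'   0..19).
#' @export
gen_model <- function(L, seed = 1L, motif_strength = 2,
                      bg_range = c(-3, -0.5), p_neginf = 0,
                      dd_range = c(0.1, 0.5), name = NULL) {
  stopifnot(L >= 1)
  withr::with_seed(as.integer(seed), {
    cons <- sample(0:19, L, replace = TRUE)
    em <- matrix(runif(L * 20, bg_range[1], bg_range[2]), L, 20)
    if (p_neginf > 0)
      em[matrix(runif(L * 20) < p_neginf, L, 20)] <- -Inf
    em[cbind(seq_len(L), cons + 1L)] <- motif_strength
    mi <- runif(L, 0.005, 0.05); md <- runif(L, 0.005, 0.05)
    ii <- runif(L, 0.1, 0.5);    dd <- runif(L, dd_range[1], dd_range[2])
    tr <- cbind(MM = log2(1 - mi - md), MI = log2(mi), MD = log2(md),
                IM = log2(1 - ii), II = log2(ii),
                DM = log2(1 - dd), DD = log2(dd))
    m <- profile_model(if (is.null(name)) sprintf("synth_L%d_s%d", L, seed)
                       else name,
                       em, insert_emissions = matrix(0, L, 20),
                       transitions = tr)
    m$consensus <- cons
    m
  })
}

#' Plant a model's consensus motif into a sequence
#'
#' Overwrites `length(consensus)` residues starting at 1-based `pos`;
#' the sequence length is unchanged. The motif must fit:
#' `pos + L - 1 <= length(seq)`.
#'
#' @param seq A `digitized_seq`.
#' @param model A `profile_hmm` (its `consensus` field, or the
#'   per-state argmax emission if absent).
#' @param pos 1-based start position.
#' @return The modified `digitized_seq`.
#' @export
plant_motif <- function(seq, model, pos) {
  cons <- model$consensus
  if (is.null(cons))
    cons <- apply(model$match_emissions, 1, which.max) - 1L
  if (pos < 1 || pos + model$L - 1 > seq$length)
    stop(sprintf("pos %d out of range for motif of length %d in sequence of length %d",
                 pos, model$L, seq$length), call. = FALSE)
  seq$residues[pos:(pos + model$L - 1)] <- cons
  seq
}
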