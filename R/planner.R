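# Hardware-aware planning models: warp work assignment, occupancy of
# the shared- vs local-memory kernel variants, and variant selection by
# model size. The planner is an advisor only — filter scores are
# identical under either variant.

#' Device specification
#'
#' Defaults model a Kepler-class accelerator: 15 multiprocessors,
#' 2048 maximum resident threads and 48 KB of shared memory per
#' multiprocessor, warp size 32.
#'
#' @param N_smx Multiprocessor count.
#' @param S_thread Maximum resident threads per multiprocessor.
#' @param S_shared Shared-memory bytes per multiprocessor.
#' @param S_warp Warp size.
#' @return Object of class `device_spec`.
#' @export
device_spec <- function(N_smx = 15L, S_thread = 2048L,
                        S_shared = 49152L, S_warp = 32L) {
  sp <- lapply(list(N_smx = N_smx, S_thread = S_thread,
                    S_shared = S_shared, S_warp = S_warp), as.integer)
  stopifnot(all(unlist(sp) > 0))
  structure(sp, class = "device_spec")
}

#' Read a device specification from a YAML file
#'
#' Recognized keys: `N_smx`, `S_thread`, `S_shared`, `S_warp`; missing
#' keys keep the [device_spec()] defaults.
#'
#' @param path YAML file path.
#' @return A `device_spec`.
#' @export
read_device_spec <- function(path) {
  y <- yaml::read_yaml(path)
  known <- intersect(names(y), c("N_smx", "S_thread", "S_shared", "S_warp"))
  do.call(device_spec, y[known])
}

#' @export
print.device_spec <- function(x, ...) {
  cat(sprintf("<device_spec %d SMX, %d threads/SMX, %d B shared/SMX, warp %d>\n",
              x$N_smx, x$S_thread, x$S_shared, x$S_warp))
  invisible(x)
}

#' Next sequence index for a warp
#'
#' The synchronization-free work schedule: warp `O_warp` (ordinal id
#' across all multiprocessors), having completed `C_warp` sequences,
#' takes sequence index `O_warp + C_warp * N_warp * N_smx`. The caller
#' stops once the index reaches the database size; the schedule
#' partitions any index range exactly.
#'
#' @param O_warp Warp ordinal, `0 <= O_warp < N_warp * N_smx`.
#' @param C_warp Per-warp completed-sequence counter, >= 0.
#' @param N_warp Resident warps per multiprocessor.
#' @param N_smx Multiprocessor count.
#' @return Integer sequence index (0-based).
#' @export
next_sequence_index <- function(O_warp, C_warp, N_warp, N_smx) {
  stopifnot(O_warp >= 0, C_warp >= 0, N_warp >= 1, N_smx >= 1)
  if (O_warp >= N_warp * N_smx)
    stop("O_warp out of range: must be < N_warp * N_smx", call. = FALSE)
  as.integer(O_warp + C_warp * N_warp * N_smx)
}

#' Partition sequence indices across warps
#'
#' Applies [next_sequence_index()] for every warp until the database is
#' exhausted.
#'
#' @param n_seq Database size.
#' @param N_warp Resident warps per multiprocessor.
#' @param N_smx Multiprocessor count.
#' @return List (one element per warp ordinal) of 0-based index vectors.
#' @export
warp_partition <- function(n_seq, N_warp, N_smx) {
  total_warps <- N_warp * N_smx
  lapply(seq_len(total_warps) - 1L, function(o) {
    idx <- integer(0); cw <- 0L
    repeat {
      i <- next_sequence_index(o, cw, N_warp, N_smx)
      if (i >= n_seq) break
      idx <- c(idx, i); cw <- cw + 1L
    }
    idx
  })
}

stage_alpha <- function(stage) if (tolower(stage) == "vit") 2L else 4L

#' Occupancy of a kernel variant
#'
#' Shared variant: the candidate Delete/Match row storage uses
#' `U = (Q + 1) * S_warp * 4 * N_warp` bytes per multiprocessor for
#' MSV/SSV and `(3 Q + 1) * S_warp * 4 * N_warp` for Viterbi (three DP
#' rows); the resident warp count is maximized subject to `U <=
#' S_shared` and `N_warp * S_warp <= S_thread`, and occupancy is
#' `P = N_warp * S_warp / S_thread * 100`. Local variant: alignment
#' rows live in per-thread local memory, shared usage is 0 and the
#' launched warp count (32 by default) is resident regardless of model
#' size.
#'
#' @param L Model length.
#' @param stage `"msv"`, `"ssv"` or `"vit"`.
#' @param variant `"shared"` or `"local"`.
#' @param dev A [device_spec()].
#' @param launched_warps Warps launched per multiprocessor for the
#'   local variant.
#' @return Object of class `occupancy_plan` with fields `Q`, `variant`,
#'   `N_hat_warp`, `U` (bytes per multiprocessor), `P` (percent) and
#'   `N_warp_launched`.
#' @export
occupancy <- function(L, stage = c("msv", "ssv", "vit"),
                      variant = c("shared", "local"),
                      dev = device_spec(), launched_warps = 32L) {
  stage <- match.arg(tolower(stage), c("msv", "ssv", "vit"))
  variant <- match.arg(variant)
  stopifnot(L >= 1)
  alpha <- stage_alpha(stage)
  Q <- compute_q(L, alpha, dev$S_warp)
  rows <- if (stage == "vit") 3L * Q + 1L else Q + 1L
  bytes_per_warp <- rows * dev$S_warp * 4L
  max_resident <- dev$S_thread %/% dev$S_warp
  if (variant == "shared") {
    n_hat <- min(dev$S_shared %/% bytes_per_warp, max_resident)
    if (n_hat < 1)
      stop(sprintf("infeasible: one warp needs %d B shared, only %d available",
                   bytes_per_warp, dev$S_shared), call. = FALSE)
    U <- bytes_per_warp * n_hat
    launched <- n_hat
  } else {
    n_hat <- min(as.integer(launched_warps), max_resident)
    U <- 0L
    launched <- as.integer(launched_warps)
  }
  P <- n_hat * dev$S_warp / dev$S_thread * 100
  structure(list(Q = Q, variant = variant, N_hat_warp = as.integer(n_hat),
                 U = as.integer(U), P = P,
                 N_warp_launched = as.integer(launched)),
            class = "occupancy_plan")
}

#' @export
print.occupancy_plan <- function(x, ...) {
  cat(sprintf("<occupancy_plan %s: Q = %d, %d resident warps, U = %d B, P = %.1f%%>\n",
              x$variant, x$Q, x$N_hat_warp, x$U, x$P))
  invisible(x)
}

#' Select the kernel variant for a model size
#'
#' Shared memory pays off only for small models; the default
#' crossovers are 300 states for MSV/SSV and 200 for Viterbi.
#'
#' @param L Model length.
#' @param stage `"msv"`, `"ssv"` or `"vit"`.
#' @param thresholds Named crossover lengths.
#' @return `"shared"` or `"local"`.
#' @export
select_variant <- function(L, stage = c("msv", "ssv", "vit"),
                           thresholds = c(msv = 300L, ssv = 300L, vit = 200L)) {
  stage <- match.arg(tolower(stage), c("msv", "ssv", "vit"))
  stopifnot(L >= 1)
  if (L <= thresholds[[stage]]) "shared" else "local"
}

#' Theoretical maximum model length via local memory
#'
#' With `N_local` KB of local memory per thread and three 4-byte DP
#' rows per state slot, a thread can hold
#' `(N_local * 1024 / (4 * 3)) - 1` stripe slots, bounding the model at
#' `((N_local * 1024 / 12) - 1) * alpha * S_warp + 1` states.
#'
#' @param N_local_kb Local memory per thread in KB (default 512).
#' @param alpha Sublanes per thread (2 for Viterbi).
#' @param S_warp Warp size.
#' @return Numeric upper bound on model length.
#' @export
max_local_model_length <- function(N_local_kb = 512, alpha = 2L, S_warp = 32L) {
  (N_local_kb * 1024 / (4 * 3) - 1) * alpha * S_warp + 1
}

#' Full per-stage plan for a model length
#'
#' Convenience wrapper: for each stage, the stripe interval, the
#' selected variant and the occupancy of both variants.
#'
#' @param L Model length.
#' @param dev A [device_spec()].
#' @param launched_warps Local-variant launch count.
#' @return Data frame with one row per stage.
#' @export
plan_stages <- function(L, dev = device_spec(), launched_warps = 32L) {
  do.call(rbind, lapply(c("ssv", "msv", "vit"), function(st) {
    sh <- tryCatch(occupancy(L, st, "shared", dev, launched_warps),
                   error = function(e) NULL)
    lo <- occupancy(L, st, "local", dev, launched_warps)
    data.frame(stage = st, L = L, Q = lo$Q,
               lanes = stage_alpha(st) * dev$S_warp,
               variant = select_variant(L, st),
               U_shared = if (is.null(sh)) NA_integer_ else sh$U,
               P_shared = if (is.null(sh)) NA_real_ else sh$P,
               P_local = lo$P)
  }))
}
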