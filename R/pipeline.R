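# The filter funnel: SSV -> MSV -> Viterbi over a sequence database
# with per-stage thresholds, per-sequence records and pass statistics.

#' Run the heuristic filter pipeline
#'
#' Every sequence is scored by SSV; SSV survivors (a saturated SSV
#' score always survives, since clipping can only underestimate) go on
#' to MSV; MSV survivors to the Viterbi filter. Thresholds are bit
#' scores; `-Inf` lets everything through.
#'
#' @param profile A `profile_hmm` (transitions required only when
#'   `"vit"` is among `stages`).
#' @param seqs List of `digitized_seq`.
#' @param thresholds Named numeric: bits per stage, e.g.
#'   `c(ssv = 10, msv = 10, vit = 15)`; missing stages default `-Inf`.
#' @param stages Character subset of `c("ssv", "msv", "vit")`, run in
#'   funnel order.
#' @param S_warp,alpha_msv,alpha_vit Lane geometry (defaults 32 x 4 =
#'   128 lanes for MSV/SSV, 32 x 2 = 64 for Viterbi).
#' @param variant_policy `"auto"`, `"shared"` or `"local"`; advisory
#'   (recorded in the report; scores are identical under any variant).
#' @param seed Recorded in the report metadata.
#' @return Object of class `pipeline_report`: `total_sequences`,
#'   `stages` (evaluated / passed / pass_fraction per stage),
#'   `records` (one row per evaluated sequence-stage) and `meta`.
#' @export
run_pipeline <- function(profile, seqs,
                         thresholds = c(ssv = -Inf, msv = -Inf, vit = -Inf),
                         stages = c("ssv", "msv", "vit"),
                         S_warp = 32L, alpha_msv = 4L, alpha_vit = 2L,
                         variant_policy = c("auto", "shared", "local"),
                         seed = NA_integer_) {
  stages <- match.arg(stages, c("ssv", "msv", "vit"), several.ok = TRUE)
  stages <- intersect(c("ssv", "msv", "vit"), stages)
  variant_policy <- match.arg(variant_policy)
  if (!is.numeric(thresholds) || is.null(names(thresholds)))
    stop("thresholds must be a named numeric vector of bit scores",
         call. = FALSE)
  thr <- c(ssv = -Inf, msv = -Inf, vit = -Inf)
  thr[names(thresholds)] <- thresholds

  sp8 <- if (any(c("ssv", "msv") %in% stages))
    stripe(quantize(profile, "8u"), lane_geometry(S_warp, alpha_msv))
  sp16 <- if ("vit" %in% stages)
    striped_viterbi_profile(profile, lane_geometry(S_warp, alpha_vit))

  ov <- profile$special_params
  consts <- function(stage, len)
    filter_constants(stage, profile$L, len,
                     scale = if (stage == "vit") sp16$scale else sp8$scale,
                     tloop = ov$tloop, tmove = ov$tmove,
                     tbm = ov$tbm, tec = ov$tec)

  recs <- list()
  alive <- rep(TRUE, length(seqs))
  for (stage in stages) {
    for (i in seq_along(seqs)) {
      if (!alive[i]) next
      s <- seqs[[i]]
      r <- switch(stage,
        ssv = ssv_score(s, sp8, consts("ssv", s$length), thr[["ssv"]]),
        msv = msv_score(s, sp8, consts("msv", s$length), thr[["msv"]]),
        vit = viterbi_score(s, sp16, consts("vit", s$length), thr[["vit"]]))
      recs[[length(recs) + 1L]] <- data.frame(
        seq_id = r$seq_id, stage = stage, raw_score = r$raw_score,
        bits = r$real_score, saturated = r$saturated, passed = r$passed)
      alive[i] <- r$passed
    }
  }
  records <- if (length(recs)) do.call(rbind, recs)
             else data.frame(seq_id = character(), stage = character(),
                             raw_score = integer(), bits = numeric(),
                             saturated = logical(), passed = logical())
  total <- length(seqs)
  stats <- do.call(rbind, lapply(stages, function(st) {
    r <- records[records$stage == st, , drop = FALSE]
    data.frame(stage = st, evaluated = nrow(r), passed = sum(r$passed),
               pass_fraction = if (total) sum(r$passed) / total else 0)
  }))
  structure(list(total_sequences = total, stages = stats,
                 records = records,
                 meta = list(profile = profile$name, thresholds = thr,
                             stages = stages, S_warp = S_warp,
                             alpha_msv = alpha_msv, alpha_vit = alpha_vit,
                             variant_policy = variant_policy,
                             variant = if (variant_policy == "auto")
                               select_variant(profile$L, "msv")
                             else variant_policy,
                             seed = seed)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Filter pipeline report — profile '%s', %d sequences\n",
              x$meta$profile, x$total_sequences))
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-4s evaluated %4d  passed %4d  pass_fraction %.3f\n",
                toupper(x$stages$stage[i]), x$stages$evaluated[i],
                x$stages$passed[i], x$stages$pass_fraction[i]))
  invisible(x)
}

#' Run the pipeline under the warp work schedule
#'
#' Partitions the database across `N_warp * N_smx` simulated warps via
#' [next_sequence_index()], runs the pipeline independently per warp
#' and merges the records back into database order. The merged report
#' is identical to the sequential [run_pipeline()] report.
#'
#' @inheritParams run_pipeline
#' @param N_warp Resident warps per multiprocessor.
#' @param N_smx Multiprocessor count.
#' @param ... Passed to [run_pipeline()].
#' @return A `pipeline_report`.
#' @export
run_pipeline_warped <- function(profile, seqs, N_warp = 4L, N_smx = 3L, ...) {
  parts <- warp_partition(length(seqs), N_warp, N_smx)
  sub <- lapply(parts, function(idx)
    if (length(idx)) run_pipeline(profile, seqs[idx + 1L], ...) else NULL)
  recs <- do.call(rbind, lapply(sub, function(r) if (is.null(r)) NULL else r$records))
  ids <- vapply(seqs, `[[`, character(1), "id")
  # restore database order within each stage
  stage_order <- c(ssv = 1L, msv = 2L, vit = 3L)
  recs <- recs[order(stage_order[recs$stage], match(recs$seq_id, ids)), ,
               drop = FALSE]
  rownames(recs) <- NULL
  template <- run_pipeline(profile, seqs[0], ...)
  stages <- template$meta$stages
  total <- length(seqs)
  stats <- do.call(rbind, lapply(stages, function(st) {
    r <- recs[recs$stage == st, , drop = FALSE]
    data.frame(stage = st, evaluated = nrow(r), passed = sum(r$passed),
               pass_fraction = if (total) sum(r$passed) / total else 0)
  }))
  out <- template
  out$total_sequences <- total
  out$stages <- stats
  out$records <- recs
  out
}

#' Write per-sequence filter records as TSV
#'
#' Fixed column layout: `seq_id`, `stage`, `raw_score`, `bits`,
#' `saturated`, `passed`.
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @export
write_report_tsv <- function(report, path) {
  write.table(report$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Convert a tail P-value to a bit-score threshold
#'
#' High filter scores are Gumbel/exponential tailed with slope
#' `lambda = log 2`; under calibration `(lambda, tau)` the score
#' exceeded with probability `p` is `tau - log(p) / lambda`. The
#' calibration constants are user-supplied (no calibration is
#' performed here).
#'
#' @param p Tail probability.
#' @param tau Location parameter, bits.
#' @param lambda Slope (natural-log units per bit), default `log(2)`.
#' @return Bit-score threshold.
#' @export
score_threshold_from_pvalue <- function(p, tau, lambda = log(2)) {
  stopifnot(p > 0, p <= 1)
  tau - log(p) / lambda
}
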