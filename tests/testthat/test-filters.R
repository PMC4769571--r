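test_that("a single-cell SSV alignment equals the closed-form entry+emission+exit score", {
  em <- matrix(-2, 1, 20); em[1, 1] <- 3      # L = 1, emits A at +3 bits
  m <- profile_model("one", em)
  qs <- quantize(m, "8u", scale = 1, bias = 10L)
  cs <- filter_constants("ssv", 1, 1, scale = 1, base = 100L,
                         tloop = -2, tmove = -1, tbm = -3, tec = -1)
  s <- digitize_sequence("a", "A")
  # entry = base - move - bm; cell = entry + (q(e) - bias); exit = - ec - move
  expected <- (100 - 1 - 3) + (qs$values[1, 1] - 10) - 1 - 1
  r <- ssv_score(s, stripe(qs, lane_geometry(2, 1)), cs)
  expect_equal(r$raw_score, expected)
  expect_equal(naive_ssv(s, qs, cs), expected)
  expect_false(r$saturated)
})

test_that("striped SSV/MSV/Viterbi equal the naive sequential DP bit-exactly (randomized)", {
  for (i in 1:40) {
    cfg <- rand_case(i, L_range = c(3, 120), len_range = c(0, 200))
    m <- gen_model(cfg$L, seed = 10 + i, p_neginf = 0.04,
                   dd_range = if (i %% 3 == 0) c(0.85, 0.99) else c(0.1, 0.5))
    s <- rand_seq(cfg$len, 7000 + i)
    qs <- quantize(m, "8u")
    sp <- stripe(qs, cfg$geom)
    cs <- filter_constants("ssv", cfg$L, s$length)
    cm <- filter_constants("msv", cfg$L, s$length)
    expect_identical(ssv_score(s, sp, cs)$raw_score, naive_ssv(s, qs, cs))
    expect_identical(msv_score(s, sp, cm)$raw_score, naive_msv(s, qs, cm))
    qc <- quantize_core(m)
    spv <- striped_viterbi_profile(qc, cfg$geom)
    cv <- filter_constants("vit", cfg$L, s$length)
    expect_identical(viterbi_score(s, spv, cv)$raw_score,
                     naive_viterbi(s, qc, cv))
  }
})

test_that("a two-segment planted fixture scores strictly higher under MSV than SSV", {
  m <- gen_model(8, seed = 7, motif_strength = 2)
  s <- gen_sequences(1, 60, 60, seed = 8)[[1]]
  s <- plant_motif(s, m, 5)
  s <- plant_motif(s, m, 40)
  qs <- quantize(m, "8u")
  cs <- filter_constants("ssv", 8, 60)
  cm <- filter_constants("msv", 8, 60)
  v_ssv <- naive_ssv(s, qs, cs, saturating = FALSE)
  v_msv <- naive_msv(s, qs, cm, saturating = FALSE)
  expect_gt(v_msv, v_ssv)     # the J rejoin chains both segments
  # engine agrees with the saturating oracle on the same fixture
  sp <- stripe(qs)
  expect_identical(msv_score(s, sp, cm)$raw_score, naive_msv(s, qs, cm))
  expect_identical(ssv_score(s, sp, cs)$raw_score, naive_ssv(s, qs, cs))
})

test_that("Lazy-F exits after one check pass when the D-D chain is dead", {
  m <- gen_model(20, seed = 5)
  m$transitions[, "DD"] <- -Inf
  qc <- quantize_core(m)
  spv <- striped_viterbi_profile(qc, lane_geometry(4, 2))
  s <- gen_sequences(1, 40, 40, seed = 9)[[1]]
  cv <- filter_constants("vit", 20, 40)
  r <- viterbi_score(s, spv, cv)
  expect_equal(r$lazy_passes, 1L)
  expect_identical(r$raw_score, naive_viterbi(s, qc, cv))
})

test_that("an L = 1 model has the closed-form single-column Viterbi score", {
  em <- matrix(-2, 1, 20); em[1, 3] <- 4
  m <- profile_model("one", em,
                     transitions = cbind(MM = 0, MI = -4, MD = -5,
                                         IM = -2, II = -6, DM = -3, DD = -2))
  qc <- quantize_core(m, scale = 1, bias = 0)
  cv <- filter_constants("vit", 1, 1, scale = 1, base = 100L,
                         tloop = -2, tmove = -1, tbm = -3, tec = -1)
  s <- digitize_sequence("d", "D")
  expected <- 100 - 1 - 3 + 4 - 1 - 1
  expect_equal(viterbi_score(s, striped_viterbi_profile(qc, lane_geometry(2, 1)),
                             cv)$raw_score, expected)
  expect_equal(naive_viterbi(s, qc, cv), expected)
})

test_that("empty sequences are legal and score at the floor", {
  m <- gen_model(12, seed = 3)
  s <- structure(list(id = "e", residues = integer(0), length = 0L),
                 class = "digitized_seq")
  sp <- stripe(quantize(m, "8u"))
  expect_equal(ssv_score(s, sp)$raw_score, 0L)
  expect_equal(msv_score(s, sp)$raw_score, 0L)
  rv <- viterbi_score(s, striped_viterbi_profile(m))
  expect_equal(rv$raw_score, -32768L)
  expect_equal(rv$real_score, -Inf)
})

test_that("all-sentinel emissions floor every filter", {
  em <- matrix(-Inf, 6, 20)
  m <- profile_model("void", em)
  qs <- quantize(m, "8u")
  s <- gen_sequences(1, 30, 30, seed = 12)[[1]]
  expect_equal(msv_score(s, stripe(qs))$raw_score, 0L)
  expect_equal(ssv_score(s, stripe(qs))$raw_score, 0L)
})

test_that("8-bit overflow sets the saturation flag, which forces a pass", {
  m <- gen_model(30, seed = 21, motif_strength = 6)
  s <- gen_sequences(1, 120, 120, seed = 22)[[1]]
  s <- plant_motif(s, m, 10)
  s <- plant_motif(s, m, 60)
  qs <- quantize(m, "8u")
  cm <- filter_constants("msv", 30, 120)
  r <- msv_score(s, stripe(qs), cm, threshold = 1e6)
  expect_true(r$saturated)
  expect_true(r$passed)                      # clipped score is a lower bound
  expect_identical(r$raw_score, naive_msv(s, qs, cm))  # oracle clips identically
})

test_that("raising one emission never lowers a filter score", {
  for (i in 1:6) {
    m <- gen_model(15, seed = 30 + i)
    s <- gen_sequences(1, 50, 50, seed = 40 + i)[[1]]
    qs <- quantize(m, "8u")
    cs <- filter_constants("ssv", 15, 50)
    cm <- filter_constants("msv", 15, 50)
    base_ssv <- naive_ssv(s, qs, cs, saturating = FALSE)
    base_msv <- naive_msv(s, qs, cm, saturating = FALSE)
    qs2 <- qs
    # bump a random finite, non-maximal cell by one quantized unit
    cand <- which(qs$values > 0 & qs$values < max(qs$values), arr.ind = TRUE)
    pick <- cand[withr::with_seed(i, sample(nrow(cand), 1)), ]
    qs2$values[pick[1], pick[2]] <- qs$values[pick[1], pick[2]] + 1L
    expect_gte(naive_ssv(s, qs2, cs, saturating = FALSE), base_ssv)
    expect_gte(naive_msv(s, qs2, cm, saturating = FALSE), base_msv)
    # saturating path: same holds when the bumped cell is not the max
    expect_gte(naive_msv(s, qs2, cm), naive_msv(s, qs, cm))
  }
})

test_that("scores are invariant to lane padding and deterministic", {
  m <- gen_model(23, seed = 50, p_neginf = 0.05)
  s <- gen_sequences(1, 80, 80, seed = 51)[[1]]
  qs <- quantize(m, "8u")
  qc <- quantize_core(m)
  cs <- filter_constants("ssv", 23, 80)
  cm <- filter_constants("msv", 23, 80)
  cv <- filter_constants("vit", 23, 80)
  geoms <- list(lane_geometry(2, 2), lane_geometry(8, 1),
                lane_geometry(32, 4), lane_geometry(16, 4),
                lane_geometry(7, 3))
  ssv <- vapply(geoms, function(g)
    ssv_score(s, stripe(qs, g), cs)$raw_score, integer(1))
  msv <- vapply(geoms, function(g)
    msv_score(s, stripe(qs, g), cm)$raw_score, integer(1))
  vit <- vapply(geoms, function(g)
    viterbi_score(s, striped_viterbi_profile(qc, g), cv)$raw_score, integer(1))
  expect_equal(length(unique(ssv)), 1L)
  expect_equal(length(unique(msv)), 1L)
  expect_equal(length(unique(vit)), 1L)
  # determinism: identical inputs give identical records
  sp <- stripe(qs)
  expect_identical(msv_score(s, sp, cm), msv_score(s, sp, cm))
})
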