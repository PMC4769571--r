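test_that("digitization follows the canonical alphabet and ambiguity rules", {
  s <- digitize_sequence("s1", "ACDE")
  expect_equal(s$residues, c(0L, 1L, 2L, 3L))
  expect_equal(s$length, 4L)
  # case-insensitive; B/J/O/U/X/Z collapse to code 20
  expect_equal(digitize_sequence("s2", "acWy")$residues, c(0L, 1L, 18L, 19L))
  expect_equal(digitize_sequence("s3", "BXZJOU")$residues, rep(20L, 6))
  err <- tryCatch(digitize_sequence("s4", "AC*E"), error = conditionMessage)
  expect_match(err, "illegal residue")
  expect_match(err, "s4")
})

test_that("FASTA reading handles empty files, wrapped records and round-trips", {
  ef <- withr::local_tempfile(fileext = ".fa")
  file.create(ef)
  expect_length(read_fasta(ef), 0)

  writeLines(c(">s1 some description", "ACDE", "FGH", ">s2", "WY"), ef)
  recs <- read_fasta(ef)
  expect_equal(vapply(recs, `[[`, character(1), "id"), c("s1", "s2"))
  expect_equal(recs[[1]]$length, 7L)
  expect_equal(recs[[2]]$residues, c(18L, 19L))

  # 100 random records: lengths re-counted independently from the text
  seqs <- gen_sequences(100, 1, 300, seed = 404)
  seqs[[7]]$residues[1] <- 20L   # exercise the ambiguity letter
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  txt <- readLines(f)
  lens_txt <- tapply(nchar(txt), cumsum(startsWith(txt, ">")),
                     function(n) sum(n[-1]))
  expect_equal(as.integer(lens_txt),
               vapply(seqs, `[[`, integer(1), "length"))
  back <- read_fasta(f)
  expect_identical(lapply(back, function(s) s[c("id", "residues")]),
                   lapply(seqs, function(s) s[c("id", "residues")]))
})

test_that("quantization maps bias, sentinels and round-trip error as specified", {
  m <- gen_model(40, seed = 2, p_neginf = 0.1)
  m$match_emissions[3, 4] <- 0          # exact zero log-odds
  q8 <- quantize(m, "8u", scale = 3 / log(2), bias = 190L)
  expect_equal(q8$values[3, 4], 190L)   # zero maps to the bias
  q16 <- quantize(m, "16s")
  expect_true(all(q16$values[, 1:20][!is.finite(m$match_emissions)] == -32768L))

  # representable ranges and monotonicity over random models
  for (seed in 1:5) {
    mm <- gen_model(30, seed = seed, p_neginf = 0.08)
    for (w in c("8u", "16s")) {
      q <- quantize(mm, w)
      rng <- if (w == "8u") c(0L, 255L) else c(-32768L, 32767L)
      expect_true(all(q$values >= rng[1] & q$values <= rng[2]))
      e <- mm$match_emissions
      ord <- order(e)                    # monotone: s1 <= s2 => q1 <= q2
      expect_true(all(diff(q$values[, 1:20][ord]) >= 0))
    }
  }

  # de-quantization error bound for in-range finite scores
  q <- quantize(m, "8u")
  d <- dequantize(q)[, 1:20]
  fin <- is.finite(m$match_emissions) & q$values[, 1:20] > 0 &
         q$values[, 1:20] < 255
  expect_lt(max(abs(d[fin] - m$match_emissions[fin])), 0.5 / q$scale + 1e-12)
  expect_true(all(d[!is.finite(m$match_emissions)] == -Inf))
})

test_that("the TSV profile dialect reads hand-written files and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# hmmstripe-profile-tsv v1",
               "name\tmini", "length\t3",
               paste(c("match", 1, c(2, rep(-1, 19))), collapse = "\t"),
               paste(c("match", 2, c(-1, 3, rep(-1, 18))), collapse = "\t"),
               paste(c("match", 3, c(rep(-1, 19), "-inf")), collapse = "\t")),
             f)
  m <- read_profile(f)
  expect_s3_class(m, "profile_hmm")
  expect_equal(m$L, 3L)
  expect_equal(m$match_emissions[2, 2], 3)
  expect_equal(m$match_emissions[3, 20], -Inf)

  m2 <- gen_model(25, seed = 3, p_neginf = 0.02)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_profile(m2, f2)
  back <- read_profile(f2)
  expect_equal(back$match_emissions, m2$match_emissions, tolerance = 1e-5)
  expect_equal(back$transitions, m2$transitions, tolerance = 1e-5)
  expect_equal(back$name, m2$name)
})

test_that("the HMMER3/f subset parses generated files including L = 382", {
  m <- gen_model(25, seed = 6, p_neginf = 0.02)
  f <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3_profile(m, f)
  back <- read_profile(f)
  expect_equal(back$L, 25L)
  fin <- is.finite(m$match_emissions)
  expect_equal(back$match_emissions[fin], m$match_emissions[fin],
               tolerance = 1e-4)
  expect_identical(is.finite(back$match_emissions), fin)
  expect_equal(back$transitions[is.finite(m$transitions)],
               m$transitions[is.finite(m$transitions)], tolerance = 1e-4)

  big <- gen_model(382, seed = 7)
  f2 <- withr::local_tempfile(fileext = ".hmm")
  write_hmmer3_profile(big, f2)
  expect_equal(read_profile(f2)$L, 382L)
})

test_that("unsupported or truncated profile files fail with clear errors", {
  f <- withr::local_tempfile(fileext = ".hmm")
  writeLines("HMMER3/b [3.1b2]", f)
  expect_error(read_profile(f), "unsupported profile format version")
  m <- gen_model(10, seed = 8)
  write_hmmer3_profile(m, f)
  lines <- readLines(f)
  writeLines(lines[1:(length(lines) - 5)], f)   # chop mid node block
  expect_error(read_profile(f), "truncated|mismatch|expected node")
})
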