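rand_row <- function(geom, width, seed) {
  r <- if (width == "8u") c(0L, 255L) else c(-32768L, 32767L)
  withr::with_seed(seed,
    lane_row(sample(r[1]:r[2], geom$lanes, replace = TRUE), geom, width))
}

test_that("saturating add/sub clamp at the type bounds and match a scalar oracle", {
  g <- lane_geometry(2, 2)
  r8 <- function(v) lane_row(v, g, "8u")
  r16 <- function(v) lane_row(v, g, "16s")
  expect_equal(sat_add(r8(c(200, 1, 0, 255)), r8(c(100, 2, 0, 255)))$values,
               c(255L, 3L, 0L, 255L))
  expect_equal(sat_sub(r8(c(5, 7, 0, 255)), r8(c(10, 2, 1, 0)))$values,
               c(0L, 5L, 0L, 255L))
  expect_equal(sat_add(r16(c(-32768, 32767, 0, 5)), r16(c(-1, 1, 0, -5)))$values,
               c(-32768L, 32767L, 0L, 0L))

  scalar_clamp <- function(x, lo, hi) vapply(x, function(v)
    if (v < lo) lo else if (v > hi) hi else v, numeric(1))
  for (i in 1:40) {
    geom <- lane_geometry(sample(1:8, 1), sample(1:4, 1))
    w <- sample(c("8u", "16s"), 1)
    rng <- if (w == "8u") c(0, 255) else c(-32768, 32767)
    a <- rand_row(geom, w, i); b <- rand_row(geom, w, 1000 + i)
    expect_equal(sat_add(a, b)$values,
                 as.integer(scalar_clamp(a$values + b$values, rng[1], rng[2])))
    expect_equal(sat_sub(a, b)$values,
                 as.integer(scalar_clamp(a$values - b$values, rng[1], rng[2])))
    expect_equal(vmax(a, b)$values,
                 as.integer(pmax(a$values, b$values)))
  }
  expect_error(sat_add(rand_row(lane_geometry(2, 2), "8u", 1),
                       rand_row(lane_geometry(2, 4), "8u", 1)), "mismatch")
})

test_that("algebraic identities hold: additive zero, sentinel max, commutativity, associativity", {
  g <- lane_geometry(4, 4)
  zero <- lane_row(integer(g$lanes), g, "8u")
  sent16 <- lane_row(rep(-32768L, g$lanes), g, "16s")
  for (i in 1:10) {
    x <- rand_row(g, "8u", i)
    expect_identical(sat_add(x, zero)$values, x$values)
    expect_identical(sat_sub(x, zero)$values, x$values)
    y <- rand_row(g, "8u", 50 + i)
    z <- rand_row(g, "8u", 100 + i)
    expect_identical(vmax(x, y)$values, vmax(y, x)$values)
    expect_identical(vmax(x, x)$values, x$values)
    expect_identical(vmax(vmax(x, y), z)$values, vmax(x, vmax(y, z))$values)
    v <- rand_row(g, "16s", i)
    expect_identical(vmax(v, sent16)$values, v$values)
  }
})

test_that("reorder shifts one lane, injects the sentinel and is nilpotent", {
  g <- lane_geometry(4, 1)
  x <- lane_row(c(7L, 3L, 9L, 1L), g, "8u")
  expect_equal(reorder(x, 0L)$values, c(0L, 7L, 3L, 9L))
  # SSV-style signed-byte shift-in: the 0x80 pattern
  expect_equal(reorder(x, 0x80)$values, c(128L, 7L, 3L, 9L))

  # lanes applications drive any row to all-sentinel
  y <- rand_row(lane_geometry(8, 2), "16s", 4)
  for (i in seq_len(y$geometry$lanes)) y <- reorder(y, -32768L)
  expect_true(all(y$values == -32768L))

  # multiset preserved apart from the dropped lane and injected sentinel
  z <- rand_row(lane_geometry(8, 4), "8u", 5)
  rz <- reorder(z, 0L)
  expect_equal(sort(rz$values[-1]), sort(z$values[-z$geometry$lanes]))
})

test_that("max-reduction equals a linear scan over the sublanes", {
  g <- lane_geometry(8, 4)
  expect_equal(max_reduce(lane_row(rep(9L, g$lanes), g, "8u")), 9L)
  one_hot <- integer(g$lanes); one_hot[17] <- 255L
  expect_equal(max_reduce(lane_row(one_hot, g, "8u")), 255L)
  for (i in 1:1000) {
    w <- if (i %% 2) "8u" else "16s"
    r <- rand_row(g, w, 2000 + i)
    m <- r$values[1]
    for (v in r$values) if (v > m) m <- v   # explicit linear scan
    expect_identical(max_reduce(r), m)
  }
})
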