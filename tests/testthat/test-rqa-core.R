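test_that("delay embedding matches its closed form", {
  expect_equal(embed_delay(1:8, m = 1, tau = 3), matrix(1:8, ncol = 1))
  expect_equal(nrow(embed_delay(rnorm(10), m = 3, tau = 2)), 6)
  expect_equal(embed_delay(c(1, 2, 3, 4), m = 2, tau = 1),
               cbind(c(1, 2, 3), c(2, 3, 4)))
  expect_error(embed_delay(1:4, m = 3, tau = 2), "insufficient length.*5")
})

test_that("radius calibration hits the target recurrence rate", {
  # two points: the single pairwise distance is the answer at any level
  traj <- matrix(c(0, 3), ncol = 1)
  expect_equal(calibrate_radius(traj, target_rr = 0.01), 3)
  expect_equal(calibrate_radius(traj, target_rr = 0.99), 3)

  set.seed(4)
  x <- rnorm(100)
  prm <- embedding_params(m = 1, target_rr = 0.10)
  R <- recurrence_matrix(x, prm)
  expect_lt(abs(recurrence_rate(R) - 0.10), 0.02)
  # exhaustive oracle: the chosen radius is the empirical 10% quantile of
  # all pairwise distances
  d <- sort(as.numeric(dist(x)))
  expect_equal(R$eps, d[ceiling(0.10 * length(d))])

  R99 <- recurrence_matrix(x, embedding_params(m = 1, target_rr = 0.999))
  expect_gte(recurrence_rate(R99), 0.99)

  expect_error(calibrate_radius(matrix(1, 5, 1)), "degenerate")
})

test_that("recurrence rate is non-decreasing in the radius", {
  set.seed(8)
  x <- rnorm(60)
  rrs <- sapply(seq(0.1, 3, by = 0.2), function(eps) {
    recurrence_rate(recurrence_matrix(x, embedding_params(m = 2, radius = eps)))
  })
  expect_true(all(diff(rrs) >= 0))
})

test_that("auto recurrence matrices are symmetric with unit diagonal", {
  set.seed(2)
  s <- generate_element_series(fast_params(), rng_seed = 3)
  R <- recurrence_matrix(s, embedding_params())
  expect_identical(R$R, t(R$R))
  expect_true(all(diag(R$R)))
  expect_error(recurrence_matrix(rep(2, 30), embedding_params()), "degenerate")
})

test_that("an exactly periodic series recurs on multiples of its period", {
  x <- sin(2 * pi * (0:39) / 5)  # integer sampling: exact period 5
  R <- recurrence_matrix(x, embedding_params(m = 2, radius = 1e-9))
  ij <- which(R$R, arr.ind = TRUE)
  expect_true(all((ij[, 1] - ij[, 2]) %% 5 == 0))
  # and every in-phase pair recurs
  expect_equal(sum(R$R), sum(outer(1:39, 1:39, function(i, j) (i - j) %% 5 == 0)))
})

test_that("cross recurrence of a series with itself reproduces the auto matrix", {
  # fixed radius on an already-standardized series: the identity is exact
  set.seed(10)
  raw <- generate_element_series(fast_params(), rng_seed = 11)
  v <- (raw$values - mean(raw$values)) / sd(raw$values)
  s <- toothrqa:::new_element_series("A", "Zn", raw$times, v - min(v))
  s$values <- v  # bypass nonnegativity for this synthetic check
  prm <- embedding_params(radius = 0.5)
  auto <- recurrence_matrix(s$values, prm)
  cross <- cross_recurrence_matrix(s, s, prm)
  expect_equal(cross$kind, "CROSS")
  expect_identical(unname(cross$R), unname(auto$R))
})

test_that("z-normalization makes cross recurrence affine-invariant", {
  raw <- generate_element_series(fast_params(), rng_seed = 12)
  aff <- raw
  aff$values <- 3.7 * raw$values + 2
  prm <- embedding_params(radius = 0.4)
  self_cross <- cross_recurrence_matrix(raw, raw, prm)
  affine_cross <- cross_recurrence_matrix(raw, aff, prm)
  expect_identical(self_cross$R, affine_cross$R)
})

test_that("cross recurrence rejects degenerate inputs", {
  a <- toothrqa:::new_element_series("A", "Zn", 1:30, abs(rnorm(30)))
  b <- toothrqa:::new_element_series("A", "Cu", 31:60, abs(rnorm(30)))
  expect_error(cross_recurrence_matrix(a, b, embedding_params()), "disjoint supports")
  flat <- toothrqa:::new_element_series("A", "Cu", 1:30, rep(1, 30))
  expect_error(cross_recurrence_matrix(a, flat, embedding_params()), "zero variance")
})

test_that("independent noise shows weaker cross determinism than auto", {
  # auto plots carry the line of identity (theiler = 0 keeps it), which two
  # independent signals' cross plot lacks
  prm <- embedding_params(target_rr = 0.10, theiler = 0)
  diffs <- sapply(1:50, function(seed) {
    set.seed(seed)
    a <- toothrqa:::new_element_series("A", "Zn", 1:120, abs(rnorm(120, 5)))
    b <- toothrqa:::new_element_series("A", "Cu", 1:120, abs(rnorm(120, 5)))
    cr <- crqa(a, b, prm)$DET
    au <- min(rqa(a$values, prm)$DET, rqa(b$values, prm)$DET)
    au - cr
  })
  expect_gt(mean(diffs), 0)
})

test_that("line histograms match hand-enumerated matrices", {
  # identity matrix: only the LOI, which the Theiler window masks
  h <- diagonal_histogram(diag(5) == 1, theiler = 1, kind = "AUTO")
  expect_equal(sum(h$diagonal), 0)

  # ones exactly on j = i +/- 2: two diagonals of length 3
  R <- matrix(FALSE, 5, 5)
  R[cbind(1:3, 3:5)] <- TRUE
  R[cbind(3:5, 1:3)] <- TRUE
  h <- diagonal_histogram(R, theiler = 1, kind = "AUTO")
  expect_equal(trim_counts(h$diagonal), c(0, 0, 2))

  # all-ones 4x4 cross matrix: one full diagonal plus shifted pairs; no gaps
  h <- diagonal_histogram(matrix(TRUE, 4, 4), theiler = 0, kind = "CROSS")
  expect_equal(trim_counts(h$diagonal), c(2, 2, 2, 1))
  expect_equal(sum(h$white), 0)
})

test_that("feature formulas reproduce hand-computed values", {
  # single line of length 4
  h <- structure(list(diagonal = c(0L, 0L, 0L, 1L), white = integer(4)),
                 class = "line_histogram")
  f <- rqa_features(h, l_min = 2)
  expect_equal(f$DET, 1)
  expect_equal(f$MDL, 4)
  expect_equal(f$ENTR, 0)
  expect_true(is.na(f$RT))

  # P = {2:1, 1:5}: DET = 2/7, MDL = 2, ENTR = 0 (one qualifying length)
  h <- structure(list(diagonal = c(5L, 1L), white = integer(2)),
                 class = "line_histogram")
  f <- rqa_features(h, l_min = 2)
  expect_equal(f$DET, 2 / 7)
  expect_equal(f$MDL, 2)
  expect_equal(f$ENTR, 0)
})

test_that("entropy is zero whenever one diagonal length dominates", {
  for (l in 2:5) {
    counts <- integer(6)
    counts[l] <- 3L
    h <- structure(list(diagonal = counts, white = integer(6)),
                   class = "line_histogram")
    expect_equal(rqa_features(h, l_min = 2)$ENTR, 0)
  }
})

test_that("features are invariant under matrix transposition", {
  set.seed(14)
  for (i in 1:20) {
    R <- random_binary_matrix(25, 0.2)
    prm <- embedding_params(radius = 1)
    a <- rqa_features(diagonal_histogram(R, theiler = 1, kind = "AUTO"), l_min = 2)
    b <- rqa_features(diagonal_histogram(t(R), theiler = 1, kind = "AUTO"), l_min = 2)
    expect_equal(a[c("DET", "MDL", "ENTR")], b[c("DET", "MDL", "ENTR")])
  }
})

test_that("histogram features agree exactly with the brute-force oracle", {
  # quick spot check; the full 200-matrix sweep runs in the acceptance suite
  set.seed(15)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    R <- random_binary_matrix(n, sample(c(0.05, 0.2, 0.5), 1))
    h <- diagonal_histogram(R, theiler = 1, kind = "AUTO")
    o <- oracle_line_hist(R, theiler = 1, is_auto = TRUE)
    expect_equal(trim_counts(h$diagonal), trim_counts(o$diagonal))
    expect_equal(trim_counts(h$white), trim_counts(o$white))
  }
})
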