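# Noise normalization, pseudotrials, cross-validated distances, windowed
# dissimilarity matrices, classical MDS.

test_that("whitening approximates the identity under identity noise and equalizes variances", {
  set.seed(61)
  n <- 2000; ch <- 6; nt <- 4
  dat <- array(rnorm(n * ch * nt), c(n, ch, nt))
  ep <- make_epochs(dat, srate = 100, categories = rep(c("bird", "vehicle"), n / 2))
  wh <- noise_normalize(ep)
  W <- attr(wh, "whitening")
  expect_lt(norm(W - diag(ch), type = "2"), 0.2)

  # heteroscedastic channels get equalized
  dat2 <- dat
  dat2[, 2, ] <- dat2[, 2, ] * 2
  ep2 <- make_epochs(dat2, srate = 100, categories = rep(c("bird", "vehicle"), n / 2))
  wh2 <- noise_normalize(ep2)
  v <- apply(wh2$data, 2, function(x) var(as.vector(x)))
  expect_lt(max(abs(v - 1)), 0.2)

  # applying it twice: second whitening is close to identity
  wh3 <- noise_normalize(wh2)
  expect_lt(norm(attr(wh3, "whitening") - diag(ch), type = "2"), 0.2)
})

test_that("pseudotrials partition evenly and preserve the grand mean", {
  ep <- random_epochs(n = 20, ch = 3, nt = 8, seed = 62,
                      categories = rep(c("bird", "vehicle"), each = 10))
  ps <- make_pseudotrials(ep, n_pseudo = 5, seed = 1)
  expect_equal(dim(ps)[1], 10)
  expect_equal(unname(table(ps$labels$category)), rep(5L, 2), ignore_attr = TRUE)
  # equal-sized partition: pseudotrial mean equals trial mean per condition
  for (cat in c("bird", "vehicle")) {
    m_trials <- apply(ep$data[ep$labels$category == cat, , ], c(2, 3), mean)
    m_pseudo <- apply(ps$data[ps$labels$category == cat, , ], c(2, 3), mean)
    expect_equal(m_pseudo, m_trials, tolerance = 1e-12)
  }
  # n_pseudo = trial count reproduces the trials (up to order)
  ps_all <- make_pseudotrials(ep, n_pseudo = 10, seed = 2)
  expect_equal(dim(ps_all)[1], 20)
  expect_equal(sort(as.vector(ps_all$data[, 1, 1])), sort(as.vector(ep$data[, 1, 1])))
  # identical trials give identical pseudotrials
  flat <- make_epochs(array(2, c(10, 2, 4)), categories = rep(c("bird", "vehicle"), 5))
  psf <- make_pseudotrials(flat, 5, seed = 3)
  expect_equal(max(abs(psf$data - 2)), 0)
  expect_error(make_pseudotrials(ep, n_pseudo = 11, seed = 1), "fewer than")
})

test_that("cross-validated distances are unbiased at null; plain distances are not", {
  des <- tiny_design()
  cv_means <- plain_means <- numeric(0)
  for (s in 1:25) {
    g <- generate_epochs(des, null_schedule(), seed = s)
    d <- cv_distance_timecourse(g$epochs, c("bird", "nonbird_animal"), "basic",
                                n_iterations = 5, seed = s)
    cv_means <- c(cv_means, mean(d$distance))
    plain_means <- c(plain_means,
                     mean(plain_distance_timecourse(g$epochs, c("bird", "nonbird_animal"), "basic")))
  }
  z <- abs(mean(cv_means)) / (sd(cv_means) / sqrt(length(cv_means)))
  expect_lt(z, 3)
  expect_true(all(plain_means > 0))
  expect_gt(mean(plain_means), 50 * abs(mean(cv_means)))
})

test_that("distance estimates are invariant to orthogonal channel rotations", {
  des <- tiny_design()
  g <- generate_epochs(des, geometry_schedule(), seed = 5)
  ep <- g$epochs
  Q <- qr.Q(qr(matrix(rnorm(16 * 16), 16)))
  ep_rot <- ep
  for (ti in seq_along(ep$times)) ep_rot$data[, , ti] <- ep$data[, , ti] %*% Q
  d1 <- cv_distance_timecourse(ep, c("bird", "vehicle"), "basic",
                               n_iterations = 3, seed = 2, whiten = "none")
  d2 <- cv_distance_timecourse(ep_rot, c("bird", "vehicle"), "basic",
                               n_iterations = 3, seed = 2, whiten = "none")
  expect_equal(d1$distance, d2$distance, tolerance = 1e-9)
})

test_that("iteration averaging stabilizes the estimate across seeds", {
  des <- sim_design(n_trials = 400, channels = 16, srate = 100)
  g <- generate_epochs(des, geometry_schedule(), seed = 11)
  d1 <- cv_distance_timecourse(g$epochs, c("bird", "vehicle"), "basic",
                               n_iterations = 20, seed = 1)
  d2 <- cv_distance_timecourse(g$epochs, c("bird", "vehicle"), "basic",
                               n_iterations = 20, seed = 2)
  expect_gt(cor(d1$distance, d2$distance), 0.95)
})

test_that("windowed dissimilarity matrices average correctly", {
  times <- seq(0, 100, by = 10)
  mk <- function(v) structure(list(times = times, distance = v), class = "rdm_series")
  ser <- list("bird|nonbird_animal" = mk(rep(2, 11)),
              "nonbird_animal|vehicle" = mk(seq(0, 10, by = 1)),
              "bird|vehicle" = mk(rep(-1, 11)))
  dm <- rdm_at_window(ser, center_ms = 50, half_width_ms = 15)
  expect_equal(dm$matrix["bird", "nonbird_animal"], 2)
  # linear ramp: window mean equals midpoint value
  expect_equal(dm$matrix["nonbird_animal", "vehicle"], 5)
  # negative averages are retained
  expect_equal(dm$matrix["bird", "vehicle"], -1)
  expect_true(isSymmetric(dm$matrix))
  expect_equal(diag(dm$matrix), c(bird = 0, nonbird_animal = 0, vehicle = 0))
  # single-sample window picks that sample
  dm1 <- rdm_at_window(ser, center_ms = 30, half_width_ms = 4)
  expect_equal(dm1$matrix["nonbird_animal", "vehicle"], 3)
  expect_error(rdm_at_window(ser, center_ms = 300, half_width_ms = 4), "no timepoints")
})

test_that("classical MDS reproduces known geometries and flags degenerate input", {
  # equilateral triangle with squared side d2
  d2 <- 4
  m <- matrix(d2, 3, 3); diag(m) <- 0
  rownames(m) <- colnames(m) <- c("a", "b", "c")
  sol <- classical_mds(m, k = 2)
  pd <- as.matrix(dist(sol$points))^2
  expect_equal(pd[upper.tri(pd)], rep(d2, 3), tolerance = 1e-9)

  # round trip from known 2D points
  set.seed(63)
  pts <- matrix(rnorm(10), 5, 2)
  D2 <- as.matrix(dist(pts))^2
  sol2 <- classical_mds(D2, k = 2)
  expect_equal(as.matrix(dist(sol2$points))^2, D2, tolerance = 1e-9,
               ignore_attr = TRUE)
  # agreement with the standard implementation on non-negative input
  ref <- cmdscale(sqrt(D2), k = 2)
  expect_equal(as.matrix(dist(sol2$points)), as.matrix(dist(ref)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # zero matrix: all points at the origin (no positive spectrum -> error)
  zero <- matrix(0, 3, 3)
  expect_error(classical_mds(zero), "not embeddable")
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("negative cross-validated entries pass through MDS via the Gram spectrum", {
  m <- matrix(c(0, 4, -0.5,
                4, 0, 4,
                -0.5, 4, 0), 3, 3)
  sol <- classical_mds(m, k = 2)
  expect_true(any(sol$eig < 0))       # non-embeddable direction reported
  expect_equal(dim(sol$points), c(3L, 2L))
})
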