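# Activation-pattern transform, template projection, sign-flip bootstrap,
# Gaussian z / p, consecutive-significance rule.

test_that("patterns align with the class-mean difference under isotropic noise", {
  set.seed(71)
  n <- 2000; ch <- 8; nt <- 3
  y <- rep(c("bird", "vehicle"), n / 2)
  delta <- c(2, 1, 0, 0, 0, 0, 0, -1)
  dat <- array(rnorm(n * ch * nt), c(n, ch, nt))
  for (ti in seq_len(nt)) dat[y == "bird", , ti] <- dat[y == "bird", , ti] +
      matrix(delta, sum(y == "bird"), ch, byrow = TRUE)
  ep <- make_epochs(dat, srate = 100, categories = y)
  models <- lapply(seq_len(nt), function(ti) fit_lda(dat[, , ti], y))
  pat <- weights_to_pattern(models, ep)
  for (ti in seq_len(nt)) {
    cosim <- sum(pat$pattern[, ti] * delta) / sqrt(sum(pat$pattern[, ti]^2) * sum(delta^2))
    expect_gt(cosim, 0.99)
  }
})

test_that("pattern equals the ERP difference direction on well-conditioned data", {
  des <- sim_design(n_trials = 2000, channels = 16, srate = 100)
  g <- generate_epochs(des, geometry_schedule(), seed = 72)
  pat <- pattern_for_pair(g$epochs, c("nonbird_animal", "vehicle"), "basic", seed = 1)
  sub <- catrep:::subset_pair(g$epochs, c("nonbird_animal", "vehicle"), "basic")
  dw <- differential_waveform(condition_erp(sub, list(category = "nonbird_animal")),
                              condition_erp(sub, list(category = "vehicle")))
  signal <- g$epochs$times >= 200  # where the planted separation is at plateau
  cosv <- vapply(which(signal), function(ti) {
    sum(pat$pattern[, ti] * dw[, ti]) /
      sqrt(sum(pat$pattern[, ti]^2) * sum(dw[, ti]^2))
  }, numeric(1))
  expect_gt(min(cosv), 0.95)
})

test_that("template projection solves exact linear combinations", {
  # orthonormal fixture
  q <- qr.Q(qr(matrix(rnorm(64 * 3), 64, 3)))
  tpl <- t(q); rownames(tpl) <- c("A", "B", "C")
  # pattern equal to one template
  res <- localize_templates(matrix(tpl["B", ], ncol = 1), tpl)
  expect_equal(as.vector(res$coefficients), c(0, 1, 0), tolerance = 1e-9)
  # linear combination 2A + 3B
  pat <- matrix(2 * tpl["A", ] + 3 * tpl["B", ], ncol = 1)
  res2 <- localize_templates(pat, tpl)
  expect_equal(as.vector(res2$coefficients), c(2, 3, 0), tolerance = 1e-9)
  expect_lt(res2$residual_fraction, 1e-12)
  # exact linearity in the pattern
  res3 <- localize_templates(5 * pat, tpl)
  expect_equal(res3$coefficients, 5 * res2$coefficients, tolerance = 1e-12)
  # white noise: small coefficients, residual fraction near 1
  set.seed(73)
  noise <- matrix(rnorm(64), ncol = 1)
  res4 <- localize_templates(noise, tpl)
  expect_gt(res4$residual_fraction, 0.8)
  # rank-deficient templates are rejected
  bad <- rbind(tpl, A2 = tpl["A", ])
  expect_error(localize_templates(pat, bad), "rank deficient")
})

test_that("sign-flip bootstrap nulls are centered and deterministic", {
  set.seed(74)
  tpl <- generate_templates(4, 16, seed = 1)
  pats <- lapply(1:6, function(i) matrix(rnorm(16 * 10), 16, 10))
  bs <- signflip_bootstrap_null(pats, tpl, n_boot = 300, seed = 5)
  m <- apply(bs$null, c(2, 3), mean)
  s <- apply(bs$null, c(2, 3), sd)
  expect_lt(max(abs(m / (s / sqrt(300)))), 4)
  bs2 <- signflip_bootstrap_null(pats, tpl, n_boot = 300, seed = 5)
  expect_identical(bs$null, bs2$null)
  # planted strong pattern: observed far outside the null (enough
  # participants that an all-same-sign draw is vanishingly unlikely)
  strong <- lapply(1:16, function(i) {
    matrix(tpl[2, ] * 10, 16, 10) + matrix(rnorm(16 * 10, sd = 0.1), 16, 10)
  })
  bs3 <- signflip_bootstrap_null(strong, tpl, n_boot = 300, seed = 6)
  tail_count <- sum(abs(bs3$null[, 2, 5]) >= abs(bs3$observed[2, 5]))
  expect_equal(tail_count, 0)
})

test_that("Gaussian z and the two-sided normal p behave per the formula", {
  null <- rnorm(500)
  zp <- gaussian_z_pvalue(mean(null), null)
  expect_equal(zp$z, 0)
  expect_equal(zp$p, 1)
  # the 5% two-sided quantile
  null2 <- c(scale(rnorm(1000)))  # exactly mean 0 sd 1
  zp2 <- gaussian_z_pvalue(1.959964, null2)
  expect_equal(zp2$p, 0.05, tolerance = 1e-6)
  # even function of z
  zp_neg <- gaussian_z_pvalue(-1.959964, null2)
  expect_equal(zp2$p, zp_neg$p, tolerance = 1e-12)
  expect_error(gaussian_z_pvalue(1, c(2, 2, 2)), "zero variance")
})

test_that("the consecutive-milliseconds rule masks only long runs", {
  # all p = 1: nothing significant
  expect_false(any(consecutive_significance(rep(1, 50), srate = 1000)))
  # 20-ms run at 1000 Hz: all 20 samples survive
  p <- rep(1, 100); p[41:60] <- 1e-4
  m <- consecutive_significance(p, srate = 1000)
  expect_equal(which(m), 41:60)
  # 10-ms run at 1000 Hz with a 15-ms minimum: nothing
  p2 <- rep(1, 100); p2[41:50] <- 1e-4
  expect_false(any(consecutive_significance(p2, srate = 1000)))
  # at 100 Hz, 2 samples span 20 ms and survive the 15-ms rule
  p3 <- rep(1, 30); p3[10:11] <- 1e-4
  expect_equal(which(consecutive_significance(p3, srate = 100)), 10:11)
})

test_that("end-to-end: signal planted in one template's subspace activates only that area", {
  set.seed(75)
  tpl <- generate_templates(4, 16, seed = 2)
  nt <- 66; srate <- 100
  times <- -150 + (seq_len(nt) - 1) * 10
  onset <- times >= 250
  # the sign-flip null bounds attainable |z| at sqrt(n_participants), so the
  # p < 0.005 rule needs a dozen or more participants to be reachable
  pats <- lapply(1:14, function(i) {
    base <- matrix(rnorm(16 * nt, sd = 0.3), 16, nt)
    base[, onset] <- base[, onset] + tpl[3, ] * 4
    base
  })
  stc <- source_timecourses(pats, tpl, srate = srate, n_boot = 300, seed = 7)
  active <- rowSums(stc$mask)
  expect_gt(active["area3"], 0)
  expect_equal(sum(active[c("area1", "area2", "area4")]), 0)
  onset_ms <- times[which(stc$mask["area3", ])[1]]
  expect_lte(abs(onset_ms - 250), 30)
})

test_that("the run-length rule keeps the global null rate below the pointwise level", {
  set.seed(76)
  frac <- replicate(60, {
    p <- 2 * (1 - pnorm(abs(rnorm(66))))
    mean(consecutive_significance(p, p_threshold = 0.005, min_duration_ms = 15,
                                  srate = 100))
  })
  expect_lt(mean(frac), 0.005)
})
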