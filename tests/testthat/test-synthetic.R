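# Synthetic-data generator: DDM behavior, design bookkeeping, geometry
# ground truth, posterior fabrication, templates.

# Independent closed-form first-passage probability of the upper boundary
# for a diffusion with drift v, diffusion s, boundaries {0, a}, start z.
fp_upper <- function(a, v, z, s = 1) {
  if (abs(v) < 1e-12) return(z / a)
  (1 - exp(-2 * v * z / s^2)) / (1 - exp(-2 * v * a / s^2))
}

test_that("DDM choice probabilities match the closed-form first-passage oracle", {
  n <- 20000
  for (ps in list(c(a = 1, v = 2, t = 0.3),
                  c(a = 1.3, v = 1.6, t = 0.36),
                  c(a = 0.8, v = 0.5, t = 0.25))) {
    sim <- simulate_ddm(ddm_params(ps["a"], ps["v"], ps["t"]), n, seed = 101)
    p_hat <- mean(sim$correct, na.rm = TRUE)
    p_true <- fp_upper(ps["a"], ps["v"], ps["a"] / 2)
    se <- sqrt(p_true * (1 - p_true) / sum(!is.na(sim$correct)))
    expect_lt(abs(p_hat - p_true), 3 * se)
    expect_gte(min(sim$rt_ms, na.rm = TRUE), ps["t"] * 1000)
  }
})

test_that("zero drift from the midpoint gives symmetric choices", {
  sim <- simulate_ddm(ddm_params(1, 0, 0.2), 20000, seed = 5)
  p <- mean(sim$correct, na.rm = TRUE)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / sum(!is.na(sim$correct))))
})

test_that("ddm parameter validation rejects degenerate values", {
  expect_error(ddm_params(0, 1, 0.3), "a must")
  expect_error(ddm_params(1, Inf, 0.3), "finite")
  expect_error(ddm_params(1, 1, 0.3, z_rel = 1), "z_rel")
})

test_that("behavior tables reproduce the design counts deterministically", {
  beh <- generate_behavior(seed = 2)
  expect_equal(nrow(beh), 2000)
  expect_equal(sum(beh$task == "superordinate"), 1000)
  expect_equal(sum(beh$task == "basic"), 1000)
  expect_equal(sum(beh$task == "superordinate" & beh$category == "vehicle"), 500)
  expect_equal(sum(beh$task == "basic" & beh$category == "bird"), 500)
  expect_equal(sum(beh$task == "basic" & beh$category == "nonbird_animal"), 250)
  # no-response trials carry missing correctness, and vice versa
  expect_true(all(is.na(beh$correct) == (beh$response == "none")))
  beh2 <- generate_behavior(seed = 2)
  expect_identical(beh, beh2)
  expect_error(sim_design(proportions = list(
    superordinate = c(bird = 0.6, nonbird_animal = 0.25, vehicle = 0.25),
    basic = c(bird = 0.5, nonbird_animal = 0.25, vehicle = 0.25))), "sum to 1")
})

test_that("generated epochs match the declared geometry exactly when noiseless", {
  des <- tiny_design()
  g <- generate_epochs(des, geometry_schedule(), seed = 3, noise = list(sd = 0))
  expect_equal(dim(g$epochs)[1], 120)
  expect_equal(dim(g$epochs)[2], 16)
  # squared cross-validated distance equals the squared planted separation
  for (task in c("basic", "superordinate")) {
    d <- cv_distance_timecourse(g$epochs, c("bird", "nonbird_animal"), task,
                                n_iterations = 2, seed = 1, whiten = "none")
    gt <- g$ground_truth$distances["bird-nonbird_animal", task, ]
    expect_lt(max(abs(d$distance - gt^2)), 1e-9)
  }
  # ground-truth distances recompute from the stored latent means
  sch <- geometry_schedule()
  tt <- g$ground_truth$times
  for (task in c("basic", "superordinate")) {
    m_dist <- vapply(tt, function(t) {
      m <- sch$means(task, t)
      sqrt(sum((m["bird", ] - m["nonbird_animal", ])^2))
    }, numeric(1))
    expect_equal(g$ground_truth$distances["bird-nonbird_animal", task, ], m_dist,
                 tolerance = 1e-12)
  }
})

test_that("schedule plants the hypothesized contrast structure", {
  sch <- geometry_schedule()
  t_probe <- c(-100, 100, 200, 240, 300, 400)
  for (t in t_probe) {
    # vehicle distances identical across tasks at every latency
    expect_equal(sch$distance(c("bird", "vehicle"), "basic", t),
                 sch$distance(c("bird", "vehicle"), "superordinate", t))
    expect_equal(sch$distance(c("nonbird_animal", "vehicle"), "basic", t),
                 sch$distance(c("nonbird_animal", "vehicle"), "superordinate", t))
    # superordinate bird/nonbird never separate
    expect_equal(sch$distance(c("bird", "nonbird_animal"), "superordinate", t), 0)
    # distances implied by means agree with the declared schedule
    for (task in c("basic", "superordinate")) {
      m <- sch$means(task, t)
      expect_equal(sqrt(sum((m["bird", ] - m["vehicle", ])^2)),
                   sch$distance(c("bird", "vehicle"), task, t), tolerance = 1e-9)
      expect_equal(sqrt(sum((m["bird", ] - m["nonbird_animal", ])^2)),
                   sch$distance(c("bird", "nonbird_animal"), task, t), tolerance = 1e-9)
    }
  }
  # basic-task ramp: zero before 250, maximal from 350
  expect_equal(sch$distance(c("bird", "nonbird_animal"), "basic", 250), 0)
  expect_gt(sch$distance(c("bird", "nonbird_animal"), "basic", 300), 0)
  expect_equal(sch$distance(c("bird", "nonbird_animal"), "basic", 350),
               sch$params$d_bn_max)
})

test_that("posterior fabrication matches the normal-difference oracle", {
  p <- generate_posterior_samples(spread = 0.1, n_samples = 4000, seed = 9)
  # same condition compared with itself: P = 0.5 exactly (tie rule)
  x <- p$basic$bird$v
  expect_equal(posterior_overlap_probability(x, x), 0.5)
  # drift-rate basic vs superordinate for nonbird animals: Delta known
  delta <- 2.4 - 1.6
  p_pred <- pnorm(delta / (0.1 * sqrt(2)))
  p_hat <- posterior_overlap_probability(p$superordinate$nonbird_animal$v,
                                         p$basic$nonbird_animal$v)
  expect_lt(abs(p_hat - p_pred), 0.02)
  expect_identical(p, generate_posterior_samples(spread = 0.1, n_samples = 4000, seed = 9))
})

test_that("templates are unit-norm, distinguishable and reproducible", {
  tpl <- generate_templates(6, 64, seed = 4)
  expect_equal(dim(tpl), c(6, 64))
  expect_equal(unname(sqrt(rowSums(tpl^2))), rep(1, 6), tolerance = 1e-12)
  co <- abs(tcrossprod(tpl)); diag(co) <- 0
  expect_lt(max(co), 0.95)
  expect_identical(tpl, generate_templates(6, 64, seed = 4))
  expect_false(identical(tpl, generate_templates(6, 64, seed = 5)))
  expect_error(generate_templates(1, 64), "n_areas")
})

test_that("a zero-effect schedule yields chance decoding and zero distances", {
  des <- tiny_design()
  accs <- dists <- numeric(0)
  for (seed in 1:8) {
    g <- generate_epochs(des, null_schedule(), seed = seed)
    dr <- decode_timecourse(g$epochs, c("bird", "nonbird_animal"), "basic",
                            folds = 5, repetitions = 2, seed = seed)
    accs <- c(accs, mean(dr$accuracy))
    d <- cv_distance_timecourse(g$epochs, c("bird", "nonbird_animal"), "basic",
                                n_iterations = 5, seed = seed)
    dists <- c(dists, mean(d$distance))
  }
  expect_lt(abs(mean(accs) - 0.5) / (sd(accs) / sqrt(length(accs))), 3)
  expect_lt(abs(mean(dists)) / (sd(dists) / sqrt(length(dists))), 3)
})
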