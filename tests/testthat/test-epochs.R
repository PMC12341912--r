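# Epoch data model and conditioning operations.

test_that("constructor enforces dimensional and label invariants", {
  dat <- array(0, c(4, 2, 10))
  expect_s3_class(make_epochs(dat), "eeg_epochs")
  expect_error(eeg_epochs(dat, times = 1:9, srate = 1000,
                          channels = c("a", "b"),
                          labels = data.frame(task = rep("basic", 4),
                                              category = rep("bird", 4))),
               "timepoints")
  expect_error(make_epochs(dat, tasks = rep("unknown_task", 4)), "task")
  bad_times <- seq(0, 18, by = 2)  # spacing 2 ms but srate says 1 ms
  expect_error(eeg_epochs(dat, bad_times, 1000, c("a", "b"),
                          data.frame(task = rep("basic", 4),
                                     category = rep("bird", 4))),
               "spacing")
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  # constant epoch: everything becomes zero
  const <- make_epochs(array(5, c(3, 2, 20)))
  bc <- baseline_correct(const, c(-150, 0))
  expect_equal(max(abs(bc$data)), 0)

  # random epochs: recomputed baseline means vanish
  ep <- random_epochs(n = 100, ch = 5, nt = 40, srate = 200, seed = 42)
  bc <- baseline_correct(ep, c(-150, 0))
  sel <- which(bc$times >= -150 & bc$times <= 0)
  base_means <- apply(bc$data[, , sel], c(1, 2), mean)
  expect_lt(max(abs(base_means)), 1e-10)

  # idempotence
  bc2 <- baseline_correct(bc, c(-150, 0))
  expect_lt(max(abs(bc2$data - bc$data)), 1e-9)

  expect_error(baseline_correct(ep, c(900, 1000)), "range")
})

test_that("eye rejection removes exactly the planted super-threshold trials", {
  set.seed(7)
  dat <- array(rnorm(30 * 3 * 20, sd = 5), c(30, 3, 20))
  planted <- c(4L, 11L, 27L)
  dat[planted, 2, 10] <- dat[planted, 2, 10] + 400  # VEOG1 spike
  ep <- make_epochs(dat, channels = c("Cz", "VEOG1", "VEOG2"),
                    veog_pair = c("VEOG1", "VEOG2"))
  res <- reject_eye_epochs(ep, 150)
  expect_identical(which(res$rejected), planted)
  expect_equal(dim(res$epochs)[1], 27)

  # identical eye channels: kept regardless of amplitude
  dat2 <- array(200, c(2, 3, 5))
  ep2 <- make_epochs(dat2, channels = c("Cz", "VEOG1", "VEOG2"),
                     veog_pair = c("VEOG1", "VEOG2"))
  expect_false(any(reject_eye_epochs(ep2, 150)$rejected))

  # infinite threshold removes nothing; masks partition trials
  res3 <- reject_eye_epochs(ep, Inf)
  expect_false(any(res3$rejected))

  ep_no <- make_epochs(dat)
  expect_error(reject_eye_epochs(ep_no), "veog_pair")
})

test_that("equal subsampling enforces the min-count rule reproducibly", {
  ep <- random_epochs(n = 80, categories = rep(c("bird", "nonbird_animal", "vehicle"),
                                               c(40, 20, 20)))
  eq <- subsample_equal(ep, "category", seed = 3)
  expect_equal(unname(table(eq$labels$category)), rep(20L, 3), ignore_attr = TRUE)

  eq2 <- subsample_equal(ep, "category", seed = 3)
  expect_identical(eq$data, eq2$data)
  eq3 <- subsample_equal(ep, "category", seed = 4)
  expect_false(identical(eq$data, eq3$data))

  # already equal groups: identity up to ordering
  ep_eq <- random_epochs(n = 30, categories = rep(c("bird", "vehicle"), 15))
  expect_equal(dim(subsample_equal(ep_eq, "category", 1))[1], 30)

  ep_empty <- random_epochs(n = 10, categories = rep("bird", 10))
  expect_error(subsample_equal(ep_empty, "category", 1), "2 groups")
})

test_that("time binning averages consecutive blocks and composes", {
  ep <- make_epochs(array(rep(1:8, each = 2), c(1, 2, 8)), srate = 1000)
  b <- bin_time(ep, 4)
  expect_equal(as.vector(b$data[1, 1, ]), c(2.5, 6.5))
  expect_equal(dim(b$data)[3], 2)

  # factor 1 is the identity
  expect_identical(bin_time(ep, 1)$data, ep$data)

  # brute-force block means on random data, trailing remainder dropped
  ep2 <- random_epochs(n = 5, ch = 3, nt = 23, seed = 9)
  b2 <- bin_time(ep2, 4)
  expect_equal(dim(b2$data)[3], 5)
  for (blk in 1:5) {
    idx <- ((blk - 1) * 4 + 1):(blk * 4)
    manual <- apply(ep2$data[, , idx], c(1, 2), mean)
    expect_equal(b2$data[, , blk], manual, tolerance = 1e-12)
  }

  # composition when lengths divide exactly
  ep3 <- random_epochs(n = 2, ch = 2, nt = 24, seed = 5)
  expect_equal(bin_time(bin_time(ep3, 2), 3)$data, bin_time(ep3, 6)$data,
               tolerance = 1e-9)
  expect_error(bin_time(ep3, 0), "factor")
})

test_that("ROI averaging equals the explicit electrode mean", {
  ep <- random_epochs(n = 4, ch = 10, nt = 15, seed = 11)
  erp <- condition_erp(ep, list(task = "basic"))
  rois <- roi_defaults()
  avg <- roi_average(erp, rois$occipital)
  manual <- colMeans(erp[match(rois$occipital$electrodes, rownames(erp)), ])
  expect_equal(avg, manual, tolerance = 1e-12)

  one <- roi_spec("single", "Cz")
  expect_equal(roi_average(erp, one), erp["Cz", ], tolerance = 1e-12)

  # antisymmetric traces cancel
  m <- matrix(rnorm(20), 2, 10)
  m[2, ] <- -m[1, ]
  rownames(m) <- c("A", "B")
  expect_equal(roi_average(m, roi_spec("pair", c("A", "B"))), rep(0, 10))

  expect_error(roi_average(erp, roi_spec("bad", "NOPE")), "available")
})

test_that("interchange container round trips data and labels", {
  ep <- random_epochs(n = 10, ch = 4, nt = 12, seed = 2,
                      categories = rep(c("bird", "vehicle"), 5))
  ep$labels$correct <- c(rep(TRUE, 4), rep(FALSE, 4), NA, NA)
  ep$labels$rt_ms <- runif(10, 300, 900)
  path <- tempfile("epochs_")
  write_epochs(ep, path)
  back <- read_epochs(path)
  expect_lt(max(abs(back$data - ep$data)), 1e-6)
  expect_identical(back$labels$task, ep$labels$task)
  expect_identical(back$labels$category, ep$labels$category)
  expect_identical(back$labels$correct, ep$labels$correct)
  expect_equal(back$srate, ep$srate)
  expect_equal(back$times, ep$times)
  expect_identical(back$channels, ep$channels)

  # missing field is named in the error
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  meta$srate <- NULL
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE, null = "null")
  expect_error(read_epochs(path), "missing field srate")
})
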