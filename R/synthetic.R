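# Synthetic-data generator: study-design behavior (drift-diffusion), epoched
# EEG with a fully known representational ground truth, fabricated posterior
# samples, and template fixtures. Every downstream stage has a
# parameter-recovery test against the planted quantities.

#' Drift-diffusion model parameters
#'
#' Accuracy-coded parameterization: evidence starts at `z_rel * a` and drifts
#' at rate `v` (evidence/s) between an upper boundary `a` (correct) and a
#' lower boundary 0 (error); `t` (seconds) is added as non-decision time.
#' The within-trial diffusion coefficient is fixed at `s = 1`, the scaling
#' convention of common hierarchical DDM tools, so drift rates are directly
#' comparable with fits from those tools.
#'
#' @param a boundary separation (> 0, evidence units).
#' @param v drift rate (evidence/s); positive drifts toward correct.
#' @param t non-decision time (s, >= 0).
#' @param s diffusion coefficient (evidence/sqrt(s)); fixed scaling constant.
#' @param z_rel relative start point in (0, 1); 0.5 = unbiased.
#' @return an object of class `ddm_params`.
#' @export
ddm_params <- function(a, v, t, s = 1, z_rel = 0.5) {
  vals <- c(a = a, v = v, t = t, s = s, z_rel = z_rel)
  if (any(!is.finite(vals))) stopf("ddm_params: all parameters must be finite")
  if (a <= 0) stopf("ddm_params: a must be > 0")
  if (t < 0) stopf("ddm_params: t must be >= 0")
  if (s <= 0) stopf("ddm_params: s must be > 0")
  if (z_rel <= 0 || z_rel >= 1) stopf("ddm_params: z_rel must be in (0, 1)")
  structure(list(a = a, v = v, t = t, s = s, z_rel = z_rel), class = "ddm_params")
}

#' Simulate first-passage choices and response times from a DDM
#'
#' Euler-Maruyama simulation of `dX = v dt + s sqrt(dt) N(0,1)` from
#' `z_rel * a`, absorbing at 0 and `a`. Upper crossings are coded correct;
#' RT = `t` + first-passage time, with the crossing linearly interpolated
#' within the final step to reduce discretization bias. Trials that have not
#' crossed by `max_t_s` (including non-decision time) are marked no-response.
#'
#' @param params a [ddm_params] object.
#' @param n_trials number of trials.
#' @param dt_s Euler step (s); 0.0005 by default.
#' @param max_t_s response deadline (s) from stimulus onset.
#' @param seed integer seed.
#' @return data.frame with columns `correct` (logical, NA if no response),
#'   `rt_ms` (NA if no response), `response` ("upper"/"lower"/"none").
#' @export
simulate_ddm <- function(params, n_trials, dt_s = 5e-4, max_t_s = 2, seed = 1) {
  stopifnot(inherits(params, "ddm_params"), n_trials >= 1)
  a <- params$a; v <- params$v; tnd <- params$t; s <- params$s
  n_steps <- floor((max_t_s - tnd) / dt_s)
  rt <- rep(NA_real_, n_trials)
  correct <- rep(NA, n_trials)
  with_seed(seed, {
    x <- rep(params$z_rel * a, n_trials)
    active <- seq_len(n_trials)
    sq <- s * sqrt(dt_s)
    step <- 0L
    while (length(active) && step < n_steps) {
      step <- step + 1L
      xo <- x[active]
      xn <- xo + v * dt_s + sq * rnorm(length(active))
      up <- xn >= a
      dn <- xn <= 0
      # Brownian-bridge correction: excursions can cross a boundary between
      # endpoints that both lie inside; without this the first-passage
      # probability is biased at any finite step size.
      inside <- !(up | dn)
      if (any(inside)) {
        p_up <- exp(-2 * (a - xo[inside]) * (a - xn[inside]) / (s^2 * dt_s))
        p_dn <- exp(-2 * xo[inside] * xn[inside] / (s^2 * dt_s))
        u <- runif(sum(inside))
        bu <- u < p_up
        bd <- !bu & u < p_up + p_dn   # disjoint approximation; both tiny
        up[inside] <- bu
        dn[inside] <- bd
      }
      hit <- up | dn
      if (any(hit)) {
        bound <- ifelse(up[hit], a, 0)
        denom <- xn[hit] - xo[hit]
        frac <- ifelse(abs(denom) > 0 & ((bound - xo[hit]) / denom) >= 0 &
                         ((bound - xo[hit]) / denom) <= 1,
                       (bound - xo[hit]) / denom, 0.5)
        idx <- active[hit]
        rt[idx] <- tnd + (step - 1 + frac) * dt_s
        correct[idx] <- up[hit]
      }
      x[active] <- xn
      active <- active[!hit]
    }
  })
  data.frame(
    correct = correct,
    rt_ms = rt * 1000,
    response = ifelse(is.na(correct), "none", ifelse(correct, "upper", "lower")),
    stringsAsFactors = FALSE
  )
}

#' Default DDM parameters per task and category
#'
#' Arbitrary but behaviorally plausible values (accuracy ~0.83-0.95, mean RT
#' ~0.55-0.65 s) with the hypothesized direction of task effects: drift rates
#' drop at the basic level for bird and especially non-bird animal trials and
#' rise for vehicles; non-decision time is slightly longer for basic-level
#' non-bird animals.
#' @return nested list `task -> category -> ddm_params`.
#' @export
ddm_defaults <- function() {
  list(
    superordinate = list(
      bird = ddm_params(1.3, 2.6, 0.30),
      nonbird_animal = ddm_params(1.3, 2.4, 0.30),
      vehicle = ddm_params(1.3, 2.6, 0.30)
    ),
    basic = list(
      bird = ddm_params(1.3, 2.2, 0.32),
      nonbird_animal = ddm_params(1.3, 1.6, 0.36),
      vehicle = ddm_params(1.3, 3.0, 0.30)
    )
  )
}

#' Experimental design of a synthetic session
#'
#' Defaults reproduce the study design: 10 blocks x 200 trials split evenly
#' between the two tasks; superordinate blocks show 25% birds, 25% non-bird
#' animals and 50% vehicles, basic blocks 50% birds, 25% non-bird animals and
#' 25% vehicles; 64 channels sampled at 256 Hz over a -150..500 ms epoch.
#'
#' @param n_trials total trial count (split evenly across tasks).
#' @param channels number of EEG channels.
#' @param srate sampling rate (Hz).
#' @param epoch_ms epoch span, c(start, end) in ms.
#' @param proportions named list task -> named numeric of category proportions
#'   (must sum to 1 per task).
#' @param veog if TRUE, two extra eye channels (VEOG1/VEOG2) carrying noise
#'   are appended and registered as the `veog_pair`.
#' @param artifact_trials number of trials to plant a super-threshold
#'   (+400 microvolt) eye-channel deflection into (requires `veog`).
#' @return a list of class `sim_design`.
#' @export
sim_design <- function(n_trials = 2000, channels = 64, srate = 256,
                       epoch_ms = c(-150, 500),
                       proportions = list(
                         superordinate = c(bird = 0.25, nonbird_animal = 0.25, vehicle = 0.5),
                         basic = c(bird = 0.5, nonbird_animal = 0.25, vehicle = 0.25)
                       ),
                       veog = FALSE, artifact_trials = 0) {
  for (task in names(proportions)) {
    p <- proportions[[task]]
    if (abs(sum(p) - 1) > 1e-9) stopf("sim_design: %s proportions must sum to 1", task)
    if (any(p < 0)) stopf("sim_design: proportions must be non-negative")
  }
  if (artifact_trials > 0 && !veog) stopf("sim_design: artifact_trials requires veog = TRUE")
  structure(list(n_trials = n_trials, channels = channels, srate = srate,
                 epoch_ms = epoch_ms, proportions = proportions,
                 veog = veog, artifact_trials = artifact_trials),
            class = "sim_design")
}

design_times <- function(design) {
  step <- 1000 / design$srate
  seq(design$epoch_ms[1], design$epoch_ms[2] + 1e-9, by = step)
}

# Deterministic per-trial task/category assignment honoring the design
# proportions exactly, with randomized trial order.
design_labels <- function(design, seed, participant = "p01") {
  per_task <- design$n_trials / 2
  rows <- do.call(rbind, lapply(names(design$proportions), function(task) {
    p <- design$proportions[[task]]
    counts <- round(p * per_task)
    # fix rounding drift on the largest category
    counts[which.max(counts)] <- counts[which.max(counts)] + per_task - sum(counts)
    data.frame(task = task, category = rep(names(p), counts), stringsAsFactors = FALSE)
  }))
  ord <- with_seed(derive_seed(seed, "labels"), sample(nrow(rows)))
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  rows$participant <- participant
  rows
}

#' Generate a trial-level behavior table for the study design
#'
#' Tasks and categories follow the design proportions exactly; responses and
#' RTs come from [simulate_ddm()] per task x category condition. Yes/no
#' responses are decoded from correctness and target status (targets:
#' animals in the superordinate task, birds in the basic task).
#'
#' @param design a [sim_design].
#' @param ddm nested list task -> category -> [ddm_params] ([ddm_defaults()]).
#' @param seed integer seed.
#' @param participant participant id recorded in the table.
#' @return data.frame: participant, task, category, response (yes/no/none),
#'   correct (logical, NA when none), rt_ms.
#' @export
generate_behavior <- function(design = sim_design(), ddm = ddm_defaults(),
                              seed = 1, participant = "p01") {
  lab <- design_labels(design, seed, participant)
  lab$correct <- NA
  lab$rt_ms <- NA_real_
  for (task in unique(lab$task)) {
    for (cat in unique(lab$category[lab$task == task])) {
      sel <- which(lab$task == task & lab$category == cat)
      sim <- simulate_ddm(ddm[[task]][[cat]], length(sel),
                          seed = derive_seed(seed, "ddm", task, cat))
      lab$correct[sel] <- sim$correct
      lab$rt_ms[sel] <- sim$rt_ms
    }
  }
  target <- ifelse(lab$task == "superordinate",
                   lab$category %in% c("bird", "nonbird_animal"),
                   lab$category == "bird")
  yes_is_correct <- target  # "yes" is the correct response on target trials
  lab$response <- ifelse(is.na(lab$correct), "none",
                         ifelse(lab$correct == yes_is_correct, "yes", "no"))
  lab[, c("participant", "task", "category", "response", "correct", "rt_ms")]
}

#' Representational geometry schedule
#'
#' Declares, for every task, category and latency, a latent position whose
#' pairwise Euclidean distances implement the hypothesized effect structure:
#' both animal categories and the vehicle category separate from `av_onset`
#' (120 ms) in both tasks, with identical bird-vehicle and animal-vehicle
#' distances across tasks; the bird vs non-bird-animal distance is zero at
#' all times in the superordinate task and ramps linearly from 0 to
#' `d_bn_max` between `bn_onset` (250 ms) and `bn_peak` (350 ms) in the basic
#' task. Task-equality of the vehicle distances is exact by construction:
#' bird and non-bird positions rotate on a circle of radius `r(t)` around the
#' vehicle position, so opening the bird/non-bird angle changes only their
#' mutual distance.
#'
#' @param d_av vehicle-to-animal separation at plateau (signal units).
#' @param d_bn_max basic-task bird vs non-bird separation at plateau; must
#'   not exceed `2 * d_av`.
#' @param av_onset,av_peak onset and plateau latency (ms) of the common
#'   category separation.
#' @param bn_onset,bn_peak onset and plateau latency (ms) of the basic-task
#'   bird/non-bird separation.
#' @return an object of class `geometry_schedule` with `$means(task, t)`
#'   returning a 3 (category) x 2 (latent dim) matrix and
#'   `$distance(pair, task, t)` the implied pairwise distance.
#' @export
geometry_schedule <- function(d_av = 14, d_bn_max = 14,
                              av_onset = 120, av_peak = 200,
                              bn_onset = 250, bn_peak = 350) {
  if (d_bn_max > 2 * d_av + 1e-12) {
    stopf("geometry_schedule: d_bn_max must be <= 2 * d_av (circle construction)")
  }
  ramp <- function(t, onset, peak, height) {
    pmax(0, pmin(1, (t - onset) / (peak - onset))) * height
  }
  r_of <- function(t) ramp(t, av_onset, av_peak, d_av)
  bn_of <- function(t, task) {
    if (task == "superordinate") rep(0, length(t)) else ramp(t, bn_onset, bn_peak, d_bn_max)
  }
  means <- function(task, t) {
    stopifnot(length(t) == 1)
    r <- r_of(t)
    bn <- bn_of(t, task)
    half <- if (r > 0) asin(pmin(1, bn / (2 * r))) else 0
    m <- rbind(
      bird = c(r * cos(half), r * sin(half)),
      nonbird_animal = c(r * cos(half), -r * sin(half)),
      vehicle = c(0, 0)
    )
    colnames(m) <- c("d1", "d2")
    m
  }
  distance <- function(pair, task, t) {
    r <- r_of(t)
    if (setequal(pair, c("bird", "nonbird_animal"))) bn_of(t, task) else r
  }
  structure(list(means = means, distance = distance,
                 params = list(d_av = d_av, d_bn_max = d_bn_max,
                               av_onset = av_onset, av_peak = av_peak,
                               bn_onset = bn_onset, bn_peak = bn_peak),
                 latent_dim = 2L),
            class = "geometry_schedule")
}

#' Zero-effect schedule (all pairwise distances 0 at every latency)
#' @return a `geometry_schedule` whose latent means are identically zero.
#' @export
null_schedule <- function() geometry_schedule(d_av = 0, d_bn_max = 0)

ring_covariance <- function(n, sd, falloff = 2) {
  idx <- seq_len(n)
  d <- outer(idx, idx, function(i, j) pmin(abs(i - j), n - abs(i - j)))
  sd^2 * exp(-d / falloff)
}

# 1/f temporal coloring of a channels x time white-noise matrix via FFT.
pink_filter <- function(e) {
  nt <- ncol(e)
  f <- c(1, seq_len(nt - 1))  # avoid division by zero at DC
  w <- 1 / sqrt(pmin(f, nt - f + 1))
  ft <- t(apply(e, 1, function(row) Re(stats::fft(stats::fft(row) * w, inverse = TRUE)) / nt))
  # rescale to unit variance per channel
  ft / sqrt(rowMeans(ft^2))
}

#' Generate epoched EEG with a known representational ground truth
#'
#' Each trial is `mixing %*% latent_mean(task, category, t)` plus spatially
#' correlated Gaussian noise (stationary, exponential falloff over a ring
#' channel layout; optionally 1/f temporal coloring). The mixing matrix has
#' orthonormal columns, so channel-space mean separations equal the latent
#' distances declared by the schedule.
#'
#' @param design a [sim_design].
#' @param schedule a [geometry_schedule].
#' @param seed integer seed for labels and noise.
#' @param mixing_seed seed for the latent-to-channel mixing matrix (defaults
#'   to a fixed stream derived from `seed` so one participant = one seed).
#' @param noise list: `sd` per-channel noise SD (microvolts), `falloff`
#'   spatial correlation length (channels), `pink` logical 1/f flag.
#' @param snr multiplier applied to the schedule's latent means.
#' @param participant participant id.
#' @param labels optional precomputed label data.frame (from
#'   [generate_behavior()]) so epochs and behavior share trials.
#' @return list with `epochs` ([eeg_epochs]) and `ground_truth` (mixing
#'   matrix, true pairwise distance time courses per task, planted artifact
#'   indices, seeds).
#' @export
generate_epochs <- function(design = sim_design(), schedule = geometry_schedule(),
                            seed = 1, mixing_seed = NULL,
                            noise = list(sd = 10, falloff = 2, pink = FALSE),
                            snr = 1, participant = "p01", labels = NULL) {
  times <- design_times(design)
  nt <- length(times)
  nch <- design$channels
  if (nch < schedule$latent_dim) stopf("generate_epochs: need channels >= latent_dim")
  if (is.null(labels)) labels <- design_labels(design, seed, participant)
  n <- nrow(labels)
  mixing_seed <- mixing_seed %||% derive_seed(seed, "mixing")
  M <- with_seed(mixing_seed, {
    qr.Q(qr(matrix(rnorm(nch * schedule$latent_dim), nch, schedule$latent_dim)))
  })
  # per task x category signal time course in channel space (nch x nt)
  combos <- unique(labels[, c("task", "category")])
  signals <- list()
  for (i in seq_len(nrow(combos))) {
    task <- combos$task[i]; cat <- combos$category[i]
    lat <- vapply(times, function(t) schedule$means(task, t)[cat, ], numeric(schedule$latent_dim))
    signals[[paste(task, cat)]] <- snr * (M %*% lat)
  }
  sd <- noise$sd %||% 10
  falloff <- noise$falloff %||% 2
  pink <- isTRUE(noise$pink)
  total_ch <- nch + if (design$veog) 2L else 0L
  ch_names <- default_channels(nch)
  if (design$veog) ch_names <- c(ch_names, "VEOG1", "VEOG2")
  L <- if (sd > 0) t(chol(ring_covariance(total_ch, sd, falloff))) else NULL
  with_seed(derive_seed(seed, "noise"), {
    if (!is.null(L) && !pink) {
      # white temporal noise: one draw + one mixing product for all trials
      e <- L %*% matrix(rnorm(total_ch * nt * n), total_ch, nt * n)
      dim(e) <- c(total_ch, nt, n)
      dat <- aperm(e, c(3, 1, 2))
    } else {
      dat <- array(0, dim = c(n, total_ch, nt))
      if (!is.null(L)) {
        for (i in seq_len(n)) {
          w <- pink_filter(matrix(rnorm(total_ch * nt), total_ch, nt))
          dat[i, , ] <- L %*% w
        }
      }
    }
  })
  key <- paste(labels$task, labels$category)
  for (k in unique(key)) {
    ix <- which(key == k)
    dat[ix, seq_len(nch), ] <- dat[ix, seq_len(nch), , drop = FALSE] +
      rep(signals[[k]], each = length(ix))
  }
  artifact_idx <- integer(0)
  if (design$artifact_trials > 0) {
    artifact_idx <- with_seed(derive_seed(seed, "artifacts"),
                              sort(sample(n, design$artifact_trials)))
    # blink-like transient confined to the post-stimulus window so baseline
    # correction cannot cancel it
    post <- times > 50 & times < 350
    dat[artifact_idx, nch + 1L, post] <- dat[artifact_idx, nch + 1L, post] + 400
  }
  epochs <- eeg_epochs(dat, times, design$srate, ch_names, labels,
                       veog_pair = if (design$veog) c("VEOG1", "VEOG2") else NULL)
  pairs <- list(c("bird", "nonbird_animal"), c("nonbird_animal", "vehicle"), c("bird", "vehicle"))
  dist_true <- array(NA_real_, dim = c(3, 2, nt),
                     dimnames = list(c("bird-nonbird_animal", "nonbird_animal-vehicle", "bird-vehicle"),
                                     TASKS, NULL))
  for (p in 1:3) for (tk in 1:2) {
    dist_true[p, tk, ] <- snr * schedule$distance(pairs[[p]], TASKS[tk], times)
  }
  gt <- list(mixing = M, times = times, distances = dist_true,
             artifact_trials = artifact_idx,
             seeds = list(seed = seed, mixing_seed = mixing_seed),
             schedule_params = schedule$params, snr = snr, noise = list(sd = sd, falloff = falloff, pink = pink))
  list(epochs = epochs, ground_truth = gt)
}

#' Generate one synthetic participant (behavior + epochs, shared trials)
#'
#' @inheritParams generate_epochs
#' @param ddm nested list task -> category -> [ddm_params].
#' @return list with `behavior`, `epochs`, `ground_truth`.
#' @export
generate_participant <- function(design = sim_design(), schedule = geometry_schedule(),
                                 ddm = ddm_defaults(), seed = 1,
                                 noise = list(sd = 10, falloff = 2, pink = FALSE),
                                 snr = 1, participant = "p01") {
  beh <- generate_behavior(design, ddm, seed, participant)
  ep <- generate_epochs(design, schedule, seed, noise = noise, snr = snr,
                        participant = participant,
                        labels = beh[, c("task", "category", "participant", "correct", "rt_ms")])
  list(behavior = beh, epochs = ep$epochs, ground_truth = ep$ground_truth)
}

#' Fabricate Gaussian posterior samples around true DDM parameters
#'
#' Stand-in for MCMC posteriors of a hierarchical DDM fit: independent
#' Gaussian draws centered on the true per-condition parameter values.
#'
#' @param true_params nested list task -> category -> [ddm_params].
#' @param spread posterior SD (same for every parameter).
#' @param n_samples draws per chain.
#' @param seed integer seed.
#' @return nested list task -> category -> list(a = , v = , t = ) of numeric
#'   vectors of length `n_samples`.
#' @export
generate_posterior_samples <- function(true_params = ddm_defaults(), spread = 0.1,
                                       n_samples = 2000, seed = 1) {
  if (spread <= 0) stopf("generate_posterior_samples: spread must be > 0")
  out <- list()
  for (task in names(true_params)) {
    out[[task]] <- list()
    for (cat in names(true_params[[task]])) {
      p <- true_params[[task]][[cat]]
      out[[task]][[cat]] <- with_seed(derive_seed(seed, "post", task, cat), list(
        a = rnorm(n_samples, p$a, spread),
        v = rnorm(n_samples, p$v, spread),
        t = rnorm(n_samples, p$t, spread)
      ))
    }
  }
  out
}

#' Generate smooth unit-norm area templates
#'
#' Rows are smooth random scalp topographies (circular moving-average
#' smoothed Gaussian noise over the channel ring), normalized to unit norm
#' and mutually distinguishable (pairwise |cosine| < 0.95).
#'
#' @param n_areas number of areas (rows), >= 2.
#' @param channels number of channels (columns).
#' @param smoothness half-width of the circular smoothing window (channels).
#' @param seed integer seed.
#' @return `n_areas x channels` matrix with rownames `area1..areaN` and
#'   colnames from [default_channels()].
#' @export
generate_templates <- function(n_areas = 6, channels = 64, smoothness = 3, seed = 1) {
  if (n_areas < 2) stopf("generate_templates: n_areas must be >= 2")
  smooth_row <- function(x) {
    k <- 2 * smoothness + 1
    idx <- outer(seq_along(x), -smoothness:smoothness, function(i, o) ((i + o - 1) %% length(x)) + 1)
    rowMeans(matrix(x[idx], nrow = length(x)))
  }
  for (attempt in 1:100) {
    tpl <- with_seed(derive_seed(seed, "templates", attempt), {
      m <- matrix(rnorm(n_areas * channels), n_areas, channels)
      m <- t(apply(m, 1, smooth_row))
      m / sqrt(rowSums(m^2))
    })
    co <- abs(tcrossprod(tpl))
    diag(co) <- 0
    if (max(co) < 0.95) {
      rownames(tpl) <- paste0("area", seq_len(n_areas))
      colnames(tpl) <- default_channels(channels)
      return(tpl)
    }
  }
  stopf("generate_templates: could not achieve pairwise |cosine| < 0.95; try more channels")
}

#' Default channel labels
#'
#' The first `n` labels from a fixed 64-name scalp montage ordered so the
#' standard occipital, central and frontal ROI electrodes appear first.
#' @param n number of channels.
#' @return character vector of length `n`.
#' @export
default_channels <- function(n) {
  base <- c(
    "O1", "PO3", "PO7", "Oz", "O2", "PO4", "PO8",          # occipital ROI
    "C3", "C1", "Cz", "C2", "C4",                           # central ROI
    "AF3", "F1", "AFz", "Fz", "F2", "AF4",                  # frontal ROI
    "Fp1", "Fp2", "F7", "F5", "F3", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO9", "POz", "PO10", "O9", "Iz", "O10", "Fpz"
  )
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("ch%02d", seq_len(n - length(base))))
}
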