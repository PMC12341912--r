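# Pipeline orchestration: a single validated config drives
# simulate -> behavior -> ERP -> decoding -> temporal generalization ->
# RSA/MDS -> sources, with deterministic per-stage child seeds and
# machine-readable TSV/JSON outputs plus a run manifest.

PIPELINE_STAGES <- c("simulate", "behavior", "erp", "decode", "tgen", "rsa", "mds", "sources")

config_schema <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    n_participants = 17L,
    design = list(n_trials = 2000L, channels = 64L, srate = 256,
                  epoch_ms = c(-150, 500), veog = FALSE, artifact_trials = 0L),
    noise = list(sd = 10, falloff = 2, pink = FALSE),
    schedule = list(d_av = 8, d_bn_max = 8, av_onset = 120, av_peak = 200,
                    bn_onset = 250, bn_peak = 350),
    snr = 1,
    stages = as.list(stats::setNames(rep(TRUE, length(PIPELINE_STAGES)), PIPELINE_STAGES)),
    folds = 10L, repetitions = 10L, pseudotrials = 5L, iterations = 20L,
    n_perm = 1000L, n_boot = 1000L,
    cluster_alpha = 0.05, alpha = 0.05,
    p_threshold = 0.005, min_duration_ms = 15,
    bin_factor = 4L,
    tgen_pairs = list(c("bird", "nonbird_animal")),
    n_areas = 6L,
    correct_only = FALSE,
    baseline_window = c(-150, 0),
    eye_threshold_uv = 150,
    mds_timepoints = c(seq(50, 400, by = 50), 480),
    mds_half_width = 15,
    write_epochs = "first",
    rois = NULL
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (folds 10, repetitions 10, pseudotrials 5, iterations 20,
#' n_perm 1000, n_boot 1000, p threshold 0.005 with a 15-ms minimum
#' duration), checks value ranges, and rejects unknown keys with their path.
#'
#' @param config a named list, or a path to a YAML file.
#' @return the normalized config (class `run_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  schema <- config_schema()
  errors <- character(0)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) errors <- c(errors, sprintf("unknown key '%s'", unknown))
  out <- schema
  for (k in intersect(names(config), names(schema))) {
    if (k %in% c("design", "noise", "schedule", "stages") && is.list(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(schema[[k]]))
      if (length(bad)) errors <- c(errors, sprintf("unknown key '%s.%s'", k, bad))
      for (kk in intersect(names(config[[k]]), names(schema[[k]]))) {
        out[[k]][[kk]] <- config[[k]][[kk]]
      }
    } else {
      out[[k]] <- config[[k]]
    }
  }
  if (out$folds < 2) errors <- c(errors, "folds must be >= 2")
  if (out$repetitions < 1) errors <- c(errors, "repetitions must be >= 1")
  if (out$pseudotrials < 2) errors <- c(errors, "pseudotrials must be >= 2")
  if (out$iterations < 1) errors <- c(errors, "iterations must be >= 1")
  if (out$n_participants < 2) errors <- c(errors, "n_participants must be >= 2")
  if (out$p_threshold <= 0 || out$p_threshold >= 1) errors <- c(errors, "p_threshold must be in (0, 1)")
  if (length(errors)) stopf("invalid config:\n  - %s", paste(errors, collapse = "\n  - "))
  if (is.null(out$rois)) out$rois <- lapply(roi_defaults(), function(r) r$electrodes)
  class(out) <- "run_config"
  out
}

#' Reduced-size demonstration configuration
#'
#' The full pipeline at desk scale: 4 participants, 400 trials, 24 channels
#' plus eye channels at 100 Hz, 2 decoding repetitions, 10 RSA iterations,
#' 200 permutations/bootstraps. Completes in a few minutes on one CPU.
#' @param out_dir output directory.
#' @param seed master seed.
#' @return a validated `run_config`.
#' @export
demo_config <- function(out_dir = tempfile("catrep_run_"), seed = 1) {
  validate_config(list(
    seed = seed, out_dir = out_dir, n_participants = 4,
    design = list(n_trials = 400, channels = 24, srate = 100, veog = TRUE,
                  artifact_trials = 4),
    repetitions = 2, iterations = 10, n_perm = 200, n_boot = 200,
    mds_timepoints = c(seq(50, 400, by = 50), 480)
  ))
}

pair_names <- function() list(c("bird", "nonbird_animal"),
                              c("nonbird_animal", "vehicle"),
                              c("bird", "vehicle"))
pair_id <- function(pair) paste(pair, collapse = "|")

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  path
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  path
}

cluster_summary <- function(ct, times) {
  list(n_clusters = nrow(ct$clusters),
       clusters = if (nrow(ct$clusters)) {
         lapply(seq_len(nrow(ct$clusters)), function(i) {
           idx <- ct$members[[i]]
           list(mass = ct$clusters$mass[i], p = ct$clusters$p[i],
                onset_ms = if (!is.null(times)) times[min(idx)] else min(idx),
                offset_ms = if (!is.null(times)) times[max(idx)] else max(idx))
         })
       } else list(),
       significant = any(ct$clusters$p <= ct$params$alpha))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic participants
#' generated from the config, writing plain TSV/JSON outputs and a manifest
#' (seeds, parameters, output checksums). Rerunning with the same config and
#' master seed reproduces every stage output byte-identically.
#'
#' @param config a `run_config` from [validate_config()] (or a list / YAML
#'   path, validated on the fly).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (is.null(config$out_dir)) stopf("run_pipeline: config$out_dir is required")
  st <- config$stages
  if (isTRUE(st$sources) && !isTRUE(st$decode)) {
    stopf("run_pipeline: the sources stage requires the decode stage (it localizes decoding patterns); enable stages$decode or disable stages$sources")
  }
  if (isTRUE(st$mds) && !isTRUE(st$rsa)) {
    stopf("run_pipeline: the mds stage requires the rsa stage; enable stages$rsa or disable stages$mds")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("catrep")),
                   seed = config$seed, stages = list())
  outputs <- character(0)
  t0 <- Sys.time()
  design <- sim_design(n_trials = config$design$n_trials, channels = config$design$channels,
                       srate = config$design$srate, epoch_ms = config$design$epoch_ms,
                       veog = isTRUE(config$design$veog),
                       artifact_trials = config$design$artifact_trials)
  schedule <- do.call(geometry_schedule, config$schedule)
  pairs <- pair_names()
  participants <- sprintf("p%02d", seq_len(config$n_participants))

  ## ---- simulate ----------------------------------------------------------
  epochs_list <- list(); behavior_all <- list()
  if (!isTRUE(st$simulate)) stopf("run_pipeline: the simulate stage cannot be disabled (it provides all inputs)")
  stage_files <- character(0)
  for (i in seq_along(participants)) {
    pid <- participants[i]
    gp <- generate_participant(design, schedule, ddm_defaults(),
                               seed = derive_seed(config$seed, "participant", i),
                               noise = config$noise, snr = config$snr, participant = pid)
    ep <- baseline_correct(gp$epochs, config$baseline_window)
    if (!is.null(ep$veog_pair)) {
      ep <- reject_eye_epochs(ep, config$eye_threshold_uv)$epochs
    }
    epochs_list[[pid]] <- ep
    behavior_all[[pid]] <- gp$behavior
    if (identical(config$write_epochs, "all") ||
        (identical(config$write_epochs, "first") && i == 1)) {
      stage_files <- c(stage_files, write_epochs(ep, file.path(config$out_dir, paste0("epochs_", pid))))
    }
  }
  templates <- generate_templates(config$n_areas, length(epochs_list[[1]]$channels),
                                  seed = derive_seed(config$seed, "templates"))
  behavior_tbl <- do.call(rbind, behavior_all)
  stage_files <- c(stage_files,
                   write_tsv(behavior_tbl, file.path(config$out_dir, "behavior.tsv")),
                   write_tsv(data.frame(area = rownames(templates), templates),
                             file.path(config$out_dir, "templates.tsv")),
                   write_json_out(list(schedule = config$schedule, snr = config$snr,
                                       noise = config$noise, seed = config$seed),
                                  file.path(config$out_dir, "ground_truth.json")))
  manifest$stages$simulate <- list(outputs = basename(stage_files),
                                   n_participants = length(participants))
  outputs <- c(outputs, stage_files)
  times <- epochs_list[[1]]$times
  srate <- epochs_list[[1]]$srate

  ## ---- behavior ----------------------------------------------------------
  if (isTRUE(st$behavior)) {
    filt <- lapply(behavior_all, filter_trials)
    dprimes <- t(vapply(filt, dprime_by_task, numeric(2)))
    rt_task <- t(vapply(filt, function(b) {
      vapply(split(b, b$task), function(x) mean(x$rt_ms[x$correct], na.rm = TRUE), numeric(1))
    }, numeric(2)))
    task_tests <- paired_comparisons(cbind(dprime_sup = dprimes[, "superordinate"],
                                           dprime_basic = dprimes[, "basic"],
                                           rt_sup = rt_task[, "superordinate"],
                                           rt_basic = rt_task[, "basic"]),
                                     list(c("dprime_sup", "dprime_basic"), c("rt_sup", "rt_basic")),
                                     family_size = 1)
    rates <- lapply(filt, category_rates)
    # per-category RT paired comparisons within each task, Bonferroni x3
    cat_tests <- list()
    for (task in TASKS) {
      rt_cat <- t(vapply(filt, function(b) {
        bb <- b[b$task == task, ]
        vapply(split(bb, bb$category)[CATEGORIES], function(x) {
          mean(x$rt_ms[x$correct], na.rm = TRUE)
        }, numeric(1))
      }, numeric(3)))
      colnames(rt_cat) <- CATEGORIES
      cat_tests[[task]] <- paired_comparisons(rt_cat, list(
        c("bird", "nonbird_animal"), c("nonbird_animal", "vehicle"), c("bird", "vehicle")
      ))
    }
    post <- generate_posterior_samples(ddm_defaults(), spread = 0.1, n_samples = 2000,
                                       seed = derive_seed(config$seed, "posterior"))
    overlap <- list()
    for (cat in CATEGORIES) {
      overlap[[cat]] <- lapply(c(a = "a", v = "v", t = "t"), function(par) {
        posterior_overlap_probability(post$superordinate[[cat]][[par]],
                                      post$basic[[cat]][[par]])
      })
    }
    f1 <- write_tsv(data.frame(participant = rownames(dprimes), dprimes, rt_task),
                    file.path(config$out_dir, "behavior_summary.tsv"))
    f2 <- write_json_out(list(task_tests = task_tests, rt_category_tests = cat_tests,
                              posterior_overlap = overlap,
                              removed = lapply(filt, function(x) as.list(attr(x, "removed")))),
                         file.path(config$out_dir, "behavior_tests.json"))
    manifest$stages$behavior <- list(outputs = basename(c(f1, f2)))
    outputs <- c(outputs, f1, f2)
  }

  ## ---- erp ---------------------------------------------------------------
  if (isTRUE(st$erp)) {
    rois <- lapply(names(config$rois), function(nm) roi_spec(nm, config$rois[[nm]]))
    names(rois) <- names(config$rois)
    rois <- Filter(function(r) all(r$electrodes %in% epochs_list[[1]]$channels), rois)
    erp_rows <- list(); erp_tests <- list()
    for (roi in rois) for (pair in pairs) for (task in TASKS) {
      diffs <- t(vapply(epochs_list, function(ep) {
        ea <- condition_erp(ep, list(task = task, category = pair[1]))
        eb <- condition_erp(ep, list(task = task, category = pair[2]))
        roi_average(differential_waveform(ea, eb), roi)
      }, numeric(length(times))))
      ct <- cluster_permutation_test(diffs, n_perm = config$n_perm,
                                     cluster_alpha = config$cluster_alpha,
                                     alpha = config$alpha,
                                     seed = derive_seed(config$seed, "erp", roi$name, pair_id(pair), task))
      key <- paste(roi$name, pair_id(pair), task, sep = "/")
      erp_tests[[key]] <- cluster_summary(ct, times)
      erp_rows[[key]] <- data.frame(roi = roi$name, pair = pair_id(pair), task = task,
                                    time_ms = times, diff_uv = colMeans(diffs),
                                    significant = as.vector(ct$sig_mask))
    }
    f1 <- write_tsv(do.call(rbind, erp_rows), file.path(config$out_dir, "erp_roi_diffs.tsv"))
    f2 <- write_json_out(erp_tests, file.path(config$out_dir, "erp_tests.json"))
    manifest$stages$erp <- list(outputs = basename(c(f1, f2)), n_rois = length(rois))
    outputs <- c(outputs, f1, f2)
  }

  ## ---- decode ------------------------------------------------------------
  dec <- NULL
  if (isTRUE(st$decode)) {
    dec <- list(); dec_rows <- list(); dec_tests <- list()
    for (pair in pairs) for (task in TASKS) {
      key <- paste(pair_id(pair), task, sep = "/")
      real <- t(vapply(epochs_list, function(ep) {
        decode_timecourse(ep, pair, task, config$folds, config$repetitions,
                          seed = derive_seed(config$seed, "decode", pair_id(pair), task,
                                             ep$labels$participant[1]),
                          correct_only = config$correct_only)$accuracy
      }, numeric(length(times))))
      shuf <- t(vapply(epochs_list, function(ep) {
        shuffled_baseline(ep, pair, task, config$folds, config$repetitions,
                          seed = derive_seed(config$seed, "shuffle", pair_id(pair), task,
                                             ep$labels$participant[1]),
                          correct_only = config$correct_only)$accuracy
      }, numeric(length(times))))
      dec[[key]] <- list(real = real, shuffled = shuf)
      ct <- cluster_permutation_test(real, shuf, n_perm = config$n_perm,
                                     cluster_alpha = config$cluster_alpha, alpha = config$alpha,
                                     seed = derive_seed(config$seed, "decstat", key))
      dec_tests[[key]] <- cluster_summary(ct, times)
      dec_rows[[key]] <- data.frame(pair = pair_id(pair), task = task, time_ms = times,
                                    accuracy = colMeans(real), baseline = colMeans(shuf),
                                    significant = as.vector(ct$sig_mask))
    }
    for (pair in pairs) {
      key <- pair_id(pair)
      ct <- cluster_permutation_test(dec[[paste(key, "basic", sep = "/")]]$real,
                                     dec[[paste(key, "superordinate", sep = "/")]]$real,
                                     n_perm = config$n_perm,
                                     cluster_alpha = config$cluster_alpha, alpha = config$alpha,
                                     seed = derive_seed(config$seed, "dectask", key))
      dec_tests[[paste(key, "task_effect", sep = "/")]] <- cluster_summary(ct, times)
    }
    f1 <- write_tsv(do.call(rbind, dec_rows), file.path(config$out_dir, "decoding.tsv"))
    f2 <- write_json_out(dec_tests, file.path(config$out_dir, "decoding_tests.json"))
    manifest$stages$decode <- list(outputs = basename(c(f1, f2)))
    outputs <- c(outputs, f1, f2)
  }

  ## ---- temporal generalization ------------------------------------------
  if (isTRUE(st$tgen)) {
    tg_tests <- list(); tg_files <- character(0)
    for (pair in config$tgen_pairs) for (task in TASKS) {
      key <- paste(pair_id(pair), task, sep = "/")
      tgs <- lapply(epochs_list, function(ep) {
        temporal_generalization(ep, pair, task, config$bin_factor, config$folds,
                                config$repetitions,
                                seed = derive_seed(config$seed, "tgen", key,
                                                   ep$labels$participant[1]))
      })
      tg_times <- tgs[[1]]$times
      arr <- array(NA_real_, c(length(tgs), length(tg_times), length(tg_times)))
      for (i in seq_along(tgs)) arr[i, , ] <- tgs[[i]]$accuracy
      ct <- cluster_permutation_test(arr, array(0.5, dim(arr)), n_perm = config$n_perm,
                                     cluster_alpha = config$cluster_alpha, alpha = config$alpha,
                                     fill_holes = TRUE,
                                     seed = derive_seed(config$seed, "tgstat", key))
      tg_tests[[key]] <- list(n_clusters = nrow(ct$clusters),
                              significant_fraction = mean(ct$sig_mask))
      gm <- apply(arr, c(2, 3), mean)
      fn <- file.path(config$out_dir, sprintf("tg_%s_%s.tsv", gsub("[|]", "_", pair_id(pair)), task))
      tg_files <- c(tg_files, write_tsv(data.frame(train_ms = rep(tg_times, times = length(tg_times)),
                                                   test_ms = rep(tg_times, each = length(tg_times)),
                                                   accuracy = as.vector(gm),
                                                   significant = as.vector(ct$sig_mask)), fn))
    }
    f2 <- write_json_out(tg_tests, file.path(config$out_dir, "tg_tests.json"))
    manifest$stages$tgen <- list(outputs = basename(c(tg_files, f2)))
    outputs <- c(outputs, tg_files, f2)
  }

  ## ---- rsa ---------------------------------------------------------------
  rsa_series <- NULL
  if (isTRUE(st$rsa)) {
    rsa_series <- list(); rsa_rows <- list(); rsa_tests <- list()
    for (pair in pairs) for (task in TASKS) {
      key <- paste(pair_id(pair), task, sep = "/")
      dists <- t(vapply(epochs_list, function(ep) {
        cv_distance_timecourse(ep, pair, task, config$pseudotrials, config$iterations,
                               seed = derive_seed(config$seed, "rsa", key,
                                                  ep$labels$participant[1]),
                               correct_only = config$correct_only)$distance
      }, numeric(length(times))))
      rsa_series[[key]] <- dists
      ct <- cluster_permutation_test(dists, n_perm = config$n_perm,
                                     cluster_alpha = config$cluster_alpha, alpha = config$alpha,
                                     seed = derive_seed(config$seed, "rsastat", key))
      rsa_tests[[key]] <- cluster_summary(ct, times)
      rsa_rows[[key]] <- data.frame(pair = pair_id(pair), task = task, time_ms = times,
                                    distance = colMeans(dists),
                                    significant = as.vector(ct$sig_mask))
    }
    for (pair in pairs) {
      key <- pair_id(pair)
      ct <- cluster_permutation_test(rsa_series[[paste(key, "basic", sep = "/")]],
                                     rsa_series[[paste(key, "superordinate", sep = "/")]],
                                     n_perm = config$n_perm,
                                     cluster_alpha = config$cluster_alpha, alpha = config$alpha,
                                     seed = derive_seed(config$seed, "rsatask", key))
      rsa_tests[[paste(key, "task_effect", sep = "/")]] <- cluster_summary(ct, times)
    }
    f1 <- write_tsv(do.call(rbind, rsa_rows), file.path(config$out_dir, "rsa_distances.tsv"))
    f2 <- write_json_out(rsa_tests, file.path(config$out_dir, "rsa_tests.json"))
    manifest$stages$rsa <- list(outputs = basename(c(f1, f2)))
    outputs <- c(outputs, f1, f2)
  }

  ## ---- mds ---------------------------------------------------------------
  if (isTRUE(st$mds)) {
    mds_rows <- list()
    for (task in TASKS) {
      prev <- NULL
      for (tp in config$mds_timepoints) {
        ser <- lapply(pairs, function(pair) {
          key <- paste(pair_id(pair), task, sep = "/")
          structure(list(times = times, distance = colMeans(rsa_series[[key]])),
                    class = "rdm_series")
        })
        names(ser) <- vapply(pairs, pair_id, character(1))
        dm <- rdm_at_window(ser, tp, config$mds_half_width)
        sol <- tryCatch(classical_mds(dm, k = 2), error = function(e) NULL)
        if (is.null(sol)) next
        pts <- if (!is.null(prev)) procrustes_align(sol$points, prev) else sol$points
        prev <- pts
        mds_rows[[paste(task, tp)]] <- data.frame(
          task = task, time_ms = tp, category = rownames(pts),
          dim1 = pts[, 1], dim2 = pts[, 2],
          eig1 = sol$eig[1], eig2 = sol$eig[2], eig3 = sol$eig[3])
      }
    }
    f1 <- write_tsv(do.call(rbind, mds_rows), file.path(config$out_dir, "mds_coordinates.tsv"))
    manifest$stages$mds <- list(outputs = basename(f1))
    outputs <- c(outputs, f1)
  }

  ## ---- sources -----------------------------------------------------------
  if (isTRUE(st$sources)) {
    src_rows <- list()
    for (pair in pairs) for (task in TASKS) {
      key <- paste(pair_id(pair), task, sep = "/")
      pats <- lapply(epochs_list, function(ep) {
        pattern_for_pair(ep, pair, task,
                         seed = derive_seed(config$seed, "srcpat", key,
                                            ep$labels$participant[1]))
      })
      stc <- source_timecourses(pats, templates, srate = srate,
                                n_boot = config$n_boot,
                                seed = derive_seed(config$seed, "sources", key),
                                p_threshold = config$p_threshold,
                                min_duration_ms = config$min_duration_ms)
      for (a in rownames(stc$contribution)) {
        src_rows[[paste(key, a)]] <- data.frame(
          pair = pair_id(pair), task = task, area = a, time_ms = times,
          contribution = stc$contribution[a, ], z = stc$z[a, ],
          p = stc$p[a, ], significant = stc$mask[a, ])
      }
    }
    f1 <- write_tsv(do.call(rbind, src_rows), file.path(config$out_dir, "sources.tsv"))
    manifest$stages$sources <- list(outputs = basename(f1))
    outputs <- c(outputs, f1)
  }

  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)), function(f) {
    if (dir.exists(f)) {
      fs <- list.files(f, full.names = TRUE)
      fs <- fs[order(basename(fs))]
      as.list(stats::setNames(unname(tools::md5sum(fs)), basename(fs)))
    } else unname(tools::md5sum(f))
  })
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  write_json_out(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}

#' Per-timepoint LDA pattern for a category pair
#'
#' Fits a shrinkage LDA at every timepoint on the equalized trials of the
#' pair within one task and applies the activation-pattern transform.
#' @param epochs an [eeg_epochs].
#' @param pair length-2 character vector of categories.
#' @param task task to restrict to.
#' @param seed seed for trial equalization.
#' @param shrinkage passed to [fit_lda()].
#' @return an `activation_pattern`.
#' @export
pattern_for_pair <- function(epochs, pair, task, seed = 1, shrinkage = "auto") {
  sub <- subset_pair(epochs, pair, task)
  eq <- subsample_equal(sub, "category", seed)
  models <- lapply(seq_along(eq$times), function(ti) {
    fit_lda(eq$data[, , ti, drop = TRUE], eq$labels$category, shrinkage,
            classes = pair)
  })
  weights_to_pattern(models, eq)
}
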