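#' Configuration of an end-to-end simulated study
#'
#' Collects every tunable of the pipeline in one object. The defaults are
#' the analysis constants used throughout: 30 deg/s velocity and
#' 8000 deg/s^2 acceleration thresholds, a 300 ms baseline window, a
#' 3 s.d. recursive outlier criterion, a 20% blink exclusion limit, the
#' 8th saliency decile as ROI cutoff and 1000 bootstrap samples.
#'
#' @param n_participants,n_trials_per_task,n_scenes Design size.
#' @param scene_width_px,scene_height_px Scene resolution; the viewing
#'   geometry maps this area onto 30.6 x 23.0 cm at 52.5 cm.
#' @param saliency A [saliency_params()] object.
#' @param tasks Named list of [behaviour_params()] per task.
#' @param vel_thresh,acc_thresh,min_saccade_ms,blink_pad_ms Event parsing,
#'   see [detect_events()].
#' @param baseline_window_ms,outlier_sd,max_blink_fraction Preprocessing,
#'   see [compute_baseline()], [recursive_outlier_removal()],
#'   [exclude_trials()].
#' @param decile_cutoff ROI saliency decile, see [build_roi_partition()].
#' @param max_fix_index Leading fixation indices analysed singly.
#' @param n_boot Bootstrap samples for shift functions.
#' @param seed Master seed; every random stage derives its seed from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_participants = 33, n_trials_per_task = 40,
                       n_scenes = 80,
                       scene_width_px = 640L, scene_height_px = 480L,
                       saliency = saliency_params(),
                       tasks = default_task_params(),
                       vel_thresh = 30, acc_thresh = 8000,
                       min_saccade_ms = 4, blink_pad_ms = 25,
                       baseline_window_ms = 300, outlier_sd = 3,
                       max_blink_fraction = 0.20,
                       decile_cutoff = 8, max_fix_index = 5,
                       n_boot = 1000, seed = 1L) {
  cfg <- as.list(environment())
  thr <- c(cfg$vel_thresh, cfg$acc_thresh, cfg$baseline_window_ms,
           cfg$outlier_sd, cfg$max_blink_fraction, cfg$n_boot)
  if (any(thr <= 0)) abort("all thresholds must be positive")
  cfg$geometry <- geometry(screen_width_px = scene_width_px,
                           screen_height_px = scene_height_px)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' Scalar fields map directly; the per-task behaviour parameters live
#' under `tasks:` and the saliency parameters under `saliency:`. Fields
#' absent from the file keep their defaults.
#'
#' @param path YAML file path.
#' @param config A [run_config()].
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), c("tasks", "saliency", "geometry"))]
  if (!is.null(raw$saliency)) {
    args$saliency <- do.call(saliency_params, raw$saliency)
  }
  if (!is.null(raw$tasks)) {
    args$tasks <- lapply(raw$tasks, function(tp) {
      for (nm in c("first_target_probs", "subsequent_target_probs")) {
        if (!is.null(tp[[nm]])) tp[[nm]] <- unlist(tp[[nm]])
      }
      do.call(behaviour_params, tp)
    })
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$geometry <- NULL
  out$saliency <- unclass(out$saliency)
  out$tasks <- lapply(out$tasks, function(tp) {
    tp <- unclass(tp)
    tp$first_target_probs <- as.list(tp$first_target_probs)
    tp$subsequent_target_probs <- as.list(tp$subsequent_target_probs)
    tp
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full simulated study
#'
#' Simulate, analyse and summarise one complete experiment:
#' scene generation, saliency maps and ROI partitions, streamed per-trial
#' gaze simulation and event parsing, baseline extraction with recursive
#' outlier removal and trial exclusion, drift correction, ROI assignment,
#' area-normalized fixation-course scores, first-entry latencies
#' (unconditional and conditional on the first fixation), the
#' repeated-measures ANOVAs, Bonferroni-corrected paired contrasts and the
#' three head-orienting shift functions.
#'
#' Trials are processed one at a time; raw sample streams are discarded
#' after event parsing, so memory stays flat in the design size.
#'
#' @param config A [run_config()].
#' @param progress Print stage progress.
#' @return An object of class `study_results`: a list of tibbles
#'   (`scene_stats`, `fixation_course`, `latency`, `latency_conditional`,
#'   `exclusions`), fitted objects (`anova_course`, `anova_latency`,
#'   `anova_relative_saliency`, post-hoc tables, `shift_functions`) and the
#'   `config`.
#' @export
run_study <- function(config = run_config(), progress = interactive()) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (progress) message(sprintf(...))
  geom <- config$geometry

  say("building %d scenes", config$n_scenes)
  scenes <- build_scene_bank(config$n_scenes, config$seed,
                             width_px = config$scene_width_px,
                             height_px = config$scene_height_px)

  say("saliency maps and ROI partitions")
  partitions <- vector("list", config$n_scenes)
  scene_rows <- vector("list", config$n_scenes)
  for (i in seq_along(scenes)) {
    sal <- compute_saliency_map(scenes[[i]], config$saliency)
    part <- build_roi_partition(scenes[[i]], sal, config$decile_cutoff)
    partitions[[i]] <- part
    fr <- area_fractions(part)
    fr$scene_id <- scenes[[i]]$scene_id
    fr$rel_saliency <- vapply(roi_levels(), function(r) {
      m <- part$labels == match(r, roi_levels())
      if (!any(m)) NA_real_ else relative_roi_saliency(sal, m)
    }, numeric(1))
    scene_rows[[i]] <- fr
  }
  scene_stats <- dplyr::bind_rows(scene_rows)
  roi_areas <- scene_stats[, c("scene_id", "roi", "area_px")]

  ids <- vapply(scenes, function(s) s$scene_id, integer(1))
  plan <- dataset_plan(config$n_participants, config$n_trials_per_task,
                       ids, config$seed, config$tasks)

  say("simulating and parsing %d trials", nrow(plan))
  trial_rows <- vector("list", nrow(plan))
  fix_rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    pl <- plan[i, ]
    k <- match(pl$scene_id, ids)
    trial <- generate_gaze_trial(
      scenes[[k]], partitions[[k]], config$tasks[[pl$task]], pl$task,
      seed = pl$trial_seed, participant_id = pl$participant_id,
      trial_id = pl$trial_id,
      latency_shift_ms = pl$latency_shift_ms,
      head_logit_shift = pl$head_logit_shift
    )
    ev <- detect_events(trial$samples, geom,
                        vel_thresh = config$vel_thresh,
                        acc_thresh = config$acc_thresh,
                        min_saccade_ms = config$min_saccade_ms,
                        blink_pad_ms = config$blink_pad_ms)
    bl <- compute_baseline(trial, window_ms = config$baseline_window_ms)
    bf <- blink_fraction(trial)
    fx <- ev[ev$kind == "fixation" &
               ev$onset_ms >= trial$scene_onset_ms &
               ev$onset_ms < trial$scene_offset_ms, ]
    trial_rows[[i]] <- tibble(
      participant_id = pl$participant_id, task = pl$task,
      trial_id = pl$trial_id, scene_id = pl$scene_id,
      baseline_x = bl$x_px, baseline_y = bl$y_px,
      baseline_valid = bl$valid, blink_fraction = bf
    )
    if (nrow(fx) > 0) {
      fix_rows[[i]] <- tibble(
        participant_id = pl$participant_id, task = pl$task,
        trial_id = pl$trial_id, scene_id = pl$scene_id,
        fix_index = seq_len(nrow(fx)),
        latency_ms = fx$onset_ms - trial$scene_onset_ms,
        x_px = fx$x_px, y_px = fx$y_px
      )
    }
  }
  trial_info <- dplyr::bind_rows(trial_rows)
  fixations <- dplyr::bind_rows(fix_rows)

  say("exclusion and drift correction")
  exclusions <- exclude_trials(trial_info,
                               max_blink_fraction = config$max_blink_fraction,
                               sd_mult = config$outlier_sd)
  kept <- exclusions[exclusions$retained, ]
  fixations <- dplyr::inner_join(
    fixations,
    kept[, c("participant_id", "task", "trial_id", "baseline_x", "baseline_y")],
    by = c("participant_id", "task", "trial_id")
  )
  ctr <- screen_centre(geom)
  fixations$x_px <- fixations$x_px + (ctr["x"] - fixations$baseline_x)
  fixations$y_px <- fixations$y_px + (ctr["y"] - fixations$baseline_y)
  fixations$baseline_x <- NULL
  fixations$baseline_y <- NULL
  fixations$roi <- NA
  for (sid in unique(fixations$scene_id)) {
    sel <- fixations$scene_id == sid
    fixations$roi[sel] <- as.character(assign_fixation_roi(
      fixations$x_px[sel], fixations$y_px[sel], partitions[[match(sid, ids)]]))
  }
  fixations$roi <- factor(fixations$roi, levels = roi_levels())

  say("descriptive statistics")
  course <- area_normalized_frequency(fixations, roi_areas,
                                      max_index = config$max_fix_index)
  latency <- first_entry_latency(fixations)
  latency_cond <- first_entry_latency(fixations, conditional_on_first = TRUE)

  say("inference")
  course15 <- dplyr::filter(course, .data$fix_bin != "6+")
  course15 <- droplevels(course15)
  anova_course <- rm_anova(complete_cells(course15, "score",
                                          c("task", "roi", "fix_bin")),
                           "score", c("task", "roi", "fix_bin"),
                           "participant_id")
  anova_latency <- rm_anova(complete_cells(latency, "median_latency_ms",
                                           c("task", "roi")),
                            "median_latency_ms", c("task", "roi"),
                            "participant_id")
  anova_relsal <- rm_anova(scene_stats, "rel_saliency", "roi", "scene_id")

  posthoc_roi <- pairwise_roi_t(course15, "score")
  posthoc_task <- task_difference_t(course15, "score")
  posthoc_task_latency <- task_difference_t(latency, "median_latency_ms")

  sf_data <- list(
    head_score_fix1 = task_pairs(
      dplyr::filter(course15, .data$roi == "head", .data$fix_bin == "1"),
      "score"),
    head_latency = task_pairs(
      dplyr::filter(latency, .data$roi == "head"), "median_latency_ms"),
    head_latency_first = task_pairs(
      dplyr::filter(latency_cond, .data$roi == "head"), "median_latency_ms")
  )
  shift_functions <- purrr::imap(sf_data, function(d, nm) {
    shift_function_dependent(d$free_viewing, d$social_detection,
                             n_boot = config$n_boot,
                             seed = derive_seed(config$seed,
                                                match(nm, names(sf_data))))
  })

  structure(
    list(scene_stats = scene_stats, fixation_course = course,
         latency = latency, latency_conditional = latency_cond,
         exclusions = exclusions,
         anova_course = anova_course, anova_latency = anova_latency,
         anova_relative_saliency = anova_relsal,
         posthoc_roi = posthoc_roi, posthoc_task = posthoc_task,
         posthoc_task_latency = posthoc_task_latency,
         shift_functions = shift_functions,
         config = config),
    class = "study_results"
  )
}

# average a score table to participant x task means per ROI pair member and
# keep only participants present in every cell of the within grid
complete_cells <- function(data, dv, within) {
  n_cells <- prod(vapply(within, function(f) length(unique(data[[f]])),
                         integer(1)))
  counts <- dplyr::count(dplyr::distinct(data[c("participant_id", within)]),
                         .data$participant_id)
  keep <- counts$participant_id[counts$n == n_cells]
  data[data$participant_id %in% keep & !is.na(data[[dv]]), ]
}

# paired-sample vectors per task, aligned on participants present in both
task_pairs <- function(data, dv) {
  wide <- tidyr::pivot_wider(data[, c("participant_id", "task", dv)],
                             names_from = "task",
                             values_from = dplyr::all_of(dv))
  wide <- wide[stats::complete.cases(wide), ]
  list(free_viewing = wide$free_viewing,
       social_detection = wide$social_detection)
}

# Bonferroni table of the 6 pairwise ROI contrasts on participant means
pairwise_roi_t <- function(data, dv) {
  means <- dplyr::summarise(
    dplyr::group_by(data, .data$participant_id, .data$roi),
    m = mean(.data[[dv]]), .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "roi", values_from = "m")
  wide <- wide[stats::complete.cases(wide), ]
  pairs <- utils::combn(roi_levels(), 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    tt <- paired_t(wide[[pr[2]]], wide[[pr[1]]])
    dplyr::bind_cols(tibble(roi_a = pr[1], roi_b = pr[2]), tidy(tt))
  })
  out <- dplyr::bind_rows(rows)
  out$alpha_bonferroni <- bonferroni_alpha(0.05, length(pairs))
  out
}

# task difference (social detection - free viewing) per ROI, on participant
# means (averaging over any further cells such as fixation bins)
task_difference_t <- function(data, dv) {
  means <- dplyr::summarise(
    dplyr::group_by(data, .data$participant_id, .data$task, .data$roi),
    .val = mean(.data[[dv]]), .groups = "drop")
  rows <- purrr::map(roi_levels(), function(r) {
    d <- task_pairs(means[means$roi == r, ], ".val")
    tt <- paired_t(d$free_viewing, d$social_detection)
    dplyr::bind_cols(tibble(roi = r), tidy(tt))
  })
  out <- dplyr::bind_rows(rows)
  out$alpha_bonferroni <- bonferroni_alpha(0.05, length(roi_levels()))
  out
}

#' @export
print.study_results <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<study_results> %d participants x %d trials/task, %d scenes\n",
              cfg$n_participants, cfg$n_trials_per_task, cfg$n_scenes))
  cat(sprintf("  trials retained: %d of %d\n",
              sum(x$exclusions$retained), nrow(x$exclusions)))
  cat("  fixation-course ANOVA:\n")
  print(as.data.frame(tidy(x$anova_course)[, c("effect", "df_num", "df_den",
                                               "statistic", "epsilon_hf",
                                               "p_value", "pes")]),
        digits = 3)
  invisible(x)
}

#' Write all result tables of a study run as delimited text
#'
#' @param results A [run_study()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(results, dir) {
  stopifnot(inherits(results, "study_results"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, name) {
    write.table(as.data.frame(x), file.path(dir, paste0(name, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  }
  wr(results$scene_stats, "scene_stats")
  wr(results$fixation_course, "fixation_course")
  wr(results$latency, "latency")
  wr(results$latency_conditional, "latency_conditional")
  wr(results$exclusions, "exclusion_audit")
  wr(tidy(results$anova_course), "anova_fixation_course")
  wr(tidy(results$anova_latency), "anova_latency")
  wr(tidy(results$anova_relative_saliency), "anova_relative_saliency")
  wr(results$posthoc_roi, "posthoc_roi")
  wr(results$posthoc_task, "posthoc_task")
  wr(results$posthoc_task_latency, "posthoc_task_latency")
  for (nm in names(results$shift_functions)) {
    wr(tidy(results$shift_functions[[nm]]), paste0("shift_", nm))
  }
  invisible(dir)
}
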