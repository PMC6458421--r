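#' Assign fixation centroids to ROI labels
#'
#' Looks up the partition label of the pixel under each (drift-corrected)
#' centroid. Coordinates are continuous with the screen spanning
#' `[0, width] x [0, height]`; the pixel under a point is
#' `floor(coord) + 1`. Off-screen centroids receive `NA` — the trial still
#' contributes its remaining fixations.
#'
#' @param x_px,y_px Centroid coordinates (vectors of equal length).
#' @param partition A [build_roi_partition()] object.
#' @return A factor with levels `head`, `body`, `lower`, `higher` (`NA` for
#'   off-screen centroids).
#' @export
assign_fixation_roi <- function(x_px, y_px, partition) {
  stopifnot(inherits(partition, "roi_partition"))
  h <- nrow(partition$labels); w <- ncol(partition$labels)
  col <- floor(x_px) + 1
  row <- floor(y_px) + 1
  # points exactly on the right/bottom edge belong to the last pixel
  col[x_px == w] <- w
  row[y_px == h] <- h
  on <- !is.na(x_px) & !is.na(y_px) &
    col >= 1 & col <= w & row >= 1 & row <= h
  lab <- rep(NA_integer_, length(x_px))
  lab[on] <- partition$labels[cbind(row[on], col[on])]
  factor(roi_levels()[lab], levels = roi_levels())
}

#' Area-normalized fixation frequency by fixation index
#'
#' For each participant, task, ROI and fixation index (1-5 plus a pooled
#' `"6+"` bin) the relative frequency that the ROI received the index-th
#' fixation is computed across trials: the count of index-th fixations
#' landing in the ROI divided by the count of index-th fixations landing in
#' any ROI. Because the partition is exhaustive, the denominator equals the
#' number of trials with a valid (on-screen) fixation at that index.
#' Off-screen fixations are excluded from numerator and denominator alike.
#' Each relative frequency is then divided by the mean pixel area of the
#' ROI across the trials contributing to its denominator, correcting for
#' the higher capture probability of larger regions. The `"6+"` bin pools
#' all fixations from the sixth to the last.
#'
#' @param fixations Tibble with one row per scene fixation: columns
#'   `participant_id`, `task`, `trial_id`, `scene_id`, `fix_index`
#'   (1-based index among fixations starting at or after scene onset) and
#'   `roi` (factor from [assign_fixation_roi()], `NA` = off-screen).
#' @param roi_areas Tibble with `scene_id`, `roi`, `area_px` (one row per
#'   scene and ROI, e.g. from [area_fractions()] per scene).
#' @param max_index Number of leading fixation indices analysed singly.
#'
#' @return A tibble with `participant_id`, `task`, `roi`, `fix_bin`
#'   (factor: `"1"`..`"5"`, `"6+"`), `n_trials` (denominator), `rel_freq`,
#'   `mean_area_px` and `score` (`rel_freq / mean_area_px`, units 1/px).
#'   Cells whose denominator is zero are absent.
#' @export
area_normalized_frequency <- function(fixations, roi_areas, max_index = 5) {
  stopifnot(all(c("participant_id", "task", "trial_id", "scene_id",
                  "fix_index", "roi") %in% names(fixations)),
            all(c("scene_id", "roi", "area_px") %in% names(roi_areas)))
  valid <- dplyr::filter(fixations, !is.na(.data$roi))
  valid$fix_bin <- fix_bin_of(valid$fix_index, max_index)
  valid <- dplyr::filter(valid, !is.na(.data$fix_bin))

  bins <- fix_bin_levels(max_index)
  cells <- dplyr::group_by(valid, .data$participant_id, .data$task, .data$fix_bin)
  # counts per ROI within each cell, over an exhaustive ROI grid
  counts <- dplyr::ungroup(dplyr::count(cells, roi = .data$roi, .drop = FALSE))
  denom <- dplyr::summarise(cells, n_trials = dplyr::n(),
                            .groups = "drop")

  # mean ROI area over the trials feeding each cell's denominator
  trials <- dplyr::distinct(valid, .data$participant_id, .data$task,
                            .data$fix_bin, .data$trial_id, .data$scene_id)
  trials <- dplyr::inner_join(trials, roi_areas, by = "scene_id",
                              relationship = "many-to-many")
  areas <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id, .data$task,
                    .data$fix_bin, .data$roi),
    mean_area_px = mean(.data$area_px), .groups = "drop"
  )

  out <- dplyr::left_join(counts, denom,
                          by = c("participant_id", "task", "fix_bin"))
  out <- dplyr::left_join(out, areas,
                          by = c("participant_id", "task", "fix_bin", "roi"))
  out <- dplyr::mutate(
    out,
    fix_bin = factor(.data$fix_bin, levels = bins),
    rel_freq = .data$n / .data$n_trials,
    score = .data$rel_freq / .data$mean_area_px
  )
  out$n <- NULL
  dplyr::arrange(out, .data$participant_id, .data$task, .data$fix_bin, .data$roi)
}

fix_bin_levels <- function(max_index = 5) c(as.character(seq_len(max_index)), "6+")

fix_bin_of <- function(fix_index, max_index = 5) {
  lv <- fix_bin_levels(max_index)
  out <- ifelse(fix_index > max_index, "6+", as.character(fix_index))
  out[fix_index < 1] <- NA
  factor(out, levels = lv)
}

#' First-entry latency per ROI
#'
#' For each trial and ROI, the latency (ms after scene onset) of the first
#' fixation landing in that ROI; per participant, task and ROI the median
#' of these latencies across all trials with at least one valid fixation on
#' the ROI. With `conditional_on_first = TRUE`, only trials whose very
#' first scene fixation landed in the ROI contribute — the follow-up
#' analysis isolating genuinely first-glance captures.
#'
#' @param fixations As in [area_normalized_frequency()], plus a column
#'   `latency_ms` (fixation onset relative to scene onset).
#' @param conditional_on_first Restrict to trials whose index-1 fixation is
#'   in the ROI.
#' @return A tibble: `participant_id`, `task`, `roi`, `median_latency_ms`,
#'   `n_trials`. ROIs never fixated by a participant produce no row.
#' @export
first_entry_latency <- function(fixations, conditional_on_first = FALSE) {
  stopifnot(all(c("participant_id", "task", "trial_id", "fix_index",
                  "roi", "latency_ms") %in% names(fixations)))
  valid <- dplyr::filter(fixations, !is.na(.data$roi), .data$fix_index >= 1)
  per_trial <- dplyr::summarise(
    dplyr::group_by(valid, .data$participant_id, .data$task,
                    .data$trial_id, .data$roi),
    latency_ms = min(.data$latency_ms),
    first_roi = min(.data$fix_index) == 1,
    .groups = "drop"
  )
  if (conditional_on_first) {
    per_trial <- dplyr::filter(per_trial, .data$first_roi)
  }
  dplyr::summarise(
    dplyr::group_by(per_trial, .data$participant_id, .data$task, .data$roi),
    median_latency_ms = median(.data$latency_ms),
    n_trials = dplyr::n(),
    .groups = "drop"
  )
}

#' Plot the area-normalized fixation course
#'
#' Group-mean normalized score per ROI and fixation bin, one panel per
#' task.
#'
#' @param course Output of [area_normalized_frequency()].
#' @return A ggplot object.
#' @export
plot_fixation_course <- function(course) {
  dat <- dplyr::summarise(
    dplyr::group_by(course, .data$task, .data$roi, .data$fix_bin),
    score = mean(.data$score, na.rm = TRUE), .groups = "drop"
  )
  ggplot2::ggplot(dat, ggplot2::aes(.data$fix_bin, .data$score,
                                    colour = .data$roi, group = .data$roi)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$task)) +
    ggplot2::labs(x = "fixation number", y = "area-normalized fixation frequency (1/px)")
}
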