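#' Thresholds of the six release criteria
#'
#' The defaults are the stationary-phase release definition: the feature's
#' global maximum must not sit in an external-control replicate; the minimum
#' 45-h (last time point) replicate peak area must be at least `noise_ratio`
#' (3) times the control maximum; every time point's replicate CV must stay
#' below `cv_max` (20%); the mean trajectory minimum must be at the first,
#' exponential-phase time point; the last/first log2 fold change must exceed
#' `lfc_min` (1); and the Pearson correlation of abundance with time must be
#' at least `r_min` (0.7).
#'
#' @param noise_ratio Last-time-point minimum over control maximum ratio.
#' @param cv_max Replicate CV bound in percent (strict `<`).
#' @param lfc_min Log2 fold-change bound (strict `>`).
#' @param r_min Pearson correlation bound (`>=`).
#' @return A named list of thresholds.
#' @export
release_thresholds <- function(noise_ratio = 3, cv_max = 20, lfc_min = 1, r_min = 0.7) {
  list(
    noise_ratio = noise_ratio, cv_max = cv_max,
    lfc_min = lfc_min, r_min = r_min
  )
}

#' Individual release criteria
#'
#' Single-feature building blocks of [classify_released()], operating on the
#' peak areas of one feature. `value`, `time_h` and (where present)
#' `is_control` are parallel vectors over the feature's samples in one strain
#' plus the external controls. Conventions, chosen once and fixed:
#' ties between a strain sample and a control at the global maximum fail the
#' control-maximum criterion (conservative); a zero last-time-point minimum
#' fails the noise criterion even against an all-zero control; a zero
#' replicate standard deviation gives CV 0 (a reproducibly absent signal is
#' reproducible); the trajectory-minimum criterion is non-strict (a tie with a
#' later time point still passes); a zero first-time-point mean with positive
#' last-time-point mean gives an infinite log2 fold change and passes; a
#' constant abundance has an undefined correlation and fails.
#'
#' @param value Peak areas.
#' @param time_h Sampling times (hours), strain samples only for `crit_cv`,
#'   `crit_min_first`, `crit_lfc`, `crit_pearson`.
#' @param is_control Logical, `TRUE` for external-control samples.
#' @param thresholds A [release_thresholds()] list.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @name release_criteria
NULL

#' @rdname release_criteria
#' @export
crit_control_max <- function(value, is_control, thresholds = release_thresholds()) {
  if (!any(is_control)) {
    abort_exomet("no external-control samples", "missing_controls")
  }
  max(value[!is_control]) > max(value[is_control])
}

#' @rdname release_criteria
#' @export
crit_noise <- function(value, time_h, is_control, thresholds = release_thresholds()) {
  if (!any(is_control)) {
    abort_exomet("no external-control samples", "missing_controls")
  }
  t_last <- max(time_h[!is_control], na.rm = TRUE)
  at_last <- !is_control & !is.na(time_h) & time_h == t_last
  if (!any(at_last)) {
    abort_exomet("no samples at the last time point", "missing_timepoint")
  }
  min_last <- min(value[at_last])
  min_last > 0 && min_last >= thresholds$noise_ratio * max(value[is_control])
}

#' @rdname release_criteria
#' @export
crit_cv <- function(value, time_h, thresholds = release_thresholds()) {
  cvs <- vapply(
    split(value, time_h),
    function(v) if (length(v) < 2) NA_real_ else cv_percent(v),
    numeric(1)
  )
  all(cvs[!is.na(cvs)] < thresholds$cv_max)
}

#' @rdname release_criteria
#' @export
crit_min_first <- function(value, time_h) {
  means <- vapply(split(value, time_h), mean, numeric(1))
  means[[1]] <= min(means)
}

#' @rdname release_criteria
#' @export
crit_lfc <- function(value, time_h, thresholds = release_thresholds()) {
  lfc <- lfc_value(value, time_h)
  !is.na(lfc) && lfc > thresholds$lfc_min
}

#' @rdname release_criteria
#' @export
crit_pearson <- function(value, time_h, thresholds = release_thresholds()) {
  r <- suppressWarnings(stats::cor(time_h, value))
  !is.na(r) && r >= thresholds$r_min
}

# Log2 fold change of time-point means, last vs first. 0/0 is undefined (NA,
# fails the criterion); x/0 with x > 0 is +Inf (passes).
lfc_value <- function(value, time_h) {
  means <- vapply(split(value, time_h), mean, numeric(1))
  m_first <- means[[1]]
  m_last <- means[[length(means)]]
  if (m_first == 0 && m_last == 0) {
    return(NA_real_)
  }
  log2(m_last / m_first)
}

#' Classify features as released exometabolites for one strain
#'
#' Applies the six release criteria to every feature of a wide feature table,
#' using the strain's samples and the external-control pool of the same
#' table (all control samples across the time series). All six criteria are
#' evaluated for every feature - there is no short-circuiting - so the report
#' doubles as a per-criterion diagnostic. A feature is released iff it passes
#' all six. Results are invariant to row order, to sample-column order and to
#' global positive rescaling of the peak areas.
#'
#' @param features Wide feature tibble.
#' @param meta Sample metadata tibble covering every sample column.
#' @param strain Strain name (a `class` level of `meta`).
#' @param thresholds A [release_thresholds()] list.
#' @param pearson `"replicates"` (default) correlates replicate-level
#'   (time, abundance) pairs; `"means"` correlates time-point means.
#' @return A tibble with one row per feature: `feature_id`, `strain`,
#'   criterion verdicts `c1_control_max` .. `c6_pearson`, the computed
#'   statistics (`control_max`, `strain_max`, `min_last`, `max_cv`, `lfc`,
#'   `pearson_r`), and `released`.
#' @examples
#' sim <- simulate_feature_table(sim_config(n_released = 5, replicate_cv = 0, seed = 3))
#' rep <- classify_released(sim$features, sim$meta, "S1")
#' table(rep$released)
#' @export
classify_released <- function(features, meta, strain,
                              thresholds = release_thresholds(),
                              pearson = c("replicates", "means")) {
  pearson <- match.arg(pearson)
  long <- feature_long(features, meta)
  ctrl <- dplyr::filter(long, .data$class == "external_control")
  if (nrow(ctrl) == 0) {
    abort_exomet("no external-control samples", "missing_controls")
  }
  own <- dplyr::filter(long, .data$class == strain)
  if (nrow(own) == 0) {
    abort_exomet(paste0("no samples for strain ", strain), "unknown_sample")
  }
  tps <- sort(unique(own$time_h))
  if (!max(tps) %in% own$time_h) {
    abort_exomet("no samples at the last time point", "missing_timepoint")
  }

  ctrl_stats <- ctrl |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(control_max = max(.data$value), .groups = "drop")

  by_tp <- own |>
    dplyr::group_by(.data$feature_id, .data$time_h) |>
    dplyr::summarise(
      m = mean(.data$value),
      cv = dplyr::if_else(dplyr::n() >= 2, cv_percent(.data$value), NA_real_),
      .groups = "drop"
    )

  tp_stats <- by_tp |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      m_first = .data$m[.data$time_h == tps[1]],
      m_last = .data$m[.data$time_h == tps[length(tps)]],
      min_mean = min(.data$m),
      max_cv = if (all(is.na(.data$cv))) NA_real_ else max(.data$cv, na.rm = TRUE),
      c3_cv = all(.data$cv[!is.na(.data$cv)] < thresholds$cv_max),
      r_means = suppressWarnings(stats::cor(.data$time_h, .data$m)),
      .groups = "drop"
    )

  own_stats <- own |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      strain_max = max(.data$value),
      min_last = min(.data$value[.data$time_h == tps[length(tps)]]),
      r_reps = suppressWarnings(stats::cor(.data$time_h, .data$value)),
      n_tp = dplyr::n_distinct(.data$time_h),
      .groups = "drop"
    )

  out <- features |>
    dplyr::select("feature_id") |>
    dplyr::left_join(ctrl_stats, by = "feature_id") |>
    dplyr::left_join(tp_stats, by = "feature_id") |>
    dplyr::left_join(own_stats, by = "feature_id") |>
    dplyr::mutate(
      strain = strain,
      lfc = dplyr::if_else(.data$m_first == 0 & .data$m_last == 0,
        NA_real_, log2(.data$m_last / .data$m_first)
      ),
      pearson_r = if (pearson == "replicates") .data$r_reps else .data$r_means,
      c1_control_max = .data$strain_max > .data$control_max,
      c2_noise = .data$min_last > 0 &
        .data$min_last >= thresholds$noise_ratio * .data$control_max,
      c4_min_first = .data$m_first <= .data$min_mean,
      c5_lfc = !is.na(.data$lfc) & .data$lfc > thresholds$lfc_min,
      c6_pearson = .data$n_tp >= 3 & !is.na(.data$pearson_r) &
        .data$pearson_r >= thresholds$r_min,
      released = .data$c1_control_max & .data$c2_noise & .data$c3_cv &
        .data$c4_min_first & .data$c5_lfc & .data$c6_pearson
    ) |>
    dplyr::select(
      "feature_id", "strain",
      "c1_control_max", "c2_noise", "c3_cv", "c4_min_first", "c5_lfc",
      "c6_pearson", "released",
      "control_max", "strain_max", "min_last", "max_cv", "lfc", "pearson_r"
    )
  attr(out, "thresholds") <- thresholds
  attr(out, "pearson") <- pearson
  out
}

#' Released feature ids from a classification report
#'
#' @param report Output of [classify_released()].
#' @return Character vector of released feature ids.
#' @export
released_ids <- function(report) {
  report$feature_id[report$released]
}
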