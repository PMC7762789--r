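#' Simulate an aligned LC-MS feature table with known ground truth
#'
#' Generates one acquisition mode of the monoculture time-course design:
#' strain samples over the configured time points and replicates, medium-only
#' external controls, extraction blanks, spiked internal standards, planted
#' released features and one decoy family per release criterion (see
#' [sim_config()] for the trajectory and decoy constructions). Replicate noise
#' is multiplicative lognormal at the configured coefficient of variation, so
#' peak areas stay nonnegative and the CV target holds across magnitudes.
#'
#' Each planted feature targets a single strain; in all other strains (and in
#' the controls) it sits at the background `control_level`. Identical
#' configurations and seeds yield identical tables.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `exomet_sim` with elements
#'   \describe{
#'     \item{features}{wide feature tibble (`feature_id`, `mz`, `rt`, one
#'       peak-area column per sample).}
#'     \item{meta}{sample metadata tibble (`sample_id`, `class`, `time_h`,
#'       `replicate`, `mode`).}
#'     \item{truth}{ground-truth tibble (`feature_id`, `label`, `strain`);
#'       labels are `released`, the six decoy classes, or `itsd`.}
#'     \item{itsd_ids}{feature ids of the internal standards.}
#'     \item{dropped}{sample ids removed by the dropout option.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' sim <- simulate_feature_table(sim_config(n_released = 5, seed = 42))
#' dim(sim$features)
#' @export
simulate_feature_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed)

  tp <- cfg$time_points_h
  n_tp <- length(tp)
  meta <- sim_sample_meta(cfg)
  strain_meta <- dplyr::filter(meta, !.data$class %in% c("external_control", "extraction_blank"))

  # Registry of planted features: per strain, released then one decoy family
  # per criterion.
  registry <- purrr::map(cfg$strains, function(s) {
    tibble::tibble(
      label = c(
        rep("released", cfg$n_released),
        rep(names(cfg$decoy_counts), cfg$decoy_counts)
      ),
      strain = s
    )
  }) |>
    dplyr::bind_rows()
  registry <- dplyr::bind_rows(
    registry,
    tibble::tibble(
      label = rep("itsd", cfg$n_itsd),
      strain = NA_character_
    )
  )
  n_feat <- nrow(registry)
  registry$feature_id <- sprintf("F%05d", seq_len(n_feat))

  # Expected trajectory (time-point means) for each feature in its target
  # strain.
  x <- (tp - tp[1]) / (tp[n_tp] - tp[1])
  traj <- matrix(0, n_feat, n_tp)
  spread <- matrix(1, n_feat, cfg$n_replicates) # replicate multipliers (D3)
  itsd_level <- stats::runif(n_feat, 2e5, 1e6)
  control_spike <- rep(NA_real_, n_feat) # D1 planted control maximum

  for (i in seq_len(n_feat)) {
    lab <- registry$label[i]
    a <- stats::runif(1, 2000, 8000)
    if (lab %in% c("released", "D1_control_max", "D3_high_cv")) {
      k <- stats::runif(1, 1.5, 3)
      traj[i, ] <- a * 2^(k * x)
    } else if (lab == "D2_below_noise") {
      # 45-h mean at 2x the control level: below the 3x noise threshold but
      # otherwise a clean doubling trajectory.
      traj[i, ] <- (2 * cfg$control_level) * 2^(2 * (x - 1))
    } else if (lab == "D4_min_not_first") {
      k <- stats::runif(1, 2, 3)
      traj[i, ] <- a * 2^(k * x)
      traj[i, 3] <- a / 2 # trajectory minimum moved to the third time point
    } else if (lab == "D5_low_lfc") {
      traj[i, ] <- a * 2^(0.5 * x)
    } else if (lab == "D6_low_pearson") {
      # Rise-then-fall: ends above 2x start (LFC ~ 1.58) yet poorly
      # correlated with time.
      traj[i, ] <- a * c(1, seq(8, 3, length.out = n_tp - 1))
    }
    if (lab == "D1_control_max") {
      control_spike[i] <- 2 * max(traj[i, ])
    }
    if (lab == "D3_high_cv") {
      e <- seq_len(cfg$n_replicates) - (cfg$n_replicates + 1) / 2
      spread[i, ] <- 1 + 0.4 * e / stats::sd(e)
    }
  }

  # Expected value of every (feature, sample) cell.
  mu <- matrix(0, n_feat, nrow(meta), dimnames = list(registry$feature_id, meta$sample_id))
  is_blank <- meta$class == "extraction_blank"
  is_control <- meta$class == "external_control"
  d3_tp <- max(2, n_tp - 2) # time point carrying the inflated spread
  for (i in seq_len(n_feat)) {
    lab <- registry$label[i]
    if (lab == "itsd") {
      mu[i, ] <- itsd_level[i]
      next
    }
    mu[i, !is_blank] <- cfg$control_level
    own <- which(meta$class == registry$strain[i])
    tp_idx <- match(meta$time_h[own], tp)
    mu[i, own] <- traj[i, tp_idx]
    if (lab == "D3_high_cv") {
      at <- own[tp_idx == d3_tp]
      mu[i, at] <- mu[i, at] * spread[i, meta$replicate[at]]
    }
    if (lab == "D1_control_max") {
      target <- which(is_control & meta$time_h == tp[n_tp] & meta$replicate == 1)[1]
      mu[i, target] <- control_spike[i]
    }
  }

  values <- apply_lognormal_noise(
    mu,
    ifelse(registry$label == "itsd", cfg$itsd_cv, cfg$replicate_cv)
  )

  features <- tibble::tibble(
    feature_id = registry$feature_id,
    mz = round(stats::runif(n_feat, 70, 1200), 4),
    rt = round(stats::runif(n_feat, 0.5, 17), 2)
  )
  features <- dplyr::bind_cols(features, tibble::as_tibble(values))

  dropped <- character(0)
  if (cfg$dropout > 0) {
    dropped <- pick_dropout(strain_meta, cfg$dropout)
    features <- dplyr::select(features, -dplyr::all_of(dropped))
    meta <- dplyr::filter(meta, !.data$sample_id %in% dropped)
  }

  structure(
    list(
      features = features,
      meta = meta,
      truth = dplyr::select(registry, "feature_id", "label", "strain"),
      itsd_ids = registry$feature_id[registry$label == "itsd"],
      dropped = dropped,
      config = cfg
    ),
    class = "exomet_sim"
  )
}

sim_sample_meta <- function(cfg) {
  tp <- cfg$time_points_h
  strain_meta <- tidyr::expand_grid(
    class = cfg$strains, time_h = tp, replicate = seq_len(cfg$n_replicates)
  )
  ctrl_meta <- tidyr::expand_grid(
    class = "external_control", time_h = tp, replicate = seq_len(cfg$n_controls)
  )
  blank_meta <- tibble::tibble(
    class = "extraction_blank", time_h = NA_real_,
    replicate = seq_len(cfg$n_blanks)
  )
  meta <- dplyr::bind_rows(strain_meta, ctrl_meta, blank_meta)
  meta$mode <- cfg$mode
  meta$sample_id <- ifelse(
    meta$class == "extraction_blank",
    sprintf("BLANK_R%d", meta$replicate),
    sprintf(
      "%s_T%g_R%d",
      ifelse(meta$class == "external_control", "CTRL", meta$class),
      meta$time_h, meta$replicate
    )
  )
  dplyr::select(meta, "sample_id", "class", "time_h", "replicate", "mode")
}

# Multiplicative lognormal noise with exact mean mu and per-row CV target.
apply_lognormal_noise <- function(mu, cv) {
  out <- mu
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  for (i in seq_len(nrow(mu))) {
    if (cv[i] == 0) next
    sigma <- sqrt(log1p(cv[i]^2))
    out[i, ] <- mu[i, ] * exp(sigma * eps[i, ] - sigma^2 / 2)
  }
  out
}

# Whole-sample dropout: at most one sample per strain/time-point group.
pick_dropout <- function(strain_meta, n_drop) {
  groups <- strain_meta |>
    dplyr::group_by(.data$class, .data$time_h) |>
    dplyr::slice_sample(n = 1) |>
    dplyr::ungroup()
  if (n_drop > nrow(groups)) {
    abort_exomet("dropout exceeds the number of strain/time-point groups",
      "infeasible_config"
    )
  }
  sample(groups$sample_id, n_drop)
}
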