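#' Configuration for the synthetic study-design generator
#'
#' Bundles every knob of the synthetic exometabolomics/transcriptomics
#' generator. The defaults emulate the monoculture study design this package
#' targets: 3 strains followed over an exponential-phase time point (12.5 h)
#' and five stationary-phase time points (25-45 h, every 5 h), with up to 4
#' destructively sampled replicates per time point, medium-only external
#' controls and extraction blanks, and spiked internal standards (ITSDs).
#'
#' Planted "released" features follow a monotone trajectory
#' \eqn{\mu(t) = a \cdot 2^{k (t - t_0)/(t_{last} - t_0)}} with \eqn{k > 1},
#' which guarantees a log2 fold change above 1, a mean minimum at the first
#' time point and a strong positive correlation with time. Each decoy class
#' violates exactly one release criterion:
#' \describe{
#'   \item{D1_control_max}{global peak-area maximum planted in a control
#'     replicate (fails the control-maximum rule; because the noise rule
#'     compares against the same control pool, this decoy necessarily fails
#'     the noise rule too - the two criteria are logically nested).}
#'   \item{D2_below_noise}{trajectory scaled so the 45-h minimum is only twice
#'     the control maximum, below the 3x noise threshold.}
#'   \item{D3_high_cv}{one time point's replicate spread inflated to a 40%
#'     coefficient of variation.}
#'   \item{D4_min_not_first}{trajectory minimum moved to 30 h.}
#'   \item{D5_low_lfc}{exponent chosen so the 45 h / 12.5 h log2 fold change
#'     is 0.5.}
#'   \item{D6_low_pearson}{rise-then-fall trajectory tuned so the Pearson
#'     correlation with time falls below 0.7.}
#' }
#'
#' @param n_strains Number of strains.
#' @param strains Strain names; defaults to `S1`, `S2`, ...
#' @param time_points_h Strictly increasing sampling times in hours.
#' @param n_replicates Replicates per strain and time point.
#' @param n_controls External-control (medium-only) replicates per time point.
#' @param n_blanks Extraction-blank samples.
#' @param n_released Planted true released features per strain.
#' @param decoy_counts Named integer vector over decoy classes `D1_control_max`
#'   .. `D6_low_pearson`; per-strain counts.
#' @param replicate_cv Within-time-point coefficient of variation of the
#'   multiplicative lognormal replicate noise (fraction, e.g. 0.05). Must be
#'   below 0.2: at or above the 20% CV release threshold the high-CV decoy is
#'   indistinguishable from noise and the construction is infeasible.
#' @param control_level Mean background peak area in external-control samples.
#' @param itsd_cv Target coefficient of variation of the ITSD features
#'   (fraction); must be below 0.2.
#' @param n_itsd Number of spiked internal-standard features.
#' @param mode Acquisition mode label stamped on the samples, one of
#'   `"polar_pos"`, `"polar_neg"`, `"nonpolar_pos"`, `"nonpolar_neg"`.
#' @param dropout Number of whole strain samples to drop, emulating failed
#'   injections; at most one per strain/time-point group.
#' @param n_genes Genes in the synthetic count matrix.
#' @param frac_low_expression Fraction of genes drawn from the low-expression
#'   block; at the default 0.25 the 25th-percentile low-expression minimum
#'   falls in the gap between blocks, so planted labels are exactly
#'   recoverable.
#' @param n_transporters Annotated transporter genes.
#' @param n_transporter_below Transporters drawn from the low-expression block.
#' @param n_transporter_de Above-minimum transporters planted as differentially
#'   expressed (Q < 0.01).
#' @param n_transporter_lfc Of the differentially expressed transporters, how
#'   many carry a stationary-phase log2 fold change above 1.
#' @param seed Integer RNG seed; identical configurations with identical seeds
#'   generate identical outputs.
#'
#' @return A `sim_config` list.
#' @seealso [simulate_feature_table()], [simulate_count_table()]
#' @export
sim_config <- function(n_strains = 3,
                       strains = paste0("S", seq_len(n_strains)),
                       time_points_h = c(12.5, 25, 30, 35, 40, 45),
                       n_replicates = 4,
                       n_controls = 4,
                       n_blanks = 4,
                       n_released = 40,
                       decoy_counts = c(
                         D1_control_max = 10, D2_below_noise = 10,
                         D3_high_cv = 10, D4_min_not_first = 10,
                         D5_low_lfc = 10, D6_low_pearson = 10
                       ),
                       replicate_cv = 0.05,
                       control_level = 200,
                       itsd_cv = 0.02,
                       n_itsd = 3,
                       mode = c("polar_pos", "polar_neg", "nonpolar_pos", "nonpolar_neg"),
                       dropout = 0,
                       n_genes = 800,
                       frac_low_expression = 0.25,
                       n_transporters = 20,
                       n_transporter_below = 5,
                       n_transporter_de = 6,
                       n_transporter_lfc = 2,
                       seed = 1) {
  mode <- match.arg(mode)
  decoys <- decoy_classes()
  full <- stats::setNames(rep(0, length(decoys)), decoys)
  if (length(decoy_counts) > 0) {
    bad <- setdiff(names(decoy_counts), decoys)
    if (length(bad) > 0) {
      abort_exomet(paste0("unknown decoy class: ", paste(bad, collapse = ", ")),
        "infeasible_config"
      )
    }
    full[names(decoy_counts)] <- decoy_counts
  }
  cfg <- list(
    n_strains = n_strains, strains = strains, time_points_h = time_points_h,
    n_replicates = n_replicates, n_controls = n_controls, n_blanks = n_blanks,
    n_released = n_released, decoy_counts = full, replicate_cv = replicate_cv,
    control_level = control_level, itsd_cv = itsd_cv, n_itsd = n_itsd,
    mode = mode, dropout = dropout, n_genes = n_genes,
    frac_low_expression = frac_low_expression, n_transporters = n_transporters,
    n_transporter_below = n_transporter_below,
    n_transporter_de = n_transporter_de,
    n_transporter_lfc = n_transporter_lfc, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

decoy_classes <- function() {
  c(
    "D1_control_max", "D2_below_noise", "D3_high_cv",
    "D4_min_not_first", "D5_low_lfc", "D6_low_pearson"
  )
}

validate_sim_config <- function(cfg) {
  tp <- cfg$time_points_h
  if (length(tp) < 2 || any(diff(tp) <= 0)) {
    abort_exomet("time_points_h must be strictly increasing with >= 2 points",
      "infeasible_config"
    )
  }
  counts <- c(
    cfg$n_strains, cfg$n_replicates, cfg$n_controls, cfg$n_blanks,
    cfg$n_released, cfg$decoy_counts, cfg$n_itsd, cfg$dropout,
    cfg$n_genes, cfg$n_transporters, cfg$n_transporter_below,
    cfg$n_transporter_de, cfg$n_transporter_lfc
  )
  if (any(counts < 0)) {
    abort_exomet("all counts must be >= 0", "infeasible_config")
  }
  if (cfg$replicate_cv < 0) {
    abort_exomet("replicate_cv must be >= 0", "infeasible_config")
  }
  if (cfg$replicate_cv >= 0.2) {
    abort_exomet(
      "replicate_cv >= 0.2 makes the high-CV decoy indistinguishable from noise",
      "infeasible_config"
    )
  }
  if (cfg$itsd_cv < 0 || cfg$itsd_cv >= 0.2) {
    abort_exomet("itsd_cv must lie in [0, 0.2)", "infeasible_config")
  }
  if (length(cfg$strains) != cfg$n_strains) {
    abort_exomet("strains must have length n_strains", "infeasible_config")
  }
  if (cfg$decoy_counts[["D3_high_cv"]] > 0 && cfg$n_replicates < 2) {
    abort_exomet("the high-CV decoy needs >= 2 replicates", "infeasible_config")
  }
  if ((cfg$decoy_counts[["D4_min_not_first"]] > 0 ||
    cfg$decoy_counts[["D6_low_pearson"]] > 0) && length(tp) < 4) {
    abort_exomet("trajectory decoys need >= 4 time points", "infeasible_config")
  }
  if (cfg$n_transporter_lfc > cfg$n_transporter_de ||
    cfg$n_transporter_de + cfg$n_transporter_below > cfg$n_transporters) {
    abort_exomet("transporter class counts must nest within n_transporters",
      "infeasible_config"
    )
  }
  invisible(cfg)
}
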