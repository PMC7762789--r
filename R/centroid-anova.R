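#' Bray-Curtis dissimilarity between group centroids
#'
#' Computes the arithmetic mean profile (centroid) of each group in
#' normalized-profile space and reports the Bray-Curtis dissimilarity of each
#' group's centroid to the baseline group's centroid, or - with
#' `stepwise = TRUE` - between consecutive groups. With time-point groups
#' this traces how far the exometabolite composition has moved from the
#' exponential-phase baseline, and how large each successive step is.
#'
#' @param profiles Samples-by-features matrix (see [as_profile_matrix()]).
#' @param groups Group label per sample (e.g. time point); groups are ordered
#'   by `sort(unique(groups))`.
#' @param baseline Baseline group for the non-stepwise variant; defaults to
#'   the first group in sort order.
#' @param stepwise Compare consecutive groups instead of each group to the
#'   baseline.
#' @return A tibble with columns `from`, `to`, `dissimilarity`.
#' @export
centroid_dissimilarity <- function(profiles, groups, baseline = NULL, stepwise = FALSE) {
  m <- as.matrix(profiles)
  lev <- sort(unique(groups))
  counts <- table(factor(groups, levels = lev))
  if (any(counts == 0)) {
    abort_exomet("empty group", "empty_group")
  }
  centroids <- do.call(rbind, lapply(lev, function(g) {
    colMeans(m[groups == g, , drop = FALSE])
  }))
  rownames(centroids) <- as.character(lev)
  dm <- as.matrix(bray_curtis(centroids))
  if (stepwise) {
    idx <- seq_len(length(lev) - 1)
    return(tibble::tibble(
      from = lev[idx], to = lev[idx + 1],
      dissimilarity = unname(dm[cbind(idx, idx + 1)])
    ))
  }
  if (is.null(baseline)) baseline <- lev[1]
  if (!baseline %in% lev) {
    abort_exomet("baseline group not present", "empty_group")
  }
  others <- lev[lev != baseline]
  tibble::tibble(
    from = rep(baseline, length(others)), to = others,
    dissimilarity = unname(dm[as.character(baseline), as.character(others)])
  )
}

#' Per-feature ANOVA across strains with FDR control
#'
#' One-way ANOVA of (normalized) feature abundance across strains at a single
#' time point (by default the last, 45-h point), with Benjamini-Hochberg
#' adjustment across features - the test behind "distinct for each strain"
#' calls on abundant exometabolites. Degenerate features are resolved by
#' convention: no between-group variation gives F = 0, p = 1; between-group
#' variation with zero residual variation gives F = Inf, p = 0.
#'
#' @param features Wide feature tibble (typically normalized).
#' @param meta Sample metadata tibble.
#' @param time_h Time point to test at; default the maximum strain time.
#' @param strains Strains to compare; default every non-control class.
#' @return A tibble: `feature_id`, `statistic`, `p_value`, `q_value`.
#' @export
feature_anova <- function(features, meta, time_h = NULL, strains = NULL) {
  long <- feature_long(features, meta)
  if (is.null(strains)) {
    strains <- setdiff(unique(meta$class), c("external_control", "extraction_blank"))
  }
  long <- dplyr::filter(long, .data$class %in% strains)
  if (is.null(time_h)) time_h <- max(long$time_h, na.rm = TRUE)
  long <- dplyr::filter(long, .data$time_h == !!time_h)
  sizes <- table(long$class[!duplicated(long$sample_id)])
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort_exomet("need >= 2 strains with >= 2 replicates", "degenerate_factor")
  }
  res <- long |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(anova_f_p(.data$value, .data$class), .groups = "drop")
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res
}

anova_f_p <- function(value, group) {
  # degenerate fits (constant features) are resolved by the documented
  # conventions below, so the perfect-fit warning carries no information
  fit <- suppressWarnings(stats::anova(stats::lm(value ~ factor(group))))
  ss_between <- fit$`Sum Sq`[1]
  ss_within <- fit$`Sum Sq`[2]
  if (ss_between <= .Machine$double.eps * sum(value^2 + 1)) {
    return(tibble::tibble(statistic = 0, p_value = 1))
  }
  if (ss_within <= .Machine$double.eps * sum(value^2 + 1)) {
    return(tibble::tibble(statistic = Inf, p_value = 0))
  }
  tibble::tibble(statistic = fit$`F value`[1], p_value = fit$`Pr(>F)`[1])
}
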