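# Internal helpers shared across modules.

# Columns of a wide feature table that hold per-sample peak areas.
sample_cols <- function(tbl) {
  setdiff(names(tbl), c("feature_id", "mz", "rt"))
}

# Percent coefficient of variation with the n-1 standard deviation.
# A zero (or undefined) spread maps to 0: a reproducibly constant signal,
# including one that is reproducibly absent, has no replicate variation.
cv_percent <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(0)
  }
  100 * s / mean(x)
}

# Round half away from zero, the convention behind one-decimal percentages
# such as 18.57 -> 18.6.
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

percent_of <- function(num, den, digits = 1) {
  if (length(den) == 0 || is.na(den) || den == 0) {
    return(NA_real_)
  }
  round_half_up(100 * num / den, digits)
}

abort_exomet <- function(message, class) {
  rlang::abort(message, class = paste0("exomet_", class))
}

#' Sample-by-feature profile matrix from a wide feature table
#'
#' Transposes a wide feature table (features in rows) into the
#' samples-in-rows matrix consumed by [bray_curtis()] and the other
#' composition statistics.
#'
#' @param tbl Wide feature tibble (`feature_id`, `mz`, `rt`, sample columns).
#' @return A numeric matrix, samples in rows and features in columns.
#' @export
as_profile_matrix <- function(tbl) {
  sc <- sample_cols(tbl)
  m <- t(as.matrix(tbl[, sc, drop = FALSE]))
  colnames(m) <- tbl$feature_id
  m
}

# Long view of a wide feature table joined with sample metadata.
feature_long <- function(features, meta) {
  sc <- sample_cols(features)
  missing <- setdiff(sc, meta$sample_id)
  if (length(missing) > 0) {
    abort_exomet(
      paste0("samples absent from metadata: ", paste(missing, collapse = ", ")),
      "unknown_sample"
    )
  }
  features |>
    tidyr::pivot_longer(dplyr::all_of(sc),
      names_to = "sample_id", values_to = "value"
    ) |>
    dplyr::inner_join(meta, by = "sample_id")
}
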