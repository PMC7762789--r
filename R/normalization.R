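#' Select the reference internal standard
#'
#' Among the candidate internal-standard (ITSD) features, returns the one with
#' the lowest percent coefficient of variation across all samples of the
#' table. Candidates with a zero (or missing) peak area in any sample cannot
#' serve as a per-sample divisor and are excluded. Ties are broken by
#' lexicographic feature id. On the real data this selection recovers the
#' spiked amino-acid standards (e.g. labelled proline in polar positive mode)
#' but nothing is hard-coded: the winner is recomputed per table and per
#' mode.
#'
#' @param features Wide feature tibble.
#' @param itsd_ids Candidate ITSD feature ids.
#' @return The selected feature id (character scalar) with the candidate CV
#'   table attached as attribute `candidates`.
#' @export
select_reference_itsd <- function(features, itsd_ids) {
  cand <- dplyr::filter(features, .data$feature_id %in% itsd_ids)
  if (nrow(cand) == 0) {
    abort_exomet("no ITSD candidate present in the table", "no_valid_itsd")
  }
  sc <- sample_cols(cand)
  mat <- as.matrix(cand[, sc, drop = FALSE])
  valid <- apply(mat, 1, function(x) all(!is.na(x) & x > 0))
  if (!any(valid)) {
    abort_exomet("every ITSD candidate has a zero value in some sample", "no_valid_itsd")
  }
  cvs <- tibble::tibble(
    feature_id = cand$feature_id[valid],
    cv = apply(mat[valid, , drop = FALSE], 1, cv_percent)
  ) |>
    dplyr::arrange(.data$cv, .data$feature_id)
  out <- cvs$feature_id[1]
  attr(out, "candidates") <- cvs
  out
}

#' Normalize by the reference internal standard and cube-root transform
#'
#' Divides every feature's peak area by the reference feature's peak area in
#' the same sample, then takes the cube root:
#' \eqn{v_{fs} = (a_{fs} / a_{ref,s})^{1/3}}. Per-sample multiplicative
#' scaling (injection-volume effects) cancels exactly, the reference feature
#' maps to 1 in every sample, and the monotone cube root preserves
#' within-sample rank order while compressing the dynamic range.
#'
#' @param features Wide feature tibble.
#' @param ref_id Reference feature id, e.g. from [select_reference_itsd()].
#' @return A wide tibble of the same shape with transformed values.
#' @export
normalize_features <- function(features, ref_id) {
  idx <- match(ref_id, features$feature_id)
  if (is.na(idx)) {
    abort_exomet(paste0("reference feature not in table: ", ref_id), "invalid_reference")
  }
  sc <- sample_cols(features)
  ref <- as.numeric(features[idx, sc])
  bad <- which(is.na(ref) | ref <= 0)
  if (length(bad) > 0) {
    abort_exomet(
      paste0("reference has a non-positive value in sample ", sc[bad[1]]),
      "invalid_reference"
    )
  }
  out <- features
  out[sc] <- purrr::map2(features[sc], ref, function(col, r) (col / r)^(1 / 3))
  out
}

#' Z-score features across samples
#'
#' Centers and scales every feature (row) with the n-1 standard deviation, as
#' used for Euclidean-distance heat maps of normalized profiles. Constant
#' rows (zero standard deviation) map to all zeros.
#'
#' @param features Wide (typically normalized) feature tibble.
#' @return A wide tibble of Z-scores.
#' @export
zscore_features <- function(features) {
  sc <- sample_cols(features)
  if (length(sc) < 2) {
    abort_exomet("Z-scoring needs >= 2 samples", "parse_error")
  }
  mat <- as.matrix(features[, sc, drop = FALSE])
  mu <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  z <- (mat - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  out <- features
  out[sc] <- tibble::as_tibble(z)
  out
}
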