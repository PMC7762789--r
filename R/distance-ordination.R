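#' Bray-Curtis dissimilarity between sample profiles
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, computed with
#' \pkg{vegan}. Two all-zero profiles are defined to have distance 0.
#'
#' @param profiles Numeric matrix or data frame, samples in rows and features
#'   in columns (see [as_profile_matrix()] to transpose a wide feature
#'   table), all values nonnegative.
#' @return A `dist` object with attribute `metric = "bray-curtis"`.
#' @export
bray_curtis <- function(profiles) {
  m <- as.matrix(profiles)
  if (any(m < 0)) {
    abort_exomet("Bray-Curtis requires nonnegative abundances", "negative_abundance")
  }
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  d[is.nan(d)] <- 0 # all-zero pairs
  attr(d, "metric") <- "bray-curtis"
  d
}

#' Principal-coordinate analysis (classical metric scaling)
#'
#' Gower double-centering of \eqn{-\tfrac{1}{2} D^2} followed by an
#' eigendecomposition. Coordinates are returned for positive-eigenvalue axes
#' only, scaled by the square root of the eigenvalue, so that when the
#' distance matrix is of Euclidean origin the pairwise coordinate distances
#' reproduce it exactly. Negative eigenvalues (metric distortion under
#' semi-metrics such as Bray-Curtis) are reported unaltered - no Lingoes or
#' Cailliez correction is applied - so users can see the distortion.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @return An object of class `exomet_pcoa`: `eigenvalues` (all, descending),
#'   `coordinates` (samples x positive axes, named `Axis1`, `Axis2`, ...),
#'   `prop_explained` (share of the positive eigenvalue sum per axis), and
#'   `n_negative`.
#' @export
pcoa_ord <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  a <- -0.5 * dm^2
  # double-centered Gower matrix: subtract row and column means, add back the
  # grand mean (the second sweep operates on the row-swept matrix, so the
  # grand mean is already restored)
  g <- sweep(a, 1, rowMeans(a))
  g <- sweep(g, 2, colMeans(g))
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- sqrt(.Machine$double.eps) * max(abs(e$values), 1)
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
  dimnames(coords) <- list(rownames(dm), if (length(pos)) paste0("Axis", seq_along(pos)))
  structure(
    list(
      eigenvalues = e$values,
      coordinates = coords,
      prop_explained = e$values[pos] / sum(e$values[pos]),
      n_negative = sum(e$values < -tol)
    ),
    class = "exomet_pcoa"
  )
}

#' @export
print.exomet_pcoa <- function(x, ...) {
  cat(
    "PCoA:", nrow(x$coordinates), "samples,", ncol(x$coordinates),
    "positive axes,", x$n_negative, "negative eigenvalues\n"
  )
  if (ncol(x$coordinates) >= 2) {
    cat(sprintf(
      "Axis1 %.1f%%, Axis2 %.1f%% of positive-eigenvalue variation\n",
      100 * x$prop_explained[1], 100 * x$prop_explained[2]
    ))
  }
  invisible(x)
}

#' Tidy PCoA axes and scores
#'
#' `tidy()` returns one row per positive axis (eigenvalue and proportion
#' explained); `glance()` summarises the decomposition; `pcoa_scores()`
#' returns per-sample coordinates as a tibble for plotting or Protest.
#'
#' @param x An `exomet_pcoa` object.
#' @param ... Unused.
#' @method tidy exomet_pcoa
#' @export
tidy.exomet_pcoa <- function(x, ...) {
  tibble::tibble(
    axis = colnames(x$coordinates),
    eigenvalue = x$eigenvalues[seq_len(ncol(x$coordinates))],
    prop_explained = x$prop_explained
  )
}

#' @rdname tidy.exomet_pcoa
#' @method glance exomet_pcoa
#' @export
glance.exomet_pcoa <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_positive = ncol(x$coordinates),
    n_negative = x$n_negative,
    prop_first_two = sum(x$prop_explained[seq_len(min(2, length(x$prop_explained)))])
  )
}

#' @rdname tidy.exomet_pcoa
#' @param pc An `exomet_pcoa` object.
#' @export
pcoa_scores <- function(pc) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(pc$coordinates)),
    tibble::as_tibble(pc$coordinates)
  )
}

#' Plot a PCoA ordination
#'
#' Scatter plot of the first two principal coordinates, optionally joined
#' with sample metadata for colour (time) and shape (strain) mappings, in the
#' style of longitudinal exometabolite ordination figures.
#'
#' @param object An `exomet_pcoa` object.
#' @param meta Optional metadata tibble with a `sample_id` column.
#' @param colour,shape Optional metadata column names (strings).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot exomet_pcoa
#' @export
autoplot.exomet_pcoa <- function(object, meta = NULL, colour = NULL, shape = NULL, ...) {
  sc <- pcoa_scores(object)
  if (!is.null(meta)) {
    sc <- dplyr::left_join(sc, meta, by = "sample_id")
  }
  mapping <- ggplot2::aes(x = .data$Axis1, y = .data$Axis2)
  if (!is.null(colour)) {
    mapping <- utils::modifyList(mapping, ggplot2::aes(colour = .data[[colour]]))
  }
  if (!is.null(shape)) {
    mapping <- utils::modifyList(mapping, ggplot2::aes(shape = .data[[shape]]))
  }
  ggplot2::ggplot(sc, mapping) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PCoA 1 (%.1f%%)", 100 * object$prop_explained[1]),
      y = sprintf("PCoA 2 (%.1f%%)", 100 * object$prop_explained[2])
    ) +
    ggplot2::theme_minimal()
}
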