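#' Procrustes concordance test (Protest) between two ordinations
#'
#' Superimposes configuration `y` onto `x` by optimal translation, rotation
#' and scaling and reports the scaled residual statistic
#' \eqn{m_{12}^2} (0 for configurations identical up to those
#' transformations, approaching 1 for unrelated ones), the Procrustes
#' correlation \eqn{\sqrt{1 - m_{12}^2}}, and a permutation p value obtained
#' by row-permuting one configuration. Used to ask whether independent
#' replicate time series trace the same temporal trajectory in PCoA space
#' (typically on the first two axes).
#'
#' @param x,y Numeric matrices with matched rows (e.g. time points) and the
#'   same number of columns.
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @return An object of class `exomet_protest` with fields `m12_squared`,
#'   `correlation`, `p_value`, `n_perm`, `seed`.
#' @export
protest_comparison <- function(x, y, n_perm = 999, seed = NULL) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) {
    abort_exomet("configurations must have the same number of rows", "degenerate_configuration")
  }
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  if (qr(xc)$rank == 0 || qr(yc)$rank == 0) {
    abort_exomet("rank-deficient configuration", "degenerate_configuration")
  }
  if (!is.null(seed)) set.seed(seed)
  pr <- suppressMessages(vegan::protest(x, y, permutations = n_perm))
  structure(
    list(
      m12_squared = unname(pr$ss),
      correlation = unname(pr$t0),
      p_value = unname(pr$signif),
      n_perm = pr$permutations,
      seed = seed
    ),
    class = "exomet_protest"
  )
}

#' @export
print.exomet_protest <- function(x, ...) {
  cat(sprintf(
    "Protest: m12^2 = %.4f, correlation = %.4f, p = %.4g (%d permutations)\n",
    x$m12_squared, x$correlation, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @rdname protest_comparison
#' @param x An `exomet_protest` object.
#' @param ... Unused.
#' @method glance exomet_protest
#' @export
glance.exomet_protest <- function(x, ...) {
  tibble::tibble(
    m12_squared = x$m12_squared,
    correlation = x$correlation,
    p_value = x$p_value,
    n_perm = x$n_perm
  )
}
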