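#' Permutation matrices for distance-based tests
#'
#' Builds the permutation set consumed by [permanova()] and
#' [rm_permanova()]: either `n_perm` seeded random permutations, or - with
#' `exact = TRUE` - the complete set of distinct permutations (minus the
#' identity, which the observed statistic accounts for). When `blocks` is
#' given, samples are permuted only within blocks; the exact set is then the
#' Cartesian product of per-block permutations.
#'
#' @param n Number of samples.
#' @param n_perm Number of random permutations (ignored when `exact`).
#' @param seed Optional RNG seed for the random set.
#' @param blocks Optional block labels of length `n` restricting permutation.
#' @param exact Enumerate the full permutation set (capped at 40320 rows).
#' @return An integer matrix, one permutation per row.
#' @export
permutation_matrix <- function(n, n_perm = 999, seed = NULL, blocks = NULL, exact = FALSE) {
  idx_sets <- if (is.null(blocks)) list(seq_len(n)) else split(seq_len(n), blocks)
  if (exact) {
    per_block <- lapply(idx_sets, function(ix) all_permutations(length(ix)))
    total <- prod(vapply(per_block, nrow, numeric(1)))
    if (total > 40320) {
      abort_exomet("exact enumeration capped at 40320 permutations", "infeasible_config")
    }
    pm <- matrix(seq_len(n), 1, n)
    for (b in seq_along(idx_sets)) {
      ix <- idx_sets[[b]]
      blk <- per_block[[b]]
      pm <- pm[rep(seq_len(nrow(pm)), each = nrow(blk)), , drop = FALSE]
      pm[, ix] <- ix[blk[rep(seq_len(nrow(blk)), times = nrow(pm) / nrow(blk)), , drop = FALSE]]
    }
    identity <- apply(pm, 1, function(p) all(p == seq_len(n)))
    return(pm[!identity, , drop = FALSE])
  }
  if (!is.null(seed)) set.seed(seed)
  t(vapply(seq_len(n_perm), function(i) {
    p <- seq_len(n)
    for (ix in idx_sets) p[ix] <- ix[sample.int(length(ix))]
    p
  }, integer(n)))
}

# All permutations of 1..n as rows (n <= 8).
all_permutations <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' PERMANOVA on a distance matrix
#'
#' Distance-based permutational multivariate analysis of variance
#' (McArdle-Anderson partitioning, via \pkg{vegan}'s `adonis2`) with
#' sequential (Type I) sums of squares in the order the terms appear in the
#' formula - for the longitudinal design, `~ strain * time` partitions into
#' strain, time and their interaction. P values use the add-one permutation
#' estimator \eqn{p = (\#\{F^* \ge F\} + 1)/(n_{perm} + 1)} over a seeded
#' random permutation set, or over the complete enumeration when
#' `exact = TRUE`.
#'
#' @param d A `dist` object.
#' @param data Data frame/tibble of sample factors, rows aligned with `d`.
#' @param formula Right-hand-side formula over columns of `data`, e.g.
#'   `~ strain * time`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed for the permutation draw.
#' @param exact Use the full permutation set instead of a random sample.
#' @param blocks Optional block labels restricting permutation.
#' @return An object of class `exomet_permanova`; see [tidy.exomet_permanova()].
#' @examples
#' sim <- simulate_feature_table(sim_config(n_released = 10, seed = 5))
#' norm <- normalize_features(sim$features, select_reference_itsd(sim$features, sim$itsd_ids))
#' keep <- sim$meta$class %in% sim$config$strains
#' d <- bray_curtis(as_profile_matrix(norm)[sim$meta$sample_id[keep], ])
#' fit <- permanova(d, sim$meta[keep, ], ~ class * time_h, n_perm = 99, seed = 1)
#' tidy(fit)
#' @export
permanova <- function(d, data, formula = ~ strain * time, n_perm = 999,
                      seed = NULL, exact = FALSE, blocks = NULL) {
  data <- as.data.frame(data)
  vars <- all.vars(formula)
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0) {
    abort_exomet(paste0("factors not in data: ", paste(missing, collapse = ", ")),
      "degenerate_factor"
    )
  }
  for (v in vars) {
    data[[v]] <- factor(data[[v]])
    if (nlevels(data[[v]]) < 2) {
      abort_exomet(paste0("factor has a single level: ", v), "degenerate_factor")
    }
  }
  n <- attr(d, "Size")
  pm <- permutation_matrix(n, n_perm, seed, blocks, exact)
  f <- stats::as.formula(
    paste("d ~", as.character(formula)[2]),
    env = environment() # `d` is this function's argument
  )
  fit <- vegan::adonis2(f, data = data, permutations = pm, by = "terms")
  structure(
    list(
      table = adonis_to_tibble(fit),
      n_perm = nrow(pm), seed = seed, exact = exact
    ),
    class = "exomet_permanova"
  )
}

adonis_to_tibble <- function(fit) {
  tibble::tibble(
    term = rownames(fit),
    df = fit$Df,
    sum_sq = fit$SumOfSqs,
    r_squared = fit$R2,
    statistic = fit$F,
    p_value = fit[["Pr(>F)"]]
  )
}

#' @export
print.exomet_permanova <- function(x, ...) {
  cat("PERMANOVA (", x$n_perm, if (x$exact) " exact" else " random",
    " permutations)\n",
    sep = ""
  )
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Tidy PERMANOVA results
#'
#' `tidy()` returns the sequential partition, one row per term plus the
#' residual and total rows; `glance()` returns a one-row summary.
#'
#' @param x An `exomet_permanova` object.
#' @param ... Unused.
#' @method tidy exomet_permanova
#' @export
tidy.exomet_permanova <- function(x, ...) {
  x$table
}

#' @rdname tidy.exomet_permanova
#' @method glance exomet_permanova
#' @export
glance.exomet_permanova <- function(x, ...) {
  terms <- dplyr::filter(x$table, !.data$term %in% c("Residual", "Total"))
  tibble::tibble(
    r_squared_model = sum(terms$r_squared),
    n_perm = x$n_perm,
    exact = x$exact,
    p_min = min(terms$p_value, na.rm = TRUE)
  )
}

#' Repeated-measures PERMANOVA over replicated time series
#'
#' Tests the effect of time within independently replicated time series by
#' restricting permutations: time labels are shuffled only within each
#' replicate series (each series acts as a block), respecting the
#' repeated-measures structure. Each series must contain every time point
#' exactly once.
#'
#' @param d A `dist` object over the samples of one strain.
#' @param data Data frame with the series and time columns.
#' @param series,time Column names (strings) identifying the replicate series
#'   and the time point.
#' @inheritParams permanova
#' @return An `exomet_permanova` object.
#' @export
rm_permanova <- function(d, data, series = "series", time = "time",
                         n_perm = 999, seed = NULL, exact = FALSE) {
  data <- as.data.frame(data)
  tab <- table(data[[series]], data[[time]])
  if (any(tab != 1)) {
    abort_exomet("each series must contain every time point exactly once",
      "unbalanced_series"
    )
  }
  permanova(d, data,
    formula = stats::reformulate(time),
    n_perm = n_perm, seed = seed, exact = exact, blocks = data[[series]]
  )
}

#' Pairwise PERMANOVA with FDR adjustment
#'
#' Runs a one-factor PERMANOVA for every pair of groups and adjusts the
#' permutation p values across the pair family with Benjamini-Hochberg,
#' mirroring pairwise Adonis comparisons with Q values.
#'
#' @param d A `dist` object.
#' @param groups Group labels, one per sample of `d`.
#' @inheritParams permanova
#' @return A tibble with one row per pair: `group1`, `group2`, `df`,
#'   `r_squared`, `statistic`, `p_value`, `q_value`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = NULL, exact = FALSE) {
  groups <- as.character(groups)
  dm <- as.matrix(d)
  lev <- unique(groups)
  if (length(lev) < 2) {
    abort_exomet("need >= 2 groups", "degenerate_factor")
  }
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  res <- purrr::imap(pairs, function(pr, i) {
    idx <- which(groups %in% pr)
    sub <- stats::as.dist(dm[idx, idx])
    fit <- permanova(sub, data.frame(g = groups[idx]), ~g,
      n_perm = n_perm,
      seed = if (is.null(seed)) NULL else seed + i, exact = exact
    )
    row <- dplyr::filter(fit$table, .data$term == "g")
    tibble::tibble(
      group1 = pr[1], group2 = pr[2], df = row$df,
      r_squared = row$r_squared, statistic = row$statistic,
      p_value = row$p_value
    )
  }) |>
    dplyr::bind_rows()
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res
}
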