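#' Partition released features across three strains
#'
#' Exact set algebra over the per-strain released feature id sets: the seven
#' disjoint regions of a three-set partition (unique to each strain, each
#' pairwise-only overlap, and the triple overlap), per-strain totals, and the
#' grand total of distinct features. Feature identity across strains is by
#' feature id (the aligned-table key); features from different acquisition
#' modes are never merged. Percentages of the grand total are reported to one
#' decimal, rounded half up.
#'
#' @param sets Named list of exactly three character vectors of released
#'   feature ids, one per strain.
#' @return An object of class `venn_partition`: `regions` (tibble with
#'   `region`, `n`, `pct`), `ids` (named list of the seven disjoint id sets),
#'   `strain_totals` (tibble with `strain`, `n`), and `grand_total`.
#' @examples
#' vp <- venn_partition(list(A = c("f1", "f2"), B = c("f2", "f3"), C = "f4"))
#' vp$regions
#' @export
venn_partition <- function(sets) {
  if (length(sets) != 3 || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort_exomet("sets must be a named list of three id vectors", "parse_error")
  }
  sets <- lapply(sets, unique)
  nm <- names(sets)
  a <- sets[[1]]
  b <- sets[[2]]
  c_ <- sets[[3]]
  ids <- list(
    setdiff(a, union(b, c_)),
    setdiff(b, union(a, c_)),
    setdiff(c_, union(a, b)),
    setdiff(intersect(a, b), c_),
    setdiff(intersect(a, c_), b),
    setdiff(intersect(b, c_), a),
    Reduce(intersect, sets)
  )
  names(ids) <- c(
    nm,
    paste(nm[1], nm[2], sep = "&"), paste(nm[1], nm[3], sep = "&"),
    paste(nm[2], nm[3], sep = "&"), paste(nm, collapse = "&")
  )
  n <- vapply(ids, length, integer(1))
  grand <- sum(n)
  regions <- tibble::tibble(
    region = names(ids), n = unname(n),
    pct = vapply(n, percent_of, numeric(1), den = grand)
  )
  strain_totals <- tibble::tibble(
    strain = nm,
    n = unname(vapply(sets, length, integer(1)))
  )
  structure(
    list(
      regions = regions, ids = ids,
      strain_totals = strain_totals, grand_total = grand
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Released-feature partition:", x$grand_total, "distinct features\n")
  print(as.data.frame(x$regions), row.names = FALSE)
  invisible(x)
}

#' Shared and unique fractions of a released-feature partition
#'
#' Summary fractions over the seven-region partition: the number of features
#' shared by at least two strains, that count as a percentage of the sum of
#' the per-strain unique counts, the triple overlap as a percentage of the
#' shared features, and each strain's unique count as a percentage of the
#' grand total. Fractions with a zero denominator are reported as `NA` rather
#' than raising an error.
#'
#' @param p A [venn_partition()].
#' @return A tibble with columns `metric` and `value` (counts, and
#'   percentages rounded half up to one decimal).
#' @export
shared_fraction <- function(p) {
  stopifnot(inherits(p, "venn_partition"))
  n <- stats::setNames(p$regions$n, p$regions$region)
  nm <- p$strain_totals$strain
  uniques <- n[nm]
  shared_ge2 <- sum(n) - sum(uniques)
  triple <- n[[length(n)]]
  tibble::tibble(
    metric = c(
      "shared_ge2", "shared_ge2_pct", "triple_of_shared_pct",
      paste0("unique_pct_", nm)
    ),
    value = unname(c(
      shared_ge2,
      percent_of(shared_ge2, sum(uniques)),
      percent_of(triple, shared_ge2),
      vapply(uniques, percent_of, numeric(1), den = p$grand_total)
    ))
  )
}

#' Summarise identification levels of released features
#'
#' Attaches Metabolomics Standards Initiative (MSI) identification levels to
#' released features from an annotation table: level 1 (identified against an
#' authentic standard), level 2 (putative MS/MS match), level 3
#' (compound-class ontology only). Released features without an annotation
#' are `unidentified`. The identified fraction counts levels 1 and 2 only.
#'
#' @param released Character vector of released feature ids.
#' @param annotation Optional tibble with columns `feature_id` and
#'   `msi_level` (values in 1:3); annotations for unknown ids are dropped
#'   with a warning.
#' @return A list of class `identification_summary`: `counts` (tibble with
#'   `msi_level` in `"1"`, `"2"`, `"3"`, `"unidentified"` and `n`),
#'   `n_released`, `n_identified` (levels 1-2) and `identified_pct`
#'   (percentage, one decimal).
#' @export
identification_summary <- function(released, annotation = NULL) {
  released <- unique(released)
  level <- rep("unidentified", length(released))
  names(level) <- released
  if (!is.null(annotation) && nrow(annotation) > 0) {
    if (!all(annotation$msi_level %in% 1:3)) {
      abort_exomet("msi_level must be 1, 2 or 3", "parse_error")
    }
    unknown <- setdiff(annotation$feature_id, released)
    if (length(unknown) > 0) {
      rlang::warn(paste0(
        length(unknown), " annotation(s) for ids not in the released set ignored"
      ))
      annotation <- dplyr::filter(annotation, .data$feature_id %in% released)
    }
    level[annotation$feature_id] <- as.character(annotation$msi_level)
  }
  counts <- tibble::tibble(
    msi_level = c("1", "2", "3", "unidentified"),
    n = unname(vapply(
      c("1", "2", "3", "unidentified"),
      function(l) sum(level == l), integer(1)
    ))
  )
  n_ident <- sum(counts$n[counts$msi_level %in% c("1", "2")])
  structure(
    list(
      counts = counts,
      n_released = length(released),
      n_identified = n_ident,
      identified_pct = percent_of(n_ident, length(released))
    ),
    class = "identification_summary"
  )
}

#' @export
print.identification_summary <- function(x, ...) {
  cat(
    x$n_identified, "of", x$n_released, "released features identified (",
    x$identified_pct, "%)\n"
  )
  print(as.data.frame(x$counts), row.names = FALSE)
  invisible(x)
}
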