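#' Quality-filter a gene count matrix
#'
#' Two rules, applied in order: genes with zero counts in every sample are
#' removed, then genes with a count of 10 or less in strictly more than 90%
#' of samples are removed. Idempotent.
#'
#' @param counts Tibble with a `gene_id` column and one integer count column
#'   per sample.
#' @return The filtered tibble.
#' @export
filter_genes <- function(counts) {
  sc <- setdiff(names(counts), "gene_id")
  mat <- as.matrix(counts[, sc, drop = FALSE])
  keep <- rowSums(mat) > 0
  keep <- keep & (rowSums(mat <= 10) <= 0.9 * ncol(mat))
  counts[keep, , drop = FALSE]
}

#' Low-expression minimum from per-gene mean counts
#'
#' Summarises each gene by its mean count across samples and takes the 25th
#' percentile (linear-interpolation quantile) of those summaries as the
#' low-expression minimum (LEM): the transcript count below which a gene is
#' considered not expressed regardless of longitudinal differential
#' expression. A gene is above the minimum iff its mean count is strictly
#' greater than the LEM, which makes the flag monotone in the mean count.
#'
#' @param counts Tibble with `gene_id` plus count columns (usually the output
#'   of [filter_genes()]); at least 4 genes.
#' @return A list of class `lem_result`: `lem` (the threshold) and `genes`
#'   (tibble with `gene_id`, `mean_count`, `above_lem`).
#' @examples
#' counts <- tibble::tibble(gene_id = paste0("g", 1:4), s1 = 1:4, s2 = 1:4)
#' compute_lem(counts)$lem # 1.75
#' @export
compute_lem <- function(counts) {
  if (nrow(counts) < 4) {
    abort_exomet("need >= 4 genes to place a quartile threshold", "infeasible_config")
  }
  sc <- setdiff(names(counts), "gene_id")
  means <- rowMeans(as.matrix(counts[, sc, drop = FALSE]))
  lem <- stats::quantile(means, 0.25, names = FALSE)
  structure(
    list(
      lem = lem,
      genes = tibble::tibble(
        gene_id = counts$gene_id,
        mean_count = unname(means),
        above_lem = means > lem
      )
    ),
    class = "lem_result"
  )
}

#' @export
print.lem_result <- function(x, ...) {
  cat(sprintf(
    "Low-expression minimum: %.3f (%d of %d genes above)\n",
    x$lem, sum(x$genes$above_lem), nrow(x$genes)
  ))
  invisible(x)
}

#' Nested transporter expression classification
#'
#' Classifies annotated transporter genes by three nested criteria: (i)
#' above the low-expression minimum, (ii) additionally differentially
#' expressed (Q < 0.01 at any time point), and (iii) additionally carrying a
#' stationary-phase log2 fold change above 1. Also reports the below-minimum
#' count. Transporter ids absent from the count table are dropped with a
#' warning; an above-minimum transporter without a row in the DE table
#' counts as not differentially expressed, with a warning.
#'
#' @param lem A [compute_lem()] result.
#' @param de DE results tibble: `gene_id`, `q` (FDR-adjusted p), and one
#'   `lfc_<t>h` column per stationary time point.
#' @param transporter_ids Annotated transporter gene ids.
#' @param q_max DE threshold on `q` (strict `<`).
#' @param lfc_min Fold-change threshold (strict `>`) on any stationary LFC.
#' @return A one-row tibble: `total`, `above_lem`, `above_lem_de`,
#'   `above_lem_de_lfc`, `below_lem`. The nesting
#'   `total >= above_lem >= above_lem_de >= above_lem_de_lfc` and
#'   `above_lem + below_lem = total` hold by construction and are asserted.
#' @export
classify_transporters <- function(lem, de, transporter_ids, q_max = 0.01, lfc_min = 1) {
  stopifnot(inherits(lem, "lem_result"))
  transporter_ids <- unique(transporter_ids)
  missing <- setdiff(transporter_ids, lem$genes$gene_id)
  if (length(missing) > 0) {
    rlang::warn(paste0(
      length(missing), " transporter id(s) not in the count table dropped"
    ))
    transporter_ids <- setdiff(transporter_ids, missing)
  }
  genes <- dplyr::filter(lem$genes, .data$gene_id %in% transporter_ids)
  above <- genes$gene_id[genes$above_lem]

  lfc_cols <- grep("^lfc_", names(de), value = TRUE)
  if (length(lfc_cols) == 0) {
    abort_exomet("DE table has no lfc_<t>h columns", "parse_error")
  }
  no_de <- setdiff(above, de$gene_id)
  if (length(no_de) > 0) {
    rlang::warn(paste0(
      length(no_de), " above-minimum transporter(s) missing from the DE table",
      " counted as not differentially expressed"
    ))
  }
  de_sub <- dplyr::filter(de, .data$gene_id %in% above)
  is_de <- de_sub$gene_id[de_sub$q < q_max]
  lfc_hit <- apply(
    as.matrix(de_sub[, lfc_cols, drop = FALSE]) > lfc_min, 1,
    any,
    na.rm = TRUE
  )
  is_lfc <- intersect(de_sub$gene_id[lfc_hit], is_de)

  out <- tibble::tibble(
    total = length(transporter_ids),
    above_lem = length(above),
    above_lem_de = length(is_de),
    above_lem_de_lfc = length(is_lfc),
    below_lem = length(transporter_ids) - length(above)
  )
  stopifnot(
    out$total >= out$above_lem,
    out$above_lem >= out$above_lem_de,
    out$above_lem_de >= out$above_lem_de_lfc,
    out$above_lem + out$below_lem == out$total
  )
  out
}
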