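#' Read a wide feature table
#'
#' Parses an aligned feature export: columns `feature_id`, `mz`, `rt`, then
#' one peak-area column per sample. Empty cells are non-detections and become
#' zero. The delimiter is chosen from the file extension (`.tsv`/`.txt` are
#' tab-separated, everything else comma-separated) unless `dialect` overrides
#' it.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"csv"` or `"tsv"`.
#' @return A wide feature tibble.
#' @export
read_feature_table <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  delim <- io_delim(path, dialect)
  tbl <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(tbl))) {
    abort_exomet("feature table must have feature_id, mz and rt columns", "parse_error")
  }
  if (anyDuplicated(tbl$feature_id)) {
    dup <- unique(tbl$feature_id[duplicated(tbl$feature_id)])
    abort_exomet(paste0("duplicate feature ids: ", paste(dup, collapse = ", ")),
      "duplicate_id"
    )
  }
  for (col in setdiff(names(tbl), "feature_id")) {
    raw <- tbl[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & trimws(raw) != "")
    if (length(bad) > 0) {
      abort_exomet(
        sprintf("non-numeric value '%s' at row %d, column '%s'", raw[bad[1]], bad[1], col),
        "parse_error"
      )
    }
    if (!col %in% c("mz", "rt")) num[is.na(num)] <- 0
    tbl[[col]] <- num
  }
  tbl
}

#' Write a wide feature table
#'
#' Counterpart of [read_feature_table()]; round-trips losslessly.
#'
#' @param tbl Wide feature tibble.
#' @inheritParams read_feature_table
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tbl, path, dialect = c("auto", "csv", "tsv")) {
  delim <- io_delim(path, match.arg(dialect))
  readr::write_delim(tbl, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Sample metadata has columns `sample_id`, `class` (a strain name,
#' `external_control` or `extraction_blank`), `time_h`, `replicate` and
#' `mode`.
#'
#' @inheritParams read_feature_table
#' @return A metadata tibble.
#' @export
read_sample_meta <- function(path, dialect = c("auto", "csv", "tsv")) {
  delim <- io_delim(path, match.arg(dialect))
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      sample_id = readr::col_character(), class = readr::col_character(),
      time_h = readr::col_double(), replicate = readr::col_integer(),
      mode = readr::col_character()
    )
  )
}

#' @rdname read_sample_meta
#' @param meta Metadata tibble.
#' @export
write_sample_meta <- function(meta, path, dialect = c("auto", "csv", "tsv")) {
  delim <- io_delim(path, match.arg(dialect))
  readr::write_delim(meta, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a plain id list (one id per line)
#'
#' Used for internal-standard feature lists and transporter gene lists.
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids[nzchar(trimws(ids))]
}

io_delim <- function(path, dialect) {
  if (dialect == "csv") {
    return(",")
  }
  if (dialect == "tsv") {
    return("\t")
  }
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Replicate-reproducibility QC
#'
#' For every sample, computes the Pearson correlation between its feature
#' vector and the mean feature vector of the other replicates in its
#' (`class`, `time_h`, `mode`) group, and flags samples at or below the
#' threshold. The default threshold of r = 0.14 reproduces the intragroup
#' reproducibility cut used for sample removal in stationary-phase
#' exometabolomics QC. Singleton groups have no co-replicates: they are
#' skipped with a warning and never flagged.
#'
#' @param features Wide feature tibble.
#' @param meta Sample metadata tibble.
#' @param threshold Flag a sample when its intragroup r is `<= threshold`.
#' @return A tibble with one row per sample present in `features`:
#'   `sample_id`, `class`, `time_h`, `mode`, `r`, `flagged`; the numbers of
#'   retained and flagged samples are attached as attributes `retained` and
#'   `removed`.
#' @export
replicate_qc <- function(features, meta, threshold = 0.14) {
  sc <- sample_cols(features)
  meta_use <- dplyr::filter(meta, .data$sample_id %in% sc)
  mat <- as.matrix(features[, sc, drop = FALSE])
  groups <- split(
    meta_use$sample_id,
    interaction(meta_use$class, meta_use$time_h, meta_use$mode, drop = TRUE)
  )
  res <- purrr::map(groups, function(ids) {
    if (length(ids) < 2) {
      rlang::warn(paste0("singleton replicate group skipped: ", ids))
      return(tibble::tibble(sample_id = ids, r = NA_real_, flagged = FALSE))
    }
    r <- vapply(ids, function(id) {
      others <- setdiff(ids, id)
      suppressWarnings(stats::cor(mat[, id], rowMeans(mat[, others, drop = FALSE])))
    }, numeric(1))
    tibble::tibble(sample_id = ids, r = unname(r), flagged = !is.na(r) & r <= threshold)
  }) |>
    dplyr::bind_rows()
  out <- meta_use |>
    dplyr::select("sample_id", "class", "time_h", "mode") |>
    dplyr::inner_join(res, by = "sample_id")
  attr(out, "removed") <- sum(out$flagged)
  attr(out, "retained") <- nrow(out) - sum(out$flagged)
  out
}

#' Sample accounting against the factorial design
#'
#' The designed sample number is the product of the distinct strain, time
#' point, replicate and mode counts among the strain samples in `meta`; the
#' retained number subtracts the removed samples. With the full 3-strain,
#' 6-time-point, 4-replicate, 4-mode design and 31 removals this reproduces
#' the 288 designed / 257 retained accounting of the monoculture study
#' design.
#'
#' @param meta Sample metadata tibble (controls and blanks are ignored for
#'   the design count).
#' @param removed_ids Sample ids removed by QC or failed injection.
#' @return A one-row tibble: `designed`, `removed`, `retained`.
#' @export
sample_accounting <- function(meta, removed_ids = character(0)) {
  removed_ids <- unique(removed_ids)
  unknown <- setdiff(removed_ids, meta$sample_id)
  if (length(unknown) > 0) {
    abort_exomet(paste0("removed ids not in metadata: ", paste(unknown, collapse = ", ")),
      "unknown_sample"
    )
  }
  strain_meta <- dplyr::filter(
    meta, !.data$class %in% c("external_control", "extraction_blank")
  )
  designed <- dplyr::n_distinct(strain_meta$class) *
    dplyr::n_distinct(strain_meta$time_h) *
    dplyr::n_distinct(strain_meta$replicate) *
    dplyr::n_distinct(strain_meta$mode)
  tibble::tibble(
    designed = designed,
    removed = length(removed_ids),
    retained = designed - length(removed_ids)
  )
}
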