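#' Simulate a gene count matrix, DE table and transporter list
#'
#' Generates, for one strain, a negative-binomial-like RNA-seq count matrix
#' over the configured time points and replicates, a fabricated
#' differential-expression results table (FDR-adjusted Q values and per
#' stationary-time-point log2 fold changes versus the first, exponential-phase
#' time point), and an annotated transporter id list with planted class
#' membership. Gene means are drawn from two well-separated blocks - a
#' low-expression block (fraction `frac_low_expression` of genes, means 12-30)
#' and an expressed block (means 200-2000) - so the 25th-percentile
#' low-expression minimum computed downstream falls between them when the low
#' fraction is 25%. Ground-truth `below_LEM` labels record the quartile rule
#' applied to the noiseless per-gene means, so planted labels are exactly
#' recoverable at zero noise for any low-block size.
#'
#' When `cfg$replicate_cv` is zero, counts are the rounded expected values
#' (deterministic); otherwise counts are negative binomial with dispersion
#' matched to the configured CV.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `exomet_sim_counts` with elements `counts` (tibble:
#'   `gene_id` plus one column per sample), `de` (tibble: `gene_id`, `q`, one
#'   `lfc_<t>h` column per stationary time point), `transporter_ids`, `truth`
#'   (tibble: `gene_id`, `label` in `expressed`, `below_LEM`,
#'   `DE_transporter`, `stable_transporter`), and `config`.
#' @examples
#' simc <- simulate_count_table(sim_config(n_genes = 100, seed = 7))
#' head(simc$de)
#' @export
simulate_count_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)

  n <- cfg$n_genes
  n_low <- round(cfg$frac_low_expression * n)
  if (n < 4 || n_low < cfg$n_transporter_below ||
    (n - n_low) < (cfg$n_transporters - cfg$n_transporter_below)) {
    abort_exomet("gene blocks too small for the requested transporter classes",
      "infeasible_config"
    )
  }

  gene_id <- sprintf("g%05d", seq_len(n))
  low <- sample(n, n_low)
  mu <- numeric(n)
  mu[low] <- stats::runif(n_low, 12, 30)
  mu[-low] <- stats::runif(n - n_low, 200, 2000)

  tp <- cfg$time_points_h
  samples <- tidyr::expand_grid(time_h = tp, replicate = seq_len(cfg$n_replicates))
  sample_id <- sprintf("T%g_R%d", samples$time_h, samples$replicate)
  n_s <- nrow(samples)

  if (cfg$replicate_cv == 0) {
    counts <- matrix(rep(round(mu), n_s), n, n_s)
  } else {
    size <- 1 / cfg$replicate_cv^2
    counts <- matrix(
      stats::rnbinom(n * n_s, mu = rep(mu, n_s), size = size), n, n_s
    )
  }
  dimnames(counts) <- list(gene_id, sample_id)

  # Ground-truth low-expression label: quartile rule on the noiseless means
  # (rounded, as emitted at zero noise).
  lem0 <- stats::quantile(round(mu), 0.25, names = FALSE)
  below <- round(mu) <= lem0

  # Transporters: planted below-minimum members come from the low block,
  # everything else from the expressed block.
  t_below <- sample(gene_id[below], cfg$n_transporter_below)
  t_above <- sample(gene_id[!below], cfg$n_transporters - cfg$n_transporter_below)
  transporter_ids <- c(t_below, t_above)
  t_de <- sample(t_above, cfg$n_transporter_de)
  t_lfc <- sample(t_de, cfg$n_transporter_lfc)

  stat_tp <- tp[-1]
  q <- stats::runif(n, 0.05, 1)
  lfc <- matrix(stats::runif(n * length(stat_tp), -0.5, 0.5), n, length(stat_tp))
  rownames(lfc) <- gene_id
  q[gene_id %in% t_de] <- stats::runif(length(t_de), 0, 0.009)
  for (g in t_lfc) {
    lfc[g, sample(length(stat_tp), 1)] <- stats::runif(1, 1.5, 3)
  }
  colnames(lfc) <- sprintf("lfc_%gh", stat_tp)
  de <- dplyr::bind_cols(
    tibble::tibble(gene_id = gene_id, q = q),
    tibble::as_tibble(lfc, .name_repair = "minimal")
  )

  label <- ifelse(below, "below_LEM", "expressed")
  label[gene_id %in% t_de] <- "DE_transporter"
  label[gene_id %in% setdiff(t_above, t_de)] <- "stable_transporter"

  structure(
    list(
      counts = dplyr::bind_cols(
        tibble::tibble(gene_id = gene_id), tibble::as_tibble(counts)
      ),
      de = de,
      transporter_ids = transporter_ids,
      truth = tibble::tibble(gene_id = gene_id, label = label),
      config = cfg
    ),
    class = "exomet_sim_counts"
  )
}
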