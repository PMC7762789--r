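# Small in-code fixtures shared across test files.

# Wide feature table + metadata from an explicit feature-by-sample value
# matrix for one strain plus controls.
toy_design <- function(values, time_h, class, replicate = NULL) {
  n_s <- ncol(values)
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_len(n_s), class, time_h, FUN = seq_along)
  }
  sample_id <- sprintf("smp%02d", seq_len(n_s))
  features <- tibble::tibble(
    feature_id = sprintf("f%03d", seq_len(nrow(values))),
    mz = 100 + seq_len(nrow(values)),
    rt = 1 + seq_len(nrow(values)) / 10
  )
  colnames(values) <- sample_id
  features <- dplyr::bind_cols(features, tibble::as_tibble(values))
  meta <- tibble::tibble(
    sample_id = sample_id, class = class, time_h = time_h,
    replicate = as.integer(replicate), mode = "polar_pos"
  )
  list(features = features, meta = meta)
}

# Single-feature design: one row over strain samples (2 replicates per time
# point by default) plus control samples.
one_feature <- function(strain_means, times = c(12.5, 25, 30, 35, 40, 45),
                        reps = 2, control = c(100, 100)) {
  v <- rep(strain_means, each = reps)
  toy_design(
    matrix(c(v, control), nrow = 1),
    time_h = c(rep(times, each = reps), rep(45, length(control))),
    class = c(rep("ST", length(v)), rep("external_control", length(control)))
  )
}

# The published three-strain partition region counts, reconstructed as id
# sets: 4327/1922/2609 unique, 367/333/605 pairwise-only, 189 in all three.
table2_sets <- function() {
  u_bt <- sprintf("bt%04d", 1:4327)
  u_cv <- sprintf("cv%04d", 1:1922)
  u_ps <- sprintf("ps%04d", 1:2609)
  bt_cv <- sprintf("btcv%03d", 1:367)
  bt_ps <- sprintf("btps%03d", 1:333)
  cv_ps <- sprintf("cvps%03d", 1:605)
  all3 <- sprintf("all%03d", 1:189)
  list(
    Bt = c(u_bt, bt_cv, bt_ps, all3),
    Cv = c(u_cv, bt_cv, cv_ps, all3),
    Ps = c(u_ps, bt_ps, cv_ps, all3)
  )
}

# Saturating (decelerating) per-feature trajectories: profiles whose distance
# from the first time point grows while successive steps shrink.
saturating_profiles <- function(n_feat = 20, times = c(12.5, 25, 30, 35, 40, 45),
                                reps = 2, seed = 99) {
  set.seed(seed)
  amp <- runif(n_feat, 1, 5)
  tau <- runif(n_feat, 5, 15)
  rows <- list()
  groups <- numeric(0)
  for (t in times) {
    level <- 0.2 + amp * (1 - exp(-(t - times[1]) / tau))
    for (r in seq_len(reps)) {
      rows[[length(rows) + 1]] <- level
      groups <- c(groups, t)
    }
  }
  list(profiles = do.call(rbind, rows), groups = groups)
}
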