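# Independent brute-force evaluators, base R only. These deliberately avoid
# the package's vectorized code paths (and vegan) so that agreement between
# the two routes is informative.

oracle_release <- function(features, meta, strain,
                           noise_ratio = 3, cv_max = 20, lfc_min = 1, r_min = 0.7) {
  sc <- setdiff(names(features), c("feature_id", "mz", "rt"))
  meta <- as.data.frame(meta)
  ctrl_ids <- meta$sample_id[meta$class == "external_control"]
  own_ids <- intersect(meta$sample_id[meta$class == strain], sc)
  tt <- meta$time_h[match(own_ids, meta$sample_id)]
  tps <- sort(unique(tt))
  t_last <- tps[length(tps)]
  n <- nrow(features)
  out <- data.frame(
    feature_id = features$feature_id,
    c1 = logical(n), c2 = logical(n), c3 = logical(n),
    c4 = logical(n), c5 = logical(n), c6 = logical(n)
  )
  for (i in seq_len(n)) {
    v_ctrl <- as.numeric(features[i, ctrl_ids])
    v_own <- as.numeric(features[i, own_ids])
    cmax <- max(v_ctrl)
    means <- sapply(tps, function(t) mean(v_own[tt == t]))
    cvs <- sapply(tps, function(t) {
      v <- v_own[tt == t]
      if (length(v) < 2) {
        return(NA_real_)
      }
      s <- sd(v)
      if (s == 0) 0 else 100 * s / mean(v)
    })
    min_last <- min(v_own[tt == t_last])
    out$c1[i] <- max(v_own) > cmax
    out$c2[i] <- min_last > 0 && min_last >= noise_ratio * cmax
    out$c3[i] <- all(cvs[!is.na(cvs)] < cv_max)
    out$c4[i] <- means[1] <= min(means)
    lfc <- if (means[1] == 0 && means[length(means)] == 0) {
      NA_real_
    } else {
      log2(means[length(means)] / means[1])
    }
    out$c5[i] <- !is.na(lfc) && lfc > lfc_min
    r <- suppressWarnings(cor(tt, v_own))
    out$c6[i] <- length(tps) >= 3 && !is.na(r) && r >= r_min
  }
  out$released <- out$c1 & out$c2 & out$c3 & out$c4 & out$c5 & out$c6
  out
}

# One-factor distance-based pseudo-F from the direct within/between sum of
# squared distances formulas.
oracle_pseudo_f <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  ss_total <- sum(dm[lower.tri(dm)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dm[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  a <- length(unique(groups))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# Exact one-factor PERMANOVA p value by enumerating every relabeling
# (identity included), using the add-one-free exhaustive convention
# p = #{F* >= F_obs} / N.
oracle_exact_p <- function(d, groups, perms) {
  ident <- apply(perms, 1, function(p) all(p == seq_along(groups)))
  perms <- perms[!ident, , drop = FALSE]
  f_obs <- oracle_pseudo_f(d, groups)
  f_all <- apply(perms, 1, function(p) oracle_pseudo_f(d, groups[p]))
  mean(c(f_all, f_obs) >= f_obs - 1e-12)
}

oracle_bc <- function(x, y) {
  if (sum(x + y) == 0) {
    return(0)
  }
  sum(abs(x - y)) / sum(x + y)
}

# Closed-form symmetric Procrustes residual m12^2 via SVD of the
# cross-product of the centered, unit-norm configurations.
oracle_m12sq <- function(x, y) {
  xc <- scale(as.matrix(x), scale = FALSE)
  yc <- scale(as.matrix(y), scale = FALSE)
  xc <- xc / sqrt(sum(xc^2))
  yc <- yc / sqrt(sum(yc^2))
  1 - sum(svd(crossprod(xc, yc))$d)^2
}

# Base enumeration of all permutations of 1..n (rows), independent of the
# package's builder.
oracle_all_perms <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- oracle_all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  out
}
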