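test_that("Bray-Curtis matches the direct formula and stated conventions", {
  m <- rbind(
    a = c(1, 2, 0), b = c(0, 2, 2), c = c(1, 2, 0),
    d = c(5, 0, 0), e = c(0, 3, 1), z1 = c(0, 0, 0), z2 = c(0, 0, 0)
  )
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 3 / 7)
  expect_equal(d["a", "c"], 0) # identical profiles
  expect_equal(d["d", "e"], 1) # disjoint supports
  expect_equal(d["z1", "z2"], 0) # all-zero convention
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(diag(d)), rep(0, nrow(m)))
  # random profiles agree with the scalar oracle
  set.seed(71)
  r <- matrix(rexp(40), 5, 8)
  dr <- as.matrix(bray_curtis(r))
  for (i in 1:4) {
    for (j in (i + 1):5) expect_equal(dr[i, j], oracle_bc(r[i, ], r[j, ]))
  }
  expect_error(bray_curtis(rbind(c(-1, 2), c(0, 1))), class = "exomet_negative_abundance")
})

test_that("PCoA reconstructs distances of Euclidean origin", {
  # collinear 1-D points: a single positive axis recovering the distances
  pc1 <- pcoa_ord(dist(c(0, 3, 5)))
  expect_equal(ncol(pc1$coordinates), 1)
  expect_equal(sort(as.numeric(dist(pc1$coordinates))), c(2, 3, 5))

  set.seed(72)
  x <- matrix(rnorm(30), 10, 3)
  d <- dist(x)
  pc <- pcoa_ord(d)
  expect_lt(max(abs(dist(pc$coordinates) - d)), 1e-9)
  expect_equal(pc$n_negative, 0)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9)) # descending
  expect_equal(sum(pc$prop_explained), 1)

  # degenerate all-zero distances: no positive axes
  d0 <- as.dist(matrix(0, 4, 4))
  pc0 <- pcoa_ord(d0)
  expect_equal(ncol(pc0$coordinates), 0)
  expect_equal(max(abs(pc0$eigenvalues)), 0, tolerance = 1e-12)
})

test_that("PCoA on Bray-Curtis reports negative eigenvalues rather than correcting them", {
  set.seed(73)
  m <- matrix(rexp(60), 10, 6)
  pc <- pcoa_ord(bray_curtis(m))
  expect_gt(pc$n_negative, 0)
  expect_true(any(pc$eigenvalues < 0))
})

test_that("PERMANOVA decomposes the total sum of squares exactly", {
  sim <- simulate_feature_table(sim_config(n_released = 8, seed = 74))
  norm <- normalize_features(sim$features, select_reference_itsd(sim$features, sim$itsd_ids))
  keep <- sim$meta$class %in% sim$config$strains & sim$meta$time_h %in% c(12.5, 45)
  ids <- sim$meta$sample_id[keep]
  d <- bray_curtis(as_profile_matrix(norm)[ids, ])
  fit <- permanova(d, sim$meta[keep, ], ~ class * time_h, n_perm = 49, seed = 1)
  tab <- tidy(fit)
  terms <- tab$sum_sq[!tab$term %in% "Total"]
  expect_equal(sum(terms), tab$sum_sq[tab$term == "Total"], tolerance = 1e-10)
  expect_equal(sum(tab$r_squared[!tab$term %in% "Total"]), 1, tolerance = 1e-10)
  expect_true(all(tab$r_squared >= 0 & tab$r_squared <= 1))
  # strain x time interaction present in the sequential partition
  expect_true("class:time_h" %in% tab$term)
})

test_that("exact PERMANOVA p values equal full-enumeration oracle values", {
  set.seed(75)
  prof <- rbind(
    matrix(rexp(12, 1 / 2), 3),
    matrix(rexp(12, 1 / 40), 3)
  )
  d <- bray_curtis(prof)
  g <- rep(c("A", "B"), each = 3)
  fit <- permanova(d, data.frame(g = g), ~g, exact = TRUE)
  expect_equal(fit$n_perm, factorial(6) - 1)
  p_oracle <- oracle_exact_p(d, g, oracle_all_perms(6))
  expect_equal(tidy(fit)$p_value[1], p_oracle)
  # the clearly separated 3+3 design has exact p = 2/20
  expect_equal(p_oracle, 0.1)
  # observed pseudo-F agrees with the direct formula
  expect_equal(tidy(fit)$statistic[1], oracle_pseudo_f(d, g), tolerance = 1e-10)
})

test_that("PERMANOVA under the null keeps strain R2 small and p well above the floor", {
  set.seed(76)
  prof <- matrix(rexp(240), 24, 10)
  d <- bray_curtis(prof)
  g <- rep(c("A", "B", "C"), each = 8)
  ps <- vapply(1:8, function(i) {
    tidy(permanova(d, data.frame(g = sample(g)), ~g, n_perm = 99, seed = i))$p_value[1]
  }, numeric(1))
  expect_gt(mean(ps), 0.2) # roughly uniform, not clustered at the floor
  fit <- permanova(d, data.frame(g = g), ~g, n_perm = 99, seed = 1)
  expect_lt(tidy(fit)$r_squared[1], 0.25)
})

test_that("duplicated identical groups give a near-zero pseudo-F", {
  prof <- rbind(c(1, 2, 3), c(4, 5, 6), c(1, 2, 3), c(4, 5, 6))
  d <- bray_curtis(prof)
  fit <- permanova(d, data.frame(g = c("A", "A", "B", "B")), ~g, n_perm = 23, seed = 1)
  expect_lt(abs(tidy(fit)$statistic[1]), 1e-8)
})

test_that("PERMANOVA rejects degenerate factors and seeded runs reproduce", {
  d <- bray_curtis(matrix(rexp(20), 5, 4))
  expect_error(
    permanova(d, data.frame(g = rep("A", 5)), ~g),
    class = "exomet_degenerate_factor"
  )
  df <- data.frame(g = c("A", "A", "B", "B", "B"))
  f1 <- permanova(d, df, ~g, n_perm = 199, seed = 4)
  f2 <- permanova(d, df, ~g, n_perm = 199, seed = 4)
  expect_identical(tidy(f1), tidy(f2))
})

test_that("repeated-measures PERMANOVA restricts permutations within series", {
  # 2 series x 2 time points: 4 restricted relabelings, 3 non-identity
  set.seed(77)
  prof <- matrix(rexp(16, 1 / 10), 4)
  d <- bray_curtis(prof)
  df <- data.frame(series = c("r1", "r1", "r2", "r2"), time = c(1, 2, 1, 2))
  fit <- rm_permanova(d, df, exact = TRUE)
  expect_equal(fit$n_perm, 3)
  # oracle: enumerate the 4 within-series relabelings directly
  perms <- rbind(c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3))
  p_oracle <- oracle_exact_p(d, as.character(df$time), perms)
  expect_equal(tidy(fit)$p_value[1], p_oracle)

  expect_error(
    rm_permanova(d, data.frame(series = c("r1", "r1", "r1", "r2"), time = c(1, 2, 2, 1))),
    class = "exomet_unbalanced_series"
  )
})

test_that("repeated-measures PERMANOVA detects a planted monotone time trend", {
  sp <- saturating_profiles(n_feat = 15, reps = 4, seed = 78)
  df <- data.frame(
    time = sp$groups,
    series = rep(sprintf("r%d", 1:4), times = 6)
  )
  # perturb so replicates are not identical
  set.seed(79)
  prof <- sp$profiles * exp(matrix(rnorm(length(sp$profiles), 0, 0.03), nrow(sp$profiles)))
  fit <- rm_permanova(bray_curtis(prof), df, n_perm = 499, seed = 1)
  expect_lt(tidy(fit)$p_value[1], 0.01)

  # profiles without any time structure: one p per independent null dataset,
  # roughly uniform across datasets
  ps <- vapply(1:8, function(i) {
    set.seed(800 + i)
    prof_null <- matrix(rexp(length(prof), 1 / 10), nrow(prof))
    tidy(rm_permanova(bray_curtis(prof_null), df, n_perm = 99, seed = i))$p_value[1]
  }, numeric(1))
  expect_gt(mean(ps), 0.2)
  expect_gt(max(ps), 0.4)
})

test_that("pairwise PERMANOVA applies Benjamini-Hochberg over the pair family", {
  set.seed(81)
  prof <- rbind(
    matrix(rexp(20, 1 / 2), 4), matrix(rexp(20, 1 / 20), 4),
    matrix(rexp(20, 1 / 200), 4)
  )
  d <- bray_curtis(prof)
  g <- rep(c("A", "B", "C"), each = 4)
  pw <- pairwise_permanova(d, g, n_perm = 99, seed = 5)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$q_value, p.adjust(pw$p_value, method = "BH"))
  # single pair: Q = p
  pw2 <- pairwise_permanova(as.dist(as.matrix(d)[1:8, 1:8]), g[1:8], n_perm = 99, seed = 5)
  expect_equal(pw2$q_value, pw2$p_value)
})

test_that("centroid dissimilarities are zero for identical samples and track planted trends", {
  m <- matrix(rep(c(1, 2, 3), 6), 6, byrow = TRUE)
  cd0 <- centroid_dissimilarity(m, rep(c(12.5, 25, 45), each = 2))
  expect_equal(cd0$dissimilarity, c(0, 0))

  sp <- saturating_profiles(seed = 82)
  base <- centroid_dissimilarity(sp$profiles, sp$groups, baseline = 12.5)
  expect_true(all(diff(base$dissimilarity) > 0)) # grows away from baseline
  step <- centroid_dissimilarity(sp$profiles, sp$groups, stepwise = TRUE)
  expect_true(all(diff(step$dissimilarity) < 0)) # decelerating steps shrink

  expect_error(
    centroid_dissimilarity(sp$profiles, sp$groups, baseline = 99),
    class = "exomet_empty_group"
  )
})

test_that("Protest recovers exact concordance, disagreement, and the closed form", {
  set.seed(83)
  x <- matrix(rnorm(12), 6, 2)
  th <- 0.8
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  y <- 4 * x %*% rot + 2
  pr <- protest_comparison(x, y, n_perm = 199, seed = 1)
  expect_equal(pr$m12_squared, 0, tolerance = 1e-10)
  expect_equal(pr$correlation, 1, tolerance = 1e-10)
  expect_lte(pr$p_value, 0.01)

  y_ind <- matrix(rnorm(12), 6, 2)
  pr2 <- protest_comparison(x, y_ind, n_perm = 199, seed = 1)
  expect_equal(pr2$m12_squared, oracle_m12sq(x, y_ind), tolerance = 1e-10)

  # hand-checkable 3-point configuration
  a <- rbind(c(0, 0), c(1, 0), c(0, 1))
  b <- rbind(c(0, 0), c(1, 0), c(1, 1))
  pr3 <- protest_comparison(a, b, n_perm = 99, seed = 1)
  expect_equal(pr3$m12_squared, oracle_m12sq(a, b), tolerance = 1e-10)

  expect_error(
    protest_comparison(matrix(0, 4, 2), matrix(rnorm(8), 4, 2)),
    class = "exomet_degenerate_configuration"
  )
  expect_error(
    protest_comparison(matrix(rnorm(8), 4, 2), matrix(rnorm(6), 3, 2)),
    class = "exomet_degenerate_configuration"
  )
})

test_that("per-feature ANOVA matches the hand-computed toy and flags planted effects", {
  td <- toy_design(
    rbind(c(1, 2, 3, 4, 5, 6), c(5, 5, 5, 5, 5, 5)),
    time_h = rep(45, 6), class = rep(c("A", "B"), each = 3)
  )
  fa <- feature_anova(td$features, td$meta)
  expect_equal(fa$statistic[1], 13.5) # SSB 13.5 / MSW 1
  expect_equal(fa$statistic[2], 0) # no between-group variation
  expect_equal(fa$p_value[2], 1)

  # planted strain-specific features reach Q < 0.01 at modest noise
  set.seed(84)
  n_rep <- 4
  hit <- c(
    exp(rnorm(n_rep, log(1000), 0.1)), exp(rnorm(n_rep, log(40), 0.1)),
    exp(rnorm(n_rep, log(40), 0.1))
  )
  null_rows <- t(replicate(20, exp(rnorm(3 * n_rep, log(50), 0.1))))
  td2 <- toy_design(rbind(hit, null_rows),
    time_h = rep(45, 3 * n_rep),
    class = rep(c("A", "B", "C"), each = n_rep)
  )
  fa2 <- feature_anova(td2$features, td2$meta)
  expect_lt(fa2$q_value[1], 0.01)

  expect_error(
    feature_anova(td$features, td$meta, strains = "A"),
    class = "exomet_degenerate_factor"
  )
})

test_that("distance and ordination outputs are invariant to sample order", {
  set.seed(85)
  prof <- matrix(rexp(36), 6, 6)
  rownames(prof) <- sprintf("s%02d", 1:6)
  perm <- sample(6)
  d1 <- as.matrix(bray_curtis(prof))
  d2 <- as.matrix(bray_curtis(prof[perm, ]))[rownames(prof), rownames(prof)]
  expect_equal(d1, d2)
  g <- rep(c("A", "B"), 3)
  f1 <- tidy(permanova(bray_curtis(prof), data.frame(g = g), ~g, exact = TRUE))
  f2 <- tidy(permanova(bray_curtis(prof[perm, ]), data.frame(g = g[perm]), ~g, exact = TRUE))
  expect_equal(f1$sum_sq, f2$sum_sq, tolerance = 1e-10)
  expect_equal(f1$p_value, f2$p_value)
})
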