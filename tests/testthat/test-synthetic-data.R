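test_that("identical configuration and seed give identical outputs", {
  cfg <- sim_config(n_released = 8, seed = 11)
  s1 <- simulate_feature_table(cfg)
  s2 <- simulate_feature_table(cfg)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$meta, s2$meta)
  expect_identical(s1$truth, s2$truth)
  c1 <- simulate_count_table(cfg)
  c2 <- simulate_count_table(cfg)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$de, c2$de)
  expect_false(identical(
    s1$features,
    simulate_feature_table(sim_config(n_released = 8, seed = 12))$features
  ))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(replicate_cv = 0.2), class = "exomet_infeasible_config")
  expect_error(sim_config(replicate_cv = -0.1), class = "exomet_infeasible_config")
  expect_error(
    sim_config(time_points_h = c(45, 25, 12.5)),
    class = "exomet_infeasible_config"
  )
  expect_error(sim_config(n_released = -1), class = "exomet_infeasible_config")
  expect_error(
    sim_config(n_transporter_de = 30, n_transporters = 20),
    class = "exomet_infeasible_config"
  )
  expect_error(
    sim_config(n_replicates = 1, decoy_counts = c(D3_high_cv = 2)),
    class = "exomet_infeasible_config"
  )
  expect_error(
    sim_config(decoy_counts = c(D7_bogus = 1)),
    class = "exomet_infeasible_config"
  )
})

test_that("noiseless planted features are recovered with perfect sensitivity and specificity", {
  sim <- simulate_feature_table(sim_config(replicate_cv = 0, itsd_cv = 0, seed = 21))
  for (s in sim$config$strains) {
    rep <- classify_released(sim$features, sim$meta, s)
    planted <- sim$truth$feature_id[
      sim$truth$label == "released" & !is.na(sim$truth$strain) & sim$truth$strain == s
    ]
    expect_setequal(released_ids(rep), planted)
  }
})

test_that("planted recovery also holds with a zero control level", {
  sim <- simulate_feature_table(
    sim_config(replicate_cv = 0, itsd_cv = 0, control_level = 0, seed = 22)
  )
  rep <- classify_released(sim$features, sim$meta, "S1")
  planted <- sim$truth$feature_id[
    sim$truth$label == "released" & !is.na(sim$truth$strain) & sim$truth$strain == "S1"
  ]
  expect_setequal(released_ids(rep), planted)
})

test_that("each decoy class fails its designated criterion and passes the rest", {
  sim <- simulate_feature_table(sim_config(replicate_cv = 0, itsd_cv = 0, seed = 23))
  rep <- classify_released(sim$features, sim$meta, "S2")
  truth <- dplyr::filter(sim$truth, !is.na(strain), strain == "S2")
  joined <- dplyr::inner_join(rep, truth, by = "feature_id")
  crit_cols <- c(
    "c1_control_max", "c2_noise", "c3_cv", "c4_min_first", "c5_lfc", "c6_pearson"
  )
  fails <- list(
    # The control-max and noise criteria are logically nested: a control
    # global maximum forces the noise ratio to fail too.
    D1_control_max = c("c1_control_max", "c2_noise"),
    D2_below_noise = "c2_noise",
    D3_high_cv = "c3_cv",
    D4_min_not_first = "c4_min_first",
    D5_low_lfc = "c5_lfc",
    D6_low_pearson = "c6_pearson"
  )
  for (decoy in names(fails)) {
    rows <- dplyr::filter(joined, label == decoy)
    expect_gt(nrow(rows), 0)
    for (cc in crit_cols) {
      if (cc %in% fails[[decoy]]) {
        expect_true(all(!rows[[cc]]), label = paste(decoy, "fails", cc))
      } else {
        expect_true(all(rows[[cc]]), label = paste(decoy, "passes", cc))
      }
    }
    expect_false(any(rows$released))
  }
})

test_that("per-criterion pass rates at moderate noise match a brute-force evaluation", {
  sim <- simulate_feature_table(sim_config(n_released = 15, replicate_cv = 0.05, seed = 24))
  rep <- classify_released(sim$features, sim$meta, "S3")
  ora <- oracle_release(sim$features, sim$meta, "S3")
  expect_equal(rep$c1_control_max, ora$c1)
  expect_equal(rep$c2_noise, ora$c2)
  expect_equal(rep$c3_cv, ora$c3)
  expect_equal(rep$c4_min_first, ora$c4)
  expect_equal(rep$c5_lfc, ora$c5)
  expect_equal(rep$c6_pearson, ora$c6)
  expect_equal(rep$released, ora$released)
})

test_that("internal standards are near-constant at the configured CV", {
  sim <- simulate_feature_table(sim_config(itsd_cv = 0.02, seed = 25))
  sc <- setdiff(names(sim$features), c("feature_id", "mz", "rt"))
  for (id in sim$itsd_ids) {
    v <- as.numeric(sim$features[sim$features$feature_id == id, sc])
    expect_lt(sd(v) / mean(v), 0.05)
  }
})

test_that("sample dropout removes whole samples deterministically", {
  cfg <- sim_config(dropout = 5, seed = 26)
  sim <- simulate_feature_table(cfg)
  expect_length(sim$dropped, 5)
  expect_false(any(sim$dropped %in% names(sim$features)))
  expect_false(any(sim$dropped %in% sim$meta$sample_id))
  expect_identical(sim$dropped, simulate_feature_table(cfg)$dropped)
  # at most one dropout per strain/time-point group: every group keeps samples
  kept <- dplyr::count(
    dplyr::filter(sim$meta, !class %in% c("external_control", "extraction_blank")),
    class, time_h
  )
  expect_true(all(kept$n >= cfg$n_replicates - 1))
})

test_that("noiseless count simulation recovers planted transporter classes exactly", {
  simc <- simulate_count_table(sim_config(replicate_cv = 0, seed = 27))
  filtered <- filter_genes(simc$counts)
  expect_identical(filtered, simc$counts) # generated genes survive both rules
  lem <- compute_lem(filtered)
  below_truth <- simc$truth$gene_id[simc$truth$label == "below_LEM"]
  expect_setequal(lem$genes$gene_id[!lem$genes$above_lem], below_truth)
  cls <- classify_transporters(lem, simc$de, simc$transporter_ids)
  cfg <- simc$config
  expect_equal(
    as.numeric(cls),
    c(
      cfg$n_transporters,
      cfg$n_transporters - cfg$n_transporter_below,
      cfg$n_transporter_de, cfg$n_transporter_lfc,
      cfg$n_transporter_below
    )
  )
})

test_that("planted DE transporters carry Q below 0.01 and a stationary LFC above 1", {
  simc <- simulate_count_table(sim_config(seed = 28))
  de_ids <- simc$truth$gene_id[simc$truth$label == "DE_transporter"]
  q <- simc$de$q[simc$de$gene_id %in% de_ids]
  expect_true(all(q < 0.01))
  lfc_cols <- grep("^lfc_", names(simc$de), value = TRUE)
  cls <- classify_transporters(compute_lem(filter_genes(simc$counts)), simc$de, simc$transporter_ids)
  expect_equal(cls$above_lem_de_lfc, simc$config$n_transporter_lfc)
})
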