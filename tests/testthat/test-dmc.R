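test_that("Mann-Whitney U handles separation, ties and matches wilcox on clean data", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$u_statistic, 0)
  tied <- mann_whitney_u(rep(0.5, 3), rep(0.5, 3))
  expect_equal(tied$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")

  set.seed(21)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  ours <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$u_statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("Mann-Whitney p matches a 100,000-resample permutation oracle", {
  set.seed(8)
  x <- runif(30); y <- runif(30)
  ours <- mann_whitney_u(x, y)
  expect_equal(ours$u_statistic, oracle_mw_u(x, y))
  p_perm <- oracle_mw_perm_p(x, y, n_perm = 100000L, seed = 99)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / 100000)
  expect_lt(abs(ours$p_value - p_perm), max(5 * mc_sd, 0.01))

  # exact small-arm path against the same oracle
  set.seed(9)
  xs <- runif(8); ys <- runif(9) + 0.3
  ours_s <- mann_whitney_u(xs, ys)
  p_perm_s <- oracle_mw_perm_p(xs, ys, n_perm = 100000L, seed = 100)
  expect_lt(abs(ours_s$p_value - p_perm_s), 0.01)
})

test_that("class statistics contrast in-class against the rest of the group only", {
  sim <- demo_cohort()
  cls <- sim$class_map$type_to_class
  recs <- compute_class_statistics(sim$bm, sim$ann, "class01", "non_squamous")
  expect_equal(nrow(recs), nrow(sim$bm$values))
  expect_true(all(abs(recs$delta_median) <= 1))
  expect_true(all(recs$p_value >= 0 & recs$p_value <= 1))

  # forced medians: implant a probe 0.9 in-class vs 0.1 elsewhere
  v <- sim$bm$values
  in_ids <- sim$ann$sample_id[sim$ann$origin_class == "class01"]
  grp_ids <- sim$ann$sample_id[sim$ann$group == "non_squamous"]
  v["cg000399", ] <- 0.1
  v["cg000399", in_ids] <- 0.9
  recs2 <- compute_class_statistics(BetaMatrix(v), sim$ann, "class01", "non_squamous")
  expect_equal(recs2$delta_median[recs2$probe_id == "cg000399"], 0.8)

  # a probe that differs only OUTSIDE the group must not register:
  # change squamous samples only and check the non-squamous contrast is blind
  v2 <- sim$bm$values
  sq_ids <- sim$ann$sample_id[sim$ann$group == "squamous"]
  v2["cg000398", sq_ids] <- 1
  base <- compute_class_statistics(sim$bm, sim$ann, "class01", "non_squamous")
  mod <- compute_class_statistics(BetaMatrix(v2), sim$ann, "class01", "non_squamous")
  expect_equal(mod[mod$probe_id == "cg000398", c("delta_median", "p_value")],
               base[base$probe_id == "cg000398", c("delta_median", "p_value")])

  expect_error(compute_class_statistics(sim$bm, sim$ann, "nope", "squamous"),
               "need >= 2")
})

test_that("panel selection filters, orders and excludes deterministically", {
  recs <- data.frame(probe_id = sprintf("cg%03d", 1:200),
                     class_label = "a",
                     delta_median = seq(0.9, 0.05, length.out = 200) *
                       rep(c(1, -1), 100),
                     u_statistic = 1,
                     p_value = rep(c(1e-5, 0.5), 100))
  sel <- select_panel_for_class(recs, k = 30)
  expect_equal(nrow(sel), 30L)
  expect_true(all(sel$p_value < 0.001))
  expect_true(all(diff(abs(sel$delta_median)) <= 0))
  # prefix property
  sel_small <- select_panel_for_class(recs, k = 10)
  expect_equal(sel_small$probe_id, sel$probe_id[1:10])
  # exclusion re-runs equal an oracle recomputation on the reduced set
  sel_b <- select_panel_for_class(recs, k = 30, already_taken = sel$probe_id)
  reduced <- recs[!(recs$probe_id %in% sel$probe_id), ]
  oracle <- select_panel_for_class(reduced, k = 30)
  expect_equal(sel_b$probe_id, oracle$probe_id)
  expect_length(intersect(sel_b$probe_id, sel$probe_id), 0)

  all_null <- transform(recs, p_value = 0.5)
  expect_error(select_panel_for_class(all_null, k = 10), "empty panel")
  few <- recs[recs$p_value < 0.001, ][1:5, ]
  expect_warning(select_panel_for_class(few, k = 10), "shortfall")
})

test_that("group panels are disjoint, ordered by class, and reproducible", {
  sim <- demo_cohort()
  cfg <- panel_config(k_nonsq = 15, k_sq = 15)
  panels <- build_group_panels(sim$bm, sim$ann, cfg)
  for (g in c("non_squamous", "squamous")) {
    p <- panels[[g]]
    expect_equal(p$class_order, sort(p$class_order))
    expect_false(anyDuplicated(p$probes_flat) > 0)
    expect_equal(p$probes_flat,
                 unlist(lapply(p$per_class[p$class_order], `[[`, "probe_id"),
                        use.names = FALSE))
  }
  panels2 <- build_group_panels(sim$bm, sim$ann, cfg)
  expect_identical(panels, panels2)
})

test_that("panel selection never sees validation or test samples", {
  sim <- demo_cohort()
  part <- split_train_val_test(sim$ann, seed = 13)
  cfg <- panel_config(k_nonsq = 15, k_sq = 15)
  base <- build_group_panels(sim$bm, sim$ann, cfg, partition = part)
  # poison every non-training sample with a signal that would dominate
  # selection if leaked
  v <- sim$bm$values
  held_out <- setdiff(colnames(v), part$train_ids)
  in_ids <- intersect(sim$ann$sample_id[sim$ann$origin_class == "class01"], held_out)
  out_ids <- setdiff(held_out, in_ids)
  v["cg000400", in_ids] <- 0.99
  v["cg000400", out_ids] <- 0.01
  poisoned <- build_group_panels(BetaMatrix(v), sim$ann, cfg, partition = part)
  expect_identical(lapply(poisoned, `[[`, "probes_flat"),
                   lapply(base, `[[`, "probes_flat"))
})

test_that("implanted probes are recovered at delta 0.4 over five seeds", {
  for (sd in 1:5) {
    sim <- simulate_cohort(simulation_config(
      n_classes = 6L, n_squamous_classes = 3L, samples_per_class = 40L,
      n_probes = 800L, dmc_per_class = 15L, effect_delta = 0.4,
      missing_frac = 0, metastatic_frac = 0, seed = 100 + sd))
    ann <- annotate_samples(sim$annotations, sim$class_map)
    panels <- build_group_panels(sim$beta, ann,
                                 panel_config(k_nonsq = 15, k_sq = 15))
    for (g in c("non_squamous", "squamous")) {
      for (cl in panels[[g]]$class_order) {
        rec <- mean(sim$truth$per_class[[cl]]$probe_id %in%
                      panels[[g]]$per_class[[cl]]$probe_id)
        expect_gte(rec, 0.95)
      }
    }
  }
})

test_that("panels serialize to TSV + JSON and read back equal", {
  sim <- demo_cohort()
  panels <- build_group_panels(sim$bm, sim$ann, panel_config(15, 15))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panels$non_squamous, tmp)
  back <- read_panel(tmp)
  expect_equal(back$probes_flat, panels$non_squamous$probes_flat)
  expect_equal(back$class_order, panels$non_squamous$class_order)
  expect_equal(back$per_class$class01$delta_median,
               panels$non_squamous$per_class$class01$delta_median)
})
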