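test_that("Welch volcano matches the textbook formulas and conventions", {
  # identical groups: t = 0, p = 1, log2fc = 0
  x <- rbind(rep(4, 8))
  ft <- make_ft(x, design = make_design(5, 3))
  v <- volcano_welch(ft)
  expect_equal(c(v$t, v$log2fc), c(0, 0))
  expect_equal(v$p, 1)
  expect_equal(v$direction, "none")

  # plant {4,...} vs control {2,...}: log2fc = 1
  ft2 <- make_ft(rbind(c(4, 4, 4, 4, 4, 2, 2, 2)),
                 design = make_design(5, 3))
  expect_equal(volcano_welch(ft2)$log2fc, 1)

  # realistic replicate vectors against the brute-force Welch oracle
  plant <- c(10.2, 11.1, 9.8, 10.5, 10.9)
  control <- c(5.1, 4.8, 5.3)
  ft3 <- make_ft(rbind(c(plant, control)), design = make_design(5, 3))
  v3 <- volcano_welch(ft3)
  o <- oracle_welch_t(plant, control)
  expect_equal(v3$t, o$t, tolerance = 1e-10)
  expect_equal(v3$df, o$df, tolerance = 1e-10)
  expect_equal(v3$p, o$p, tolerance = 1e-10)
})

test_that("volcano requires two replicates per soil type", {
  ft <- make_ft(rbind(1:3), design = make_design(2, 1))
  expect_error(volcano_welch(ft), "two replicates")
})

test_that("selection uses strict inequalities at both cut-offs", {
  v <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                      p = c(0.005, 0.01, 0.005, 0.005),
                      log2fc = c(1.5, 1.5, 1.0, -1.5))
  sel <- select_enriched(v, selection_params())
  expect_equal(sel$plant, "a")       # b fails p = 0.01, c fails fc = 2
  expect_equal(sel$control, "d")
})

test_that("presence/overlap partitions detected ions", {
  # constructed 6-ion fixture: 2 plant-only, 1 control-only, 3 shared
  x <- rbind(c(5, 1, 0, 0, 0),  # plant only
             c(0, 2, NA, 0, 0), # plant only
             c(0, 0, 0, 3, 1),  # control only
             c(1, 0, 0, 2, 0),
             c(4, 4, 4, 4, 4),
             c(0, 1, 0, 1, 0))
  ft <- make_ft(x, design = make_design(3, 2))
  ov <- presence_overlap(ft)
  expect_equal(ov$n, c(2L, 1L, 3L))
  expect_equal(sum(ov$n), 6)
  expect_equal(sum(ov$pct), 100)
})

test_that("top-k pooling returns k per plot and warns on shortfall", {
  set.seed(10)
  plots <- setNames(lapply(1:6, function(i) make_volcano(25, prefix = paste0("p", i))),
                    paste0("plot", 1:6))
  mk <- pool_top_k(plots, selection_params(top_k = 20), "plant")
  expect_equal(nrow(mk), 120)
  expect_true(all(table(mk$plot_id) == 20))
  expect_true(all(tapply(mk$rank, mk$plot_id, function(r) all(r == 1:20))))

  short <- list(only = make_volcano(7))
  expect_warning(mk2 <- pool_top_k(short, selection_params(top_k = 20),
                                   "plant"), "only 7")
  expect_equal(nrow(mk2), 7)
  expect_error(pool_top_k(list(), selection_params(), "plant"), "empty")
  expect_error(pool_top_k(unname(plots), selection_params(), "plant"),
               "named")
})

test_that("ranking ties on p break by |log2fc| then feature id", {
  v <- tibble::tibble(
    feature_id = c("ion_b", "ion_a", "ion_c"),
    mz = 1:3, rt = 1:3, mode = "positive",
    mean_plant = 1, mean_control = 1,
    log2fc = c(2, 3, 2), t = 1, df = 4,
    p = c(0.001, 0.001, 0.001),
    neg_log10_p = 3, direction = "plant"
  )
  mk <- pool_top_k(list(pl = v), selection_params(top_k = 3), "plant")
  expect_equal(mk$feature_id, c("ion_a", "ion_b", "ion_c"))
  # fc-first ranking is available as the alternative reading
  mk2 <- pool_top_k(list(pl = v),
                    selection_params(top_k = 3, rank_by = "fc"), "plant")
  expect_equal(mk2$feature_id[1], "ion_a")
})

test_that("ANOVA/BH refinement agrees with stats oracles and keeps by q", {
  set.seed(21)
  cfg <- synth_config(n_features_per_mode = 300, missing_rate = 0, seed = 21)
  ft <- simulate_feature_table(cfg, 50, "positive")$table |>
    impute_half_min() |> normalize_median()
  v <- volcano_welch(ft)
  mk <- suppressWarnings(pool_top_k(list(sol50_positive = v),
                                    selection_params(top_k = 15), "plant"))
  ref <- refine_markers_anova(mk, list(sol50_positive = ft), alpha = 0.01)

  x <- intensity_matrix(ft)
  groups <- sample_design(ft)$soil_type
  for (i in seq_len(nrow(ref))) {
    o <- oracle_oneway_f(x[ref$feature_id[i], ], groups)
    expect_equal(ref$anova_p[i], o$p, tolerance = 1e-10)
    ow <- stats::oneway.test(vals ~ g,
                             data.frame(vals = x[ref$feature_id[i], ],
                                        g = groups), var.equal = TRUE)
    expect_equal(ref$anova_p[i], ow$p.value, tolerance = 1e-10)
  }
  expect_equal(ref$bh_q, oracle_bh(ref$anova_p), tolerance = 1e-12)
  expect_identical(ref$kept, ref$bh_q < 0.01)
  # BH q non-decreasing in sorted p
  expect_true(all(diff(ref$bh_q[order(ref$anova_p)]) > -1e-12))
})

test_that("the BH step-up hand example keeps only the smallest p", {
  p <- c(0.001, 0.008, 0.039)
  q <- oracle_bh(p)
  expect_equal(q, c(0.003, 0.012, 0.039), tolerance = 1e-12)
  expect_equal(p.adjust(p, "BH"), q, tolerance = 1e-12)
})

test_that("the Welch-ANOVA variant of refinement is exposed and sane", {
  cfg <- synth_config(n_features_per_mode = 100, missing_rate = 0, seed = 5)
  ft <- simulate_feature_table(cfg, 50, "positive")$table |>
    impute_half_min() |> normalize_median()
  v <- volcano_welch(ft)
  mk <- suppressWarnings(pool_top_k(list(a = v), selection_params(top_k = 5),
                                    "plant"))
  ref <- refine_markers_anova(mk, list(a = ft), welch = TRUE)
  x <- intensity_matrix(ft)
  g <- sample_design(ft)$soil_type
  o <- oracle_welch_f(x[ref$feature_id[1], ], g)
  expect_equal(ref$anova_p[1], o$p, tolerance = 1e-10)
})
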