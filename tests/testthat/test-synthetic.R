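test_that("generation is a pure function of (config, seed)", {
  cfg <- synth_config(n_features_per_mode = 100, seed = 11)
  a <- simulate_feature_table(cfg, 50, "positive")
  b <- simulate_feature_table(cfg, 50, "positive")
  expect_identical(intensity_matrix(a$table), intensity_matrix(b$table))
  expect_identical(a$truth$true_log2fc, b$truth$true_log2fc)
  # different solution/mode fan out to different draws
  c <- simulate_feature_table(cfg, 0, "positive")
  expect_false(identical(a$table$mz, c$table$mz))
})

test_that("null config produces a pure null dataset", {
  cfg <- synth_config(n_features_per_mode = 50, frac_enriched_plant = 0,
                      frac_enriched_control = 0, seed = 3)
  truth <- simulate_feature_table(cfg, 50, "positive")$truth
  expect_length(truth$enriched_plant_ids, 0)
  expect_length(truth$enriched_control_ids, 0)
  expect_true(all(truth$true_log2fc == 0))
})

test_that("invalid configurations are rejected up front", {
  expect_error(synth_config(frac_enriched_plant = 0.7,
                            frac_enriched_control = 0.5), "sum")
  expect_error(synth_config(log2fc_range = c(0.5, 2)), "exceed 1")
  expect_error(synth_config(solutions = c(10, 50)), "drawn from")
})

test_that("generated tables satisfy the container invariants", {
  cfg <- synth_config(n_features_per_mode = 80, n_spiked_compounds = 2,
                      seed = 9)
  ft <- simulate_feature_table(cfg, 95, "negative")$table
  # constructor re-validates: no error means mz > 0, rt >= 0, unique ids
  expect_s3_class(ft, "feature_table")
  expect_true(all(ft$mz > 0))
  expect_false(anyDuplicated(ft$feature_id) > 0)
})

test_that("enriched ions realize their nominal fold changes on average", {
  ratios <- c()
  for (s in 1:20) {
    cfg <- synth_config(n_features_per_mode = 1000,
                        frac_enriched_plant = 0.02,
                        frac_enriched_control = 0, missing_rate = 0,
                        seed = s)
    sim <- simulate_feature_table(cfg, 50, "positive")
    x <- intensity_matrix(sim$table)
    design <- sample_design(sim$table)
    ids <- sim$truth$enriched_plant_ids
    mp <- rowMeans(x[ids, design$soil_type == "plant", drop = FALSE])
    mc <- rowMeans(x[ids, design$soil_type == "control", drop = FALSE])
    ratios <- c(ratios, (mp / mc) / 2^sim$truth$true_log2fc[ids])
  }
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("spiked families have exact adduct/isotope mass structure", {
  cfg <- synth_config(n_features_per_mode = 30, seed = 2)
  ft <- simulate_feature_table(cfg, 50, "positive")$table
  lib <- soil_compound_library()
  dimboa <- lib[lib$name == "DIMBOA", ]
  res <- spike_compound_ions(ft, dimboa, adducts = c("[M+H]+", "[M+Na]+"),
                             rt = 300, direction = "plant", config = cfg)
  added <- res$table[grepl("spk", res$table$feature_id), ]
  parents <- added[!grepl("13C", added$feature_id), ]
  expect_equal(sort(parents$mz), sort(c(212.0554, 234.0373)),
               tolerance = 1e-3)
  isotopes <- added[grepl("13C", added$feature_id), ]
  expect_equal(sort(isotopes$mz - parents$mz[match(
    sub("_13C", "", isotopes$feature_id), parents$feature_id)]),
    rep(1.00336, 2), tolerance = 1e-3)
  # siblings share retention time within +/- 2 s of the requested rt
  expect_true(all(abs(added$rt - 300) <= 2))
  # isotope intensity is the configured fraction of its parent
  x <- intensity_matrix(res$table)
  for (i in seq_len(nrow(parents))) {
    expect_equal(x[paste0(parents$feature_id[i], "_13C"), ],
                 x[parents$feature_id[i], ] * cfg$isotope_fraction,
                 tolerance = 1e-9)
  }
})

test_that("spiking with no adducts or unknown labels behaves as specified", {
  cfg <- synth_config(n_features_per_mode = 10, seed = 1)
  ft <- simulate_feature_table(cfg, 50, "positive")$table
  lib <- soil_compound_library()
  res <- spike_compound_ions(ft, lib[1, ], adducts = character(), rt = 100)
  expect_identical(res$table, ft)
  expect_error(
    spike_compound_ions(ft, lib[1, ], adducts = "[M-H]-", rt = 100),
    "supported"
  )
})

test_that("OTU generator respects depth and exchangeability contracts", {
  sim <- simulate_otu_table(n_otus = 100, n_per_group = 4, depth = 2000,
                            seed = 7)
  expect_true(all(colSums(sim$counts) == 2000))
  expect_true(all(sim$counts >= 0))
  expect_identical(sim$counts,
                   simulate_otu_table(n_otus = 100, n_per_group = 4,
                                      depth = 2000, seed = 7)$counts)
  expect_error(simulate_otu_table(depth = 0), "depth")
  expect_error(simulate_otu_table(n_otus = 10, n_effect_otus = 11),
               "exceed")
})

test_that("leakage generator honours mean/CV contracts", {
  lk <- simulate_leakage(c(water = 8, wounded = 60), cv = 0, n = 4)
  expect_true(all(lk$data$relative_conductivity[
    lk$data$treatment == "water"] == 8))
  expect_error(simulate_leakage(c(a = 10, b = 20), n = 1), "n must be >= 2")
  expect_error(simulate_leakage(c(a = 150)), "\\[0, 100\\]")
  a <- simulate_leakage(c(x = 10, y = 50), cv = 0.2, n = 4, seed = 3)
  b <- simulate_leakage(c(x = 10, y = 50), cv = 0.2, n = 4, seed = 3)
  expect_identical(a$data, b$data)
})
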