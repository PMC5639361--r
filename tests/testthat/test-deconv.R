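.ions <- function(mz, rt, mode = "positive") {
  tibble::tibble(feature_id = sprintf("i%02d", seq_along(mz)),
                 mz = mz, rt = rt, mode = mode)
}

test_that("adduct pairs at one retention time merge with correct mass", {
  # DIMBOA as [M+H]+ and [M+Na]+ (Na - H delta 21.9819)
  g <- group_adducts(.ions(c(212.0553, 234.0373), c(300, 301)))
  expect_equal(nrow(g), 1)
  expect_equal(g$neutral_mass, 211.048, tolerance = 1e-3)
  expect_equal(g$support, 2L)
  labs <- g$members[[1]]$label
  expect_setequal(labs, c("[M+H]+", "[M+Na]+"))
})

test_that("the retention-time tolerance separates distant ions", {
  g <- group_adducts(.ions(c(212.0553, 234.0373), c(300, 315)))
  expect_equal(nrow(g), 2)
  expect_true(all(g$n_members == 1))
  # singletons fall back to the default rule
  expect_equal(g$neutral_mass[1], 212.0553 - 1.00728, tolerance = 1e-3)
})

test_that("13C isotopologue pairs join their parent", {
  g <- group_adducts(.ions(c(180.0634, 181.0668), c(200, 200.5)))
  expect_equal(nrow(g), 1)
  m <- g$members[[1]]
  expect_identical(m$is_isotope, c(FALSE, TRUE))
  expect_match(m$label[2], "\\+13C")
})

test_that("negative-mode families resolve through formate and chloride", {
  dimboa <- mass_from_formula("C9H9NO5")
  mzs <- c(adduct_mz(dimboa, "[M-H]-"), adduct_mz(dimboa, "[M+HCOO]-"))
  g <- group_adducts(.ions(mzs, c(400, 401), mode = "negative"))
  expect_equal(nrow(g), 1)
  expect_equal(g$neutral_mass, dimboa, tolerance = 1e-3)
})

test_that("grouping is invariant to ion input order", {
  set.seed(4)
  dimboa <- mass_from_formula("C9H9NO5")
  quercetin <- mass_from_formula("C15H10O7")
  mz <- c(adduct_mz(dimboa, "[M+H]+"), adduct_mz(dimboa, "[M+Na]+"),
          adduct_mz(dimboa, "[M+H]+") + C13_DELTA,
          adduct_mz(quercetin, "[M+H]+"), adduct_mz(quercetin, "[M+K]+"),
          runif(4, 300, 900))
  rt <- c(120, 121, 120.5, 119, 120, 500, 600, 700, 800)
  ions <- .ions(mz, rt)
  partition <- function(g) {
    sets <- lapply(g$members, function(m) sort(m$feature_id))
    sets[order(vapply(sets, `[`, "", 1))]
  }
  g1 <- group_adducts(ions)
  for (r in 1:3) {
    g2 <- group_adducts(ions[sample(nrow(ions)), ])
    expect_identical(partition(g2), partition(g1))
  }
})

test_that("vanishing tolerances leave every ion a singleton", {
  set.seed(9)
  ions <- .ions(runif(12, 100, 1000), runif(12, 50, 800))
  g <- group_adducts(ions, deconv_params(mz_tol = 1e-9, rt_tol = 1e-9))
  expect_equal(nrow(g), 12)
})

test_that("spiked families from the generator come back as one group", {
  cfg <- synth_config(n_features_per_mode = 150, seed = 31)
  ft <- simulate_feature_table(cfg, 50, "positive")$table
  lib <- soil_compound_library()
  res <- spike_compound_ions(ft, lib[lib$name == "rutin", ],
                             adducts = c("[M+H]+", "[M+Na]+", "[M+K]+"),
                             rt = 444, direction = "plant", config = cfg)
  spiked_ids <- res$truth$spiked_groups$member_ids[[1]]
  sub <- res$table[res$table$feature_id %in% spiked_ids, ]
  g <- group_adducts(sub)
  expect_equal(nrow(g), 1)
  expect_equal(g$neutral_mass, lib$monoisotopic_mass[lib$name == "rutin"],
               tolerance = 0.01)
})

test_that("mixed ionization modes are refused", {
  ions <- .ions(c(100, 200), c(50, 60))
  ions$mode <- c("positive", "negative")
  expect_error(group_adducts(ions), "mix")
})

test_that("annotation matches, flags decoys, and falls back to unknown", {
  lib <- soil_compound_library()
  g <- group_adducts(.ions(c(212.0553, 234.0373), c(300, 301)))
  ann <- annotate_groups(g, lib)
  expect_equal(ann$matches[[1]]$name[1], "DIMBOA")
  expect_lte(abs(ann$matches[[1]]$mass_error[1]), 0.001)
  expect_equal(ann$met_class, "benzoxazinoid")
  expect_false(ann$excluded)

  far <- group_adducts(.ions(7000, 100))
  ann2 <- annotate_groups(far, lib)
  expect_equal(ann2$met_class, "unknown")
  expect_false(ann2$excluded)
})

test_that("equidistant plausible and implausible matches are both listed", {
  lib <- tibble::tibble(
    name = c("flavo", "drug"), formula = NA_character_,
    monoisotopic_mass = c(299.99, 300.01),
    met_class = c("flavonoid", "synthetic drug"),
    plausible_in_soil = c(TRUE, FALSE)
  )
  g <- tibble::tibble(group_id = "G1", neutral_mass = 300.0,
                      rt_centroid = 100, support = 1L, n_members = 1L,
                      members = list(tibble::tibble()))
  ann <- annotate_groups(g, lib)
  expect_equal(nrow(ann$matches[[1]]), 2)
  expect_identical(ann$matches[[1]]$excluded,
                   c(FALSE, TRUE)[order(c(0.01, 0.01))])
  expect_equal(ann$met_class, "flavonoid")

  # all-implausible group is excluded as a whole
  g$neutral_mass <- 300.01
  lib2 <- lib[2, ]
  ann2 <- annotate_groups(g, lib2)
  expect_true(ann2$excluded)
})

test_that("class composition counts ions additively and excludes decoys", {
  ann <- tibble::tibble(
    group_id = c("a", "b", "c"),
    neutral_mass = 1:3, n_members = c(2L, 1L, 1L),
    matches = list(tibble::tibble()),
    met_class = c("flavonoid", "flavonoid", "unknown"),
    excluded = FALSE, reason = NA_character_
  )
  comp <- class_composition(ann)
  expect_equal(comp$pct[comp$met_class == "flavonoid"], 75)
  expect_equal(sum(comp$pct), 100, tolerance = 0.1)

  # adding an excluded decoy group leaves percentages unchanged
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(
    group_id = "d", neutral_mass = 4, n_members = 5L,
    matches = list(tibble::tibble()), met_class = "synthetic drug",
    excluded = TRUE, reason = "all matches implausible in soil"))
  expect_equal(class_composition(ann2), comp)

  # single annotation -> 100%
  expect_equal(class_composition(ann[2, ])$pct, 100)
  # everything excluded -> explicit error
  expect_error(class_composition(ann2[4, ]), "empty composition")
})
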