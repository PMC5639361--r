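test_that("relative conductivity and RWC follow their definitions", {
  expect_equal(relative_conductivity(2, 2), 100)
  expect_equal(relative_conductivity(0, 2), 0)
  expect_equal(relative_conductivity(0.5, 2), 25)
  expect_error(relative_conductivity(-1, 2), "negative")
  expect_error(relative_conductivity(1, 0), "positive")

  expect_equal(compute_rwc(5, 5, 10), 0)
  expect_equal(compute_rwc(10, 5, 10), 1)
  expect_equal(compute_rwc(9, 5, 10), 0.8)
  expect_error(compute_rwc(5, 5, 5), "exceed")
  expect_error(compute_rwc(11, 5, 10), "between")
})

test_that("Welch ANOVA on ranks matches the direct Welch 1951 formulas", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  mine <- welch_anova_ranked(g)
  ranks <- rank(unlist(g))
  o <- oracle_welch_f(ranks, rep(names(g), lengths(g)))
  expect_equal(mine$f, o$f, tolerance = 1e-10)
  expect_equal(mine$df2, o$df2, tolerance = 1e-10)
  expect_equal(mine$p, o$p, tolerance = 1e-10)
})

test_that("rank transform makes the test invariant to monotone maps", {
  set.seed(6)
  g <- list(w = rnorm(4, 0), x = rnorm(4, 1), y = rnorm(4, 3))
  base <- welch_anova_ranked(g)
  for (f in list(exp, function(v) v^3, function(v) 5 * v + 2)) {
    tr <- welch_anova_ranked(lapply(g, f))
    expect_equal(tr$f, base$f, tolerance = 1e-12)
    expect_equal(tr$p, base$p, tolerance = 1e-12)
  }
})

test_that("degenerate rank patterns are handled explicitly", {
  flat <- list(a = c(2, 2, 2), b = c(2, 2, 2))
  expect_equal(welch_anova_ranked(flat)$p, 1)
  expect_warning(
    res <- welch_anova_ranked(list(a = c(1, 1, 1), b = c(5, 6, 7))),
    "floored")
  expect_lt(res$p, 0.05)
  expect_error(welch_anova_ranked(list(a = 1:3)), "two groups")
  expect_error(welch_anova_ranked(list(a = 1:3, b = 2)), "two replicates")
})

test_that("Welch ANOVA on ranks is calibrated under unequal variances", {
  set.seed(99)
  rejections <- replicate(2000, {
    g <- list(a = rnorm(8, 0, 1), b = rnorm(8, 0, 2), c = rnorm(8, 0, 1.5))
    welch_anova_ranked(g)$p < 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("Games-Howell at k = 2 matches the quadrature oracle", {
  set.seed(17)
  g <- list(a = rnorm(4, 0, 1), b = rnorm(5, 1.5, 2))
  res <- games_howell(g)
  o <- oracle_welch_t(g$a, g$b)
  expect_equal(res$pairs$q, abs(o$t) * sqrt(2), tolerance = 1e-10)
  expect_equal(res$pairs$df, o$df, tolerance = 1e-10)
  expect_equal(res$pairs$p,
               oracle_ptukey_upper(res$pairs$q, 2, res$pairs$df),
               tolerance = 1e-6)
  # and the vetted base-R approximation agrees to its own accuracy
  expect_equal(res$pairs$p,
               ptukey(res$pairs$q, 2, res$pairs$df, lower.tail = FALSE),
               tolerance = 5e-5)
})

test_that("identical groups share a letter at p ~ 1", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  res <- games_howell(g)
  expect_gte(res$pairs$p, 0.999)
  expect_equal(res$letters$letters, c("a", "a"))
})

test_that("three-group letter display isolates the single difference", {
  # only A vs C differs: the high-variance B overlaps both
  g <- list(A = c(0.1, -0.1, 0.05, 0), B = c(0.2, 1.2, 2.2, 3.2),
            C = c(3.0, 3.1, 2.9, 3.05))
  res <- games_howell(g)
  sig <- res$pairs$p < 0.05
  expect_identical(sig, c(FALSE, TRUE, FALSE))  # AB, AC, BC
  expect_equal(res$letters$letters, c("a", "ab", "b"))
})

test_that("letters reproduce the pairwise significance pattern exactly", {
  set.seed(55)
  for (trial in 1:25) {
    k <- sample(3:5, 1)
    g <- lapply(seq_len(k), function(i) rnorm(4, mean = sample(0:3, 1)))
    names(g) <- LETTERS[seq_len(k)]
    res <- games_howell(g)
    shares <- function(g1, g2) {
      l <- setNames(res$letters$letters, res$letters$group)
      length(intersect(strsplit(l[[g1]], "")[[1]],
                       strsplit(l[[g2]], "")[[1]])) > 0
    }
    for (r in seq_len(nrow(res$pairs))) {
      expect_identical(shares(res$pairs$group1[r], res$pairs$group2[r]),
                       res$pairs$p[r] >= 0.05)
    }
  }
})

test_that("CFU t-test matches summary statistics route and guards logs", {
  expect_equal(cfu_ttest(c(3, 3, 3), c(3, 3, 3))$p, 1)
  res <- cfu_ttest(c(1e6, 1.1e6, 0.9e6), c(1e4, 1.2e4, 0.8e4))
  expect_lt(res$p, 0.05)
  a <- c(2.3e5, 3e5, 2.8e5, 2e5); b <- c(1.1e5, 1.4e5, 9e4)
  mine <- cfu_ttest(a, b)
  via_summary <- summary_ttest(mean(a), sd(a), 4, mean(b), sd(b), 3)
  expect_equal(mine$t, via_summary$t, tolerance = 1e-10)
  expect_equal(mine$p, via_summary$p, tolerance = 1e-10)
  expect_error(cfu_ttest(c(0, 10), c(5, 6), log_transform = TRUE),
               "pseudo-count")
})

test_that("the simulated leakage experiment reproduces the figure's design", {
  lk <- simulate_leakage(
    c(neg_ctrl = 8, meoh_0 = 9, meoh_50 = 10, meoh_95 = 12, wounded = 60),
    cv = 0.15, n = 4, seed = 20)
  omnibus <- welch_anova_ranked(
    split(lk$data$relative_conductivity, lk$data$treatment))
  expect_lt(omnibus$p, 0.05)
  ph <- games_howell(split(lk$data$relative_conductivity, lk$data$treatment))
  letters <- setNames(ph$letters$letters, ph$letters$group)
  # the wounded positive control never shares a letter with the solvents
  for (trt in c("neg_ctrl", "meoh_0", "meoh_50", "meoh_95")) {
    expect_length(intersect(strsplit(letters[["wounded"]], "")[[1]],
                            strsplit(letters[[trt]], "")[[1]]), 0)
  }
})
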