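# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive -- textbook formulas, direct enumeration, quadrature --
# and never call the package code paths they are used to check.

# Welch two-sample t from first principles.
oracle_welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

# Classical one-way F from sums of squares.
oracle_oneway_f <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups); n <- length(values)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) {
    length(v) * (mean(v) - grand)^2
  }))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  f_val <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f_val, p = stats::pf(f_val, k - 1, n - k, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up, written as the definition.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- p[ord] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

# Welch's heteroscedastic one-way ANOVA (Welch 1951), direct formulas.
oracle_welch_f <- function(values, groups) {
  groups <- as.factor(groups)
  ns <- tapply(values, groups, length)
  ms <- tapply(values, groups, mean)
  vs <- tapply(values, groups, stats::var)
  k <- length(ms)
  w <- ns / vs
  sw <- sum(w)
  mw <- sum(w * ms) / sw
  a <- sum(w * (ms - mw)^2) / (k - 1)
  lambda <- sum((1 - w / sw)^2 / (ns - 1))
  b <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  f_val <- a / b
  df2 <- (k^2 - 1) / (3 * lambda)
  list(f = f_val, df1 = k - 1, df2 = df2,
       p = stats::pf(f_val, k - 1, df2, lower.tail = FALSE))
}

# Upper-tail probability of the studentized range by nested numerical
# integration: P(Q > q) with k means and df degrees of freedom.
oracle_ptukey_upper <- function(q, k, df) {
  inner <- function(u) {
    # P(range of k std normals <= u)
    f <- function(z) stats::dnorm(z) *
      (stats::pnorm(z) - stats::pnorm(z - u))^(k - 1)
    k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-10,
                         subdivisions = 500L)$value
  }
  # s = chi_df / sqrt(df); density via the chi distribution
  dens <- function(s) {
    exp((df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  cdf <- stats::integrate(function(s) {
    vapply(s, function(si) dens(si) * inner(q * si), numeric(1))
  }, 0, Inf, rel.tol = 1e-9, subdivisions = 500L)$value
  1 - cdf
}

# -- fixture builders -------------------------------------------------------

make_design <- function(n_plant = 5, n_control = 3, solution = 50) {
  tibble::tibble(
    sample_id = c(sprintf("plant_%d_%d", solution, seq_len(n_plant)),
                  sprintf("control_%d_%d", solution, seq_len(n_control))),
    soil_type = c(rep("plant", n_plant), rep("control", n_control)),
    solution = solution,
    replicate = c(seq_len(n_plant), seq_len(n_control))
  )
}

make_ft <- function(x, mz = NULL, rt = NULL, mode = "positive",
                    design = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(design)) {
    half <- ceiling(ncol(x) / 2)
    design <- make_design(half, ncol(x) - half)
  }
  feature_table(
    tibble::tibble(
      feature_id = sprintf("ft%03d", seq_len(n)),
      mz = mz %||% seq(100, by = 50, length.out = n),
      rt = rt %||% seq(60, by = 60, length.out = n),
      mode = mode
    ),
    design, x
  )
}

# A volcano-result tibble fabricated directly (no simulation) for funnel
# arithmetic tests.
make_volcano <- function(n_qualifying, n_other = 5, direction = "plant",
                         prefix = "v", p = NULL, log2fc = NULL) {
  n <- n_qualifying + n_other
  sgn <- if (direction == "plant") 1 else -1
  p_vals <- c(p %||% seq(1e-6, 5e-3, length.out = n_qualifying),
              runif(n_other, 0.2, 0.9))
  fc <- c(log2fc %||% rep(2.5, n_qualifying) * sgn,
          rnorm(n_other, 0, 0.2))
  tibble::tibble(
    feature_id = sprintf("%s_f%03d", prefix, seq_len(n)),
    mz = runif(n, 80, 1200), rt = runif(n, 30, 900), mode = "positive",
    mean_plant = 1, mean_control = 1, log2fc = fc, t = 0, df = 4,
    p = p_vals, neg_log10_p = -log10(p_vals),
    direction = ifelse(fc > 0, "plant", ifelse(fc < 0, "control", "none"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
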