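# Vectorized statistical kernels shared by the volcano, marker-refinement
# and damage modules.

.row_means <- function(x) rowMeans(x)

.row_vars <- function(x) {
  n <- ncol(x)
  rowSums((x - rowMeans(x))^2) / (n - 1L)
}

# Welch two-sample t on matrix rows. Zero pooled SE with equal means gives
# t = 0, p = 1 (a flat ion is not evidence); with unequal means p = 0.
.welch_t_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- .row_means(x1); m2 <- .row_means(x2)
  v1 <- .row_vars(x1); v2 <- .row_vars(x2)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(t_stat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    equal <- degenerate & (m1 == m2)
    t_stat[equal] <- 0
    df[equal] <- n1 + n2 - 2L
    p[equal] <- 1
    unequal <- degenerate & (m1 != m2)
    t_stat[unequal] <- sign(m1 - m2)[unequal] * Inf
    df[unequal] <- n1 + n2 - 2L
    p[unequal] <- 0
  }
  list(mean1 = m1, mean2 = m2, t = t_stat, df = df, p = p)
}

# Classical equal-variance one-way F on matrix rows for a grouping factor.
.oneway_f_rows <- function(x, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- ncol(x)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than two replicates: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  grand <- rowMeans(x)
  ssb <- 0
  ssw <- 0
  for (g in levels(groups)) {
    idx <- groups == g
    mg <- rowMeans(x[, idx, drop = FALSE])
    ssb <- ssb + sum(idx) * (mg - grand)^2
    ssw <- ssw + rowSums((x[, idx, drop = FALSE] - mg)^2)
  }
  f_stat <- (ssb / (k - 1L)) / (ssw / (n - k))
  p <- pf(f_stat, k - 1L, n - k, lower.tail = FALSE)
  flat <- ssw == 0 & ssb == 0
  f_stat[flat] <- 0
  p[flat] <- 1
  exact <- ssw == 0 & ssb > 0
  f_stat[exact] <- Inf
  p[exact] <- 0
  list(f = f_stat, df1 = k - 1L, df2 = n - k, p = p)
}

# Welch's heteroscedastic one-way ANOVA from group summary statistics
# (Welch 1951). Variances below `var_floor` are floored so the weights
# stay finite when a group is constant.
.welch_f_from_stats <- function(means, vars, ns, var_floor = 0) {
  k <- length(means)
  vars <- pmax(vars, var_floor)
  w <- ns / vars
  sw <- sum(w)
  mw <- sum(w * means) / sw
  a <- sum(w * (means - mw)^2) / (k - 1)
  lambda <- sum((1 - w / sw)^2 / (ns - 1))
  b <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  f_stat <- unname(a / b)
  df1 <- k - 1
  df2 <- unname((k^2 - 1) / (3 * lambda))
  p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  if (is.nan(f_stat)) { f_stat <- 0; p <- 1 }
  list(f = f_stat, df1 = df1, df2 = df2, p = p)
}

# Upper-tail probability of the studentized range with k means and df
# degrees of freedom, by nested numerical integration over the chi-square
# mixing density (accuracy ~1e-8; stats::ptukey is only ~1e-5 in places).
.stud_range_sf <- function(q, k, df) {
  if (q <= 0) return(1)
  if (!is.finite(q)) return(0)
  range_cdf <- function(u) {
    f <- function(z) stats::dnorm(z) *
      (stats::pnorm(z) - stats::pnorm(z - u))^(k - 1)
    k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-11,
                         subdivisions = 400L)$value
  }
  cdf <- stats::integrate(function(x) {
    stats::dchisq(x, df) *
      vapply(x, function(xi) range_cdf(q * sqrt(xi / df)), numeric(1))
  }, 0, Inf, rel.tol = 1e-9, subdivisions = 400L)$value
  max(0, min(1, 1 - cdf))
}
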