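# Statistics for the extraction-damage controls: relative conductivity,
# relative water content, Welch's heteroscedastic ANOVA on ranks,
# Games-Howell post-hoc comparisons with a compact letter display, and
# CFU t-tests.

#' Conductivity relative to the lysis maximum
#'
#' `100 * value / lysis_max`, expressing electrolyte leakage as a
#' percentage of the conductivity of fully lysed tissue.
#'
#' @param value Measured conductivity, uS/cm (non-negative).
#' @param lysis_max Conductivity after full tissue lysis, uS/cm (> 0).
#' @return Relative conductivity, percent.
#' @export
relative_conductivity <- function(value, lysis_max) {
  if (lysis_max <= 0) stop("lysis_max must be positive", call. = FALSE)
  if (any(value < 0)) stop("conductivity cannot be negative", call. = FALSE)
  100 * value / lysis_max
}

#' Relative water content of soil
#'
#' `RWC = (W - DW) / (SW - DW)` from soil weight `W`, dry weight `DW` and
#' water-saturated weight `SW`.
#'
#' @param w Soil weight, g.
#' @param dw Dry weight, g.
#' @param sw Saturated weight, g.
#' @return RWC as a fraction in [0, 1].
#' @export
compute_rwc <- function(w, dw, sw) {
  if (any(sw <= dw)) stop("saturated weight must exceed dry weight",
                          call. = FALSE)
  if (any(w < dw) || any(w > sw)) {
    stop("soil weight must lie between dry and saturated weight",
         call. = FALSE)
  }
  (w - dw) / (sw - dw)
}

.as_group_list <- function(groups, values = NULL) {
  if (is.data.frame(groups)) {
    stopifnot(!is.null(values))
    groups <- split(groups[[values]], groups$treatment)
  }
  if (!is.list(groups)) stop("groups must be a named list or data frame",
                             call. = FALSE)
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) < 2)) {
    stop("every group needs at least two replicates", call. = FALSE)
  }
  groups
}

#' Welch's heteroscedastic one-way ANOVA on ranks
#'
#' All observations are jointly rank-transformed (mid-ranks for ties) and
#' Welch's one-way ANOVA (weights n_j / s_j^2, Welch 1951 degrees of
#' freedom) is applied to the ranks: a heteroscedasticity-robust omnibus
#' test that is invariant to monotone transforms of the data. A group
#' with zero rank variance is handled with a variance floor of 1e-12 (and
#' a warning) so the Welch weights stay finite.
#'
#' @param groups Named list of replicate value vectors, or a data frame
#'   with columns `treatment` and `value`.
#' @return Tibble with `f`, `df1`, `df2`, `p`.
#' @export
welch_anova_ranked <- function(groups) {
  groups <- .as_group_list(groups, "value")
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))
  r <- rank(values)  # mid-ranks for ties
  by_group <- split(r, factor(labels, levels = names(groups)))
  means <- vapply(by_group, mean, 0)
  vars <- vapply(by_group, var, 0)
  if (any(vars == 0) && !all(vars == 0)) {
    warning("group(s) with zero rank variance floored at 1e-12",
            call. = FALSE)
  }
  res <- .welch_f_from_stats(means, vars, lengths(by_group),
                             var_floor = 1e-12)
  if (all(vars == 0)) res <- list(f = 0, df1 = length(groups) - 1,
                                  df2 = NA_real_, p = 1)
  tibble::tibble(f = res$f, df1 = res$df1, df2 = res$df2, p = res$p)
}

#' Games-Howell post-hoc comparisons with compact letter display
#'
#' For every group pair, `q = |m_i - m_j| / sqrt((s_i^2/n_i + s_j^2/n_j)/2)`
#' with Welch-Satterthwaite degrees of freedom, referred to the
#' studentized-range distribution with `k` groups. The letter display is
#' built by the standard insert-absorb algorithm at level `alpha`: groups
#' sharing a letter are not significantly different. Tail probabilities of
#' the studentized range are computed by numerical integration (accuracy
#' ~1e-8).
#'
#' @param groups Named list of replicate value vectors, or a data frame
#'   with columns `treatment` and `value`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A `posthoc_result`: list with `pairs` (tibble: `group1`,
#'   `group2`, `mean_diff`, `q`, `df`, `p`) and `letters` (tibble:
#'   `group`, `letters`).
#' @export
games_howell <- function(groups, alpha = 0.05) {
  groups <- .as_group_list(groups, "value")
  k <- length(groups)
  nm <- names(groups)
  means <- vapply(groups, mean, 0)
  vars <- vapply(groups, var, 0)
  ns <- lengths(groups)
  combos <- utils::combn(k, 2)
  pairs <- purrr::map(seq_len(ncol(combos)), function(c_idx) {
    i <- combos[1, c_idx]; j <- combos[2, c_idx]
    se2 <- vars[i] / ns[i] + vars[j] / ns[j]
    diff <- means[i] - means[j]
    if (se2 == 0) {
      p <- if (diff == 0) 1 else 0
      return(tibble::tibble(group1 = nm[i], group2 = nm[j],
                            mean_diff = unname(diff),
                            q = if (diff == 0) 0 else Inf,
                            df = unname(ns[i] + ns[j] - 2), p = p))
    }
    df <- se2^2 / ((vars[i] / ns[i])^2 / (ns[i] - 1) +
                     (vars[j] / ns[j])^2 / (ns[j] - 1))
    q <- abs(diff) / sqrt(se2 / 2)
    tibble::tibble(group1 = nm[i], group2 = nm[j],
                   mean_diff = unname(diff), q = unname(q), df = unname(df),
                   p = .stud_range_sf(unname(q), k, unname(df)))
  }) |> dplyr::bind_rows()
  letters <- .compact_letters(nm, pairs, alpha)
  structure(list(pairs = pairs, letters = letters, alpha = alpha),
            class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat("Games-Howell post-hoc (alpha =", x$alpha, ")\n")
  print(x$pairs)
  print(x$letters)
  invisible(x)
}

#' @export
tidy.posthoc_result <- function(x, ...) x$pairs

# Insert-absorb compact letter display. Letter sets start as one set of
# all groups; each significant pair splits every set containing both
# members; duplicated/contained sets are absorbed. Letters are assigned
# alphabetically in group-input order.
.compact_letters <- function(group_names, pairs, alpha) {
  sets <- list(group_names)
  sig <- pairs[pairs$p < alpha, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    g1 <- sig$group1[r]; g2 <- sig$group2[r]
    new_sets <- list()
    for (s in sets) {
      if (g1 %in% s && g2 %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  sets <- sets[lengths(sets) > 0]
  # order letter sets by first member's input position for stable output
  first_pos <- vapply(sets, function(s) min(match(s, group_names)), 0)
  sets <- sets[order(first_pos)]
  codes <- vapply(group_names, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, TRUE))],
          collapse = "")
  }, "")
  tibble::tibble(group = group_names, letters = unname(codes))
}

#' Student's t-test on colony-forming-unit counts
#'
#' Two-sided pooled-variance t-test of treated vs control CFU/g values,
#' optionally after a log10 transform (CFU data are often log-normal).
#'
#' @param treated,control CFU/g replicate vectors (each n >= 2).
#' @param log_transform Test log10(CFU) instead of raw counts.
#' @return Tibble with `t`, `df`, `p`.
#' @export
cfu_ttest <- function(treated, control, log_transform = FALSE) {
  if (length(treated) < 2 || length(control) < 2) {
    stop("each group needs at least two replicates", call. = FALSE)
  }
  if (log_transform) {
    if (any(c(treated, control) <= 0)) {
      stop("zero CFU cannot be log-transformed; add a pseudo-count first",
           call. = FALSE)
    }
    treated <- log10(treated)
    control <- log10(control)
  }
  if (sd(treated) == 0 && sd(control) == 0 &&
      mean(treated) == mean(control)) {
    return(tibble::tibble(t = 0, df = length(treated) + length(control) - 2,
                          p = 1))
  }
  fit <- stats::t.test(treated, control, var.equal = TRUE)
  tibble::tibble(t = unname(fit$statistic), df = unname(fit$parameter),
                 p = fit$p.value)
}
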