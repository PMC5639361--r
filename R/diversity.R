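# Microbial-diversity statistics supporting the rhizosphere-effect check:
# prevalence filtering, alpha diversity, rarefaction, Bray-Curtis
# distances and a seeded one-way PERMANOVA.

#' Prevalence/abundance filter for OTU tables
#'
#' Keeps an OTU iff its count exceeds `min_count` in at least
#' `min_prevalence` of the samples AND its total count across all samples
#' exceeds `min_total`. Both inequalities on counts are strict, matching
#' the published "more than five times across 30% of the samples, and
#' more than 20 times across all samples" rule; `strict = FALSE` switches
#' to `>=` for sensitivity checks.
#'
#' @param counts Integer matrix, OTUs x samples.
#' @param min_count Per-sample count threshold (default 5).
#' @param min_prevalence Required fraction of samples (default 0.30).
#' @param min_total Total-count threshold (default 20).
#' @param strict Use strict `>` on the count thresholds (default TRUE).
#' @return The filtered count matrix.
#' @export
filter_prevalence <- function(counts, min_count = 5, min_prevalence = 0.30,
                              min_total = 20, strict = TRUE) {
  counts <- as.matrix(counts)
  cmp <- if (strict) `>` else `>=`
  prev_ok <- rowMeans(cmp(counts, min_count)) >= min_prevalence
  total_ok <- cmp(rowSums(counts), min_total)
  counts[prev_ok & total_ok, , drop = FALSE]
}

#' Shannon diversity of one sample
#'
#' `H = -sum(p * log(p))` over OTUs with positive counts. Natural log
#' (nats) by default; `base = 2` gives bits.
#'
#' @param counts Non-negative count vector for one sample.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (sum(counts) <= 0) stop("all-zero sample has no diversity",
                             call. = FALSE)
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Observed OTU richness
#'
#' @param counts Non-negative count vector for one sample.
#' @return Number of OTUs with positive count.
#' @export
otu_richness <- function(counts) {
  as.integer(vegan::specnumber(counts))
}

#' Rarefaction curve for one sample
#'
#' Mean and SD of observed richness over `reps` seeded subsamples drawn
#' WITHOUT replacement at each depth (multivariate hypergeometric, the
#' standard ecological definition).
#'
#' @param counts Non-negative integer count vector for one sample.
#' @param depths Subsampling depths, each at most `sum(counts)`.
#' @param reps Subsamples per depth.
#' @param seed Integer seed.
#' @return Tibble with `depth`, `mean_richness`, `sd_richness`.
#' @export
rarefaction_curve <- function(counts, depths, reps = 100, seed = 1L) {
  total <- sum(counts)
  if (any(depths > total)) {
    stop("depth(s) exceed the sample total of ", total, call. = FALSE)
  }
  if (any(depths < 1)) stop("depths must be positive", call. = FALSE)
  set.seed(as.integer(seed) %% 2147483629L)
  pool <- rep.int(seq_along(counts), counts)
  rows <- lapply(depths, function(d) {
    rich <- vapply(seq_len(reps), function(r) {
      length(unique(pool[sample.int(total, d)]))
    }, numeric(1))
    tibble::tibble(depth = d, mean_richness = mean(rich),
                   sd_richness = sd(rich))
  })
  dplyr::bind_rows(rows)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = 1 - 2 sum(min(a_i, b_i)) / (sum(a) + sum(b))` via
#' `vegan::vegdist`. A stand-in for phylogenetic distances when no tree is
#' available; [permanova()] accepts any externally computed distance
#' matrix.
#'
#' @param counts Matrix, OTUs x samples.
#' @return Symmetric distance matrix, samples x samples.
#' @export
bray_curtis <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two samples", call. = FALSE)
  if (any(colSums(counts) == 0)) {
    stop("empty sample(s): ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "),
         call. = FALSE)
  }
  as.matrix(vegan::vegdist(t(counts), method = "bray"))
}

# Pseudo-F of a one-way design from squared distances (Anderson's
# distance-based formulation): SST = sum d^2 / n over all pairs, SSW the
# within-group analogue with per-group divisors.
.permanova_f <- function(d2, groups, lev) {
  n <- nrow(d2)
  sst <- sum(d2) / (2 * n)
  ssw <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
  }
  k <- length(lev)
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

#' One-way PERMANOVA with seeded label permutations
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' the pseudo-F statistic from total and within-group sums of squared
#' distances, with `P = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` under
#' seeded permutations of the group labels.
#'
#' @param dist Distance matrix (`dist` or square symmetric matrix).
#' @param groups Factor with >= 2 levels, each with >= 2 samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A `permanova` object: list with `pseudo_f`, `df_between`,
#'   `df_within`, `p`, `n_perm`, `seed`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1L) {
  d <- as.matrix(dist)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  if (nrow(d) != length(groups)) {
    stop("distance matrix and groups disagree in size", call. = FALSE)
  }
  d2 <- d^2
  lev <- levels(groups)
  f_obs <- .permanova_f(d2, groups, lev)
  set.seed(as.integer(seed) %% 2147483629L)
  count <- 0L
  for (i in seq_len(n_perm)) {
    f_perm <- .permanova_f(d2, sample(groups), lev)
    if (f_perm >= f_obs) count <- count + 1L
  }
  structure(
    list(pseudo_f = f_obs, df_between = nlevels(groups) - 1L,
         df_within = nrow(d) - nlevels(groups),
         p = (1 + count) / (1 + n_perm), n_perm = n_perm,
         seed = as.integer(seed)),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: F(%d,%d) = %.3f, P = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$pseudo_f, x$p, x$n_perm))
  invisible(x)
}

#' @export
tidy.permanova <- function(x, ...) {
  tibble::tibble(pseudo_f = x$pseudo_f, df_between = x$df_between,
                 df_within = x$df_within, p = x$p, n_perm = x$n_perm)
}

#' @export
glance.permanova <- function(x, ...) tidy(x)

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance (Student) or Welch two-sided t from group means, SDs
#' and sizes; useful when only summary statistics are reported. Two
#' constant groups with equal means give `t = 0`, `p = 1`.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param variant `"pooled"` (Student) or `"welch"`.
#' @return Tibble with `t`, `df`, `p`.
#' @export
summary_ttest <- function(mean1, sd1, n1, mean2, sd2, n2,
                          variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (sd1 < 0 || sd2 < 0) stop("sds must be >= 0", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("both n must be >= 2", call. = FALSE)
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2) {
    return(tibble::tibble(t = 0, df = n1 + n2 - 2, p = 1))
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t_stat <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  tibble::tibble(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}
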