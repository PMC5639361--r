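# Multivariate models on the fully processed (imputed, median-normalized,
# cube-root, Pareto-scaled) sample x feature matrix: PCA, two-class PLS-DA
# with cross-validated Q2, and average-linkage clustering on 1 - Pearson r.

#' Principal component analysis with a fixed sign convention
#'
#' PCA of the column-mean-centered matrix via singular value decomposition
#' (`stats::prcomp`). Each component's sign is fixed so its
#' largest-magnitude loading is positive, making outputs comparable across
#' runs.
#'
#' @param x Numeric matrix, samples x features (already preprocessed).
#' @param n_components Components to retain (default 3, as in a 3D score
#'   plot).
#' @return A `pca_model`: list with `scores` (samples x components),
#'   `loadings` (features x components), `explained_pct` and `center`.
#' @export
fit_pca <- function(x, n_components = 3) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs at least two samples", call. = FALSE)
  if (anyNA(x)) stop("PCA input must not contain missing values",
                     call. = FALSE)
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_comp) {
    stop("n_components = ", n_components, " exceeds the rank bound ",
         max_comp, call. = FALSE)
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  explained <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  keep <- seq_len(n_components)
  loadings <- fit$rotation[, keep, drop = FALSE]
  scores <- fit$x[, keep, drop = FALSE]
  for (j in keep) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(scores = scores, loadings = loadings,
         explained_pct = explained[keep],
         explained_pct_all = explained,
         center = fit$center),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", ncol(x$scores), "components;",
      "explained %:", paste(sprintf("%.1f", x$explained_pct), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.pca_model <- function(x, ...) {
  tibble::tibble(
    sample_id = rownames(x$scores) %||% as.character(seq_len(nrow(x$scores))),
    tibble::as_tibble(x$scores)
  )
}

#' @export
glance.pca_model <- function(x, ...) {
  out <- as.list(setNames(x$explained_pct,
                          paste0("pc", seq_along(x$explained_pct), "_pct")))
  tibble::as_tibble(out)
}

# NIPALS PLS1 on a centered 0/1 class indicator.
.nipals_pls1 <- function(x, y, n_components) {
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  e <- sweep(x, 2L, x_mean)
  f <- y - y_mean
  n <- nrow(x)
  w_mat <- p_mat <- matrix(0, ncol(x), n_components)
  t_mat <- matrix(0, n, n_components)
  c_vec <- numeric(n_components)
  for (h in seq_len(n_components)) {
    w <- crossprod(e, f)[, 1L]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {  # residual indicator exhausted
      w_mat <- w_mat[, seq_len(h - 1L), drop = FALSE]
      p_mat <- p_mat[, seq_len(h - 1L), drop = FALSE]
      t_mat <- t_mat[, seq_len(h - 1L), drop = FALSE]
      c_vec <- c_vec[seq_len(h - 1L)]
      break
    }
    w <- w / nw
    t_vec <- e %*% w
    tt <- sum(t_vec^2)
    p <- crossprod(e, t_vec)[, 1L] / tt
    c_h <- sum(f * t_vec) / tt
    e <- e - t_vec %*% t(p)
    f <- f - c_h * t_vec
    w_mat[, h] <- w
    p_mat[, h] <- p
    t_mat[, h] <- t_vec
    c_vec[h] <- c_h
  }
  # Regression coefficients in original X space: B = W (P'W)^-1 c
  b <- w_mat %*% solve(crossprod(p_mat, w_mat), c_vec)
  list(weights = w_mat, loadings = p_mat, scores = t_mat, c = c_vec,
       coef = b[, 1L], x_mean = x_mean, y_mean = y_mean)
}

.pls1_predict <- function(fit, x_new) {
  sweep(as.matrix(x_new), 2L, fit$x_mean) %*% fit$coef + fit$y_mean
}

#' Two-class PLS-DA with cross-validated Q2
#'
#' NIPALS PLS1 regression of a centered 0/1 class indicator on the
#' processed matrix. `R2` is 1 - RSS/TSS on the indicator; `Q2` is
#' 1 - PRESS/TSS with PRESS from cross-validation in which every fold
#' refits the model from scratch, including centering. Leave-one-out is
#' the default, suiting the small designs (5 + 3 samples) the pipeline
#' targets; seeded k-fold is available.
#'
#' @param x Numeric matrix, samples x features (preprocessed).
#' @param labels Two-level factor (or character) of class membership.
#' @param n_components Latent components (default 2).
#' @param cv `"loo"` or `"kfold"`.
#' @param k Folds when `cv = "kfold"`.
#' @param seed Seed for the k-fold split.
#' @return A `plsda_model`: list with `r2`, `q2`, `scores`, `n_components`,
#'   `labels` and the fitted NIPALS components.
#' @export
fit_plsda <- function(x, labels, n_components = 2, cv = c("loo", "kfold"),
                      k = 5, seed = 1L) {
  cv <- match.arg(cv)
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) {
    stop("PLS-DA here is two-class; got ", nlevels(labels), " level(s)",
         call. = FALSE)
  }
  if (any(table(labels) < 2L)) {
    stop("both classes need at least two samples", call. = FALSE)
  }
  n <- nrow(x)
  if (n_components >= n) {
    stop("n_components must be smaller than the number of samples",
         call. = FALSE)
  }
  y <- as.numeric(labels == levels(labels)[2L])
  fit <- .nipals_pls1(x, y, n_components)
  resid <- y - .pls1_predict(fit, x)[, 1L]
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(resid^2) / tss

  folds <- if (cv == "loo") as.list(seq_len(n)) else {
    set.seed(as.integer(seed))
    split(sample.int(n), rep_len(seq_len(k), n))
  }
  press <- 0
  for (hold in folds) {
    sub <- .nipals_pls1(x[-hold, , drop = FALSE], y[-hold],
                        min(n_components, n - length(hold) - 1L))
    pred <- .pls1_predict(sub, x[hold, , drop = FALSE])[, 1L]
    press <- press + sum((y[hold] - pred)^2)
  }
  q2 <- 1 - press / tss

  structure(
    list(n_components = ncol(fit$scores), r2 = r2, q2 = q2,
         scores = fit$scores, coef = fit$coef, labels = labels,
         positive_class = levels(labels)[2L], cv = cv),
    class = "plsda_model"
  )
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("PLS-DA (%d component%s, %s CV): R2 = %.3f, Q2 = %.3f\n",
              x$n_components, if (x$n_components > 1) "s" else "",
              x$cv, x$r2, x$q2))
  invisible(x)
}

#' @export
tidy.plsda_model <- function(x, ...) {
  scores <- x$scores
  colnames(scores) <- paste0("comp", seq_len(ncol(scores)))
  tibble::tibble(
    sample_id = rownames(scores) %||% as.character(seq_len(nrow(scores))),
    label = as.character(x$labels),
    tibble::as_tibble(scores)
  )
}

#' @export
glance.plsda_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, r2 = x$r2, q2 = x$q2,
                 cv = x$cv)
}

#' Average-linkage clustering on Pearson-correlation distance
#'
#' Pairwise distance `1 - Pearson r` between sample intensity profiles,
#' agglomerated with average linkage (`stats::hclust`). Zero-variance
#' samples have no defined correlation and are rejected by name.
#'
#' @param x Numeric matrix, samples x features.
#' @return An `hclust` dendrogram whose leaves are the samples.
#' @export
cluster_pearson <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("clustering needs at least two samples",
                        call. = FALSE)
  vars <- apply(x, 1L, var)
  if (any(vars == 0)) {
    stop("zero-variance sample(s): ",
         paste(rownames(x)[vars == 0] %||% which(vars == 0), collapse = ", "),
         call. = FALSE)
  }
  d <- as.dist(1 - cor(t(x)))
  hclust(d, method = "average")
}
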