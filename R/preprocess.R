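# The preprocessing chain applied before multivariate analysis:
# impute -> median-normalize -> cube-root -> Pareto scale, in that fixed
# order. Volcano statistics are computed on the imputed, median-normalized
# (untransformed) intensities -- fold changes are intensity-ratio
# quantities and would be meaningless after Pareto scaling -- while the
# multivariate models consume the fully processed matrix.

.check_stage <- function(ft, stage) {
  if (stage %in% processed_stages(ft)) {
    stop("stage '", stage, "' has already been applied to this table",
         call. = FALSE)
  }
}

#' Half-minimum imputation of missing intensities
#'
#' Each missing cell is replaced by half the minimum observed positive
#' intensity of its feature (the metabolomics-community default when no
#' censoring model is available). Features missing in every sample are
#' dropped with a warning.
#'
#' @param ft A [feature_table].
#' @return The imputed [feature_table].
#' @export
impute_half_min <- function(ft) {
  .check_stage(ft, "impute")
  x <- intensity_matrix(ft)
  all_missing <- rowSums(!is.na(x)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " feature(s) missing in every sample dropped",
            call. = FALSE)
    x <- x[!all_missing, , drop = FALSE]
  }
  half_min <- apply(x, 1L, function(r) {
    pos <- r[!is.na(r) & r > 0]
    if (length(pos)) min(pos) / 2 else 0
  })
  na_idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na_idx)) x[na_idx] <- half_min[na_idx[, 1L]]
  set_intensities(ft, x, stage = "impute", keep_rows = !all_missing)
}

#' Median normalization across samples
#'
#' Each sample column is multiplied by `reference / sample median`, the
#' reference being the median of all sample medians, so that every sample
#' median equals the reference afterwards. Medians are taken over all
#' features, including imputed cells.
#'
#' @param ft A [feature_table] without missing values.
#' @return The normalized [feature_table].
#' @export
normalize_median <- function(ft) {
  .check_stage(ft, "normalize")
  x <- intensity_matrix(ft)
  if (anyNA(x)) {
    stop("missing values present; impute (or drop) before normalizing",
         call. = FALSE)
  }
  med <- apply(x, 2L, median)
  if (any(med == 0)) {
    stop("sample(s) with median 0 cannot be normalized: ",
         paste(colnames(x)[med == 0], collapse = ", "), call. = FALSE)
  }
  reference <- median(med)
  x <- sweep(x, 2L, reference / med, `*`)
  set_intensities(ft, x, stage = "normalize")
}

#' Cube-root transform
#'
#' Elementwise `x^(1/3)` on non-negative intensities.
#'
#' @param ft A [feature_table].
#' @return The transformed [feature_table].
#' @export
transform_cube_root <- function(ft) {
  .check_stage(ft, "cube_root")
  x <- intensity_matrix(ft)
  if (any(x < 0, na.rm = TRUE)) {
    stop("negative intensities cannot be cube-root transformed", call. = FALSE)
  }
  set_intensities(ft, x^(1 / 3), stage = "cube_root")
}

#' Pareto scaling
#'
#' Per feature, `(x - mean) / sqrt(sd)` with the n-1 sample standard
#' deviation: the compromise between unit-variance and no scaling that
#' keeps each scaled feature's variance equal to its original standard
#' deviation. Constant features map to all-zero rows.
#'
#' @param ft A [feature_table] with at least two samples.
#' @return Numeric matrix, samples x features, ready for the multivariate
#'   models.
#' @export
scale_pareto <- function(ft) {
  x <- intensity_matrix(ft)
  if (ncol(x) < 2L) {
    stop("Pareto scaling needs at least two samples", call. = FALSE)
  }
  if (anyNA(x)) stop("missing values present; impute first", call. = FALSE)
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  constant <- s == 0
  if (any(constant)) {
    message(sum(constant), " constant feature(s) map to zero rows")
  }
  denom <- ifelse(constant, 1, sqrt(s))
  scaled <- (x - mu) / denom
  scaled[constant, ] <- 0
  t(scaled)
}

#' Run the full preprocessing chain
#'
#' Applies impute -> median-normalize -> cube-root in order (each stage
#' optional) and returns the processed table; use [scale_pareto()] on the
#' result to obtain the matrix for PCA/PLS-DA/clustering.
#'
#' @param ft A [feature_table].
#' @param impute,normalize,transform Stage switches (`"half_min"`/
#'   `"median"`/`"cube_root"` or `"none"`).
#' @return The processed [feature_table].
#' @export
preprocess <- function(ft,
                       impute = c("half_min", "none"),
                       normalize = c("median", "none"),
                       transform = c("cube_root", "none")) {
  impute <- match.arg(impute)
  normalize <- match.arg(normalize)
  transform <- match.arg(transform)
  if (impute == "half_min") ft <- impute_half_min(ft)
  if (normalize == "median") ft <- normalize_median(ft)
  if (transform == "cube_root") ft <- transform_cube_root(ft)
  ft
}
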