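#' Feature tables
#'
#' The pipeline's central object: an aligned LC-MS feature table. It is a
#' tibble with one row per ion feature, annotation columns `feature_id`,
#' `mz` (Da), `rt` (seconds), `mode` (`"positive"`/`"negative"`) and one
#' intensity column per sample, plus two attributes: `design`, a tibble
#' describing the samples (`sample_id`, `soil_type` in \{control, plant\},
#' `solution` in \{0, 50, 95\} % MeOH, `replicate`), and `processed`, the
#' ordered record of preprocessing stages already applied.
#'
#' @param features Tibble with columns `feature_id`, `mz`, `rt`, `mode`.
#' @param design Tibble with columns `sample_id`, `soil_type`, `solution`,
#'   `replicate`.
#' @param intensities Numeric matrix, features x samples; `NA` = missing.
#' @return A `feature_table` tibble.
#' @export
feature_table <- function(features, design, intensities) {
  features <- tibble::as_tibble(features)
  design <- tibble::as_tibble(design)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(features) ||
      ncol(intensities) != nrow(design)) {
    stop("intensity matrix is ", nrow(intensities), " x ", ncol(intensities),
         " but there are ", nrow(features), " features and ",
         nrow(design), " samples", call. = FALSE)
  }
  colnames(intensities) <- design$sample_id
  out <- dplyr::bind_cols(features, tibble::as_tibble(intensities))
  new_feature_table(out, design, processed = character())
}

# Internal constructor: attaches design/processed attributes and the class.
new_feature_table <- function(data, design, processed = character()) {
  data <- tibble::as_tibble(data)
  validate_design(design)
  out <- structure(
    data,
    design = tibble::as_tibble(design),
    processed = processed,
    class = c("feature_table", class(tibble::tibble()))
  )
  validate_feature_table(out)
  out
}

validate_design <- function(design) {
  required <- c("sample_id", "soil_type", "solution", "replicate")
  missing <- setdiff(required, names(design))
  if (length(missing)) {
    stop("sample design is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(design$soil_type), c("control", "plant"))
  if (length(bad)) {
    stop("soil_type must be 'control' or 'plant'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(design$solution), c(0, 50, 95))
  if (length(bad)) {
    stop("solution must be one of 0, 50, 95 (% MeOH); found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(design$replicate < 1)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  invisible(design)
}

validate_feature_table <- function(ft) {
  required <- c("feature_id", "mz", "rt", "mode")
  missing <- setdiff(required, names(ft))
  if (length(missing)) {
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ft$feature_id)) {
    stop("duplicate feature_id: ",
         paste(utils::head(unique(ft$feature_id[duplicated(ft$feature_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (any(ft$mz <= 0)) stop("mz must be > 0", call. = FALSE)
  if (any(ft$rt < 0)) stop("rt must be >= 0", call. = FALSE)
  bad <- setdiff(unique(ft$mode), c("positive", "negative"))
  if (length(bad)) {
    stop("mode must be 'positive' or 'negative'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  design <- attr(ft, "design")
  missing_samples <- setdiff(design$sample_id, names(ft))
  if (length(missing_samples)) {
    stop("design sample(s) absent from table: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  x <- intensity_matrix(ft)
  if (any(x < 0, na.rm = TRUE)) {
    stop("negative intensities are not allowed", call. = FALSE)
  }
  invisible(ft)
}

#' @rdname feature_table
#' @param ft A `feature_table`.
#' @export
sample_design <- function(ft) attr(ft, "design")

#' @rdname feature_table
#' @export
processed_stages <- function(ft) attr(ft, "processed") %||% character()

#' Extract the intensity matrix of a feature table
#'
#' @param ft A `feature_table`.
#' @param samples_as_rows Return samples x features instead of the stored
#'   features x samples orientation.
#' @return Numeric matrix with dimnames from feature ids and sample ids.
#' @export
intensity_matrix <- function(ft, samples_as_rows = FALSE) {
  design <- sample_design(ft)
  x <- as.matrix(as.data.frame(ft)[, design$sample_id, drop = FALSE])
  rownames(x) <- ft$feature_id
  if (samples_as_rows) t(x) else x
}

# Replace intensities, keep annotation/design, append stage to the record.
set_intensities <- function(ft, x, stage = NULL, keep_rows = NULL) {
  design <- sample_design(ft)
  ann <- as.data.frame(ft)[, c("feature_id", "mz", "rt", "mode"), drop = FALSE]
  if (!is.null(keep_rows)) ann <- ann[keep_rows, , drop = FALSE]
  stopifnot(nrow(x) == nrow(ann))
  colnames(x) <- design$sample_id
  out <- dplyr::bind_cols(tibble::as_tibble(ann), tibble::as_tibble(x))
  new_feature_table(out, design,
                    processed = c(processed_stages(ft), stage))
}

#' @export
print.feature_table <- function(x, ...) {
  design <- sample_design(x)
  cat("# feature_table: ", nrow(x), " features x ", nrow(design),
      " samples (", sum(design$soil_type == "plant"), " plant / ",
      sum(design$soil_type == "control"), " control)\n", sep = "")
  stages <- processed_stages(x)
  if (length(stages)) cat("# processed: ", paste(stages, collapse = " -> "),
                          "\n", sep = "")
  NextMethod()
}
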