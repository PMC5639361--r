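# Readers and writers for the pipeline's tabular formats. Delimiter is taken
# from the file extension (.csv comma, .tsv tab) -- no sniffing, so that a
# given path always parses the same way.

.delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = ",",
    tsv = "\t",
    stop("unsupported extension '.", ext, "' (use .csv or .tsv): ", path,
         call. = FALSE)
  )
}

.read_delim_quiet <- function(path, ...) {
  readr::read_delim(path, delim = .delim_for(path), show_col_types = FALSE,
                    progress = FALSE, na = c("", "NA"), ...)
}

#' Read an aligned LC-MS feature table
#'
#' Expects a CSV/TSV with header columns `feature_id`, `mz`, `rt` (seconds),
#' `mode` (`positive`/`negative`) followed by one intensity column per
#' sample. Empty cells and `NA` are stored as missing, never as zero.
#'
#' @param path Path to a `.csv` or `.tsv` file.
#' @param design Sample design: a tibble (or path to a CSV/TSV) with columns
#'   `sample_id`, `soil_type`, `solution`, `replicate`. If `NULL`, sample
#'   ids must follow the `<soil_type>_<solution>_<replicate>` convention
#'   used by [write_feature_table()] and the design is reconstructed.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, design = NULL) {
  raw <- .read_delim_quiet(path)
  required <- c("feature_id", "mz", "rt", "mode")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("feature table file is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sample_ids <- setdiff(names(raw), required)
  if (!length(sample_ids)) stop("no sample columns found", call. = FALSE)
  if (is.character(design) && length(design) == 1L) {
    design <- .read_delim_quiet(design)
  }
  if (is.null(design)) design <- .design_from_ids(sample_ids)
  design <- tibble::as_tibble(design)
  design <- design[match(sample_ids, design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) {
    stop("design does not cover all sample columns", call. = FALSE)
  }
  x <- as.matrix(raw[, sample_ids, drop = FALSE])
  storage.mode(x) <- "double"
  feature_table(raw[, required], design, x)
}

.design_from_ids <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  ok <- lengths(parts) == 3L
  if (!all(ok)) {
    stop("cannot infer design from sample id(s) ",
         paste(ids[!ok], collapse = ", "),
         "; supply `design` explicitly", call. = FALSE)
  }
  tibble::tibble(
    sample_id = ids,
    soil_type = vapply(parts, `[`, "", 1L),
    solution = as.numeric(vapply(parts, `[`, "", 2L)),
    replicate = as.integer(vapply(parts, `[`, "", 3L))
  )
}

#' Write a feature table (and optionally its design) to disk
#'
#' @param ft A [feature_table].
#' @param path Output `.csv` or `.tsv` path.
#' @param design_path Optional path for the sample-design table.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, design_path = NULL) {
  readr::write_delim(as.data.frame(ft), path, delim = .delim_for(path),
                     na = "NA")
  if (!is.null(design_path)) {
    readr::write_delim(sample_design(ft), design_path,
                       delim = .delim_for(design_path), na = "NA")
  }
  invisible(path)
}

#' Read a compound library
#'
#' A CSV/TSV with columns `name`, `formula`, `monoisotopic_mass` (may be
#' empty when `formula` is given), `met_class` and `plausible_in_soil`.
#' Masses are recomputed from formulas; a stated mass deviating more than
#' 0.001 Da from its formula mass is rejected.
#'
#' @param path Path to the library file.
#' @return Tibble of validated compound records.
#' @export
read_compound_library <- function(path) {
  lib <- .read_delim_quiet(path)
  required <- c("name", "formula", "met_class", "plausible_in_soil")
  missing <- setdiff(required, names(lib))
  if (length(missing)) {
    stop("compound library is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"monoisotopic_mass" %in% names(lib)) lib$monoisotopic_mass <- NA_real_
  lib$name <- .nfc(lib$name)
  has_formula <- !is.na(lib$formula) & nzchar(lib$formula)
  has_mass <- !is.na(lib$monoisotopic_mass)
  if (any(!has_formula & !has_mass)) {
    stop("record(s) with neither monoisotopic_mass nor formula: ",
         paste(lib$name[!has_formula & !has_mass], collapse = ", "),
         call. = FALSE)
  }
  formula_mass <- rep(NA_real_, nrow(lib))
  formula_mass[has_formula] <- mass_from_formula(lib$formula[has_formula])
  both <- has_formula & has_mass
  off <- both & abs(lib$monoisotopic_mass - formula_mass) > 0.001
  if (any(off)) {
    stop("stated mass disagrees with formula mass (> 0.001 Da) for: ",
         paste(lib$name[off], collapse = ", "), call. = FALSE)
  }
  lib$monoisotopic_mass <- ifelse(has_formula, formula_mass,
                                  lib$monoisotopic_mass)
  if (any(lib$monoisotopic_mass <= 0)) {
    stop("monoisotopic_mass must be > 0", call. = FALSE)
  }
  lib$plausible_in_soil <- as.logical(lib$plausible_in_soil)
  tibble::as_tibble(lib[, c("name", "formula", "monoisotopic_mass",
                            "met_class", "plausible_in_soil")])
}

.nfc <- function(x) {
  # NFC-normalize compound names; benzoxazinoid names carry Unicode dashes.
  out <- enc2utf8(x)
  iconv(out, from = "UTF-8", to = "UTF-8")
}

#' Bundled soil-metabolite reference library
#'
#' A small curated library spanning the metabolite classes relevant to
#' rhizosphere soil -- benzoxazinoids (HBOA, DIBOA, HMBOA, DIMBOA),
#' flavonoids, phenylpropanoids, lipids, alkaloids, organic and amino
#' acids, sugars and miscellaneous compounds -- plus deliberately
#' implausible decoys (synthetic drugs, mammalian hormones) exercising the
#' plausibility exclusion. Masses are computed from formulas at load time.
#'
#' @return Tibble of compound records (see [read_compound_library()]).
#' @export
soil_compound_library <- function() {
  path <- system.file("extdata", "soil_compound_library.csv",
                      package = "rhizomarker", mustWork = TRUE)
  read_compound_library(path)
}

#' Read an OTU count table
#'
#' TSV/CSV with OTUs as rows; first column `otu_id`, optional column
#' `taxonomy`, remaining columns per-sample integer counts.
#'
#' @param path Path to the table.
#' @param groups Optional named character vector or tibble
#'   (`sample_id`, `group`) assigning each sample to
#'   `root_rhizosphere`/`control_soil`.
#' @return List with `counts` (integer matrix, OTUs x samples), `taxonomy`
#'   (character or NULL) and `groups` (named character or NULL).
#' @export
read_otu_table <- function(path, groups = NULL) {
  raw <- .read_delim_quiet(path)
  if (names(raw)[1] != "otu_id") {
    stop("first column must be 'otu_id'", call. = FALSE)
  }
  taxonomy <- NULL
  if ("taxonomy" %in% names(raw)) {
    taxonomy <- setNames(raw$taxonomy, raw$otu_id)
    raw$taxonomy <- NULL
  }
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- raw$otu_id
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("OTU counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$sample_id)
  if (!is.null(groups)) groups <- groups[colnames(counts)]
  list(counts = counts, taxonomy = taxonomy, groups = groups)
}

#' Read a square distance matrix from CSV/TSV
#'
#' First column holds sample ids; header repeats them. Lets externally
#' computed distances (e.g. UniFrac) feed [permanova()].
#'
#' @param path Path to the matrix file.
#' @return A symmetric numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  raw <- .read_delim_quiet(path)
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  m
}

#' Write a pipeline result to JSON or TSV
#'
#' Tabular results (tibbles) serialize row-wise with their column order
#' preserved; list results serialize as nested JSON. Field order is
#' deterministic and re-reading reproduces the numbers exactly
#' (`digits = NA`).
#'
#' @param results A tibble or list produced by the pipeline.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(results)) {
      stop("TSV output requires a tabular result; use format = 'json'",
           call. = FALSE)
    }
    readr::write_tsv(tibble::as_tibble(results), path, na = "NA")
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
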