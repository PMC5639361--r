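# End-to-end orchestration of the two published workflow shapes: the
# three-solution Arabidopsis-style design (6 volcano plots, top-20
# pooling) and the single-solution maize-style design (2 plots, top-50).

#' Pipeline configuration
#'
#' Bundles the synthetic-data settings, selection thresholds and
#' deconvolution tolerances for [run_differential_workflow()]. The
#' `arabidopsis` mode expects 3 solutions x 2 ionization modes (6 plots,
#' `top_k = 20`); the `maize` mode 1 solution x 2 modes (2 plots,
#' `top_k = 50`); `custom` accepts any design.
#'
#' @param mode `"arabidopsis"`, `"maize"` or `"custom"`.
#' @param synth A [synth_config()]; its `solutions` must match the mode.
#' @param selection A [selection_params()]; defaults to top-20 for
#'   arabidopsis, top-50 for maize.
#' @param deconv A [deconv_params()].
#' @param library Compound library tibble for annotation.
#' @param seed Top-level seed; overrides `synth$seed` so one seed drives
#'   the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("arabidopsis", "maize", "custom"),
                            synth = NULL, selection = NULL,
                            deconv = deconv_params(), library = NULL,
                            seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(synth)) {
    synth <- switch(mode,
      arabidopsis = synth_config(solutions = c(0, 50, 95), seed = seed),
      maize = synth_config(solutions = 50, seed = seed),
      custom = synth_config(seed = seed)
    )
  }
  synth$seed <- as.integer(seed)
  if (is.null(selection)) {
    selection <- selection_params(top_k = if (mode == "maize") 50 else 20)
  }
  n_sol <- length(synth$solutions)
  if (mode == "arabidopsis" && n_sol != 3) {
    stop("arabidopsis mode expects 3 extraction solutions, got ", n_sol,
         call. = FALSE)
  }
  if (mode == "maize" && n_sol != 1) {
    stop("maize mode expects a single extraction solution, got ", n_sol,
         call. = FALSE)
  }
  structure(list(mode = mode, synth = synth, selection = selection,
                 deconv = deconv, library = library, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the differential-metabolite workflow end to end
#'
#' For every solution x ionization mode dataset: simulate (or accept) a
#' feature table, impute and median-normalize, compute Welch volcano
#' statistics, and fit the multivariate models on the fully processed
#' (cube-root + Pareto) matrix. Qualifying ions are pooled top-k per plot
#' in each direction, refined by ANOVA with Benjamini-Hochberg FDR,
#' deconvolved into adduct/isotope groups per plot, annotated against the
#' compound library, and summarized as metabolite-class compositions.
#' Identical (config, seed) reruns give identical reports.
#'
#' @param config A [pipeline_config()].
#' @param tables Optional named list of raw [feature_table]s keyed by plot
#'   id (`sol<solution>_<mode>`); when `NULL`, tables are simulated from
#'   `config$synth`.
#' @return A `marker_report` list: `volcanoes`, `tables` (processed),
#'   `multivariate`, `markers` (per direction, refined), `groups`,
#'   `annotations`, `composition`, `truth` (when simulated) and `config`.
#' @export
run_differential_workflow <- function(config, tables = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  synth <- config$synth
  plot_ids <- as.vector(outer(synth$solutions, c("positive", "negative"),
                              function(s, m) sprintf("sol%d_%s", s, m)))
  truth <- NULL
  if (is.null(tables)) {
    sims <- purrr::map(plot_ids, function(id) {
      parts <- strsplit(id, "_", fixed = TRUE)[[1]]
      simulate_feature_table(synth,
                             solution = as.numeric(sub("sol", "", parts[1])),
                             mode = parts[2], library = config$library)
    })
    names(sims) <- plot_ids
    tables <- purrr::map(sims, "table")
    truth <- purrr::map(sims, "truth")
  } else {
    missing <- setdiff(plot_ids, names(tables))
    if (length(missing)) {
      stop("config expects plot id(s) ", paste(missing, collapse = ", "),
           " but tables lack them", call. = FALSE)
    }
    tables <- tables[plot_ids]
  }

  normalized <- purrr::map(tables, function(ft) {
    ft |> impute_half_min() |> normalize_median()
  })
  volcanoes <- purrr::map(normalized, volcano_welch)

  multivariate <- purrr::imap(normalized, function(ft, id) {
    x <- scale_pareto(transform_cube_root(ft))
    design <- sample_design(ft)
    pca <- fit_pca(x, n_components = min(3, nrow(x) - 1))
    pls <- fit_plsda(x, design$soil_type, n_components = 2)
    tibble::tibble(plot_id = id,
                   pc1_pct = pca$explained_pct[1],
                   pc2_pct = pca$explained_pct[2],
                   pc3_pct = pca$explained_pct[3],
                   r2 = pls$r2, q2 = pls$q2)
  }) |> dplyr::bind_rows()

  markers <- list()
  groups <- list()
  annotations <- list()
  composition <- list()
  lib <- config$library %||% soil_compound_library()
  for (dir in c("plant", "control")) {
    pooled <- pool_top_k(volcanoes, config$selection, direction = dir)
    refined <- refine_markers_anova(pooled, normalized,
                                    alpha = config$selection$anova_alpha)
    markers[[dir]] <- refined
    kept <- refined[refined$kept, , drop = FALSE]
    if (nrow(kept)) {
      grp <- purrr::map(split(kept, kept$plot_id), function(sub) {
        group_adducts(sub, config$deconv)
      })
      grp_all <- dplyr::bind_rows(grp, .id = "plot_id")
      grp_all$group_id <- sprintf("%s_%s", grp_all$plot_id, grp_all$group_id)
      groups[[dir]] <- grp_all
      ann <- annotate_groups(grp_all, lib,
                             match_tol = config$deconv$mz_tol)
      annotations[[dir]] <- ann
      composition[[dir]] <- tryCatch(class_composition(ann),
                                     error = function(e) NULL)
    }
  }

  structure(
    list(volcanoes = volcanoes, tables = normalized,
         multivariate = multivariate, markers = markers, groups = groups,
         annotations = annotations, composition = composition,
         truth = truth, config = config),
    class = "marker_report"
  )
}

#' @export
print.marker_report <- function(x, ...) {
  cat("Differential-metabolite workflow (", x$config$mode, " design, seed ",
      x$config$seed, ")\n", sep = "")
  cat("  plots:", paste(names(x$volcanoes), collapse = ", "), "\n")
  for (dir in names(x$markers)) {
    m <- x$markers[[dir]]
    cat(sprintf("  %s: %d pooled candidates, %d kept after ANOVA/BH\n",
                dir, nrow(m), sum(m$kept)))
  }
  invisible(x)
}

#' Run the microbial-diversity workflow
#'
#' Prevalence-filters an OTU table, computes per-sample Shannon diversity
#' and richness, rarefaction curves, Bray-Curtis distances and a seeded
#' PERMANOVA of the group labels.
#'
#' @param counts Integer OTU x sample count matrix; `NULL` to simulate.
#' @param groups Named group vector (required with `counts`).
#' @param n_perm PERMANOVA permutations.
#' @param rarefy_depths Depths for the rarefaction curves (default: 5
#'   points up to the smallest sample total).
#' @param rarefy_reps Subsamples per depth.
#' @param seed Top-level seed (drives simulation, rarefaction and
#'   PERMANOVA).
#' @param ... Passed to [simulate_otu_table()] when simulating.
#' @return A `diversity_report` list: `filtered_counts`, `alpha`
#'   (tibble), `rarefaction` (tibble), `distances`, `permanova`.
#' @export
run_diversity_workflow <- function(counts = NULL, groups = NULL,
                                   n_perm = 999, rarefy_depths = NULL,
                                   rarefy_reps = 50, seed = 1L, ...) {
  if (is.null(counts)) {
    sim <- simulate_otu_table(seed = seed, ...)
    counts <- sim$counts
    groups <- sim$groups
  }
  if (is.null(groups)) stop("groups are required", call. = FALSE)
  groups <- groups[colnames(counts)]
  if (any(table(groups) < 2)) {
    stop("every group needs at least two samples", call. = FALSE)
  }
  filtered <- filter_prevalence(counts)
  if (!nrow(filtered)) stop("no OTUs survive the prevalence filter",
                            call. = FALSE)
  alpha <- tibble::tibble(
    sample_id = colnames(filtered),
    group = as.character(groups),
    shannon = apply(filtered, 2L, shannon_index),
    richness = apply(filtered, 2L, otu_richness)
  )
  totals <- colSums(filtered)
  if (is.null(rarefy_depths)) {
    rarefy_depths <- unique(round(seq(min(totals) / 5, min(totals),
                                      length.out = 5)))
  }
  rarefaction <- purrr::imap(
    setNames(seq_len(ncol(filtered)), colnames(filtered)),
    function(j, sid) {
      dplyr::mutate(
        rarefaction_curve(filtered[, j], rarefy_depths[rarefy_depths <=
                                                         totals[j]],
                          reps = rarefy_reps, seed = seed + j),
        sample_id = sid, .before = 1)
    }) |> dplyr::bind_rows()
  distances <- bray_curtis(filtered)
  perm <- permanova(distances, groups, n_perm = n_perm, seed = seed)
  structure(
    list(filtered_counts = filtered, alpha = alpha,
         rarefaction = rarefaction, distances = distances,
         permanova = perm, seed = as.integer(seed)),
    class = "diversity_report"
  )
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("Diversity workflow:", nrow(x$filtered_counts), "OTUs after filtering,",
      ncol(x$filtered_counts), "samples\n")
  print(x$permanova)
  invisible(x)
}
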