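# The marker-selection funnel: per-ion Welch volcano statistics on imputed,
# median-normalized (untransformed) intensities; strict P/fold-change
# cut-offs; top-k pooling per volcano plot; and one-way ANOVA with
# Benjamini-Hochberg FDR refinement of the pooled candidates.

#' Selection parameters for the marker funnel
#'
#' Defaults follow the published cut-offs: Welch P < 0.01, fold change > 2
#' (both strict), top 20 ions per volcano plot (50 for the single-solution
#' crop workflow) and an FDR level of 0.01 for the ANOVA refinement.
#' Within a plot, qualifying ions are ranked by ascending P, ties broken
#' by descending |log2 FC| then feature id; `rank_by = "fc"` swaps the
#' first two keys.
#'
#' @param p_thresh Significance level for the volcano cut (strict `<`).
#' @param fc_thresh Fold-change cut (strict `>`, on the intensity scale).
#' @param top_k Ions pooled per volcano plot.
#' @param anova_alpha FDR level for the ANOVA/BH refinement.
#' @param rank_by `"p"` (default) or `"fc"` primary ranking key.
#' @return A `selection_params` list.
#' @export
selection_params <- function(p_thresh = 0.01, fc_thresh = 2, top_k = 20,
                             anova_alpha = 0.01, rank_by = c("p", "fc")) {
  rank_by <- match.arg(rank_by)
  if (p_thresh <= 0 || p_thresh >= 1) stop("p_thresh must be in (0, 1)",
                                           call. = FALSE)
  if (fc_thresh <= 1) stop("fc_thresh must exceed 1", call. = FALSE)
  if (top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  structure(list(p_thresh = p_thresh, fc_thresh = fc_thresh,
                 top_k = as.integer(top_k), anova_alpha = anova_alpha,
                 rank_by = rank_by),
            class = "selection_params")
}

#' Per-ion Welch volcano statistics
#'
#' Two-sided Welch unequal-variance t-test of plant vs control intensities
#' for every ion, with `log2fc = log2(mean_plant / mean_control)` from the
#' arithmetic group means. Run this on the imputed, median-normalized
#' table (fold changes are intensity-scale quantities; do not cube-root or
#' Pareto scale first). Ions with zero variance and equal means in both
#' groups get `t = 0`, `p = 1`.
#'
#' @param ft A [feature_table] (imputed, median-normalized).
#' @return A `volcano_result` tibble: `feature_id`, `mz`, `rt`, `mode`,
#'   `mean_plant`, `mean_control`, `log2fc`, `t`, `df`, `p`,
#'   `neg_log10_p`, `direction`.
#' @export
volcano_welch <- function(ft) {
  design <- sample_design(ft)
  x <- intensity_matrix(ft)
  if (anyNA(x)) stop("missing values present; impute first", call. = FALSE)
  p_idx <- design$soil_type == "plant"
  c_idx <- design$soil_type == "control"
  if (sum(p_idx) < 2 || sum(c_idx) < 2) {
    stop("both soil types need at least two replicates", call. = FALSE)
  }
  w <- .welch_t_rows(x[, p_idx, drop = FALSE], x[, c_idx, drop = FALSE])
  log2fc <- log2(w$mean1 / w$mean2)
  log2fc[w$mean1 == w$mean2] <- 0
  out <- tibble::tibble(
    feature_id = ft$feature_id, mz = ft$mz, rt = ft$rt, mode = ft$mode,
    mean_plant = unname(w$mean1), mean_control = unname(w$mean2),
    log2fc = unname(log2fc), t = unname(w$t), df = unname(w$df),
    p = unname(w$p),
    neg_log10_p = -log10(w$p),
    direction = dplyr::case_when(log2fc > 0 ~ "plant",
                                 log2fc < 0 ~ "control",
                                 TRUE ~ "none")
  )
  class(out) <- c("volcano_result", class(out))
  out
}

#' Select enriched ions from volcano statistics
#'
#' Plant-enriched ions satisfy `p < p_thresh` and `log2fc >
#' log2(fc_thresh)`; control-enriched ions the mirror condition. Both
#' inequalities are strict, as the published cut-offs are printed.
#'
#' @param volcano A `volcano_result` tibble from [volcano_welch()].
#' @param params A [selection_params()].
#' @return List with character vectors `plant` and `control` of feature
#'   ids.
#' @export
select_enriched <- function(volcano, params = selection_params()) {
  if (!nrow(volcano)) stop("empty volcano results", call. = FALSE)
  lfc <- log2(params$fc_thresh)
  list(
    plant = volcano$feature_id[volcano$p < params$p_thresh &
                                 volcano$log2fc > lfc],
    control = volcano$feature_id[volcano$p < params$p_thresh &
                                   volcano$log2fc < -lfc]
  )
}

#' Presence/absence accounting of detected ions
#'
#' Works on the raw (unimputed) table: an ion is "present" in a soil type
#' if its intensity is positive and non-missing in at least one sample of
#' that type. Detected ions partition into plant-only, control-only and
#' shared.
#'
#' @param ft A raw [feature_table].
#' @return Tibble with one row per category (`plant_only`, `control_only`,
#'   `shared`) carrying `n` and `pct` of detected ions.
#' @export
presence_overlap <- function(ft) {
  design <- sample_design(ft)
  x <- intensity_matrix(ft)
  present_plant <- rowSums(
    x[, design$soil_type == "plant", drop = FALSE] > 0, na.rm = TRUE) > 0
  present_ctrl <- rowSums(
    x[, design$soil_type == "control", drop = FALSE] > 0, na.rm = TRUE) > 0
  detected <- present_plant | present_ctrl
  n <- c(plant_only = sum(present_plant & !present_ctrl),
         control_only = sum(present_ctrl & !present_plant),
         shared = sum(present_plant & present_ctrl))
  tibble::tibble(category = names(n), n = as.integer(n),
                 pct = if (sum(detected)) 100 * as.integer(n) / sum(detected)
                       else rep(0, 3))
}

.rank_qualifying <- function(v, params, direction) {
  lfc <- log2(params$fc_thresh)
  keep <- v$p < params$p_thresh &
    (if (direction == "plant") v$log2fc > lfc else v$log2fc < -lfc)
  q <- v[keep, , drop = FALSE]
  ord <- if (params$rank_by == "p") {
    order(q$p, -abs(q$log2fc), q$feature_id)
  } else {
    order(-abs(q$log2fc), q$p, q$feature_id)
  }
  q[ord, , drop = FALSE]
}

#' Pool the top-k ions of each volcano plot
#'
#' Within each plot, ions passing both cut-offs in the requested direction
#' are ranked and the first `top_k` taken (all of them, with a warning, if
#' fewer qualify). The pooled candidate set is the union across plots;
#' because every plot is its own alignment namespace, entries from
#' different plots stay distinct.
#'
#' @param volcanoes Named list of `volcano_result` tibbles, one per plot
#'   (solution x ionization mode); names are the plot ids.
#' @param params A [selection_params()].
#' @param direction `"plant"` or `"control"`.
#' @return A `marker_set` tibble: `plot_id`, `feature_id`, `mz`, `rt`,
#'   `mode`, `rank`, `log2fc`, `p`, `direction`.
#' @export
pool_top_k <- function(volcanoes, params = selection_params(),
                       direction = c("plant", "control")) {
  direction <- match.arg(direction)
  if (!length(volcanoes)) stop("empty volcano plot list", call. = FALSE)
  if (is.null(names(volcanoes)) || any(!nzchar(names(volcanoes)))) {
    stop("volcanoes must be a named list (plot ids)", call. = FALSE)
  }
  pooled <- purrr::imap(volcanoes, function(v, id) {
    q <- .rank_qualifying(v, params, direction)
    if (nrow(q) < params$top_k) {
      warning("plot '", id, "': only ", nrow(q), " of ", params$top_k,
              " requested ions qualify", call. = FALSE)
    }
    q <- utils::head(q, params$top_k)
    if (!nrow(q)) return(NULL)
    tibble::tibble(plot_id = id, feature_id = q$feature_id, mz = q$mz,
                   rt = q$rt, mode = q$mode, rank = seq_len(nrow(q)),
                   log2fc = q$log2fc, p = q$p, direction = direction)
  })
  out <- dplyr::bind_rows(pooled)
  class(out) <- c("marker_set", class(out))
  out
}

#' Refine pooled markers by one-way ANOVA with Benjamini-Hochberg FDR
#'
#' Each candidate ion is tested by a classical equal-variance one-way
#' F-test across the soil x solution groups available in its own dataset;
#' the resulting P-values are BH-adjusted over the candidate pool (one
#' direction at a time) and candidates with `q < alpha` are kept. A
#' heteroscedastic Welch ANOVA is available behind `welch = TRUE`.
#'
#' @param markers A `marker_set` from [pool_top_k()].
#' @param tables Named list of imputed/normalized [feature_table]s keyed by
#'   plot id (the tables the candidates came from).
#' @param alpha FDR level (default 0.01).
#' @param welch Use Welch's heteroscedastic ANOVA instead of the classical
#'   F-test.
#' @return The `marker_set` with columns `anova_p`, `bh_q` and `kept`.
#' @export
refine_markers_anova <- function(markers, tables, alpha = 0.01,
                                 welch = FALSE) {
  if (!nrow(markers)) stop("empty marker set", call. = FALSE)
  missing <- setdiff(unique(markers$plot_id), names(tables))
  if (length(missing)) {
    stop("no table supplied for plot id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  anova_p <- rep(NA_real_, nrow(markers))
  for (id in unique(markers$plot_id)) {
    ft <- tables[[id]]
    design <- sample_design(ft)
    groups <- interaction(design$soil_type, design$solution, drop = TRUE)
    rows <- which(markers$plot_id == id)
    x <- intensity_matrix(ft)
    idx <- match(markers$feature_id[rows], rownames(x))
    if (anyNA(idx)) {
      stop("candidate ion(s) absent from table '", id, "'", call. = FALSE)
    }
    xm <- x[idx, , drop = FALSE]
    if (welch) {
      anova_p[rows] <- vapply(seq_len(nrow(xm)), function(i) {
        vals <- split(xm[i, ], groups)
        .welch_f_from_stats(vapply(vals, mean, 0), vapply(vals, var, 0),
                            lengths(vals), var_floor = 1e-12)$p
      }, numeric(1))
    } else {
      anova_p[rows] <- .oneway_f_rows(xm, groups)$p
    }
  }
  markers$anova_p <- anova_p
  markers$bh_q <- p.adjust(anova_p, method = "BH")
  markers$kept <- markers$bh_q < alpha
  markers
}
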