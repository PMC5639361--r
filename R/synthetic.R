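# Seeded generators with known ground truth. They emulate the study design
# the pipeline was built for: aligned feature tables for two soil conditions
# (5 plant vs 3 control replicates) per extraction solution and ionization
# mode, OTU count tables with a group effect, and small replicate assays.
# All generators are pure functions of (parameters, seed).

#' Configuration for the synthetic feature-table generator
#'
#' Defaults encode the study conditions the pipeline targets: 5 plant vs 3
#' control replicates, log-normal baseline intensities (log10-mean 4,
#' log10-sd 0.8, a typical untargeted LC-MS dynamic range), multiplicative
#' replicate noise with CV 0.2, condition-enriched ions with |log2 FC|
#' drawn from [1.5, 4], and inflated variance for the 95% MeOH solution,
#' which showed the highest between-replicate variation.
#'
#' @param n_features_per_mode Ion features per ionization mode.
#' @param n_plant,n_control Replicates per soil type.
#' @param solutions Extraction solutions (% MeOH) to simulate.
#' @param frac_enriched_plant,frac_enriched_control Fractions of features
#'   truly enriched in each soil type; must sum to at most 1.
#' @param log2fc_range Interval for true |log2 fold changes|; lower bound
#'   must exceed 1 so spiked ions can pass the >2-fold cut.
#' @param replicate_cv Coefficient of variation of multiplicative replicate
#'   noise.
#' @param missing_rate Fraction of cells set missing completely at random.
#' @param extra_variance_95 CV multiplier (>= 1) applied when solution = 95.
#' @param baseline_log10_mean,baseline_log10_sd Log10 location/spread of
#'   baseline mean intensities.
#' @param isotope_fraction Intensity of a 13C isotopologue relative to its
#'   parent ion when compounds are spiked.
#' @param n_spiked_compounds Library compounds spiked with adduct/isotope
#'   sibling structure per generated table.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_features_per_mode = 4000,
                         n_plant = 5, n_control = 3,
                         solutions = c(0, 50, 95),
                         frac_enriched_plant = 0.05,
                         frac_enriched_control = 0.05,
                         log2fc_range = c(1.5, 4),
                         replicate_cv = 0.2,
                         missing_rate = 0.02,
                         extra_variance_95 = 1.5,
                         baseline_log10_mean = 4,
                         baseline_log10_sd = 0.8,
                         isotope_fraction = 0.10,
                         n_spiked_compounds = 0,
                         seed = 1L) {
  cfg <- list(
    n_features_per_mode = as.integer(n_features_per_mode),
    n_plant = as.integer(n_plant), n_control = as.integer(n_control),
    solutions = solutions,
    frac_enriched_plant = frac_enriched_plant,
    frac_enriched_control = frac_enriched_control,
    log2fc_range = log2fc_range,
    replicate_cv = replicate_cv,
    missing_rate = missing_rate,
    extra_variance_95 = extra_variance_95,
    baseline_log10_mean = baseline_log10_mean,
    baseline_log10_sd = baseline_log10_sd,
    isotope_fraction = isotope_fraction,
    n_spiked_compounds = as.integer(n_spiked_compounds),
    seed = as.integer(seed)
  )
  if (cfg$frac_enriched_plant < 0 || cfg$frac_enriched_control < 0 ||
      cfg$frac_enriched_plant + cfg$frac_enriched_control > 1) {
    stop("enriched fractions must be >= 0 and sum to at most 1",
         call. = FALSE)
  }
  if (cfg$log2fc_range[1] <= 1) {
    stop("log2fc_range lower bound must exceed 1 (the >2-fold cut)",
         call. = FALSE)
  }
  if (!all(cfg$solutions %in% c(0, 50, 95))) {
    stop("solutions must be drawn from {0, 50, 95}", call. = FALSE)
  }
  if (cfg$n_plant < 1 || cfg$n_control < 1) {
    stop("n_plant and n_control must be positive", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

# Deterministic per-(solution, mode) seed fan-out from the top-level seed.
.stage_seed <- function(seed, solution, mode) {
  sol_idx <- match(solution, c(0, 50, 95))
  mode_idx <- match(mode, c("positive", "negative"))
  (as.integer(seed) * 101L + sol_idx * 13L + mode_idx * 7L) %% 2147483629L
}

# Multiplicative log-normal noise with mean 1 and coefficient of variation cv.
.rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate an aligned feature table with known ground truth
#'
#' Baseline feature mean intensities are log-normal; a configurable
#' fraction of features is enriched in one soil type with plant:control
#' mean ratio `2^f`, `f` drawn from `log2fc_range` (negative for
#' control-enriched ions); replicate noise is multiplicative log-normal
#' with the configured CV (inflated by `extra_variance_95` at 95% MeOH);
#' missing values are inserted completely at random. Feature m/z is uniform
#' on [80, 1200] Da and RT uniform on [30, 900] s. When
#' `n_spiked_compounds > 0`, that many library compounds are spiked with
#' full adduct/isotope sibling structure via [spike_compound_ions()],
#' alternating enrichment direction.
#'
#' @param config A [synth_config()].
#' @param solution Extraction solution (% MeOH) of this table.
#' @param mode Ionization mode, `"positive"` or `"negative"`.
#' @param library Compound library used when spiking (default the bundled
#'   [soil_compound_library()], plausible entries only).
#' @return List with `table` (a [feature_table]) and `truth` (list:
#'   `enriched_plant_ids`, `enriched_control_ids`, `true_log2fc` named
#'   vector, `spiked_groups` tibble, `adduct_collision_rate`).
#' @export
simulate_feature_table <- function(config, solution = 50,
                                   mode = c("positive", "negative"),
                                   library = NULL) {
  stopifnot(inherits(config, "synth_config"))
  mode <- match.arg(mode)
  if (!solution %in% config$solutions) {
    stop("solution ", solution, " not in config$solutions", call. = FALSE)
  }
  seed <- .stage_seed(config$seed, solution, mode)
  set.seed(seed)

  n <- config$n_features_per_mode
  n_p <- config$n_plant
  n_c <- config$n_control
  tag <- paste0(substr(mode, 1, 3), solution)
  ids <- sprintf("%s_f%05d", tag, seq_len(n))
  mz <- runif(n, 80, 1200)
  rt <- runif(n, 30, 900)

  n_plant_enr <- round(config$frac_enriched_plant * n)
  n_ctrl_enr <- round(config$frac_enriched_control * n)
  idx_plant <- seq_len(n_plant_enr)
  idx_ctrl <- seq_len(n_ctrl_enr) + n_plant_enr
  true_fc <- rep(0, n)
  if (n_plant_enr) {
    true_fc[idx_plant] <- runif(n_plant_enr, config$log2fc_range[1],
                                config$log2fc_range[2])
  }
  if (n_ctrl_enr) {
    true_fc[idx_ctrl] <- -runif(n_ctrl_enr, config$log2fc_range[1],
                                config$log2fc_range[2])
  }

  base_mean <- 10^rnorm(n, config$baseline_log10_mean,
                        config$baseline_log10_sd)
  mean_plant <- base_mean * 2^(pmax(true_fc, 0))
  mean_ctrl <- base_mean * 2^(-pmin(true_fc, 0))

  cv <- config$replicate_cv *
    if (solution == 95) config$extra_variance_95 else 1
  x <- cbind(
    matrix(mean_plant, n, n_p) * .rlnorm_cv(n * n_p, cv),
    matrix(mean_ctrl, n, n_c) * .rlnorm_cv(n * n_c, cv)
  )
  if (config$missing_rate > 0) {
    x[runif(length(x)) < config$missing_rate] <- NA_real_
  }

  design <- tibble::tibble(
    sample_id = c(sprintf("plant_%d_%d", solution, seq_len(n_p)),
                  sprintf("control_%d_%d", solution, seq_len(n_c))),
    soil_type = c(rep("plant", n_p), rep("control", n_c)),
    solution = solution,
    replicate = c(seq_len(n_p), seq_len(n_c))
  )
  features <- tibble::tibble(feature_id = ids, mz = mz, rt = rt, mode = mode)
  table <- feature_table(features, design, x)

  truth <- list(
    enriched_plant_ids = ids[idx_plant],
    enriched_control_ids = ids[idx_ctrl],
    true_log2fc = setNames(true_fc, ids),
    spiked_groups = tibble::tibble(
      compound = character(), neutral_mass = numeric(), rt = numeric(),
      direction = character(), member_ids = list(), labels = list()
    ),
    adduct_collision_rate = NA_real_
  )

  if (config$n_spiked_compounds > 0) {
    if (is.null(library)) {
      library <- dplyr::filter(soil_compound_library(), .data$plausible_in_soil)
    }
    labels <- if (mode == "positive") c("[M+H]+", "[M+Na]+")
              else c("[M-H]-", "[M+HCOO]-")
    k <- min(config$n_spiked_compounds, nrow(library))
    picks <- .collision_free_picks(library, k, labels)
    # well-separated retention times so distinct spiked families can never
    # fall into one RT bin at the default 10-s grouping tolerance
    slots <- seq(60, 840, by = 40)
    spike_rt <- sample(slots, k) + runif(k, -5, 5)
    for (i in seq_len(k)) {
      dir <- if (i %% 2 == 1) "plant" else "control"
      res <- spike_compound_ions(table, picks[i, ], adducts = labels,
                                 rt = spike_rt[i], direction = dir,
                                 config = config)
      table <- res$table
      truth$spiked_groups <- dplyr::bind_rows(truth$spiked_groups,
                                              res$truth$spiked_groups)
      truth$enriched_plant_ids <- c(truth$enriched_plant_ids,
                                    res$truth$enriched_plant_ids)
      truth$enriched_control_ids <- c(truth$enriched_control_ids,
                                      res$truth$enriched_control_ids)
      truth$true_log2fc <- c(truth$true_log2fc, res$truth$true_log2fc)
    }
    truth$adduct_collision_rate <- .adduct_collision_rate(table)
  }

  list(table = table, truth = truth)
}

# Greedy selection of spike compounds whose ion families cannot cross-link
# under the default deconvolution tolerances: no pair of ions from two
# different compounds (adducts plus up to two 13C offsets) may sit within
# an adduct-rule delta or an isotope spacing of each other. Compounds in
# homologous series (e.g. C16/C18 fatty acids 24.000 Da apart) are
# inherently ambiguous at a 0.1 Da tolerance and are skipped.
.collision_free_picks <- function(library, k, adducts, tol = 0.15) {
  all_shifts <- adduct_rules()$mass_shift
  shifts <- all_shifts[match(adducts, adduct_rules()$label)]
  iso <- C13_DELTA * 0:2
  ion_set <- function(mass) as.vector(outer(mass + shifts, iso, "+"))
  # deconvolution links ions through ANY rule pair of the mode, so the
  # exclusion deltas must span the full rule set, not just the spiked one
  link_deltas <- unique(c(0, iso[-1],
                          as.vector(outer(all_shifts, all_shifts, "-"))))
  collides <- function(a, b) {
    d <- abs(outer(ion_set(a), ion_set(b), "-"))
    any(vapply(link_deltas, function(ld) any(abs(d - abs(ld)) <= tol),
               logical(1)))
  }
  order_idx <- sample.int(nrow(library))
  chosen <- integer()
  for (i in order_idx) {
    mass_i <- library$monoisotopic_mass[i]
    if (!length(chosen) ||
        !any(vapply(chosen, function(j) {
          collides(mass_i, library$monoisotopic_mass[j])
        }, logical(1)))) {
      chosen <- c(chosen, i)
    }
    if (length(chosen) == k) break
  }
  if (length(chosen) < k) {
    warning("only ", length(chosen),
            " mutually collision-free spike compounds available",
            call. = FALSE)
  }
  library[chosen, ]
}

# Fraction of spiked/background ion pairs that would collide under the
# default deconvolution tolerances (same RT bin, adduct-compatible m/z).
.adduct_collision_rate <- function(table, mz_tol = 0.1, rt_tol = 10) {
  spiked <- grepl("_spk", table$feature_id)
  if (!any(spiked) || all(spiked)) return(0)
  rules <- adduct_rules(table$mode[1])$mass_shift
  hits <- 0L
  for (i in which(spiked)) {
    near <- !spiked & abs(table$rt - table$rt[i]) <= rt_tol
    if (!any(near)) next
    m_i <- table$mz[i] - rules
    m_j <- outer(table$mz[near], rules, "-")
    hits <- hits + any(abs(outer(c(m_j), m_i, "-")) <= mz_tol)
  }
  hits / sum(spiked)
}

#' Spike a compound's adduct/isotope ion family into a feature table
#'
#' Adds one ion per requested adduct plus one 13C isotopologue per adduct
#' (+1.00336 Da, intensity `isotope_fraction` of the parent). Siblings
#' share the requested retention time within +/- 2 s, their intensities are
#' correlated through a common per-sample factor, and the whole family is
#' enriched in the requested soil type.
#'
#' @param table A [feature_table].
#' @param compound One compound record (tibble row with `name`,
#'   `monoisotopic_mass`).
#' @param adducts Adduct labels from [adduct_rules()], consistent with the
#'   table's ionization mode.
#' @param rt Retention time of the family, seconds.
#' @param direction `"plant"` or `"control"` enrichment.
#' @param log2fc True absolute log2 fold change of the family (default
#'   drawn from the config range midpoint, 2.75).
#' @param config Optional [synth_config()] supplying noise settings; the
#'   table's own scale defaults are used otherwise.
#' @return List with the augmented `table` and a ground-truth fragment
#'   (`truth`) in the same shape as [simulate_feature_table()].
#' @export
spike_compound_ions <- function(table, compound, adducts, rt,
                                direction = c("plant", "control"),
                                log2fc = 2.75, config = NULL) {
  direction <- match.arg(direction)
  if (!length(adducts)) {
    return(list(table = table, truth = list(
      enriched_plant_ids = character(), enriched_control_ids = character(),
      true_log2fc = setNames(numeric(), character()),
      spiked_groups = tibble::tibble(
        compound = character(), neutral_mass = numeric(), rt = numeric(),
        direction = character(), member_ids = list(), labels = list()
      )
    )))
  }
  mode <- table$mode[1]
  rules <- adduct_rules(mode)
  unknown <- setdiff(adducts, rules$label)
  if (length(unknown)) {
    stop("adduct label(s) not valid in ", mode, " mode: ",
         paste(unknown, collapse = ", "),
         "; supported: ", paste(rules$label, collapse = ", "), call. = FALSE)
  }
  cv <- if (is.null(config)) 0.2 else config$replicate_cv
  iso_frac <- if (is.null(config)) 0.10 else config$isotope_fraction
  base <- if (is.null(config)) 1e4 else 10^config$baseline_log10_mean

  design <- sample_design(table)
  n_s <- nrow(design)
  neutral <- compound$monoisotopic_mass
  slug <- gsub("[^A-Za-z0-9]", "", compound$name)
  # Common sample-level factor induces the sibling intensity correlation.
  sample_factor <- .rlnorm_cv(n_s, cv)
  fc_mult <- ifelse(design$soil_type == direction, 2^log2fc, 1)

  new_rows <- list()
  new_x <- list()
  member_ids <- character()
  member_labels <- character()
  for (a in adducts) {
    parent_mean <- base * 10^runif(1, -0.3, 0.3)
    parent_int <- parent_mean * fc_mult * sample_factor *
      .rlnorm_cv(n_s, cv / 2)
    jitter_rt <- rt + runif(2, -2, 2)
    mz_noise <- rnorm(2, 0, 1e-4)
    id_p <- sprintf("%s%s_spk_%s", substr(mode, 1, 3), design$solution[1],
                    paste0(slug, "_", gsub("[^A-Za-z0-9]", "", a)))
    id_i <- paste0(id_p, "_13C")
    new_rows[[length(new_rows) + 1L]] <- tibble::tibble(
      feature_id = c(id_p, id_i),
      mz = c(adduct_mz(neutral, a) + mz_noise[1],
             adduct_mz(neutral, a) + C13_DELTA + mz_noise[2]),
      rt = jitter_rt, mode = mode
    )
    new_x[[length(new_x) + 1L]] <- rbind(parent_int, parent_int * iso_frac)
    member_ids <- c(member_ids, id_p, id_i)
    member_labels <- c(member_labels, a, paste0(a, " +13C"))
  }
  add_features <- dplyr::bind_rows(new_rows)
  add_x <- do.call(rbind, new_x)

  old_x <- intensity_matrix(table)
  out <- feature_table(
    dplyr::bind_rows(table[, c("feature_id", "mz", "rt", "mode")],
                     add_features),
    design,
    rbind(old_x, add_x)
  )
  fc_signed <- if (direction == "plant") log2fc else -log2fc
  truth <- list(
    enriched_plant_ids = if (direction == "plant") member_ids else character(),
    enriched_control_ids = if (direction == "control") member_ids
                           else character(),
    true_log2fc = setNames(rep(fc_signed, length(member_ids)), member_ids),
    spiked_groups = tibble::tibble(
      compound = compound$name, neutral_mass = neutral, rt = rt,
      direction = direction, member_ids = list(member_ids),
      labels = list(member_labels)
    )
  )
  list(table = out, truth = truth)
}

#' Simulate an OTU count table with a group effect
#'
#' Per-sample counts are multinomial draws over Dirichlet-perturbed base
#' proportions; in the root-plus-rhizosphere group the proportions of
#' `n_effect_otus` effect OTUs are multiplied by `effect_fold` before
#' renormalization. `effect_fold = 1` gives exchangeable (null) groups.
#'
#' @param n_otus Number of OTUs.
#' @param n_per_group Samples per group (root_rhizosphere, control_soil).
#' @param depth Sequencing depth per sample (column sums equal this).
#' @param n_effect_otus Number of OTUs carrying the group effect.
#' @param effect_fold Fold change applied to effect OTUs in the root group.
#' @param concentration Dirichlet concentration of per-sample perturbation.
#' @param seed Integer seed.
#' @return List with `counts` (integer matrix OTUs x samples), `groups`
#'   (named character) and `effect_otus` (ids).
#' @export
simulate_otu_table <- function(n_otus = 500, n_per_group = 4, depth = 10000,
                               n_effect_otus = 0, effect_fold = 1,
                               concentration = 200, seed = 1L) {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (n_effect_otus > n_otus) {
    stop("n_effect_otus cannot exceed n_otus", call. = FALSE)
  }
  set.seed(as.integer(seed) %% 2147483629L)
  base <- rgamma(n_otus, shape = 0.8, rate = 1) + 1e-6
  base <- base / sum(base)
  effect_idx <- seq_len(n_effect_otus)
  groups <- c(rep("root_rhizosphere", n_per_group),
              rep("control_soil", n_per_group))
  sample_ids <- c(sprintf("root_%d", seq_len(n_per_group)),
                  sprintf("soil_%d", seq_len(n_per_group)))
  counts <- matrix(0L, n_otus, length(groups))
  for (j in seq_along(groups)) {
    p <- base
    if (groups[j] == "root_rhizosphere" && n_effect_otus > 0) {
      p[effect_idx] <- p[effect_idx] * effect_fold
    }
    # Dirichlet perturbation around the (possibly shifted) base profile.
    p <- rgamma(n_otus, shape = concentration * p / sum(p), rate = 1)
    p <- p / sum(p)
    counts[, j] <- rmultinom(1, depth, p)[, 1]
  }
  rownames(counts) <- sprintf("OTU_%04d", seq_len(n_otus))
  colnames(counts) <- sample_ids
  list(counts = counts, groups = setNames(groups, sample_ids),
       effect_otus = rownames(counts)[effect_idx])
}

#' Simulate an electrolyte-leakage experiment
#'
#' Gamma-distributed replicate conductivities with the requested group
#' means (% of the lysis maximum) and CV, plus a fully lysed reference set
#' at 100%.
#'
#' @param group_means Named numeric vector: treatment -> mean relative
#'   conductivity (% of lysis maximum), values in [0, 100].
#' @param cv Coefficient of variation of replicates; 0 gives constant
#'   replicates.
#' @param n Replicates per treatment (>= 2).
#' @param lysis_max Conductivity of fully lysed tissue (uS/cm) used to
#'   convert percentages back to raw conductivities.
#' @param seed Integer seed.
#' @return List with `data` (tibble: treatment, replicate, conductivity,
#'   relative_conductivity) and `lysis_max`.
#' @export
simulate_leakage <- function(group_means, cv = 0.15, n = 4,
                             lysis_max = 120, seed = 1L) {
  if (n < 2) stop("n must be >= 2 for any test to be defined", call. = FALSE)
  if (any(group_means < 0 | group_means > 100)) {
    stop("group means are relative conductivities in [0, 100]", call. = FALSE)
  }
  set.seed(as.integer(seed) %% 2147483629L)
  rows <- purrr::imap(group_means, function(m, trt) {
    rel <- if (cv <= 0 || m == 0) rep(m, n) else
      rgamma(n, shape = 1 / cv^2, scale = m * cv^2)
    tibble::tibble(treatment = trt, replicate = seq_len(n),
                   conductivity = rel / 100 * lysis_max,
                   relative_conductivity = rel)
  })
  data <- dplyr::bind_rows(rows)
  data$treatment <- factor(data$treatment, levels = names(group_means))
  list(data = data, lysis_max = lysis_max)
}
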