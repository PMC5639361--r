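# Adduct / 13C-isotope deconvolution of marker ions and library-based
# annotation. Sibling ions of one compound share retention time; within an
# RT bin, ion pairs whose implied neutral masses agree under some pair of
# adduct rules are linked, and connected components become groups.

#' Deconvolution parameters
#'
#' Defaults are the published tolerances: m/z 0.1 Da and retention time
#' 10 s; the 13C spacing is 1.00336 Da with up to two isotopologues.
#' Isotope spacing gets its own tighter tolerance (`iso_tol`, default
#' `mz_tol / 5`): the difference of two measured masses is far more
#' precise than the absolute alignment tolerance, and a loose window lets
#' coincidentally spaced background ions pose as isotopologues.
#'
#' @param mz_tol m/z tolerance for adduct grouping and library matching,
#'   Da.
#' @param rt_tol Retention-time tolerance, seconds.
#' @param isotope_delta 13C-12C mass gap, Da.
#' @param max_isotopes Maximum isotopologues attached per ion.
#' @param iso_tol Tolerance on the isotope spacing, Da.
#' @return A `deconv_params` list.
#' @export
deconv_params <- function(mz_tol = 0.1, rt_tol = 10,
                          isotope_delta = C13_DELTA, max_isotopes = 2,
                          iso_tol = mz_tol / 5) {
  if (mz_tol <= 0 || rt_tol <= 0 || iso_tol <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  structure(list(mz_tol = mz_tol, rt_tol = rt_tol,
                 isotope_delta = isotope_delta,
                 max_isotopes = as.integer(max_isotopes),
                 iso_tol = iso_tol),
            class = "deconv_params")
}

# Single-linkage RT binning: sorted RTs start a new bin at gaps > rt_tol.
.rt_bins <- function(rt, rt_tol) {
  ord <- order(rt)
  gaps <- c(0, diff(rt[ord]))
  bins <- cumsum(gaps > rt_tol)
  out <- integer(length(rt))
  out[ord] <- bins
  out
}

.union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) parent[find(i)] <<- find(j)
  list(find = find, union = union,
       components = function() vapply(seq_len(n), find, 1L))
}

#' Group marker ions into adduct/isotope families
#'
#' Ions are first binned by retention-time proximity (single linkage within
#' `rt_tol`). Within a bin, every ion pair is tested under every ordered
#' pair of adduct rules: if the two implied neutral masses agree within
#' `mz_tol` the ions are linked, as are pairs separated by a multiple of
#' the 13C spacing. Each connected component is then resolved: the
#' neutral-mass hypothesis with the greatest coverage (adduct-explained
#' ions plus attachable 13C isotopologues) wins, ties broken by smaller
#' mean |error| then larger direct support; its ions form a group with
#' neutral mass the mean of the supporting implied masses, and any
#' remaining ions of the component are re-resolved into further groups.
#' Ungrouped ions fall back to the default rule ([M+H]+ / [M-H]-).
#'
#' @param ions Tibble with columns `feature_id`, `mz`, `rt`, `mode` (all
#'   one ionization mode), e.g. a `marker_set`.
#' @param params A [deconv_params()].
#' @param rules Adduct rules tibble (default [adduct_rules()] for the
#'   ions' mode).
#' @return An `adduct_groups` tibble: `group_id`, `neutral_mass`,
#'   `rt_centroid`, `support`, `n_members` and a nested `members` tibble
#'   (`feature_id`, `mz`, `rt`, `label`, `is_isotope`).
#' @export
group_adducts <- function(ions, params = deconv_params(), rules = NULL) {
  ions <- tibble::as_tibble(ions)[, c("feature_id", "mz", "rt", "mode")]
  if (!nrow(ions)) stop("no ions to group", call. = FALSE)
  mode <- unique(ions$mode)
  if (length(mode) > 1) {
    stop("ions mix ionization modes; group each mode separately",
         call. = FALSE)
  }
  if (is.null(rules)) rules <- adduct_rules(mode)
  if (!nrow(rules)) stop("empty adduct rule set", call. = FALSE)
  default_label <- if (mode == "positive") "[M+H]+" else "[M-H]-"
  if (!default_label %in% rules$label) default_label <- rules$label[1]

  n <- nrow(ions)
  bins <- .rt_bins(ions$rt, params$rt_tol)
  uf <- .union_find(n)

  for (b in unique(bins)) {
    idx <- which(bins == b)
    if (length(idx) < 2) next
    mz <- ions$mz[idx]
    # Implied neutral mass of each (ion, rule) combination.
    implied <- outer(mz, rules$mass_shift, "-")
    for (a in seq_along(idx)) {
      for (b2 in seq_along(idx)) {
        if (b2 <= a) next
        i <- idx[a]; j <- idx[b2]
        # isotope link (either order)
        dmz <- abs(mz[b2] - mz[a])
        k <- round(dmz / params$isotope_delta)
        if (k >= 1 && k <= params$max_isotopes &&
            abs(dmz - k * params$isotope_delta) <= params$iso_tol) {
          uf$union(i, j)
          next
        }
        # adduct link: any rule pair with agreeing implied neutral masses
        d <- abs(outer(implied[a, ], implied[b2, ], "-"))
        diag(d) <- Inf  # same rule twice implies two distinct compounds
        if (any(d <= params$mz_tol)) uf$union(i, j)
      }
    }
  }

  comp <- uf$components()
  groups <- split(seq_len(n), comp)
  out <- purrr::map(unname(groups), function(members) {
    .resolve_component(ions[members, ], rules, params, default_label)
  })
  res <- dplyr::bind_rows(out)
  res$group_id <- sprintf("G%04d", seq_len(nrow(res)))
  res <- res[, c("group_id", "neutral_mass", "rt_centroid", "support",
                 "n_members", "members")]
  class(res) <- c("adduct_groups", class(res))
  res
}

# Resolve one connected component, possibly into several groups: the best
# neutral-mass hypothesis claims its adduct-explained ions plus their
# attachable 13C isotopologues; the remainder (e.g. a second compound that
# was chained in through a coincidental rule-delta match) is re-resolved
# until every ion is assigned. Hypotheses are scored by total coverage,
# then mean |error| of the adduct assignments, then direct support.
.resolve_component <- function(g, rules, params, default_label) {
  rows <- list()
  repeat {
    res <- .resolve_once(g, rules, params, default_label)
    rows[[length(rows) + 1L]] <- res$row
    if (!any(!res$assigned)) break
    g <- g[!res$assigned, , drop = FALSE]
  }
  dplyr::bind_rows(rows)
}

.resolve_once <- function(g, rules, params, default_label) {
  m <- nrow(g)
  implied <- outer(g$mz, rules$mass_shift, "-")
  if (m == 1L) {
    members <- tibble::tibble(feature_id = g$feature_id, mz = g$mz,
                              rt = g$rt, label = default_label,
                              is_isotope = FALSE)
    return(list(assigned = TRUE, row = tibble::tibble(
      neutral_mass = implied[1, match(default_label, rules$label)],
      rt_centroid = g$rt, support = 1L, n_members = 1L,
      members = list(members))))
  }
  iso_of <- function(i, anchors) {
    # anchor (if any) of which ion i is a 13C isotopologue
    for (a in anchors[order(g$mz[anchors], decreasing = TRUE)]) {
      k <- round((g$mz[i] - g$mz[a]) / params$isotope_delta)
      if (k >= 1 && k <= params$max_isotopes &&
          abs(g$mz[i] - g$mz[a] - k * params$isotope_delta) <=
            params$iso_tol) {
        return(a)
      }
    }
    NA_integer_
  }
  best <- NULL
  for (i in seq_len(m)) {
    for (r in seq_len(nrow(rules))) {
      m0 <- implied[i, r]
      err <- abs(implied - m0)
      assign_rule <- apply(err, 1L, which.min)
      assign_err <- err[cbind(seq_len(m), assign_rule)]
      explained <- assign_err <= params$mz_tol
      support <- sum(explained)
      anchors <- which(explained)
      iso_anchor <- rep(NA_integer_, m)
      for (u in which(!explained)) {
        a <- iso_of(u, anchors[g$mz[anchors] < g$mz[u]])
        iso_anchor[u] <- a
      }
      coverage <- support + sum(!is.na(iso_anchor))
      mean_err <- if (support) mean(assign_err[explained]) else Inf
      if (is.null(best) || coverage > best$coverage ||
          (coverage == best$coverage && mean_err < best$mean_err) ||
          (coverage == best$coverage && mean_err == best$mean_err &&
             support > best$support)) {
        best <- list(coverage = coverage, support = support,
                     mean_err = mean_err, rule = assign_rule,
                     explained = explained, iso_anchor = iso_anchor)
      }
    }
  }
  assigned <- best$explained | !is.na(best$iso_anchor)
  labels <- character(m)
  labels[best$explained] <- rules$label[best$rule[best$explained]]
  iso_idx <- which(!is.na(best$iso_anchor))
  labels[iso_idx] <- paste0(labels[best$iso_anchor[iso_idx]], " +13C")
  keep <- which(assigned)
  neutral_members <- which(best$explained)
  # median of the supporting implied masses: identical to the mean for a
  # clean adduct family, robust to a single in-tolerance background ion
  neutral_mass <- median(implied[cbind(neutral_members,
                                       best$rule[neutral_members])])
  members <- tibble::tibble(
    feature_id = g$feature_id[keep], mz = g$mz[keep], rt = g$rt[keep],
    label = labels[keep], is_isotope = !is.na(best$iso_anchor)[keep])
  list(assigned = assigned, row = tibble::tibble(
    neutral_mass = neutral_mass, rt_centroid = mean(g$rt[keep]),
    support = best$support, n_members = length(keep),
    members = list(members)))
}

#' Annotate deconvolved groups against a compound library
#'
#' Every library record whose monoisotopic mass lies within `match_tol` of
#' a group's inferred neutral mass is listed as a putative match, sorted
#' by |mass error|. Matches flagged implausible in soil (synthetic drugs,
#' mammalian hormones) are marked excluded; a group whose matches are all
#' implausible is excluded as a whole, and a group with no match gets
#' class `"unknown"`.
#'
#' @param groups An `adduct_groups` tibble from [group_adducts()].
#' @param library Compound library tibble (see [read_compound_library()]).
#' @param match_tol Mass-match tolerance, Da (default 0.1).
#' @return An `annotation` tibble: `group_id`, `neutral_mass`,
#'   `n_members`, nested `matches`, `met_class`, `excluded`, `reason`.
#' @export
annotate_groups <- function(groups, library = soil_compound_library(),
                            match_tol = 0.1) {
  if (!nrow(library)) stop("empty compound library", call. = FALSE)
  ann <- purrr::pmap(
    list(groups$group_id, groups$neutral_mass, groups$n_members),
    function(gid, nm, nmem) {
      err <- abs(library$monoisotopic_mass - nm)
      hit <- which(err <= match_tol)
      hit <- hit[order(err[hit])]
      matches <- tibble::tibble(
        name = library$name[hit], met_class = library$met_class[hit],
        plausible_in_soil = library$plausible_in_soil[hit],
        mass_error = library$monoisotopic_mass[hit] - nm,
        excluded = !library$plausible_in_soil[hit]
      )
      plausible <- matches[matches$plausible_in_soil, , drop = FALSE]
      if (!nrow(matches)) {
        cls <- "unknown"; excl <- FALSE; reason <- NA_character_
      } else if (!nrow(plausible)) {
        cls <- matches$met_class[1]; excl <- TRUE
        reason <- "all matches implausible in soil"
      } else {
        cls <- plausible$met_class[1]; excl <- FALSE; reason <- NA_character_
      }
      tibble::tibble(group_id = gid, neutral_mass = nm, n_members = nmem,
                     matches = list(matches), met_class = cls,
                     excluded = excl, reason = reason)
    })
  out <- dplyr::bind_rows(ann)
  class(out) <- c("annotation", class(out))
  out
}

#' Metabolite-class composition of annotated markers
#'
#' Excluded groups are removed; every member ion of a remaining group
#' contributes one count to the group's best-match class (multiple ions
#' annotating to the same metabolite count additively), or to `"unknown"`
#' when no library compound matched. Percentages are over counted ions.
#'
#' @param annotations An `annotation` tibble from [annotate_groups()].
#' @return Tibble with `met_class`, `n_ions`, `pct` (sums to 100).
#' @export
class_composition <- function(annotations) {
  if (!nrow(annotations)) stop("no annotations", call. = FALSE)
  keep <- annotations[!annotations$excluded, , drop = FALSE]
  if (!nrow(keep)) stop("empty composition: all annotations excluded",
                        call. = FALSE)
  comp <- keep |>
    dplyr::group_by(met_class = .data$met_class) |>
    dplyr::summarise(n_ions = sum(.data$n_members), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_ions))
  comp$pct <- 100 * comp$n_ions / sum(comp$n_ions)
  comp
}
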