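# Monoisotopic element masses (IUPAC 2021), Da. Electron mass needed for
# adduct m/z arithmetic on singly charged ions.
.MONO_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268
)

.ELECTRON_MASS <- 0.00054857990
.PROTON_MASS <- .MONO_MASS[["H"]] - .ELECTRON_MASS

# Mass gap between 13C and 12C; one unit per extra 13C in an isotopologue.
C13_DELTA <- 1.00336

#' Monoisotopic mass of an elemental formula
#'
#' Sums IUPAC monoisotopic element masses over a Hill-style formula restricted
#' to the elements that occur in small soil metabolites and their salts
#' (C, H, N, O, P, S, Na, K, Cl).
#'
#' @param formula Character vector of elemental formulas, e.g. `"C9H9NO5"`.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' mass_from_formula("H2O")      # 18.0106
#' mass_from_formula("C9H9NO5")  # DIMBOA, 211.0481
#' @export
mass_from_formula <- function(formula) {
  vapply(formula, .mass_one_formula, numeric(1), USE.NAMES = FALSE)
}

.mass_one_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    stop("malformed elemental formula: '", formula, "'", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  total <- 0
  for (tok in tokens) {
    elem <- sub("[0-9]+$", "", tok)
    count <- sub("^[A-Za-z]+", "", tok)
    count <- if (nzchar(count)) as.integer(count) else 1L
    if (!elem %in% names(.MONO_MASS)) {
      stop("unknown element '", elem, "' in formula '", formula,
           "'; supported: ", paste(names(.MONO_MASS), collapse = ", "),
           call. = FALSE)
    }
    total <- total + .MONO_MASS[[elem]] * count
  }
  total
}

#' Electrospray adduct rules
#'
#' The singly charged adducts expected under acidified (formic acid)
#' electrospray: protonated, sodiated, potassiated and ammoniated ions in
#' positive mode; deprotonated, formate and chloride ions in negative mode.
#' `mass_shift` is the signed m/z offset from the neutral monoisotopic mass
#' (electron mass accounted for).
#'
#' @param mode `"positive"`, `"negative"` or `"both"` (default).
#' @return A tibble with columns `label`, `mode`, `mass_shift`, `charge`.
#' @export
adduct_rules <- function(mode = c("both", "positive", "negative")) {
  mode <- match.arg(mode)
  nh4 <- .MONO_MASS[["N"]] + 4 * .MONO_MASS[["H"]] - .ELECTRON_MASS
  formate <- .MONO_MASS[["C"]] + .MONO_MASS[["H"]] + 2 * .MONO_MASS[["O"]] +
    .ELECTRON_MASS
  rules <- tibble::tibble(
    label = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+",
              "[M-H]-", "[M+HCOO]-", "[M+Cl]-"),
    mode = c(rep("positive", 4), rep("negative", 3)),
    mass_shift = c(
      .PROTON_MASS,
      .MONO_MASS[["Na"]] - .ELECTRON_MASS,
      .MONO_MASS[["K"]] - .ELECTRON_MASS,
      nh4,
      -.PROTON_MASS,
      formate,
      .MONO_MASS[["Cl"]] + .ELECTRON_MASS
    ),
    charge = c(rep(1L, 4), rep(-1L, 3))
  )
  if (mode == "both") rules else rules[rules$mode == mode, ]
}

#' m/z of an adduct ion of a neutral compound
#'
#' @param neutral_mass Neutral monoisotopic mass, Da.
#' @param label Adduct label present in [adduct_rules()].
#' @return Ion m/z in Da.
#' @export
adduct_mz <- function(neutral_mass, label) {
  rules <- adduct_rules()
  idx <- match(label, rules$label)
  if (anyNA(idx)) {
    stop("unknown adduct label(s): ",
         paste(label[is.na(idx)], collapse = ", "),
         "; supported: ", paste(rules$label, collapse = ", "), call. = FALSE)
  }
  neutral_mass + rules$mass_shift[idx]
}

#' Neutral mass implied by an ion m/z under an adduct rule
#'
#' @inheritParams adduct_mz
#' @param mz Observed ion m/z, Da.
#' @return Implied neutral monoisotopic mass, Da.
#' @export
neutral_from_mz <- function(mz, label) {
  rules <- adduct_rules()
  idx <- match(label, rules$label)
  if (anyNA(idx)) {
    stop("unknown adduct label(s): ",
         paste(label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  mz - rules$mass_shift[idx]
}
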