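# Average atomic masses (Da) for the elements that occur in lipids, detergents
# and common adducts. Values are IUPAC standard atomic weights.
AVERAGE_ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Na = 22.98977, K = 39.0983, Cl = 35.45, F = 18.998403
)

#' Average molecular mass from a molecular formula
#'
#' Sums average atomic masses over a Hill-style molecular formula such as
#' `"C39H76NO8P"`. Intact-protein native MS at tens of kDa resolves average
#' (not monoisotopic) masses, so average masses are used throughout.
#'
#' @param formula Molecular formula string, e.g. `"C39H76NO8P"`.
#' @return Average mass in Da.
#' @examples
#' formula_mass("C39H76NO8P") # POPE, ~718 Da
#' @export
formula_mass <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    abort_param("`formula` must be a single non-empty string.")
  }
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    abort_param(sprintf("Cannot parse molecular formula '%s'.", formula))
  }
  elements <- sub("\\d+$", "", parts)
  counts <- as.numeric(sub("^[A-Za-z]+", "", parts))
  counts[is.na(counts)] <- 1
  unknown <- setdiff(elements, names(AVERAGE_ATOMIC_MASS))
  if (length(unknown) > 0) {
    abort_param(sprintf("Unknown element(s) in formula '%s': %s",
                        formula, paste(unknown, collapse = ", ")))
  }
  sum(AVERAGE_ATOMIC_MASS[elements] * counts)
}

#' Define a lipid species
#'
#' @param name Label, e.g. `"POPE"`.
#' @param formula Molecular formula; used to compute the average mass when
#'   `mass` is not given.
#' @param mass Average mass in Da; overrides `formula` if both are given.
#' @param lipid_class One of `"PE"`, `"PG"`, `"CDL"`, `"lipid-II"`, `"other"`.
#' @return One-row tibble with columns `name`, `mass`, `lipid_class`, `formula`.
#' @examples
#' lipid_species("POPE", formula = "C39H76NO8P", lipid_class = "PE")
#' @export
lipid_species <- function(name, formula = NULL, mass = NULL,
                          lipid_class = c("other", "PE", "PG", "CDL", "lipid-II")) {
  lipid_class <- match.arg(lipid_class)
  if (is.null(mass)) {
    if (is.null(formula)) {
      abort_param("Give either `formula` or `mass` for a lipid species.")
    }
    mass <- formula_mass(formula)
  }
  check_number(mass, "mass", strict_min = 0)
  tibble(name = name, mass = mass, lipid_class = lipid_class,
         formula = formula %||% NA_character_)
}

#' Define a detergent species
#'
#' @param name Label, e.g. `"NG"`.
#' @param average_mass Monomer average mass in Da.
#' @param cmc Critical micelle concentration in % w/v. Below the CMC the
#'   detergent is assumed not to compete for lipid binding sites.
#' @return One-row tibble with columns `name`, `average_mass`, `cmc`.
#' @export
detergent_species <- function(name, average_mass, cmc) {
  check_number(average_mass, "average_mass", strict_min = 0)
  check_number(cmc, "cmc", min = 0)
  tibble(name = name, average_mass = average_mass, cmc = cmc)
}

#' Define a protein species
#'
#' @param name Label, e.g. `"PSH"`.
#' @param average_mass Average mass in Da.
#' @param charge_min,charge_max Inclusive positive charge-state range observed
#'   for the intact protein.
#' @return One-row tibble with columns `name`, `average_mass`, `charge_min`,
#'   `charge_max`.
#' @export
protein_species <- function(name, average_mass, charge_min, charge_max) {
  check_number(average_mass, "average_mass", strict_min = 0)
  check_number(charge_min, "charge_min", min = 1)
  check_number(charge_max, "charge_max", min = 1)
  if (charge_max < charge_min) {
    abort_param("`charge_max` must be >= `charge_min`.")
  }
  tibble(name = name, average_mass = average_mass,
         charge_min = as.integer(charge_min), charge_max = as.integer(charge_max))
}

#' Convert a detergent concentration from % w/v to molar
#'
#' `conc_M = 10 * percent_wv / average_mass` with mass in g/mol (1 % w/v is
#' 10 g/L).
#'
#' @param percent_wv Concentration in % w/v.
#' @param average_mass Monomer mass in g/mol.
#' @return Concentration in mol/L.
#' @export
percent_wv_to_molar <- function(percent_wv, average_mass) {
  if (any(percent_wv < 0)) abort_param("Concentrations must be non-negative.")
  check_number(average_mass, "average_mass", strict_min = 0)
  10 * percent_wv / average_mass
}

#' Built-in lipid species
#'
#' The three main E. coli membrane lipid classes plus the peptidoglycan
#' precursor lipid-II (the natural substrate of the flippase MurJ). Lipid-II's
#' formula is not tabulated consistently in the literature; the value here is
#' the E. coli (meso-DAP) form and can be overridden via [lipid_species()].
#'
#' @return Tibble of lipid species, one row each.
#' @export
builtin_lipids <- function() {
  bind_rows(
    lipid_species("POPE", formula = "C39H76NO8P", lipid_class = "PE"),
    lipid_species("POPG", formula = "C40H77O10P", lipid_class = "PG"),
    lipid_species("CDL", formula = "C81H150O17P2", lipid_class = "CDL"),
    lipid_species("lipid-II", formula = "C94H156N8O26P2", lipid_class = "lipid-II")
  )
}

#' Built-in detergent species
#'
#' Nonylglucoside (NG), octylglucoside (OG) and dimethyl-dodecylamine N-oxide
#' (LDAO) with their monomer masses and approximate aqueous CMCs in % w/v.
#'
#' @return Tibble of detergent species.
#' @export
builtin_detergents <- function() {
  bind_rows(
    detergent_species("NG", average_mass = formula_mass("C15H30O6"), cmc = 0.20),
    detergent_species("OG", average_mass = formula_mass("C14H28O6"), cmc = 0.53),
    detergent_species("LDAO", average_mass = formula_mass("C14H31NO"), cmc = 0.023)
  )
}
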