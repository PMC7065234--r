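#' List the packaged synthetic fixtures
#'
#' @return Character vector of fixture names usable with [load_fixture()] and
#'   [run_analysis()].
#' @export
list_fixtures <- function() {
  dir <- system.file("extdata", "fixtures", package = "lipidex")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Load a packaged fixture configuration
#'
#' Fixtures are structured YAML configs describing a complete synthetic
#' experiment: `psh_titration` (annular lipid removal from a 33 kDa protease
#' by an NG titration), `murj_lipid2` (a 57 kDa flippase retaining one
#' protected substrate lipid under OG competition, plus a per-state residue
#' accessibility section), and `leut_cdl_sites` (three cardiolipin sites with
#' slow, intermediate and fast unbinding on a dimeric transporter).
#'
#' @param name Fixture name (see [list_fixtures()]) or a path to a YAML file
#'   with the same structure.
#' @return The parsed configuration list, class `lipidex_fixture`.
#' @export
load_fixture <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "fixtures", paste0(name, ".yaml"),
                package = "lipidex")
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort_input(sprintf(
      "Unknown fixture '%s'; packaged fixtures: %s",
      name, paste(list_fixtures(), collapse = ", ")))
  }
  cfg <- yaml::read_yaml(path)
  cfg$path <- path
  class(cfg) <- c("lipidex_fixture", "list")
  cfg
}

#' Build a spectrum fixture object from a fixture configuration
#'
#' @param cfg A `lipidex_fixture` (or equivalent list) with `protein`,
#'   `detergent`, `lipids`, `envelope` and `spectrum` blocks.
#' @return A [spectrum_fixture()].
#' @export
fixture_spectrum <- function(cfg) {
  if (is.null(cfg$protein) || is.null(cfg$lipids) || is.null(cfg$detergent)) {
    abort_input("Fixture config lacks `protein`, `lipids` or `detergent`.")
  }
  protein <- protein_species(cfg$protein$name, cfg$protein$average_mass,
                             cfg$protein$charge_min, cfg$protein$charge_max)
  detergent <- detergent_species(cfg$detergent$name, cfg$detergent$average_mass,
                                 cfg$detergent$cmc)
  lipids <- lapply(cfg$lipids, function(l) {
    mass <- if (!is.null(l$mass)) l$mass else formula_mass(l$formula)
    tibble(
      name = l$name, mass = mass,
      lipid_class = l$lipid_class %||% l$name,
      conc = l$conc, n_sites = as.integer(l$n_sites),
      K_L = l$K_L, K_D = l$K_D %||% NA_real_,
      protected = isTRUE(l$protected)
    )
  }) |>
    list_rbind()
  sp <- cfg$spectrum %||% list()
  spectrum_fixture(
    protein = protein, lipids = lipids, detergent = detergent,
    envelope = cfg$envelope %||% list(),
    peak_fwhm_mz = sp$peak_fwhm_mz %||% 8,
    noise_sd = sp$noise_sd %||% 0.01,
    mz_min = sp$mz_min, mz_max = sp$mz_max,
    mz_step = sp$mz_step %||% 0.25,
    seed = sp$seed %||% 1L
  )
}

# Distinct candidate species (one per lipid class) for adduct assignment:
# site groups of the same lipid share a mass and collapse into one candidate.
fixture_candidates <- function(fixture) {
  fixture$lipids |>
    distinct(.data$lipid_class, .data$mass) |>
    rename(name = "lipid_class") |>
    mutate(lipid_class = .data$name)
}
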