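#' Construct a mass spectrum
#'
#' Light validating constructor for the profile-spectrum container used
#' throughout the package: a tibble with strictly increasing `mz` and
#' non-negative `intensity`.
#'
#' @param mz m/z grid, strictly increasing.
#' @param intensity Intensities, same length, non-negative.
#' @return Tibble of class `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity)) {
    abort_input("`mz` and `intensity` must have the same length.")
  }
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    bad <- which(diff(mz) <= 0)[1] + 1L
    abort_input(sprintf("`mz` must be strictly increasing (violated at index %d).", bad))
  }
  if (any(intensity < 0)) {
    bad <- which(intensity < 0)[1]
    abort_input(sprintf("`intensity` must be non-negative (violated at index %d).", bad))
  }
  out <- tibble(mz = as.double(mz), intensity = as.double(intensity))
  class(out) <- unique(c("mass_spectrum", class(out)))
  out
}

#' Define a synthetic spectrum fixture
#'
#' Bundles everything needed to emulate a native mass spectrum of a
#' detergent-solubilized membrane protein carrying a ladder of lipid adducts:
#' the protein and its charge-state envelope, candidate lipids with their
#' binding-site counts and competition parameters, the detergent, and the
#' peak-shape / noise / m/z-grid settings.
#'
#' Each lipid row carries an occupancy model (see [occupancy()]): `n_sites`
#' independent sites, each occupied with probability
#' \eqn{\theta(L, D)}, so its adduct count is Binomial(`n_sites`, \eqn{\theta}).
#' `protected = TRUE` marks a site that detergent cannot reach.
#'
#' @param protein One-row tibble from [protein_species()].
#' @param lipids Tibble with columns `name`, `mass`, `lipid_class`, `conc`
#'   (lipid concentration, conventionally micromolar), `n_sites`, `K_L`, `K_D`,
#'   `protected`.
#' @param detergent One-row tibble from [detergent_species()]; its `cmc` may be
#'   an effective (mixed-micelle) value.
#' @param envelope List with `center`, `width` (Gaussian charge-envelope mean
#'   and sd, in charge units) and optionally `charge_shift_per_percent` (shift
#'   of the envelope mean per % w/v detergent, emulating charge-state shifts
#'   seen when micelle composition changes).
#' @param peak_fwhm_mz Peak full width at half maximum in m/z units.
#' @param noise_sd Additive Gaussian noise sd, relative to the tallest
#'   noiseless point.
#' @param mz_min,mz_max,mz_step m/z grid.
#' @param seed Default integer seed for [simulate_spectrum()].
#' @return List of class `spectrum_fixture`.
#' @export
spectrum_fixture <- function(protein, lipids, detergent,
                             envelope = list(center = NULL, width = 1),
                             peak_fwhm_mz = 8, noise_sd = 0.01,
                             mz_min, mz_max, mz_step = 0.25, seed = 1L) {
  check_number(peak_fwhm_mz, "peak_fwhm_mz", strict_min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(mz_step, "mz_step", strict_min = 0)
  if (mz_max <= mz_min) abort_param("`mz_max` must exceed `mz_min`.")
  lipids <- as_tibble(lipids)
  needed <- c("name", "mass", "conc", "n_sites", "K_L")
  missing_cols <- setdiff(needed, names(lipids))
  if (length(missing_cols) > 0) {
    abort_param(sprintf("`lipids` lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(lipids$name)) {
    abort_param("`lipids$name` must be unique (use distinct site-group names; rows of one lipid share `lipid_class`).")
  }
  if (!"protected" %in% names(lipids)) lipids$protected <- FALSE
  if (!"K_D" %in% names(lipids)) lipids$K_D <- NA_real_
  if (!"lipid_class" %in% names(lipids)) lipids$lipid_class <- lipids$name
  if (any(!lipids$protected & !is.finite(lipids$K_D))) {
    abort_param("Non-protected lipids need a finite `K_D`.")
  }
  envelope$center <- envelope$center %||%
    mean(c(protein$charge_min, protein$charge_max))
  envelope$width <- envelope$width %||% 1
  envelope$charge_shift_per_percent <- envelope$charge_shift_per_percent %||% 0
  structure(
    list(protein = protein, lipids = lipids, detergent = detergent,
         envelope = envelope, peak_fwhm_mz = peak_fwhm_mz, noise_sd = noise_sd,
         mz_min = mz_min, mz_max = mz_max, mz_step = mz_step, seed = seed),
    class = "spectrum_fixture"
  )
}

# Normalised charge-state weights at a given detergent concentration.
charge_envelope <- function(fixture, detergent_conc = 0) {
  z <- seq(fixture$protein$charge_min, fixture$protein$charge_max)
  centre <- fixture$envelope$center +
    fixture$envelope$charge_shift_per_percent * detergent_conc
  w <- dnorm(z, centre, fixture$envelope$width)
  if (sum(w) <= 0) abort_param("Charge envelope has zero total weight.")
  tibble(charge = z, weight = w / sum(w))
}

# True per-lipid adduct-count distribution at a detergent concentration.
lipid_count_distribution <- function(fixture, detergent_conc) {
  cmc <- fixture$detergent$cmc
  fixture$lipids |>
    pmap(function(name, mass, conc, n_sites, K_L, K_D, protected, ...) {
      theta <- occupancy(conc, detergent_conc, K_L,
                         K_D = if (protected) Inf else K_D,
                         cmc = cmc, protected = protected)
      tibble(name = name, n_bound = 0:n_sites,
             prob = dbinom(0:n_sites, n_sites, theta), theta = theta)
    }) |>
    list_rbind()
}

# Class-level adduct-count distribution: lipid rows of the same lipid_class
# (e.g. a protected site group and an annular site group of the same lipid)
# are convolved into one count distribution per class.
class_count_distribution <- function(fixture, detergent_conc) {
  dist <- lipid_count_distribution(fixture, detergent_conc)
  dist$lipid_class <- fixture$lipids$lipid_class[match(dist$name, fixture$lipids$name)]
  split(dist, dist$lipid_class) |>
    imap(function(d, cls) {
      pmf <- 1
      for (nm in unique(d$name)) {
        pmf <- convolve_pmf(pmf, d$prob[d$name == nm])
      }
      tibble(lipid_class = cls, n_bound = seq_along(pmf) - 1L, prob = pmf)
    }) |>
    list_rbind()
}

convolve_pmf <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    out[i:(i + length(q) - 1L)] <- out[i:(i + length(q) - 1L)] + p[i] * q
  }
  out
}

# All adduct compositions with their mass shifts and joint probabilities.
composition_table <- function(fixture, detergent_conc) {
  dist <- lipid_count_distribution(fixture, detergent_conc)
  per_lipid <- split(dist, factor(dist$name, levels = fixture$lipids$name))
  grids <- lapply(per_lipid, function(d) d$n_bound)
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(combos) <- fixture$lipids$name
  prob <- rep(1, nrow(combos))
  shift <- rep(0, nrow(combos))
  for (ln in fixture$lipids$name) {
    d <- per_lipid[[ln]]
    prob <- prob * d$prob[match(combos[[ln]], d$n_bound)]
    shift <- shift + combos[[ln]] * fixture$lipids$mass[fixture$lipids$name == ln]
  }
  label <- apply(combos, 1, function(row) {
    nz <- row[row > 0]
    if (length(nz) == 0) "apo"
    else paste(sprintf("%d x %s", nz, names(nz)), collapse = " + ")
  })
  out <- as_tibble(combos)
  out$mass_shift <- shift
  out$prob <- prob
  out$label <- label
  out$n_adducts <- rowSums(combos)
  out
}

#' Simulate a native mass spectrum with lipid adduct ladders
#'
#' Builds a profile spectrum as a sum of Gaussian peaks, one per (charge
#' state, adduct composition) pair, centred at
#' \eqn{(M_{protein} + \sum adduct\ masses + z \cdot 1.00728)/z}. Peak areas
#' are the product of the charge-envelope weight and the occupancy-model
#' probability of the composition, so the integrated noiseless intensity
#' equals the total configured amplitude. Seeded Gaussian noise (relative to
#' the tallest point) is added last and the result clipped at zero.
#'
#' @param fixture A [spectrum_fixture()].
#' @param detergent_conc Detergent concentration in % w/v.
#' @param seed Integer seed; defaults to the fixture's.
#' @param noise_sd Override the fixture's relative noise level.
#' @return A [mass_spectrum()] tibble.
#' @export
simulate_spectrum <- function(fixture, detergent_conc = 0,
                              seed = fixture$seed,
                              noise_sd = fixture$noise_sd) {
  if (!inherits(fixture, "spectrum_fixture")) {
    abort_param("`fixture` must be a `spectrum_fixture`.")
  }
  check_number(detergent_conc, "detergent_conc", min = 0)
  env <- charge_envelope(fixture, detergent_conc)
  comps <- composition_table(fixture, detergent_conc)
  mz <- seq(fixture$mz_min, fixture$mz_max, by = fixture$mz_step)
  sigma <- fixture$peak_fwhm_mz / (2 * sqrt(2 * log(2)))
  intensity <- numeric(length(mz))

  M <- fixture$protein$average_mass
  for (i in seq_len(nrow(env))) {
    z <- env$charge[i]
    centres <- (M + comps$mass_shift + z * PROTON_MASS) / z
    outside <- centres < fixture$mz_min | centres > fixture$mz_max
    if (any(outside & comps$prob > 1e-12)) {
      j <- which(outside & comps$prob > 1e-12)[1]
      abort_param(sprintf(
        "m/z grid [%g, %g] does not cover the theoretical peak at %.2f (z = %d, %s).",
        fixture$mz_min, fixture$mz_max, centres[j], z, comps$label[j]))
    }
    amps <- env$weight[i] * comps$prob
    keep <- amps > 1e-12
    for (j in which(keep)) {
      lo <- max(1L, ceiling((centres[j] - 6 * sigma - fixture$mz_min) / fixture$mz_step))
      hi <- min(length(mz), floor((centres[j] + 6 * sigma - fixture$mz_min) / fixture$mz_step) + 1L)
      idx <- lo:hi
      intensity[idx] <- intensity[idx] + amps[j] * dnorm(mz[idx], centres[j], sigma)
    }
  }

  if (noise_sd > 0) {
    intensity <- with_seed(seed, {
      pmax(0, intensity + rnorm(length(intensity), 0, noise_sd * max(intensity)))
    })
  }
  mass_spectrum(mz, intensity)
}

#' Simulate a detergent titration of spectra
#'
#' Produces one spectrum per detergent concentration from a single fixture,
#' together with the generator's ground truth: per-concentration lipid
#' adduct-count distributions and per-class true bound fractions. True bound
#' fractions are monotone non-increasing in detergent for exchangeable sites
#' and constant for protected sites.
#'
#' @param fixture A [spectrum_fixture()].
#' @param detergent_concs Non-decreasing vector of >= 2 concentrations (% w/v).
#' @param seed Base seed; spectrum `i` uses `seed + i`.
#' @return List of class `titration_sim` with elements `spectra` (named list of
#'   [mass_spectrum()]), `truth` (tibble: `detergent_conc`, `lipid_class`,
#'   `n_bound`, `prob`), `series` (tibble: `detergent_conc`, `lipid_class`,
#'   `bound_fraction` — the true P(count >= 1)), and `fixture`.
#' @export
simulate_titration <- function(fixture, detergent_concs, seed = fixture$seed) {
  if (!inherits(fixture, "spectrum_fixture")) {
    abort_param("`fixture` must be a `spectrum_fixture`.")
  }
  if (length(detergent_concs) < 2) {
    abort_param("`detergent_concs` must hold at least 2 concentrations.")
  }
  if (any(detergent_concs < 0)) abort_param("Concentrations must be >= 0.")
  if (any(diff(detergent_concs) < 0)) {
    abort_param("`detergent_concs` must be non-decreasing.")
  }

  spectra <- lapply(seq_along(detergent_concs), function(i) {
    simulate_spectrum(fixture, detergent_concs[i], seed = seed + i)
  })
  names(spectra) <- format(detergent_concs, trim = TRUE)

  truth <- lapply(seq_along(detergent_concs), function(i) {
    class_count_distribution(fixture, detergent_concs[i]) |>
      mutate(point = i, detergent_conc = detergent_concs[i])
  }) |>
    list_rbind() |>
    select("point", "detergent_conc", "lipid_class", "n_bound", "prob")

  series <- truth |>
    group_by(.data$point, .data$detergent_conc, .data$lipid_class) |>
    summarise(bound_fraction = sum(.data$prob[.data$n_bound >= 1]),
              .groups = "drop")

  structure(
    list(spectra = spectra, truth = truth, series = series, fixture = fixture,
         detergent_concs = detergent_concs),
    class = "titration_sim"
  )
}
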