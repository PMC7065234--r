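#' Pick peaks from a profile mass spectrum
#'
#' Finds local maxima above `min_snr` times the noise floor (median absolute
#' deviation of the intensity), enforces a minimal apex spacing (keeping the
#' taller of two close peaks), refines each apex by three-point parabolic
#' interpolation, and integrates the peak area between the flanking local
#' minima. A flat spectrum yields an empty peak list, not an error.
#'
#' @param spectrum A [mass_spectrum()] (or any data frame with `mz`,
#'   `intensity`).
#' @param min_snr Signal-to-noise threshold (> 0).
#' @param min_spacing_mz Minimal apex separation in m/z.
#' @return Tibble of class `peak_list` with columns `mz`, `intensity`
#'   (interpolated apex height), `area`.
#' @export
pick_peaks <- function(spectrum, min_snr = 3, min_spacing_mz = 5) {
  check_number(min_snr, "min_snr", strict_min = 0)
  check_number(min_spacing_mz, "min_spacing_mz", min = 0)
  mz <- spectrum$mz
  y <- spectrum$intensity
  n <- length(y)
  empty <- tibble(mz = double(), intensity = double(), area = double())
  class(empty) <- unique(c("peak_list", class(empty)))
  if (n < 3) return(empty)

  noise <- mad(y)
  if (noise <= 0) noise <- 1e-9 * max(y, 1e-300)
  threshold <- min_snr * noise

  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  apex <- which(is_max & y > threshold)
  if (length(apex) == 0) return(empty)

  # enforce minimal spacing: greedy from the tallest apex down
  keep <- logical(length(apex))
  ord <- order(y[apex], decreasing = TRUE)
  taken_mz <- double(0)
  for (i in ord) {
    if (all(abs(mz[apex[i]] - taken_mz) >= min_spacing_mz)) {
      keep[i] <- TRUE
      taken_mz <- c(taken_mz, mz[apex[i]])
    }
  }
  apex <- sort(apex[keep])

  peaks <- lapply(apex, function(k) {
    # flanking local minima (or threshold crossings) bound the peak
    lo <- k
    while (lo > 1 && y[lo - 1] < y[lo]) lo <- lo - 1
    hi <- k
    while (hi < n && y[hi + 1] < y[hi]) hi <- hi + 1
    area <- sum(diff(mz[lo:hi]) * (y[lo:(hi - 1)] + y[(lo + 1):hi]) / 2)
    # parabolic apex refinement
    mz_apex <- mz[k]
    int_apex <- y[k]
    if (k > 1 && k < n) {
      denom <- y[k - 1] - 2 * y[k] + y[k + 1]
      if (denom < 0) {
        delta <- 0.5 * (y[k - 1] - y[k + 1]) / denom
        delta <- max(-0.5, min(0.5, delta))
        mz_apex <- mz[k] + delta * (mz[k + 1] - mz[k])
        int_apex <- y[k] - 0.25 * (y[k - 1] - y[k + 1]) * delta
      }
    }
    tibble(mz = mz_apex, intensity = int_apex, area = area)
  }) |>
    list_rbind()
  class(peaks) <- unique(c("peak_list", class(peaks)))
  peaks
}

#' Assign lipid-adduct compositions to picked peaks
#'
#' Matches each peak to a charge state and lipid-adduct composition of a known
#' protein: for every charge in the protein's range the peak is deconvolved to
#' a neutral mass \eqn{m z - z \cdot 1.00728}, and compositions with up to
#' `max_adducts` total lipids from the candidate list are searched for the
#' smallest absolute mass error. When several compositions fall within
#' `tolerance_da`, the assignment is flagged ambiguous and resolved by the
#' documented tie-break: fewer total adducts first, then candidate-list order.
#' Peaks with no composition within tolerance are reported as unassigned rows.
#'
#' @param peaks A `peak_list` from [pick_peaks()].
#' @param protein One-row tibble from [protein_species()].
#' @param candidates Tibble of lipid species ([lipid_species()] rows); order
#'   matters for the tie-break.
#' @param max_adducts Maximal total adduct count searched.
#' @param tolerance_da Mass tolerance in Da at the deconvolved (protein) mass
#'   scale.
#' @return Tibble of class `adduct_assignments`: one row per peak with
#'   `charge`, `mass_observed`, `mass_theoretical`, `mass_error_da`,
#'   `adduct_counts` (named-integer list column), `n_adducts`, `composition`,
#'   `intensity_share` (share of assigned area within its charge state),
#'   `ambiguous`, `assigned`.
#' @export
assign_adducts <- function(peaks, protein, candidates, max_adducts = 3,
                           tolerance_da = 2.5) {
  if (nrow(candidates) == 0) abort_param("`candidates` must be non-empty.")
  check_number(tolerance_da, "tolerance_da", strict_min = 0)
  check_number(max_adducts, "max_adducts", min = 0)
  if (nrow(peaks) == 0) {
    abort_input("`peaks` is empty; nothing to assign.")
  }

  grids <- rep(list(0:max_adducts), nrow(candidates))
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(combos) <- candidates$name
  combos <- combos[rowSums(combos) <= max_adducts, , drop = FALSE]
  comp_mass <- as.matrix(combos) %*% candidates$mass
  comp_total <- unname(rowSums(combos))
  # candidate-list order tie-break: earlier candidates preferred, encoded as
  # a lexicographic score favouring counts on early list positions
  comp_order_score <- as.vector(
    as.matrix(combos) %*% rev(seq_len(nrow(candidates)))
  )

  zs <- seq(protein$charge_min, protein$charge_max)
  M <- protein$average_mass

  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    best <- NULL
    for (z in zs) {
      m_obs <- peaks$mz[i] * z - z * PROTON_MASS
      err <- m_obs - M - comp_mass[, 1]
      within <- which(abs(err) <= tolerance_da)
      if (length(within) == 0) next
      ambiguous <- length(within) > 1
      # tie-break among in-tolerance compositions: fewer adducts, then
      # candidate order, then smallest error
      sel <- within[order(comp_total[within], -comp_order_score[within],
                          abs(err[within]))][1]
      cand <- list(z = z, sel = sel, err = err[sel], m_obs = m_obs,
                   ambiguous = ambiguous)
      if (is.null(best) || abs(cand$err) < abs(best$err)) best <- cand
    }
    if (is.null(best)) {
      return(tibble(
        mz = peaks$mz[i], intensity = peaks$intensity[i], area = peaks$area[i],
        charge = NA_integer_, mass_observed = NA_real_,
        mass_theoretical = NA_real_, mass_error_da = NA_real_,
        adduct_counts = list(NULL), n_adducts = NA_integer_,
        composition = NA_character_, ambiguous = FALSE, assigned = FALSE
      ))
    }
    counts <- setNames(as.integer(combos[best$sel, ]), candidates$name)
    nz <- counts[counts > 0]
    tibble(
      mz = peaks$mz[i], intensity = peaks$intensity[i], area = peaks$area[i],
      charge = as.integer(best$z), mass_observed = best$m_obs,
      mass_theoretical = M + comp_mass[best$sel, 1],
      mass_error_da = best$err,
      adduct_counts = list(counts),
      n_adducts = comp_total[best$sel],
      composition = if (length(nz) == 0) "apo" else
        paste(sprintf("%d x %s", nz, names(nz)), collapse = " + "),
      ambiguous = best$ambiguous, assigned = TRUE
    )
  }) |>
    list_rbind()

  rows <- rows |>
    group_by(.data$charge) |>
    mutate(intensity_share = ifelse(.data$assigned,
                                    .data$area / sum(.data$area[.data$assigned]),
                                    NA_real_)) |>
    ungroup()
  class(rows) <- unique(c("adduct_assignments", class(rows)))
  rows
}

#' Quantify bound-lipid fractions from adduct assignments
#'
#' Converts peak assignments into adduct-count distributions: within each
#' charge state, the intensity share of each composition; across charge
#' states, an aggregate weighted by each charge state's total assigned area
#' (the observed envelope weight). Returns the distribution per candidate
#' lipid and for `"any"` lipid (total adduct count).
#'
#' @param assignments An `adduct_assignments` tibble from [assign_adducts()].
#' @return Tibble with `lipid_class`, `n_bound`, `fraction`; per class the
#'   fractions sum to 1.
#' @export
quantify_bound_fractions <- function(assignments) {
  a <- filter(assignments, .data$assigned)
  if (nrow(a) == 0) {
    abort_input("No assigned peaks; cannot quantify bound fractions.")
  }
  z_weight <- a |>
    group_by(.data$charge) |>
    summarise(w = sum(.data$area), .groups = "drop") |>
    mutate(w = .data$w / sum(.data$w))
  a <- left_join(a, z_weight, by = "charge")

  lipid_names <- names(a$adduct_counts[[1]])
  per_lipid <- lapply(c(lipid_names, "any"), function(ln) {
    counts <- if (ln == "any") {
      a$n_adducts
    } else {
      map_dbl(a$adduct_counts, ~ .x[[ln]])
    }
    tibble(lipid_class = ln, n_bound = counts,
           contrib = a$intensity_share * a$w) |>
      group_by(.data$lipid_class, .data$n_bound) |>
      summarise(fraction = sum(.data$contrib), .groups = "drop")
  }) |>
    list_rbind()
  per_lipid |>
    group_by(.data$lipid_class) |>
    mutate(fraction = .data$fraction / sum(.data$fraction)) |>
    ungroup()
}

#' Intensity-weighted average charge state
#'
#' Shifts of the whole charge-state envelope (e.g. when micelle composition
#' changes) are summarised by the area-weighted mean charge of the assigned
#' peaks.
#'
#' @param assignments An `adduct_assignments` tibble.
#' @return Weighted mean charge (double).
#' @export
average_charge <- function(assignments) {
  a <- filter(assignments, .data$assigned)
  if (nrow(a) == 0 || sum(a$area) <= 0) {
    abort_input("No assigned intensity; cannot compute an average charge.")
  }
  weighted.mean(a$charge, a$area)
}

#' Unassigned peaks of an assignment table
#'
#' @param assignments An `adduct_assignments` tibble.
#' @return The unassigned rows (peaks with no composition within tolerance).
#' @export
unassigned_peaks <- function(assignments) {
  filter(assignments, !.data$assigned)
}
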