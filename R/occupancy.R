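#' Fractional site occupancy under lipid-detergent competition
#'
#' Single-site competitive-Langmuir occupancy: a lipid at fixed concentration
#' `L` competes with detergent for a binding site,
#' \deqn{\theta = \frac{L/K_L}{1 + L/K_L + D_{eff}/K_D},}
#' where \eqn{D_{eff} = \max(0, D - cmc)} is the detergent concentration in
#' excess of its critical micelle concentration (monomers below the CMC do not
#' form the micellar phase that dilutes and displaces bound lipids). A
#' `protected` site is unreachable by detergent and keeps its detergent-free
#' occupancy \eqn{(L/K_L)/(1 + L/K_L)} at any `D`.
#'
#' @param L Lipid concentration (any unit, consistent with `K_L`). Vectorised.
#' @param D Detergent concentration in % w/v (or molar, consistent with `K_D`
#'   and `cmc`). Vectorised.
#' @param K_L Lipid half-occupancy constant, same unit as `L`.
#' @param K_D Detergent half-displacement constant, same unit as `D`.
#' @param cmc Detergent critical micelle concentration, same unit as `D`.
#' @param protected Logical; if `TRUE` the site ignores detergent.
#' @return Occupancy fraction(s) in `[0, 1]`.
#' @examples
#' occupancy(L = 50, D = 0, K_L = 50, K_D = 0.1)        # 0.5
#' occupancy(L = 50, D = 0.2, K_L = 50, K_D = 0.1)      # 0.25
#' @export
occupancy <- function(L, D, K_L, K_D = Inf, cmc = 0, protected = FALSE) {
  if (any(L < 0) || any(D < 0)) {
    abort_param("Concentrations `L` and `D` must be non-negative.")
  }
  check_number(K_L, "K_L", strict_min = 0)
  if (!protected) check_number(K_D, "K_D", strict_min = 0)
  check_number(cmc, "cmc", min = 0)
  x <- L / K_L
  if (protected) {
    # recycle against D so vectorised calls keep their shape
    rep_len(x / (1 + x), max(length(x), length(D)))
  } else {
    d_eff <- pmax(0, D - cmc)
    x / (1 + x + d_eff / K_D)
  }
}

#' Fit the competitive displacement model to a detergent titration
#'
#' For each lipid class in a titration series, fits the occupancy model of
#' [occupancy()] by least squares (lipid concentration `L` fixed and known),
#' computes the retention index \eqn{R = \theta(\max D)/\theta(\min D)}, and
#' classifies the class as `"annular"` (exchangeable, `R <= r_threshold`) or
#' `"non-annular"` (detergent-resistant). A series whose bound fraction does
#' not respond to detergent at all (spread below `protected_tol` while binding
#' stays above `detection_threshold`) is flagged as a protected site instead of
#' letting `K_D` diverge.
#'
#' @param series Data frame with columns `detergent_conc` (% w/v),
#'   `lipid_class`, `bound_fraction` (observed fraction of protein carrying at
#'   least one lipid of that class, in `[0, 1]`).
#' @param lipid_conc Fixed lipid concentration used in the experiment (same
#'   unit as `K_L`; conventionally micromolar). Either a single number for all
#'   classes or a vector named by `lipid_class`.
#' @param cmc Detergent CMC in % w/v.
#' @param r_threshold Retention-index threshold for the annular call.
#' @param detection_threshold Intensity fraction below which bound lipid is
#'   considered undetectable.
#' @param protected_tol Maximal spread of `bound_fraction` across the titration
#'   for the protected-site flag.
#' @return A `competition_fit` object; `tidy()` returns the per-class parameter
#'   table, `glance()` a one-row summary, `autoplot()` the fit overlay.
#' @examples
#' d <- tibble::tibble(
#'   detergent_conc = seq(0, 0.5, 0.1), lipid_class = "PE",
#'   bound_fraction = occupancy(50, seq(0, 0.5, 0.1), 50, 0.1)
#' )
#' fit <- fit_competition(d, lipid_conc = 50, cmc = 0)
#' tidy(fit)
#' @export
fit_competition <- function(series, lipid_conc, cmc = 0, r_threshold = 0.5,
                            detection_threshold = 0.03, protected_tol = 0.05) {
  series <- as_tibble(series)
  required <- c("detergent_conc", "lipid_class", "bound_fraction")
  missing_cols <- setdiff(required, names(series))
  if (length(missing_cols) > 0) {
    abort_input(sprintf("`series` lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (any(series$bound_fraction < 0 | series$bound_fraction > 1)) {
    abort_input("`bound_fraction` must lie in [0, 1].")
  }
  if (!is.numeric(lipid_conc) || any(lipid_conc <= 0)) {
    abort_param("`lipid_conc` must be positive.")
  }
  if (length(lipid_conc) > 1 && is.null(names(lipid_conc))) {
    abort_param("A multi-class `lipid_conc` must be named by lipid class.")
  }
  check_number(cmc, "cmc", min = 0)
  conc_for <- function(cls) {
    if (length(lipid_conc) == 1 && is.null(names(lipid_conc))) {
      return(lipid_conc)
    }
    if (!cls %in% names(lipid_conc)) {
      abort_param(sprintf("`lipid_conc` has no entry for class '%s'.", cls))
    }
    lipid_conc[[cls]]
  }

  fits <- series |>
    group_by(.data$lipid_class) |>
    dplyr::group_map(function(df, key) {
      fit_one_class(df, key$lipid_class, conc_for(key$lipid_class), cmc,
                    detection_threshold, protected_tol)
    }) |>
    list_rbind() |>
    mutate(classification = ifelse(.data$retention_index <= r_threshold,
                                   "annular", "non-annular"))

  structure(
    list(fits = fits, data = series, lipid_conc = lipid_conc, cmc = cmc,
         r_threshold = r_threshold, detection_threshold = detection_threshold),
    class = "competition_fit"
  )
}

fit_one_class <- function(df, class_label, lipid_conc, cmc,
                          detection_threshold, protected_tol) {
  df <- arrange(df, .data$detergent_conc)
  n_conc <- dplyr::n_distinct(df$detergent_conc)
  if (n_conc < 2) {
    abort_input(sprintf(
      "Lipid class '%s': need >= 2 distinct detergent concentrations.",
      class_label))
  }
  theta_lo <- mean(df$bound_fraction[df$detergent_conc == min(df$detergent_conc)])
  theta_hi <- mean(df$bound_fraction[df$detergent_conc == max(df$detergent_conc)])
  retention <- if (theta_lo > 0) theta_hi / theta_lo else NA_real_

  spread <- diff(range(df$bound_fraction))
  flat <- spread < protected_tol && mean(df$bound_fraction) > detection_threshold
  if (flat) {
    theta0 <- mean(df$bound_fraction)
    # invert theta = x/(1+x) for the detergent-free lipid affinity
    K_L <- if (theta0 < 1) lipid_conc * (1 - theta0) / theta0 else NA_real_
    return(tibble(
      lipid_class = class_label, K_L = K_L, K_D = NA_real_, protected = TRUE,
      retention_index = min(retention, 1), residual_rmse = sd(df$bound_fraction),
      n_points = nrow(df)
    ))
  }

  if (n_conc < 3) {
    # retention index only; a free (K_L, K_D) fit needs >= 3 concentrations
    return(tibble(
      lipid_class = class_label, K_L = NA_real_, K_D = NA_real_,
      protected = FALSE, retention_index = retention,
      residual_rmse = NA_real_, n_points = nrow(df)
    ))
  }

  d_eff <- pmax(0, df$detergent_conc - cmc)
  theta0 <- max(theta_lo, 1e-3)
  start <- list(
    K_L = lipid_conc * max(1 - theta0, 1e-3) / theta0,
    K_D = max(median(d_eff[d_eff > 0]), 1e-4)
  )
  fit <- tryCatch(
    minpack.lm::nlsLM(
      bound_fraction ~ (lipid_conc / K_L) /
        (1 + lipid_conc / K_L + d_eff / K_D),
      data = cbind(df, d_eff = d_eff),
      start = start, lower = c(K_L = 1e-9, K_D = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(tibble(
      lipid_class = class_label, K_L = NA_real_, K_D = NA_real_,
      protected = FALSE, retention_index = retention,
      residual_rmse = NA_real_, n_points = nrow(df)
    ))
  }
  cf <- coef(fit)
  tibble(
    lipid_class = class_label, K_L = unname(cf["K_L"]), K_D = unname(cf["K_D"]),
    protected = FALSE, retention_index = retention,
    residual_rmse = sqrt(mean(resid(fit)^2)), n_points = nrow(df)
  )
}

#' Classify lipid classes as annular or non-annular
#'
#' Applies the retention-index rule of the competition model: a lipid class
#' whose bound fraction at the highest tested detergent concentration falls to
#' `r_threshold` or less of its low-detergent value is `"annular"`
#' (exchangeable); otherwise it is `"non-annular"` (detergent-resistant).
#'
#' @param fit A `competition_fit` from [fit_competition()].
#' @param r_threshold Retention-index threshold (default 0.5).
#' @return Tibble with `lipid_class`, `retention_index`, `protected`,
#'   `classification`.
#' @export
classify_exchange <- function(fit, r_threshold = 0.5) {
  if (!inherits(fit, "competition_fit")) {
    abort_param("`fit` must be a `competition_fit` object.")
  }
  fit$fits |>
    mutate(classification = ifelse(.data$retention_index <= r_threshold,
                                   "annular", "non-annular")) |>
    select("lipid_class", "retention_index", "protected", "classification")
}

#' Per-adduct-position retention across a titration
#'
#' Treats the j-th bound lipid of a class as a "position": its occupancy at a
#' given detergent concentration is \eqn{P(count \ge j)}. The retention index
#' of position j is that occupancy at the highest tested detergent
#' concentration divided by its value at the lowest. Positions with retention
#' above `r_threshold` are detergent-resistant (retained); this is how the
#' number of non-annular lipids per protein is counted.
#'
#' @param count_series Data frame with columns `detergent_conc`, `lipid_class`,
#'   `n_bound`, `fraction` (per-concentration adduct-count distributions, e.g.
#'   from [quantify_bound_fractions()] across a titration).
#' @param r_threshold Retention threshold (default 0.5).
#' @param detection_threshold Positions whose low-detergent occupancy is below
#'   this fraction are dropped (never present, so not classifiable).
#' @return Tibble with `lipid_class`, `position`, `theta_low_d`, `theta_high_d`,
#'   `retention_index`, `retained`.
#' @export
retention_by_position <- function(count_series, r_threshold = 0.5,
                                  detection_threshold = 0.03) {
  count_series <- as_tibble(count_series)
  required <- c("detergent_conc", "lipid_class", "n_bound", "fraction")
  missing_cols <- setdiff(required, names(count_series))
  if (length(missing_cols) > 0) {
    abort_input(sprintf("`count_series` lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  d_lo <- min(count_series$detergent_conc)
  d_hi <- max(count_series$detergent_conc)
  if (d_lo == d_hi) {
    abort_input("Need at least two distinct detergent concentrations.")
  }
  max_n <- max(count_series$n_bound)
  if (max_n < 1) {
    return(tibble(lipid_class = character(), position = integer(),
                  theta_low_d = double(), theta_high_d = double(),
                  retention_index = double(), retained = logical()))
  }
  tidyr::expand_grid(
    lipid_class = unique(count_series$lipid_class),
    position = seq_len(max_n)
  ) |>
    pmap(function(lipid_class, position) {
      at <- function(dc) {
        rows <- count_series$lipid_class == lipid_class &
          count_series$detergent_conc == dc & count_series$n_bound >= position
        sum(count_series$fraction[rows])
      }
      tibble(lipid_class = lipid_class, position = position,
             theta_low_d = at(d_lo), theta_high_d = at(d_hi))
    }) |>
    list_rbind() |>
    filter(.data$theta_low_d >= detection_threshold) |>
    mutate(
      retention_index = .data$theta_high_d / .data$theta_low_d,
      retained = .data$retention_index > r_threshold
    )
}

#' @export
tidy.competition_fit <- function(x, ...) x$fits

#' @export
glance.competition_fit <- function(x, ...) {
  tibble(
    n_classes = nrow(x$fits),
    n_annular = sum(x$fits$classification == "annular"),
    n_non_annular = sum(x$fits$classification == "non-annular"),
    cmc = x$cmc, r_threshold = x$r_threshold
  )
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("Competition fit: %d lipid class(es), cmc = %g %%w/v\n",
              nrow(x$fits), x$cmc))
  print(x$fits)
  invisible(x)
}
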