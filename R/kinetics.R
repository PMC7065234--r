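#' Binarize a distance trace with a dual-cutoff (hysteresis) scheme
#'
#' A lipid is declared bound when its site distance first drops below `d_on`
#' and stays bound until the distance exceeds `d_off` (> `d_on`). The
#' hysteresis band suppresses spurious unbinding from fast "rattling"
#' excursions between the two cutoffs. Binary traces pass through unchanged.
#'
#' @param trace A `contact_trace` with a `distance_nm` column (per site), or an
#'   already-binary trace with a `state` column.
#' @param d_on Binding cutoff in nm.
#' @param d_off Unbinding cutoff in nm; must be >= `d_on`.
#' @return The trace with a binary `state` column (distance column dropped).
#' @export
binarize_contacts <- function(trace, d_on = 0.55, d_off = 1.0) {
  if ("state" %in% names(trace)) {
    return(trace)
  }
  if (!"distance_nm" %in% names(trace)) {
    abort_input("`trace` needs a `distance_nm` (or `state`) column.")
  }
  check_number(d_on, "d_on", strict_min = 0)
  if (d_off < d_on) {
    abort_param("`d_off` must be >= `d_on` (hysteresis band).")
  }
  dt <- trace_dt(trace)
  out <- trace |>
    group_by(.data$site_id) |>
    arrange(.data$frame, .by_group = TRUE) |>
    mutate(state = {
      s <- ifelse(.data$distance_nm < d_on, 1L,
                  ifelse(.data$distance_nm > d_off, 0L, NA_integer_))
      s <- vctrs::vec_fill_missing(s, direction = "down")
      s[is.na(s)] <- 0L # leading in-band frames: not yet entered
      s
    }) |>
    ungroup() |>
    select(-"distance_nm")
  new_contact_trace(out, dt_ns = dt)
}

#' Extract dwell times from a binary contact trace
#'
#' Finds maximal bound runs per site, merges interior unbound gaps no longer
#' than `gap_tolerance_ns` into the surrounding dwell (absorbing brief
#' detachments that survive binarization), and flags dwells touching either
#' trace end as censored: their true duration is only known to be at least the
#' observed one.
#'
#' @param trace A binary `contact_trace` (see [binarize_contacts()]).
#' @param gap_tolerance_ns Maximal unbound gap (ns) merged into a dwell.
#' @return A `dwell_times` tibble: `site_id`, `duration_ns`, `censored`.
#' @export
extract_dwells <- function(trace, gap_tolerance_ns = 5) {
  check_number(gap_tolerance_ns, "gap_tolerance_ns", min = 0)
  if (!"state" %in% names(trace)) {
    abort_input("`trace` must be binary; run binarize_contacts() first.")
  }
  if (nrow(trace) == 0) {
    return(new_dwell_times(tibble(site_id = character(), duration_ns = double(),
                                  censored = logical())))
  }
  dt <- trace_dt(trace)
  trace |>
    group_by(.data$site_id) |>
    arrange(.data$frame, .by_group = TRUE) |>
    dplyr::group_map(function(df, key) {
      s <- df$state
      r <- rle(s)
      # merge interior unbound gaps <= tolerance that are flanked by bound runs
      if (length(r$lengths) > 2) {
        interior <- seq(2, length(r$lengths) - 1)
        to_merge <- interior[r$values[interior] == 0 &
                               r$lengths[interior] * dt <= gap_tolerance_ns]
        if (length(to_merge) > 0) {
          r$values[to_merge] <- 1L
          s <- inverse.rle(r)
          r <- rle(s)
        }
      }
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      bound <- which(r$values == 1L)
      if (length(bound) == 0) {
        return(tibble(site_id = character(), duration_ns = double(),
                      censored = logical()))
      }
      tibble(
        site_id = key$site_id,
        duration_ns = r$lengths[bound] * dt,
        censored = starts[bound] == 1L | ends[bound] == length(s)
      )
    }) |>
    list_rbind() |>
    new_dwell_times()
}

#' Empirical dwell-time survival curve
#'
#' Kaplan-Meier survival of dwell durations: S(t) is the fraction of binding
#' events lasting at least t, with censored dwells contributing at-risk time
#' up to their observed length. Computed per site.
#'
#' @param dwells A `dwell_times` tibble.
#' @return Tibble of class `survival_curves` with `site_id`, `time_ns`,
#'   `survival`; each site's curve starts at S(0) = 1.
#' @export
survival_curve <- function(dwells) {
  if (nrow(dwells) == 0) abort_input("`dwells` is empty.")
  dwells |>
    group_by(.data$site_id) |>
    dplyr::group_map(function(df, key) {
      if (!any(!df$censored)) {
        abort_input(sprintf(
          "Site '%s': every dwell is censored; record longer traces before estimating survival.",
          key$site_id))
      }
      sf <- survival::survfit(
        survival::Surv(df$duration_ns, !df$censored) ~ 1
      )
      tibble(site_id = key$site_id,
             time_ns = c(0, sf$time),
             survival = c(1, sf$surv))
    }) |>
    list_rbind() |>
    (\(x) { class(x) <- unique(c("survival_curves", class(x))); x })()
}

#' Estimate k_off by censored exponential maximum likelihood
#'
#' For single-exponential dwells the censoring-aware MLE is
#' \deqn{\hat k_{off} = n_{uncensored} / \sum_i t_i} over all durations,
#' censored included (censored dwells contribute observation time but no
#' event). Reported in inverse microseconds. Uncertainty by percentile
#' bootstrap over dwell resampling. Requires at least 10 uncensored dwells per
#' site.
#'
#' @param dwells A `dwell_times` tibble (one or more sites).
#' @param n_boot Bootstrap replicates (0 skips the confidence interval).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level of the percentile interval.
#' @return Tibble of class `koff_estimates`, one row per site: `site_id`,
#'   `k_off`, `ci_low`, `ci_high` (inverse microseconds), `n_events`,
#'   `n_censored`, `mean_dwell_ns`, `method`.
#' @examples
#' d <- simulate_dwell_times(10, 2000, seed = 1)
#' estimate_koff(d, n_boot = 200, seed = 2)
#' @export
estimate_koff <- function(dwells, n_boot = 1000, seed = NULL,
                          conf_level = 0.95) {
  check_number(n_boot, "n_boot", min = 0)
  if (nrow(dwells) == 0) abort_input("`dwells` is empty.")
  if (any(dwells$duration_ns <= 0)) {
    abort_input("Dwell durations must be positive.")
  }
  alpha <- (1 - conf_level) / 2

  with_seed(seed, {
    dwells |>
      group_by(.data$site_id) |>
      dplyr::group_map(function(df, key) {
        n_unc <- sum(!df$censored)
        if (n_unc < 10) {
          abort_input(sprintf(
            "Site '%s': only %d uncensored dwells (>= 10 needed for a stable estimate).",
            key$site_id, n_unc))
        }
        khat <- 1000 * n_unc / sum(df$duration_ns)
        ci <- c(NA_real_, NA_real_)
        if (n_boot > 0) {
          boot <- vapply(seq_len(n_boot), function(b) {
            idx <- sample.int(nrow(df), replace = TRUE)
            nb <- sum(!df$censored[idx])
            if (nb == 0) NA_real_ else 1000 * nb / sum(df$duration_ns[idx])
          }, numeric(1))
          ci <- quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
        }
        tibble(
          site_id = key$site_id, k_off = khat,
          ci_low = ci[1], ci_high = ci[2],
          n_events = nrow(df), n_censored = sum(df$censored),
          mean_dwell_ns = 1000 / khat, method = "mle_censored"
        )
      }) |>
      list_rbind() |>
      (\(x) { class(x) <- unique(c("koff_estimates", class(x))); x })()
  })
}

#' k_off from the log-survival slope (cross-check method)
#'
#' Fits a straight line to log S(t) of the empirical survival curve; for
#' single-exponential dwells the negative slope is k_off. Used as an
#' independent cross-check of [estimate_koff()], not as the primary estimator.
#'
#' @param curve A `survival_curves` tibble from [survival_curve()].
#' @param s_floor Points with survival below this value are dropped (the log
#'   tail is noise-dominated).
#' @return Tibble with `site_id`, `k_off` (inverse microseconds), `method`.
#' @export
koff_from_survival <- function(curve, s_floor = 0.02) {
  curve |>
    filter(.data$survival > s_floor) |>
    group_by(.data$site_id) |>
    summarise(
      k_off = -1000 * unname(coef(lm(log(.data$survival) ~ .data$time_ns))[2]),
      method = "curve_fit", .groups = "drop"
    )
}

#' Order binding sites by k_off and compute fold ratios
#'
#' Sorts site estimates ascending by k_off (slowest, i.e. most
#' detergent-resistant, first) and reports every pairwise fold ratio
#' fast/slow, flagging pairs whose bootstrap confidence intervals overlap
#' (their separation is not resolved).
#'
#' @param estimates A `koff_estimates` tibble with >= 2 sites.
#' @return List of class `site_comparison`: `sites` (sorted estimates) and
#'   `pairs` (`site_slow`, `site_fast`, `fold`, `ci_overlap`).
#' @export
compare_sites <- function(estimates) {
  if (nrow(estimates) < 2) {
    abort_param("Need at least 2 site estimates to compare.")
  }
  sites <- arrange(estimates, .data$k_off)
  idx <- utils::combn(nrow(sites), 2)
  pairs <- lapply(seq_len(ncol(idx)), function(j) {
    s <- idx[1, j]; f <- idx[2, j]
    overlap <- !is.na(sites$ci_low[s]) && !is.na(sites$ci_low[f]) &&
      sites$ci_low[f] <= sites$ci_high[s]
    tibble(
      site_slow = sites$site_id[s], site_fast = sites$site_id[f],
      k_off_slow = sites$k_off[s], k_off_fast = sites$k_off[f],
      fold = sites$k_off[f] / sites$k_off[s],
      ci_overlap = overlap
    )
  }) |>
    list_rbind()
  structure(list(sites = sites, pairs = pairs), class = "site_comparison")
}

#' Fraction of frames spent bound
#'
#' @param trace A binary `contact_trace` (one or more sites).
#' @return Tibble with `site_id`, `occupancy`.
#' @export
site_occupancy <- function(trace) {
  if (nrow(trace) == 0) abort_input("`trace` is empty.")
  if (!"state" %in% names(trace)) {
    abort_input("`trace` must be binary; run binarize_contacts() first.")
  }
  trace |>
    group_by(.data$site_id) |>
    summarise(occupancy = mean(.data$state), .groups = "drop")
}

#' Per-state residue contact frequencies
#'
#' For each (conformational state, residue) pair, the fraction of frames in
#' which the substrate-residue distance is below `d_contact` — a single-cutoff
#' frequency measure of accessibility, not a kinetic quantity. Pairs absent
#' from the input are absent from the output (not reported as zero).
#'
#' @param contacts Data frame with columns `state`, `residue`, `frame`, and
#'   `distance_nm` (or a binary `contact` column).
#' @param d_contact Contact cutoff in nm.
#' @return Tibble of class `accessibility_profile`: `state`, `residue`,
#'   `contact_frequency`, `n_frames`.
#' @export
contact_frequency <- function(contacts, d_contact = 0.7) {
  contacts <- as_tibble(contacts)
  required <- c("state", "residue")
  missing_cols <- setdiff(required, names(contacts))
  if (length(missing_cols) > 0) {
    abort_input(sprintf("`contacts` lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if ("distance_nm" %in% names(contacts)) {
    check_number(d_contact, "d_contact", strict_min = 0)
    contacts$contact <- contacts$distance_nm < d_contact
  } else if (!"contact" %in% names(contacts)) {
    abort_input("`contacts` needs a `distance_nm` or `contact` column.")
  }
  out <- contacts |>
    group_by(.data$state, .data$residue) |>
    summarise(contact_frequency = mean(.data$contact), n_frames = dplyr::n(),
              .groups = "drop")
  class(out) <- unique(c("accessibility_profile", class(out)))
  out
}

#' @export
tidy.site_comparison <- function(x, ...) x$pairs

#' @export
glance.site_comparison <- function(x, ...) {
  tibble(
    n_sites = nrow(x$sites),
    slowest_site = x$sites$site_id[1],
    k_off_min = min(x$sites$k_off),
    k_off_max = max(x$sites$k_off),
    max_fold = max(x$pairs$fold)
  )
}

#' @export
print.site_comparison <- function(x, ...) {
  cat("Site comparison (ascending k_off, inverse microseconds):\n")
  print(x$sites)
  cat("\nPairwise fold ratios (fast / slow):\n")
  print(x$pairs)
  invisible(x)
}
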