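#' Simulate exponential lipid dwell times
#'
#' Draws i.i.d. binding-event durations from the single-exponential dwell
#' model: durations in ns with rate `k_off` in inverse microseconds, so the
#' theoretical mean dwell is `1000 / k_off` ns.
#'
#' @param k_off Dissociation rate in inverse microseconds; must be > 0.
#' @param n_events Number of binding events to draw.
#' @param seed Integer seed for reproducibility (optional).
#' @param site_id Site label attached to every event.
#' @return A tibble of class `dwell_times` with columns `site_id`,
#'   `duration_ns`, `censored` (all `FALSE`: simulated events are complete).
#' @examples
#' d <- simulate_dwell_times(k_off = 10, n_events = 1000, seed = 1)
#' mean(d$duration_ns) # ~100 ns
#' @export
simulate_dwell_times <- function(k_off, n_events, seed = NULL,
                                 site_id = "site") {
  check_number(k_off, "k_off", strict_min = 0)
  check_number(n_events, "n_events", min = 1)
  durations <- with_seed(seed, rexp(n_events, rate = k_off / 1000))
  new_dwell_times(tibble(
    site_id = site_id,
    duration_ns = durations,
    censored = FALSE
  ))
}

new_dwell_times <- function(x) {
  class(x) <- unique(c("dwell_times", class(x)))
  x
}

#' Simulate a two-state binding/contact trace
#'
#' Generates a continuous-time two-state (telegraph) process with exponential
#' unbound periods at rate `k_on` and bound periods at rate `k_off` (both in
#' inverse microseconds), discretised to frames of `dt_ns`. During bound
#' periods, brief spurious detachments ("rattling") can be injected as a
#' Poisson process at `rattle_rate` with exponential gap lengths of mean
#' `rattle_mean` ns; these emulate the fast excursions that a dual-cutoff /
#' gap-merge dwell extraction must absorb. With `rattle_rate = 0` the long-run
#' bound fraction converges to `k_on / (k_on + k_off)`.
#'
#' @param k_on Binding rate, inverse microseconds (0 gives an all-unbound trace).
#' @param k_off Unbinding rate, inverse microseconds; must be > 0.
#' @param duration_ns Total trace length in ns (>= 100 frames).
#' @param dt_ns Frame spacing in ns.
#' @param rattle_rate Rattling rate inside bound periods, inverse microseconds.
#' @param rattle_mean Mean rattle-gap length, ns.
#' @param seed Integer seed (optional).
#' @param site_id Site label.
#' @param output `"state"` for a binary trace, `"distance"` for synthetic
#'   site-lipid distances (nm): bound frames near `d_bound`, unbound frames
#'   near `d_unbound`, with Gaussian jitter `distance_sd`.
#' @param d_bound,d_unbound,distance_sd Distance-trace parameters (nm).
#' @return A tibble of class `contact_trace` with columns `frame`, `time_ns`,
#'   `site_id` and `state` (0/1) or `distance_nm`; frame spacing is stored in
#'   attribute `dt_ns`.
#' @export
simulate_contact_trace <- function(k_on, k_off, duration_ns, dt_ns = 1,
                                   rattle_rate = 0, rattle_mean = 2,
                                   seed = NULL, site_id = "site",
                                   output = c("state", "distance"),
                                   d_bound = 0.45, d_unbound = 1.4,
                                   distance_sd = 0.05) {
  output <- match.arg(output)
  check_number(k_on, "k_on", min = 0)
  check_number(k_off, "k_off", strict_min = 0)
  check_number(dt_ns, "dt_ns", strict_min = 0)
  check_number(duration_ns, "duration_ns", strict_min = 0)
  check_number(rattle_rate, "rattle_rate", min = 0)
  check_number(rattle_mean, "rattle_mean", strict_min = 0)
  if (duration_ns < 100 * dt_ns) {
    abort_param("`duration_ns` must cover at least 100 frames.")
  }
  mean_dwell <- 1000 / k_off
  if (dt_ns >= mean_dwell / 2) {
    warn(sprintf(
      "Frame spacing dt = %g ns is coarse relative to the mean dwell %g ns; dwell durations will be biased.",
      dt_ns, mean_dwell))
  }

  with_seed(seed, {
    frame_times <- seq(0, duration_ns - dt_ns, by = dt_ns)
    n_frames <- length(frame_times)

    if (k_on == 0) {
      state <- rep(0L, n_frames)
    } else {
      r_on <- k_on / 1000   # per ns, unbound -> bound
      r_off <- k_off / 1000 # per ns, bound -> unbound
      p_bound <- k_on / (k_on + k_off)
      start_bound <- rbinom(1, 1, p_bound) == 1

      # alternating exponential sojourns until the trace is covered
      mean_cycle <- 1 / r_on + 1 / r_off
      n_cycles <- ceiling(duration_ns / mean_cycle * 1.5) + 20
      repeat {
        bound_seg <- rexp(n_cycles, r_off)
        unbound_seg <- rexp(n_cycles, r_on)
        seg <- as.vector(rbind(
          if (start_bound) bound_seg else unbound_seg,
          if (start_bound) unbound_seg else bound_seg
        ))
        if (sum(seg) >= duration_ns) break
        n_cycles <- n_cycles * 2
      }
      ends <- cumsum(seg)
      seg_state <- rep(
        if (start_bound) c(1L, 0L) else c(0L, 1L),
        length.out = length(seg)
      )
      idx <- findInterval(frame_times, ends) + 1L
      state <- seg_state[idx]

      if (rattle_rate > 0) {
        starts <- c(0, ends[-length(ends)])
        bound_i <- which(seg_state == 1L & starts < duration_ns)
        for (i in bound_i) {
          len <- min(ends[i], duration_ns) - starts[i]
          n_gap <- rpois(1, rattle_rate / 1000 * len)
          if (n_gap > 0) {
            gap_start <- starts[i] + runif(n_gap) * len
            gap_len <- rexp(n_gap, 1 / rattle_mean)
            gap_end <- pmin(gap_start + gap_len, ends[i])
            for (g in seq_len(n_gap)) {
              hit <- frame_times >= gap_start[g] & frame_times < gap_end[g]
              state[hit] <- 0L
            }
          }
        }
      }
    }

    values <- if (output == "state") {
      tibble(state = state)
    } else {
      centre <- ifelse(state == 1L, d_bound, d_unbound)
      tibble(distance_nm = pmax(0, rnorm(n_frames, centre, distance_sd)))
    }

    out <- tibble(
      frame = seq_len(n_frames) - 1L,
      time_ns = frame_times,
      site_id = site_id
    )
    out <- dplyr::bind_cols(out, values)
    new_contact_trace(out, dt_ns = dt_ns)
  })
}

new_contact_trace <- function(x, dt_ns) {
  attr(x, "dt_ns") <- dt_ns
  class(x) <- unique(c("contact_trace", class(x)))
  x
}

# Frame spacing of a trace: stored attribute, else inferred per site.
trace_dt <- function(trace) {
  dt <- attr(trace, "dt_ns")
  if (!is.null(dt)) return(dt)
  if (!"time_ns" %in% names(trace)) {
    abort_input("Trace has no `dt_ns` attribute and no `time_ns` column.")
  }
  dts <- trace |>
    group_by(.data$site_id) |>
    summarise(dt = {
      d <- diff(sort(unique(.data$time_ns)))
      if (length(d) == 0) NA_real_ else d[1]
    }, uniform = {
      d <- diff(sort(unique(.data$time_ns)))
      length(d) == 0 || max(abs(d - d[1])) < 1e-9 * d[1] + 1e-12
    })
  bad <- dts$site_id[!dts$uniform]
  if (length(bad) > 0) {
    abort_input(sprintf("Non-uniform frame spacing for site(s): %s",
                        paste(bad, collapse = ", ")))
  }
  dt <- unique(round(dts$dt, 12))
  if (length(dt) != 1) {
    abort_input("Sites have differing frame spacings; split them first.")
  }
  dt
}
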